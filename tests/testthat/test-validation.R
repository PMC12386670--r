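params <- species_params()
cohorts <- build_cohorts(params)

test_that("records pair with the events their life stage maps to", {
  ev <- run_annual_cycle(const_grid(25, extent = c(0, 2, 0, 2)), params, cohorts)
  rec <- data.frame(lon = 0.5, lat = 1.5, date = "2023-07-01",
                    label = c("early_nymph", "late_nymph", "adult",
                              "oviposition", "egg_G1", "egg_OW"))
  out <- predict_at_records(ev, rec)
  expect_false(any(out$skipped))
  pick <- function(e, f) f(ev$doy[[e]][1, 1, ])
  expect_equal(out$doy_pred[1], pick("egg_hatch", min))
  expect_equal(out$doy_pred[2], pick("nymphs_halfway", min))
  expect_equal(out$doy_pred[3], pick("adult_emergence", min))
  expect_equal(out$doy_pred[4], pick("oviposition", min))
  expect_equal(out$doy_pred[5], pick("diapausing_egg", min))
  # overwintered eggs compare against the *latest* cohort's hatch
  expect_equal(out$doy_pred[6], ev$doy$egg_hatch[1, 1, which.max(ev$requirements)])
  expect_equal(out$doy_obs[1], 182)  # 2023-07-01
})

test_that("records off the grid or without the event are skipped with a reason", {
  ev_cold <- run_annual_cycle(const_grid(12.5, extent = c(0, 2, 0, 2)),
                              params, cohorts)
  rec <- data.frame(lon = c(0.5, 10), lat = c(0.5, 0.5),
                    date = "2023-08-01", label = "adult")
  expect_message(out <- predict_at_records(ev_cold, rec), "skipped")
  expect_true(all(out$skipped))
  expect_equal(out$skip_reason, c("event does not occur", "outside extent"))
  expect_error(predict_at_records(ev_cold,
                                  transform(rec, label = "larva")),
               "unknown observation label")
})

test_that("event fit summaries compute MAE, bias, and interval lengths", {
  obs <- c(100, 120, 140)
  s <- summarize_event_fit(obs + c(-2, 0, 2), obs)
  expect_equal(s$mae, 4 / 3)
  expect_equal(s$bias, 0)
  expect_equal(s$range_min, -2)
  expect_equal(s$range_max, 2)
  # perfect predictions: identity regression
  obs2 <- c(90, 110, 130, 150)
  s2 <- summarize_event_fit(obs2, obs2)
  expect_equal(s2$mae, 0)
  expect_equal(s2$slope, 1)
  expect_equal(s2$intercept, 0, tolerance = 1e-10)
  # prediction intervals are wider than confidence intervals
  set.seed(8)
  obs3 <- seq(80, 160, length.out = 20)
  pred3 <- obs3 + rnorm(20, 0, 5)
  s3 <- summarize_event_fit(pred3, obs3)
  expect_gt(s3$pi_length, s3$ci_length)
  expect_gte(s3$mae, abs(s3$bias))
  # order invariance
  idx <- sample(20)
  expect_equal(summarize_event_fit(pred3[idx], obs3[idx]), s3)
  expect_error(summarize_event_fit(NA, NA), "no complete")
})

test_that("prediction intervals cover ~95% of new observations", {
  set.seed(12)
  cover <- replicate(300, {
    obs <- runif(15, 80, 200)
    pred <- obs + rnorm(15, 0, 6)
    fit <- lm(pred ~ obs)
    new_obs <- runif(1, 80, 200)
    new_pred <- new_obs + rnorm(1, 0, 6)
    pi <- predict(fit, newdata = data.frame(obs = new_obs),
                  interval = "prediction")
    pi[, "lwr"] <= new_pred && new_pred <= pi[, "upr"]
  })
  expect_equal(mean(cover), 0.95, tolerance = 0.035)
})

test_that("one-sided Wilcoxon p-values match exact enumeration", {
  # n = 5, all differences negative, testing pred-before-obs: p = 1/32
  r <- one_sided_encounter_test(c(100, 101, 102, 103, 104),
                                c(103, 105, 107, 109, 111),
                                "pred_before_obs")
  expect_equal(r$p_value, 1 / 32)
  expect_equal(r$pct_direction, 100)
  # n = 1 in the stated direction: p = 0.5
  expect_equal(one_sided_encounter_test(10, 12, "pred_before_obs")$p_value, 0.5)
  # symmetric differences carry no directional signal
  expect_gte(one_sided_encounter_test(c(95, 105), c(100, 100),
                                      "pred_before_obs")$p_value, 0.5)
  # randomized sign patterns against the 2^n enumeration oracle
  set.seed(17)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    d <- sample(1:50, n) * sample(c(-1, 1), n, replace = TRUE)
    for (dir in c("pred_before_obs", "pred_after_obs")) {
      alt <- if (dir == "pred_before_obs") "less" else "greater"
      expect_equal(one_sided_encounter_test(d, rep(0, n), dir)$p_value,
                   wilcoxon_exact_enum(d, alt))
    }
  }
})

test_that("zero differences are dropped; all-zero pairs warn with p = 1", {
  expect_warning(r <- one_sided_encounter_test(c(5, 5), c(5, 5),
                                               "pred_before_obs"),
                 "zero")
  expect_equal(r$p_value, 1)
  # zeros dropped before ranking: same p as without them
  d <- c(-4, -7, -1, -9, -3)
  with_zeros <- one_sided_encounter_test(c(d, 0, 0), rep(0, 7), "pred_before_obs")
  expect_equal(with_zeros$p_value, 1 / 32)
  expect_equal(with_zeros$n, 5L)
})

test_that("the large-sample branch approximates the exact test", {
  set.seed(23)
  d <- c(-(1:30), 5.5)  # 31 non-zero diffs forces the normal approximation
  r <- one_sided_encounter_test(d, rep(0, 31), "pred_before_obs")
  expect_lt(r$p_value, 1e-4)
})

test_that("stage concordance compares model and observed stages in order", {
  g <- const_grid(25, nrow = 1, ncol = 1)
  traj <- cell_trajectory(g, params, 1, 1, cohorts)
  # day 5: no cohort has hatched; an overwintered egg is the same stage
  expect_equal(stage_concordance(traj, "2023-01-05", "egg_OW", cohorts, params),
               "same")
  # late season: model is past the nymph stages; late nymph reads older
  expect_equal(stage_concordance(traj, "2023-12-01", "late_nymph",
                                 cohorts, params),
               "model_older")
  # find a date where the modal cohort is an early nymph
  d <- traj[traj$cohort == 4 & traj$stage == "L" & traj$within_stage_dd < 442, ]
  expect_equal(stage_concordance(traj, d$date[ceiling(nrow(d) / 2)],
                                 "early_nymph", cohorts, params,
                                 mode = "earliest_cohort") %in%
                 c("same", "model_older"), TRUE)
  expect_error(stage_concordance(traj, "2023-06-01", "instar_9", cohorts,
                                 params), "unknown stage")
  expect_error(stage_concordance(traj, "2024-06-01", "adult", cohorts, params),
               "not in the trajectory")
})

test_that("encounters sampled from the model's own trajectory are concordant", {
  spec <- synthetic_climate_spec(nrow = 2, ncol = 2, noise_sd = 2,
                                 base_temp = 15, seed = 41)
  g <- generate_synthetic_climate(spec, 2023)
  traj <- cell_trajectory(g, params, 1, 1, cohorts)
  halfway <- params$event_dd[["L"]]
  scale_names <- c("egg_OW", "early_nymph", "late_nymph", "adult", "egg_G1")
  # independent re-derivation of the weighted modal stage from the
  # trajectory table itself
  modal_label <- function(date) {
    day <- traj[traj$date == date, ]
    sc <- ifelse(day$stage == "OE", 1L,
          ifelse(day$stage == "L" & day$within_stage_dd < halfway, 2L,
          ifelse(day$stage == "L", 3L,
          ifelse(day$stage %in% c("P", "A"), 4L, 5L))))
    w <- tapply(cohorts$weight[day$cohort], sc, sum)
    scale_names[as.integer(names(w)[which.max(w)])]
  }
  dates <- as.Date("2023-01-01") + seq(10, 350, by = 20)
  for (dt in format(dates)) {
    expect_equal(stage_concordance(traj, dt, modal_label(as.Date(dt)),
                                   cohorts, params), "same")
  }
})
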