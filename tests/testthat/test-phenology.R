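p <- species_params()

test_that("cohort builder matches the truncated-normal discretization", {
  co <- build_cohorts(p)
  expect_equal(nrow(co), 7)
  expect_true(all(co$requirement >= 135 & co$requirement <= 360))
  expect_true(all(diff(co$requirement) > 0))
  expect_equal(sum(co$weight), 1, tolerance = 1e-12)
  # equal-width bins with midpoint requirements
  width <- (360 - 135) / 7
  expect_equal(co$requirement, 135 + width * (seq_len(7) - 0.5))
  # weights against numeric integration of the truncated normal density
  total <- stats::integrate(stats::dnorm, 135, 360, mean = 190,
                            sd = sqrt(15000))$value
  for (k in 1:7) {
    mass <- stats::integrate(stats::dnorm, 135 + (k - 1) * width,
                             135 + k * width, mean = 190,
                             sd = sqrt(15000))$value
    expect_equal(co$weight[k], mass / total, tolerance = 1e-6)
  }
})

test_that("cohort builder rejects invalid configurations", {
  expect_error(species_params(xdist1 = 360, xdist2 = 135), "xdist1")
  bad <- p
  bad$ncohorts <- 0L
  expect_error(build_cohorts(bad), "ncohorts")
  bad2 <- p
  bad2$xdist2 <- bad2$xdist1
  expect_error(build_cohorts(bad2), "exceed")
})

test_that("constant 25 C: first cohort hatches on day 11; all events fire in order", {
  co <- build_cohorts(p)
  ev <- run_annual_cycle(const_grid(25), p, co)
  # daily DD = 15; first requirement 135 + (225/7)/2 = 151.07 -> day 11
  expect_equal(aggregate_cohort_events(ev, "egg_hatch", "earliest")[1, 1], 11)
  # every later cohort hatches no earlier, and per-cohort events are ordered
  hatch <- ev$doy$egg_hatch[1, 1, ]
  expect_true(all(diff(hatch) >= 0))
  for (k in 1:7) {
    doys <- vapply(EVENTS, function(e) ev$doy[[e]][1, 1, k], 0)
    expect_true(all(diff(doys) >= 0))
  }
})

test_that("below-threshold climate yields no events anywhere", {
  ev <- run_annual_cycle(const_grid(9), p)
  for (e in EVENTS)
    expect_true(all(is.na(aggregate_cohort_events(ev, e, "earliest"))))
})

test_that("insufficient annual accumulation blocks adult emergence", {
  # constant 12.5 C: 2.5 DD/day, 912.5 DD/year < min requirement + larval 890
  ev <- run_annual_cycle(const_grid(12.5), p)
  expect_false(all(is.na(aggregate_cohort_events(ev, "egg_hatch", "earliest"))))
  for (e in c("adult_emergence", "oviposition", "diapausing_egg"))
    expect_true(all(is.na(aggregate_cohort_events(ev, e, "earliest"))))
})

test_that("single cohort at the distribution mean follows the closed form", {
  co <- one_cohort(p$distro_mean)
  ev <- run_annual_cycle(const_grid(25), p, co)
  expect_equal(ev$doy$egg_hatch[1, 1, 1], ceiling(190 / 15))
  # single cohort: earliest equals the weighted mean for every event
  for (e in EVENTS)
    expect_equal(aggregate_cohort_events(ev, e, "earliest"),
                 aggregate_cohort_events(ev, e, "weighted_mean"))
})

test_that("transition-day excess degree-days carry into the next stage", {
  co <- one_cohort(151)
  traj <- cell_trajectory(const_grid(25, nrow = 1, ncol = 1), p, 1, 1, co)
  # hatch on day 11 with 15 * 11 - 151 = 14 DD carried into the larval stage
  d11 <- traj[traj$doy == 11, ]
  expect_equal(d11$stage, "L")
  expect_equal(d11$within_stage_dd, 15 * 11 - 151)
  expect_equal(traj$stage[traj$doy == 10], "OE")
})

test_that("warmer constant climates never delay any event", {
  ev1 <- run_annual_cycle(const_grid(20), p)
  ev2 <- run_annual_cycle(const_grid(25), p)
  for (e in EVENTS) {
    d1 <- ev1$doy[[e]][1, 1, ]
    d2 <- ev2$doy[[e]][1, 1, ]
    both <- !is.na(d1) & !is.na(d2)
    expect_true(all(d2[both] <= d1[both]))
    expect_false(any(is.na(d2) & !is.na(d1)))  # warmer cannot lose an event
  }
})

test_that("event ordering holds on a noisy synthetic grid", {
  spec <- synthetic_climate_spec(nrow = 5, ncol = 5, noise_sd = 3,
                                 base_temp = 16, seed = 21)
  ev <- run_annual_cycle(generate_synthetic_climate(spec, 2023), p)
  for (k in seq_along(ev$weights)) {
    prev <- NULL
    for (e in EVENTS) {
      cur <- ev$doy[[e]][, , k]
      if (!is.null(prev)) {
        both <- !is.na(prev) & !is.na(cur)
        expect_true(all(cur[both] >= prev[both]))
      }
      prev <- cur
    }
  }
})

test_that("first-adult day is non-decreasing with latitude on a lapse grid", {
  spec <- synthetic_climate_spec(nrow = 12, ncol = 3, noise_sd = 0,
                                 lapse = 1.2, base_temp = 15, seed = 1)
  ev <- run_annual_cycle(generate_synthetic_climate(spec, 2023), p)
  adult <- aggregate_cohort_events(ev, "adult_emergence", "earliest")
  adult[is.na(adult)] <- Inf  # no event counts as later than any day
  # row 1 is northernmost: going north (up the rows), DOY must not decrease
  for (j in seq_len(ncol(adult)))
    expect_true(all(diff(rev(adult[, j])) >= 0))
})

test_that("cohort aggregation renormalizes over occurring cohorts", {
  ev <- run_annual_cycle(const_grid(25), p, one_cohort(190))
  # patch in a two-cohort event layer by hand to check the arithmetic
  ev$weights <- c(0.5, 0.5)
  ev$requirements <- c(150, 250)
  ev$doy$egg_hatch <- array(c(10, 20), c(1, 1, 2))
  dims <- dim(ev$doy$egg_hatch)
  for (e in EVENTS[-1]) ev$doy[[e]] <- array(NA_real_, dims)
  ev$dims <- c(1L, 1L)
  expect_equal(aggregate_cohort_events(ev, "egg_hatch", "earliest")[1, 1], 10)
  expect_equal(aggregate_cohort_events(ev, "egg_hatch", "weighted_mean")[1, 1], 15)
  # one cohort missing the event: weights renormalize over the other
  ev$doy$egg_hatch[1, 1, 2] <- NA
  expect_equal(aggregate_cohort_events(ev, "egg_hatch", "weighted_mean")[1, 1], 10)
  expect_error(aggregate_cohort_events(ev, "egg_hatch", "midpoint"))
  expect_error(aggregate_cohort_events(ev, "no_such_event"), "unknown event")
})

test_that("nodata on any day removes a cell from every event map", {
  g <- const_grid(25, nrow = 2, ncol = 2)
  g$tmin[1, 1, 100] <- NA
  g$tmax[1, 1, 100] <- NA
  ev <- run_annual_cycle(g, p)
  for (e in EVENTS) {
    m <- aggregate_cohort_events(ev, e, "earliest")
    expect_true(is.na(m[1, 1]))
    expect_false(any(is.na(m[-1])))
  }
})

test_that("species parameter files round-trip through disk", {
  path <- tempfile(fileext = ".params")
  write_species_params(p, path)
  r <- read_species_params(path)
  expect_equal(r$stage_dd, p$stage_dd)
  expect_equal(r$event_dd, p$event_dd)
  expect_equal(r$thresholds, p$thresholds)
  expect_equal(r$distro_mean, p$distro_mean)
  expect_equal(r$stress, p$stress)
  expect_equal(build_cohorts(r), build_cohorts(p))
})

test_that("the shipped parameter file reproduces the default parameterization", {
  shipped <- read_species_params(
    system.file("extdata", "spotted_lanternfly.params", package = "slfrisk"))
  expect_equal(shipped$thresholds$OE$ldt, 10)
  expect_equal(shipped$thresholds$L$udt, 35)
  expect_equal(unname(shipped$stage_dd[c("L", "P", "A", "E")]),
               c(890, 630, 146, 202))
  expect_equal(shipped$ncohorts, 7L)
  expect_true(shipped$obligate_diapause)
})
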