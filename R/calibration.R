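#' Lower threshold and stage duration by the x-intercept method
#'
#' Fits an ordinary least-squares line `rate = a + b * T` to temperature
#' vs. development-rate data (rate in 1/days). The lower developmental
#' threshold is the x-intercept `-a / b` (the temperature at which the
#' fitted rate reaches zero) and the stage duration is `1 / b`
#' degree-days.
#'
#' @param temperature Rearing temperatures (degrees C); at least two
#'   distinct values.
#' @param rate Development rates (1/days), `>= 0`.
#' @return A list: `threshold` (degrees C), `duration` (degree-days),
#'   `r_squared`, `slope`, `intercept`, and the `lm` fit.
#' @export
#' @examples
#' x_intercept_fit(c(15, 25), c(0.005, 0.015)) # threshold 10, duration 1000
x_intercept_fit <- function(temperature, rate) {
  stopifnot(length(temperature) == length(rate))
  if (any(rate < 0)) stop("development rates must be non-negative")
  if (length(unique(temperature)) < 2)
    stop("at least two distinct temperatures are required")
  fit <- stats::lm(rate ~ temperature)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  if (b <= 0) stop("no positive thermal response (slope <= 0)")
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((rate - mean(rate))^2)
  list(threshold = -a / b, duration = 1 / b, r_squared = r2,
       slope = b, intercept = a, fit = fit)
}

# run the engine at each observation's cell and return predicted earliest
# and cohort-weighted-mean (peak) hatch DOYs
.predict_hatch_at_sites <- function(params, observations, climate) {
  stopifnot(is.data.frame(observations),
            all(c("lon", "lat", "year") %in% names(observations)))
  cohorts <- build_cohorts(params)
  n <- nrow(observations)
  pred <- data.frame(earliest = rep(NA_real_, n), peak = rep(NA_real_, n))
  for (i in seq_len(n)) {
    yr <- as.character(observations$year[i])
    grid <- climate[[yr]]
    if (is.null(grid)) stop("no climate grid for year ", yr)
    rc <- cell_from_xy(grid, observations$lon[i], observations$lat[i])
    if (is.na(rc[1, 1]))
      stop("observation outside climate extent: site ",
           if ("site" %in% names(observations)) observations$site[i] else i)
    nd <- n_days(grid)
    res <- .run_cells(matrix(grid$tmin[rc[1, 1], rc[1, 2], ], 1, nd),
                      matrix(grid$tmax[rc[1, 1], rc[1, 2], ], 1, nd),
                      params, cohorts)
    hatch <- res$event_doy[1, "egg_hatch", ]
    ok <- !is.na(hatch)
    if (any(ok)) {
      pred$earliest[i] <- min(hatch[ok])
      pred$peak[i] <- sum(cohorts$weight[ok] * hatch[ok]) / sum(cohorts$weight[ok])
    }
  }
  pred
}

#' Score one cohort-parameter candidate against hatch observations
#'
#' Runs the phenology engine with the candidate's `xdist1`, `distro_mean`
#' and `xdist2` (variance fixed) at each observation's site and year, then
#' compares the predicted earliest and peak (cohort-weighted mean) egg
#' hatch day-of-year with the observed values. Overpredictions are
#' predictions later than observed; MAE and bias (days) are computed over
#' the pooled earliest/peak differences.
#'
#' @param candidate List or one-row data frame with `xdist1`,
#'   `distro_mean`, `xdist2`.
#' @param observations Data frame with `lon`, `lat`, `year` and at least
#'   one of `obs_earliest`, `obs_peak` (day-of-year).
#' @param climate Named list (by year) of full-year [climate_grid()]s.
#' @param params Base [species_params()] providing all other parameters.
#' @return A list: `n_overpredictions`, `mae`, `bias`, and the per-site
#'   `detail` data frame.
#' @export
score_cohort_candidate <- function(candidate, observations, climate,
                                   params = species_params()) {
  if (!(candidate$xdist1 < candidate$distro_mean &&
        candidate$distro_mean < candidate$xdist2))
    stop("candidate violates xdist1 < distro_mean < xdist2")
  cand_params <- params  # all non-cohort parameters inherited unchanged
  cand_params$distro_mean <- candidate$distro_mean
  cand_params$xdist1 <- candidate$xdist1
  cand_params$xdist2 <- candidate$xdist2
  pred <- .predict_hatch_at_sites(cand_params, observations, climate)
  diffs <- numeric(0)
  if ("obs_earliest" %in% names(observations))
    diffs <- c(diffs, pred$earliest - observations$obs_earliest)
  if ("obs_peak" %in% names(observations))
    diffs <- c(diffs, pred$peak - observations$obs_peak)
  diffs <- diffs[!is.na(diffs)]
  if (!length(diffs)) stop("no comparable observations (all NA)")
  list(n_overpredictions = sum(diffs > 0),
       mae = mean(abs(diffs)), bias = mean(diffs),
       detail = cbind(observations, pred))
}

#' Grid search over cohort parameters
#'
#' Scores every candidate combination with [score_cohort_candidate()] and
#' ranks by fewest overpredictions, then lowest MAE, then smallest |bias|.
#'
#' @param candidates Data frame of candidate rows (`xdist1`,
#'   `distro_mean`, `xdist2`), each satisfying `xdist1 < distro_mean <
#'   xdist2`.
#' @inheritParams score_cohort_candidate
#' @return A list: `best` (the winning candidate row) and `scores` (the
#'   full ranked score table).
#' @export
select_cohort_params <- function(candidates, observations, climate,
                                 params = species_params()) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) < 1) stop("empty candidate grid")
  bad <- !(candidates$xdist1 < candidates$distro_mean &
             candidates$distro_mean < candidates$xdist2)
  if (any(bad))
    stop(sum(bad), " candidate(s) violate xdist1 < distro_mean < xdist2")
  scores <- candidates
  scores$n_overpredictions <- NA_integer_
  scores$mae <- NA_real_
  scores$bias <- NA_real_
  for (i in seq_len(nrow(candidates))) {
    s <- score_cohort_candidate(candidates[i, ], observations, climate, params)
    scores$n_overpredictions[i] <- s$n_overpredictions
    scores$mae[i] <- s$mae
    scores$bias[i] <- s$bias
  }
  ord <- order(scores$n_overpredictions, scores$mae, abs(scores$bias))
  scores <- scores[ord, , drop = FALSE]
  rownames(scores) <- NULL
  list(best = scores[1, , drop = FALSE], scores = scores)
}
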