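# Independent numeric oracles and fixture builders used across the suite.

# 1-minute numeric integration of the single-triangle daily temperature
# trace: rises linearly tmin -> tmax over the first half day, falls back
# over the second. Degree-days above ldt with horizontal cutoff at udt.
tri_dd_numeric <- function(tmin, tmax, ldt, udt = Inf) {
  t <- (seq_len(1440) - 0.5) / 1440
  temp <- ifelse(t < 0.5, tmin + (tmax - tmin) * 2 * t,
                 tmax - (tmax - tmin) * (2 * t - 1))
  mean(pmax(pmin(temp, udt) - ldt, 0))
}

# same trace; area below (cold) or above (heat) a stress threshold
stress_numeric <- function(tmin, tmax, threshold, direction) {
  t <- (seq_len(1440) - 0.5) / 1440
  temp <- ifelse(t < 0.5, tmin + (tmax - tmin) * 2 * t,
                 tmax - (tmax - tmin) * (2 * t - 1))
  if (direction == "cold") mean(pmax(threshold - temp, 0))
  else mean(pmax(temp - threshold, 0))
}

# exact one-sided signed-rank p-value by enumerating all 2^n sign vectors
# (midranks for tied |d|). alternative "less": P(W+ <= w_obs).
wilcoxon_exact_enum <- function(d, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  if (alternative == "less") mean(w_all <= w_obs) else mean(w_all >= w_obs)
}

# constant-temperature full-year grid
const_grid <- function(temp, nrow = 2, ncol = 2, year = 2023,
                       diurnal = 0, extent = c(0, 1, 0, 1)) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  nd <- length(dates)
  climate_grid(array(temp - diurnal / 2, c(nrow, ncol, nd)),
               array(temp + diurnal / 2, c(nrow, ncol, nd)),
               dates, extent)
}

# full-year grid from a per-day mean temperature series (same all cells)
series_grid <- function(tmean, nrow = 1, ncol = 1, year = 2023,
                        diurnal = 0, extent = c(0, 1, 0, 1)) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  stopifnot(length(tmean) == length(dates))
  a <- aperm(array(rep(tmean, each = nrow * ncol),
                   c(nrow, ncol, length(tmean))), c(1, 2, 3))
  climate_grid(a - diurnal / 2, a + diurnal / 2, dates, extent)
}

# minimal single-cohort set for closed-form engine checks
one_cohort <- function(requirement) {
  structure(data.frame(requirement = requirement, weight = 1),
            class = c("cohort_set", "data.frame"))
}
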