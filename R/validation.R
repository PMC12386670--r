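# observed life-stage scale used for concordance comparisons
STAGE_SCALE <- c("egg_OW", "early_nymph", "late_nymph", "adult", "egg_G1")

# observation label -> (event, which cohort) used for DOY comparisons;
# first appearance of a stage maps to the earliest-cohort event that
# begins it, except overwintered eggs, which are compared against the
# *last* egg hatch (latest cohort) since hatch ends their availability
.label_event <- function(label) {
  switch(label,
    egg_OW = list(event = "egg_hatch", cohort = "latest"),
    egg_hatch = ,
    first_nymphs = ,
    early_nymph = list(event = "egg_hatch", cohort = "earliest"),
    nymphs_halfway = ,
    late_nymph = list(event = "nymphs_halfway", cohort = "earliest"),
    adult_emergence = ,
    adult = list(event = "adult_emergence", cohort = "earliest"),
    oviposition = list(event = "oviposition", cohort = "earliest"),
    diapausing_egg = ,
    egg_G1 = list(event = "diapausing_egg", cohort = "earliest"),
    stop("unknown observation label: ", label))
}

#' Pair observation records with predicted event days
#'
#' Looks up the predicted day-of-year of the event matching each record's
#' life-stage label at the record's nearest grid cell. First appearances
#' map to the earliest cohort's event (first nymphs to egg hatch, late
#' nymphs to nymphs-halfway, adults to adult emergence, oviposition to
#' oviposition, first-generation eggs to diapausing egg); overwintered-egg
#' records are paired with the last egg hatch, i.e. the hatch of the
#' latest (highest-requirement) cohort. Records outside the extent, on
#' nodata cells, or where the event never occurs are flagged as skipped
#' and reported with a message.
#'
#' @param events An `event_maps` object from [run_annual_cycle()].
#' @param records Data frame with columns `lon`, `lat`, `date` (`Date` or
#'   ISO-8601) and `label` (one of `egg_OW`, `early_nymph`, `late_nymph`,
#'   `adult`, `egg_G1`, or an event name).
#' @return `records` with added columns `doy_obs`, `doy_pred`, `skipped`,
#'   `skip_reason`.
#' @export
predict_at_records <- function(events, records) {
  stopifnot(inherits(events, "event_maps"), is.data.frame(records),
            all(c("lon", "lat", "date", "label") %in% names(records)))
  dates <- as.Date(records$date)
  records$doy_obs <- as.integer(dates - as.Date(sprintf("%d-01-01", events$year))) + 1L
  records$doy_pred <- NA_real_
  records$skipped <- FALSE
  records$skip_reason <- NA_character_
  rc <- cell_from_xy(events, records$lon, records$lat, events$dims)
  latest <- which.max(events$requirements)
  earliest_req <- which.min(events$requirements)
  for (i in seq_len(nrow(records))) {
    if (is.na(rc[i, 1])) {
      records$skipped[i] <- TRUE
      records$skip_reason[i] <- "outside extent"
      next
    }
    map <- .label_event(records$label[i])
    a <- events$doy[[map$event]][rc[i, 1], rc[i, 2], ]
    doy <- if (map$cohort == "latest") a[latest] else
      suppressWarnings(min(a, na.rm = TRUE))
    if (!is.finite(doy)) {
      records$skipped[i] <- TRUE
      records$skip_reason[i] <- if (!events$valid[rc[i, 1], rc[i, 2]])
        "nodata cell" else "event does not occur"
      next
    }
    records$doy_pred[i] <- doy
  }
  if (any(records$skipped))
    message(sum(records$skipped), " record(s) skipped (",
            paste(unique(records$skip_reason[records$skipped]), collapse = "; "),
            ")")
  records
}

#' Summary statistics for predicted vs. observed event days
#'
#' Computes, for a set of (predicted, observed) day-of-year pairs: MAE
#' (mean |predicted - observed|), bias (mean of predicted - observed) with
#' its SD and range, and an OLS regression of predicted on observed day
#' with pointwise 95% confidence and prediction intervals, whose mean
#' lengths (days) quantify precision of the fitted mean and uncertainty
#' around individual observations.
#'
#' @param doy_pred,doy_obs Numeric vectors of equal length (`NA` pairs
#'   dropped).
#' @return A one-row data frame: `n`, `mae`, `bias`, `sd`, `range_min`,
#'   `range_max`, `slope`, `intercept`, `ci_length`, `pi_length`
#'   (regression fields `NA` when fewer than 2 pairs or degenerate).
#' @export
summarize_event_fit <- function(doy_pred, doy_obs) {
  ok <- !is.na(doy_pred) & !is.na(doy_obs)
  doy_pred <- doy_pred[ok]; doy_obs <- doy_obs[ok]
  n <- length(doy_pred)
  if (n < 1) stop("no complete (predicted, observed) pairs")
  d <- doy_pred - doy_obs
  out <- data.frame(n = n, mae = mean(abs(d)), bias = mean(d),
                    sd = if (n > 1) stats::sd(d) else NA_real_,
                    range_min = min(d), range_max = max(d),
                    slope = NA_real_, intercept = NA_real_,
                    ci_length = NA_real_, pi_length = NA_real_)
  if (n >= 2 && stats::var(doy_obs) > 0) {
    df <- data.frame(obs = doy_obs, pred = doy_pred)
    fit <- stats::lm(pred ~ obs, data = df)
    out$intercept <- unname(stats::coef(fit)[1])
    out$slope <- unname(stats::coef(fit)[2])
    if (n >= 3) {  # intervals need residual degrees of freedom
      ci <- stats::predict(fit, newdata = df, interval = "confidence", level = 0.95)
      pi <- stats::predict(fit, newdata = df, interval = "prediction", level = 0.95)
      out$ci_length <- mean(ci[, "upr"] - ci[, "lwr"])
      out$pi_length <- mean(pi[, "upr"] - pi[, "lwr"])
    }
  }
  out
}

#' One-sided paired Wilcoxon signed-rank test on encounter records
#'
#' Tests whether predicted event days are systematically earlier
#' (`pred_before_obs`) or later (`pred_after_obs`) than the observed
#' single-encounter days. Zero differences are dropped; the exact null
#' distribution is used for n <= 25 without tied |differences|, otherwise
#' the normal approximation with continuity correction (midranks for
#' ties).
#'
#' @param doy_pred,doy_obs Paired day-of-year vectors.
#' @param direction `"pred_before_obs"` (alternative: median difference
#'   < 0) or `"pred_after_obs"` (> 0).
#' @return A list: `n` (non-zero pairs), `median_pred`, `median_obs`,
#'   `pct_direction` (% of non-zero differences in the stated direction)
#'   and `p_value`.
#' @export
one_sided_encounter_test <- function(doy_pred, doy_obs,
                                     direction = c("pred_before_obs", "pred_after_obs")) {
  direction <- match.arg(direction)
  ok <- !is.na(doy_pred) & !is.na(doy_obs)
  doy_pred <- doy_pred[ok]; doy_obs <- doy_obs[ok]
  if (!length(doy_pred)) stop("no complete pairs")
  d <- doy_pred - doy_obs
  d0 <- d[d != 0]
  med <- list(pred = stats::median(doy_pred), obs = stats::median(doy_obs))
  if (!length(d0)) {
    warning("all differences are zero; no directional signal")
    return(list(n = 0L, median_pred = med$pred, median_obs = med$obs,
                pct_direction = NA_real_, p_value = 1))
  }
  alt <- if (direction == "pred_before_obs") "less" else "greater"
  exact <- length(d0) <= 25 && !anyDuplicated(abs(d0))
  p <- suppressWarnings(
    stats::wilcox.test(d0, mu = 0, alternative = alt, exact = exact,
                       correct = TRUE)$p.value)
  pct <- 100 * mean(if (alt == "less") d0 < 0 else d0 > 0)
  list(n = length(d0), median_pred = med$pred, median_obs = med$obs,
       pct_direction = pct, p_value = p)
}

# engine stage + within-stage DD -> position on the observed-stage scale
.scale_from_model <- function(stage, within_dd, halfway_dd) {
  ifelse(stage == "OE", 1L,
  ifelse(stage == "L", ifelse(within_dd < halfway_dd, 2L, 3L),
  ifelse(stage %in% c("P", "A"), 4L,          # both are adult periods
  ifelse(stage %in% c("E", "done"), 5L, NA_integer_))))
}

#' Life-stage concordance between the model and an encounter record
#'
#' Compares the life stage predicted for a cell on the record's date with
#' the observed stage, on the ordered scale overwintered egg < early nymph
#' < late nymph < adult < first-generation egg. Nymphs are split at the
#' nymphs-halfway trigger (within-stage degree-days below/above the
#' halfway event requirement); the pre-oviposition and oviposition periods
#' both present as adults. The predicted stage is the cohort-weighted
#' modal stage (default) or the earliest cohort's stage.
#'
#' @param trajectory A [cell_trajectory()] data frame for the record's
#'   cell.
#' @param date Observation date (`Date` or ISO-8601 string).
#' @param label Observed stage, one of `egg_OW`, `early_nymph`,
#'   `late_nymph`, `adult`, `egg_G1`.
#' @param cohorts The [build_cohorts()] set used for the trajectory
#'   (weights for the modal aggregation).
#' @param params [species_params()] supplying the nymphs-halfway trigger.
#' @param mode `"weighted_modal"` or `"earliest_cohort"`.
#' @return `"same"`, `"model_older"` or `"model_younger"` (`NA` for
#'   nodata).
#' @export
stage_concordance <- function(trajectory, date, label,
                              cohorts, params = species_params(),
                              mode = c("weighted_modal", "earliest_cohort")) {
  mode <- match.arg(mode)
  if (!label %in% STAGE_SCALE) stop("unknown stage label: ", label)
  day <- trajectory[trajectory$date == as.Date(date), ]
  if (!nrow(day)) stop("date ", date, " not in the trajectory's year")
  if (all(day$stage == "nodata")) return(NA_character_)
  sc <- .scale_from_model(day$stage, day$within_stage_dd,
                          params$event_dd[["L"]])
  pred <- if (mode == "earliest_cohort") {
    sc[day$cohort == which.min(cohorts$requirement)]
  } else {
    w <- tapply(cohorts$weight[day$cohort], sc, sum)
    as.integer(names(w)[which.max(w)])  # ties resolve to the younger stage
  }
  obs <- match(label, STAGE_SCALE)
  if (pred == obs) "same" else if (pred > obs) "model_older" else "model_younger"
}
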