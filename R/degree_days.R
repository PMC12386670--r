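#' Thermal thresholds for degree-day accumulation
#'
#' Bundle a lower and upper developmental threshold. Degree-days accumulate
#' only at temperatures above `ldt`; temperatures above `udt` contribute as
#' if they were equal to `udt` (horizontal cutoff).
#'
#' @param ldt Lower developmental threshold (degrees C).
#' @param udt Upper developmental threshold (degrees C); must exceed `ldt`.
#' @return An object of class `thermal_thresholds`.
#' @export
#' @examples
#' thermal_thresholds(10, 35)
thermal_thresholds <- function(ldt, udt) {
  stopifnot(is.numeric(ldt), is.numeric(udt), length(ldt) == 1, length(udt) == 1)
  if (!is.finite(ldt) || !is.finite(udt)) stop("thresholds must be finite")
  if (udt <= ldt) stop("upper threshold (", udt, ") must exceed lower threshold (", ldt, ")")
  structure(list(ldt = ldt, udt = udt), class = "thermal_thresholds")
}

# Area (degree-days) of the single-triangle daily temperature trace that lies
# above `thr`. The trace rises linearly from tmin to tmax and back over one
# day, so the area above a level line is a similar triangle:
#   tmax <= thr : 0
#   tmin >= thr : (tmin + tmax)/2 - thr   (whole triangle above the line)
#   else        : (tmax - thr)^2 / (2 (tmax - tmin))
# Vectorized over tmin/tmax; NA propagates.
.tri_area_above <- function(tmin, tmax, thr) {
  out <- rep(NA_real_, length(tmax))
  rng <- tmax - tmin
  below <- !is.na(tmax) & tmax <= thr
  above <- !is.na(tmin) & tmin >= thr
  mid <- !is.na(rng) & !below & !above
  out[below] <- 0
  out[above] <- (tmin[above] + tmax[above]) / 2 - thr
  out[mid] <- (tmax[mid] - thr)^2 / (2 * rng[mid])
  out
}

#' Single-triangle degree-days with an upper threshold
#'
#' Daily degree-days under the single-triangle approximation: the day's
#' temperature trace is treated as a triangle rising from `tmin` to `tmax`
#' and falling back. Accumulation is the area above the lower threshold,
#' with temperatures above the upper threshold contributing as if equal to
#' it (horizontal cutoff), i.e. `area_above(ldt) - area_above(udt)`.
#'
#' @param tmin,tmax Daily minimum and maximum temperatures (degrees C);
#'   vectors of equal length (or one recycled scalar). `tmax >= tmin`.
#' @param thresholds A [thermal_thresholds()] object.
#' @return Degree-days (degree C days), same length as the inputs; in
#'   `[0, udt - ldt]`. `NA` inputs give `NA`.
#' @export
#' @examples
#' single_triangle_dd(25, 25, thermal_thresholds(10, 35)) # 15
#' single_triangle_dd(5, 20, thermal_thresholds(10, 35))  # 10/3
single_triangle_dd <- function(tmin, tmax, thresholds) {
  stopifnot(inherits(thresholds, "thermal_thresholds"))
  n <- max(length(tmin), length(tmax))
  tmin <- rep_len(as.numeric(tmin), n)
  tmax <- rep_len(as.numeric(tmax), n)
  bad <- !is.na(tmin) & !is.na(tmax) & tmax < tmin
  if (any(bad)) stop("tmax < tmin for ", sum(bad), " input(s)")
  .tri_area_above(tmin, tmax, thresholds$ldt) -
    .tri_area_above(tmin, tmax, thresholds$udt)
}

#' Daily cold or heat stress units
#'
#' Stress units use the same triangular daily temperature trace as
#' [single_triangle_dd()]. Cold stress is the area of the trace below the
#' cold threshold; heat stress is the area above the heat threshold. There
#' is no second cutoff: every degree beyond the threshold counts.
#'
#' @param tmin,tmax Daily minimum and maximum temperatures (degrees C).
#' @param threshold Stress threshold (degrees C).
#' @param direction `"cold"` or `"heat"`.
#' @return Stress units (degree C days), `>= 0`; `NA` inputs give `NA`.
#' @export
#' @examples
#' stress_units(-20, -18, -16, "cold") # 3
#' stress_units(20, 35, 37, "heat")    # 0
stress_units <- function(tmin, tmax, threshold, direction = c("cold", "heat")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(threshold), length(threshold) == 1, is.finite(threshold))
  n <- max(length(tmin), length(tmax))
  tmin <- rep_len(as.numeric(tmin), n)
  tmax <- rep_len(as.numeric(tmax), n)
  bad <- !is.na(tmin) & !is.na(tmax) & tmax < tmin
  if (any(bad)) stop("tmax < tmin for ", sum(bad), " input(s)")
  if (direction == "heat") {
    .tri_area_above(tmin, tmax, threshold)
  } else {
    # area below the threshold = mirror image of the area-above geometry
    .tri_area_above(-tmax, -tmin, -threshold)
  }
}
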