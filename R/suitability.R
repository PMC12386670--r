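#' Climate-stress parameters
#'
#' Thresholds and unit limits for cold and heat stress. Stress units are
#' degree-day-like accumulations beyond the thresholds; the `max1` limit
#' marks where most individuals die (moderate exclusion, inhibiting
#' long-term establishment) and `max2` where all die (severe exclusion).
#' Defaults are the spotted-lanternfly calibration: cold threshold -16
#' degrees C with limits 300/475, heat threshold 37 with limits 115/175.
#'
#' @param coldstress_threshold,heatstress_threshold Degrees C.
#' @param coldstress_units_max1,coldstress_units_max2 Cold limits
#'   (degree-days), `max2 > max1 > 0`.
#' @param heatstress_units_max1,heatstress_units_max2 Heat limits.
#' @return An object of class `stress_params`.
#' @export
stress_params <- function(coldstress_threshold = -16,
                          coldstress_units_max1 = 300,
                          coldstress_units_max2 = 475,
                          heatstress_threshold = 37,
                          heatstress_units_max1 = 115,
                          heatstress_units_max2 = 175) {
  if (!(coldstress_units_max2 > coldstress_units_max1 &&
        coldstress_units_max1 > 0))
    stop("cold limits must satisfy max2 > max1 > 0")
  if (!(heatstress_units_max2 > heatstress_units_max1 &&
        heatstress_units_max1 > 0))
    stop("heat limits must satisfy max2 > max1 > 0")
  structure(list(coldstress_threshold = coldstress_threshold,
                 coldstress_units_max1 = coldstress_units_max1,
                 coldstress_units_max2 = coldstress_units_max2,
                 heatstress_threshold = heatstress_threshold,
                 heatstress_units_max1 = heatstress_units_max1,
                 heatstress_units_max2 = heatstress_units_max2),
            class = "stress_params")
}

#' Accumulate annual cold and heat stress units
#'
#' Per cell, the sum over the year of daily [stress_units()]: cold stress
#' from the triangle area of the daily temperature trace below the cold
#' threshold, heat stress from the area above the heat threshold. There is
#' no decay or recovery within the year.
#'
#' @param grid A full-year [climate_grid()].
#' @param params A [stress_params()] object (or [species_params()], whose
#'   `$stress` is used).
#' @return A list with matrices `cold` and `heat` (degree-days); `NA`
#'   where any day is missing.
#' @export
accumulate_stress <- function(grid, params = stress_params()) {
  if (inherits(params, "species_params")) params <- params$stress
  stopifnot(inherits(grid, "climate_grid"), inherits(params, "stress_params"))
  .check_full_year(grid)
  d <- dim(grid$tmin)
  ncell <- d[1] * d[2]
  tmn <- matrix(grid$tmin, ncell, d[3])
  tmx <- matrix(grid$tmax, ncell, d[3])
  cold <- matrix(stress_units(as.vector(tmn), as.vector(tmx),
                              params$coldstress_threshold, "cold"), ncell, d[3])
  heat <- matrix(stress_units(as.vector(tmn), as.vector(tmx),
                              params$heatstress_threshold, "heat"), ncell, d[3])
  list(cold = matrix(rowSums(cold), d[1], d[2]),
       heat = matrix(rowSums(heat), d[1], d[2]))
}

.classify_units <- function(units, max1, max2) {
  out <- matrix(NA_integer_, nrow(units), ncol(units))
  out[units <= max1] <- 0L
  out[units > max1 & units <= max2] <- 1L
  out[units > max2] <- 2L
  out
}

#' Classify cold/heat stress exclusion
#'
#' Categorizes each cell from its annual stress units: `none` (units `<=
#' max1`), `moderate` (`max1 < units <= max2`, most individuals die) or
#' `severe` (`units > max2`, all individuals die). The combined category
#' is the worse of the cold and heat categories; only `none` cells belong
#' to the year's potential distribution.
#'
#' @param cold,heat Matrices of annual stress units (degree-days), as
#'   returned by [accumulate_stress()].
#' @param params A [stress_params()] object.
#' @return An `exclusion_map`: list with integer category matrices `cold`,
#'   `heat`, `combined` (0 = none, 1 = moderate, 2 = severe) and the unit
#'   matrices `cold_units`, `heat_units`.
#' @export
classify_exclusion <- function(cold, heat, params = stress_params()) {
  if (inherits(params, "species_params")) params <- params$stress
  stopifnot(inherits(params, "stress_params"))
  if (any(cold < 0, na.rm = TRUE) || any(heat < 0, na.rm = TRUE))
    stop("stress units must be non-negative")
  cc <- .classify_units(cold, params$coldstress_units_max1,
                        params$coldstress_units_max2)
  hc <- .classify_units(heat, params$heatstress_units_max1,
                        params$heatstress_units_max2)
  structure(list(cold = cc, heat = hc, combined = pmax(cc, hc),
                 cold_units = cold, heat_units = heat),
            class = "exclusion_map")
}

#' @rdname classify_exclusion
#' @param grid A full-year [climate_grid()]; convenience wrapper running
#'   [accumulate_stress()] then [classify_exclusion()].
#' @export
exclusion_from_grid <- function(grid, params = stress_params()) {
  u <- accumulate_stress(grid, params)
  classify_exclusion(u$cold, u$heat, params)
}

#' Combine yearly exclusion maps into a potential-distribution count
#'
#' Counts, per cell, the years in which the cell was not excluded by any
#' climate stress (combined category `none`), i.e. the number of years the
#' cell belongs to the potential distribution.
#'
#' @param maps A list of `exclusion_map` objects on identical grids.
#' @return An integer matrix of year counts (`NA` where all years are
#'   nodata; years with nodata at a cell do not count as included).
#' @export
combine_years <- function(maps) {
  if (length(maps) < 1) stop("need at least one exclusion map")
  if (!all(vapply(maps, inherits, TRUE, "exclusion_map")))
    stop("all elements must be exclusion_map objects")
  dm <- dim(maps[[1]]$combined)
  for (m in maps) if (!identical(dim(m$combined), dm))
    stop("exclusion maps have mismatched extents/dimensions")
  cnt <- matrix(0L, dm[1], dm[2])
  anyv <- matrix(FALSE, dm[1], dm[2])
  for (m in maps) {
    ok <- !is.na(m$combined)
    anyv <- anyv | ok
    cnt <- cnt + (ok & m$combined == 0L)
  }
  cnt[!anyv] <- NA_integer_
  cnt
}

#' Fraction of presence records inside the potential distribution
#'
#' For each year's exclusion map, the fraction of presence records falling
#' in non-excluded (`none`) cells. Records outside the extent or on nodata
#' cells are reported and dropped from the denominator. If `records` has a
#' `year` column, each record is evaluated only against its year's map
#' (matched by list name); otherwise every record is evaluated against
#' every year.
#'
#' @param maps Named list of `exclusion_map` objects (names = years).
#' @param records Data frame with columns `lon`, `lat` (and optionally
#'   `year`).
#' @param extent,dims Georeferencing of the maps: `c(xmin, xmax, ymin,
#'   ymax)` and `c(nrow, ncol)`.
#' @return A list: `per_year` (data frame `year`, `n`, `included`,
#'   `fraction`), `pooled` fraction, and counts of `out_of_extent` /
#'   `nodata` records.
#' @export
evaluate_presence_inclusion <- function(maps, records, extent,
                                        dims = dim(maps[[1]]$combined)) {
  stopifnot(is.data.frame(records), all(c("lon", "lat") %in% names(records)))
  fake <- list(extent = as.numeric(extent))
  rc <- cell_from_xy(fake, records$lon, records$lat, dims)
  out_of_extent <- sum(is.na(rc[, 1]))
  if (out_of_extent > 0)
    message(out_of_extent, " record(s) outside the map extent; not counted")
  yrs <- names(maps)
  if (is.null(yrs)) yrs <- as.character(seq_along(maps))
  per <- data.frame(year = yrs, n = 0L, included = 0L, fraction = NA_real_)
  nodata <- 0L
  for (i in seq_along(maps)) {
    sel <- !is.na(rc[, 1])
    if ("year" %in% names(records))
      sel <- sel & as.character(records$year) == yrs[i]
    if (!any(sel)) next
    cat_i <- maps[[i]]$combined[cbind(rc[sel, 1], rc[sel, 2])]
    nodata <- nodata + sum(is.na(cat_i))
    per$n[i] <- sum(!is.na(cat_i))
    per$included[i] <- sum(cat_i == 0L, na.rm = TRUE)
    per$fraction[i] <- if (per$n[i] > 0) per$included[i] / per$n[i] else NA_real_
  }
  if (nodata > 0)
    message(nodata, " record-year(s) on nodata cells; dropped from denominators")
  pooled <- if (sum(per$n) > 0) sum(per$included) / sum(per$n) else NA_real_
  list(per_year = per, pooled = pooled,
       out_of_extent = out_of_extent, nodata = nodata)
}
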