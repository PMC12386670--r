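# Life-cycle stages, in developmental order. The naming follows the
# four-stage modeling convention: the nymph (instars 1-4) is the "larva",
# the pre-oviposition adult the "pupa", and the first-to-50%-oviposition
# period the "adult". OE = overwintered egg, E = first-generation egg.
STAGES <- c("OE", "L", "P", "A", "E")

#' Phenological events predicted by the model
#'
#' Five events, each tied to a life stage and a within-stage degree-day
#' trigger: egg hatch (completion of the overwintered egg), nymphs halfway
#' developed, adult emergence, oviposition, and diapausing (first
#' generation) egg.
#' @export
EVENTS <- c("egg_hatch", "nymphs_halfway", "adult_emergence",
            "oviposition", "diapausing_egg")

#' Species parameters for the phenology and suitability model
#'
#' Defaults are the spotted-lanternfly parameterization: a common lower
#' developmental threshold of 10 degrees C and upper threshold of 35 for
#' all stages; stage durations of 202 (egg), 890 (nymphs, instars 1-4),
#' 630 (pre-oviposition) and 146 (first-to-50% oviposition) degree-days;
#' event triggers of 442 (nymphs halfway), 1 (adult emergence), 1
#' (oviposition) and 100 (diapausing egg) degree-days; and a seven-cohort
#' normal distribution of overwintered-egg hatch requirements (mean 190,
#' variance 15000, bounds 135-360 degree-days). The life cycle is
#' univoltine with obligate diapause: each cohort stops after the
#' first-generation egg event.
#'
#' @param eggLDT,larvaeLDT,pupaeLDT,adultLDT Lower developmental
#'   thresholds (degrees C) per stage.
#' @param eggUDT,larvaeUDT,pupaeUDT,adultUDT Upper developmental
#'   thresholds (degrees C).
#' @param eggDD,larvaeDD,pupDD,adultDD Stage durations (degree-days).
#' @param larvaeEventDD,pupaeEventDD,adultEventDD,eggEventDD Within-stage
#'   degree-day triggers of the nymphs-halfway, adult-emergence,
#'   oviposition and diapausing-egg events. The egg-hatch trigger is the
#'   per-cohort hatch requirement and therefore varies by cohort.
#' @param distro_mean,distro_var,xdist1,xdist2 Mean, variance, minimum and
#'   maximum (degree-days) of the overwintered-egg developmental-completion
#'   distribution.
#' @param distro_shape Shape of that distribution; only `"normal"` is
#'   supported.
#' @param ncohorts Number of time-distributed cohorts.
#' @param obligate_diapause If `TRUE`, the model stops after one complete
#'   life cycle.
#' @param stress A [stress_params()] object.
#' @return An object of class `species_params`.
#' @export
species_params <- function(eggLDT = 10, larvaeLDT = 10, pupaeLDT = 10, adultLDT = 10,
                           eggUDT = 35, larvaeUDT = 35, pupaeUDT = 35, adultUDT = 35,
                           eggDD = 202, larvaeDD = 890, pupDD = 630, adultDD = 146,
                           larvaeEventDD = 442, pupaeEventDD = 1,
                           adultEventDD = 1, eggEventDD = 100,
                           distro_mean = 190, distro_var = 15000,
                           xdist1 = 135, xdist2 = 360,
                           distro_shape = "normal", ncohorts = 7,
                           obligate_diapause = TRUE,
                           stress = stress_params()) {
  if (!identical(distro_shape, "normal"))
    stop("only distro_shape = \"normal\" is supported")
  if (!(xdist1 < distro_mean && distro_mean < xdist2))
    stop("require xdist1 < distro_mean < xdist2")
  dds <- c(eggDD, larvaeDD, pupDD, adultDD,
           larvaeEventDD, pupaeEventDD, adultEventDD, eggEventDD)
  if (any(dds <= 0)) stop("all degree-day requirements must be positive")
  thr <- list(
    OE = thermal_thresholds(eggLDT, eggUDT),
    L  = thermal_thresholds(larvaeLDT, larvaeUDT),
    P  = thermal_thresholds(pupaeLDT, pupaeUDT),
    A  = thermal_thresholds(adultLDT, adultUDT),
    E  = thermal_thresholds(eggLDT, eggUDT))
  structure(list(
    thresholds = thr,
    # per-stage durations; OE is per-cohort, E terminates at its event
    stage_dd = c(OE = NA_real_, L = larvaeDD, P = pupDD, A = adultDD, E = eggDD),
    event_dd = c(OE = NA_real_, L = larvaeEventDD, P = pupaeEventDD,
                 A = adultEventDD, E = eggEventDD),
    distro_mean = distro_mean, distro_var = distro_var,
    xdist1 = xdist1, xdist2 = xdist2,
    distro_shape = distro_shape, ncohorts = as.integer(ncohorts),
    obligate_diapause = isTRUE(obligate_diapause) || identical(obligate_diapause, 1),
    stress = stress),
    class = "species_params")
}

#' Read / write a species parameter file
#'
#' Flat `key = value` text files using the standard parameter codes
#' (`eggLDT`, `larvaeDD`, `distro_mean`, `xdist1`, ...). The packaged
#' spotted-lanternfly file is at
#' `system.file("extdata", "spotted_lanternfly.params", package = "slfrisk")`.
#'
#' @param path File path.
#' @return [species_params()] for `read_species_params()`; the path,
#'   invisibly, for `write_species_params()`.
#' @export
read_species_params <- function(path) {
  cfg <- read_flat_config(path)
  num <- function(k, default = NULL) {
    if (is.null(cfg[[k]])) {
      if (is.null(default)) stop("parameter file missing key: ", k)
      default
    } else as.numeric(cfg[[k]])
  }
  species_params(
    eggLDT = num("eggLDT"), larvaeLDT = num("larvaeLDT"),
    pupaeLDT = num("pupaeLDT"), adultLDT = num("adultLDT"),
    eggUDT = num("eggUDT"), larvaeUDT = num("larvaeUDT"),
    pupaeUDT = num("pupaeUDT"), adultUDT = num("adultUDT"),
    eggDD = num("eggDD"), larvaeDD = num("larvaeDD"),
    pupDD = num("pupDD"), adultDD = num("adultDD"),
    larvaeEventDD = num("larvaeEventDD"), pupaeEventDD = num("pupaeEventDD"),
    adultEventDD = num("adultEventDD"), eggEventDD = num("eggEventDD"),
    distro_mean = num("distro_mean"), distro_var = num("distro_var"),
    xdist1 = num("xdist1"), xdist2 = num("xdist2"),
    distro_shape = if (is.null(cfg$distro_shape)) "normal" else cfg$distro_shape,
    ncohorts = num("ncohorts", 7),
    obligate_diapause = num("obligate_diapause", 1) == 1,
    stress = stress_params(
      coldstress_threshold = num("coldstress_threshold", -16),
      coldstress_units_max1 = num("coldstress_units_max1", 300),
      coldstress_units_max2 = num("coldstress_units_max2", 475),
      heatstress_threshold = num("heatstress_threshold", 37),
      heatstress_units_max1 = num("heatstress_units_max1", 115),
      heatstress_units_max2 = num("heatstress_units_max2", 175)))
}

#' @rdname read_species_params
#' @param params A [species_params()] object.
#' @export
write_species_params <- function(params, path) {
  stopifnot(inherits(params, "species_params"))
  s <- params$stress
  cfg <- list(
    eggLDT = params$thresholds$OE$ldt, larvaeLDT = params$thresholds$L$ldt,
    pupaeLDT = params$thresholds$P$ldt, adultLDT = params$thresholds$A$ldt,
    eggUDT = params$thresholds$OE$udt, larvaeUDT = params$thresholds$L$udt,
    pupaeUDT = params$thresholds$P$udt, adultUDT = params$thresholds$A$udt,
    eggDD = params$stage_dd[["E"]], larvaeDD = params$stage_dd[["L"]],
    pupDD = params$stage_dd[["P"]], adultDD = params$stage_dd[["A"]],
    OWEventDD = "varies",
    larvaeEventDD = params$event_dd[["L"]], pupaeEventDD = params$event_dd[["P"]],
    adultEventDD = params$event_dd[["A"]], eggEventDD = params$event_dd[["E"]],
    coldstress_threshold = s$coldstress_threshold,
    coldstress_units_max1 = s$coldstress_units_max1,
    coldstress_units_max2 = s$coldstress_units_max2,
    heatstress_threshold = s$heatstress_threshold,
    heatstress_units_max1 = s$heatstress_units_max1,
    heatstress_units_max2 = s$heatstress_units_max2,
    distro_mean = params$distro_mean, distro_var = params$distro_var,
    xdist1 = params$xdist1, xdist2 = params$xdist2,
    distro_shape = params$distro_shape, ncohorts = params$ncohorts,
    stgorder = STAGES,
    obligate_diapause = as.integer(params$obligate_diapause),
    calctype = "triangle")
  write_flat_config(cfg, path)
}

#' Build the time-distributed cohort set
#'
#' Discretizes the overwintered-egg developmental-completion distribution
#' into `ncohorts` cohorts: the interval `[xdist1, xdist2]` is split into
#' equal-width bins, each cohort's hatch requirement is its bin midpoint,
#' and its weight is the normal (`mean = distro_mean`, `var = distro_var`)
#' probability mass of the bin renormalized over the truncated range, so
#' the weights sum to 1.
#'
#' @param params A [species_params()] object.
#' @return A `cohort_set`: data frame with columns `requirement`
#'   (degree-days) and `weight`.
#' @export
build_cohorts <- function(params) {
  stopifnot(inherits(params, "species_params"))
  n <- params$ncohorts
  if (n < 1) stop("ncohorts must be >= 1")
  x1 <- params$xdist1; x2 <- params$xdist2
  if (x2 <= x1) stop("xdist2 must exceed xdist1")
  sd <- sqrt(params$distro_var)
  edges <- seq(x1, x2, length.out = n + 1)
  mids <- (edges[-1] + edges[-(n + 1)]) / 2
  mass <- stats::pnorm(edges[-1], params$distro_mean, sd) -
    stats::pnorm(edges[-(n + 1)], params$distro_mean, sd)
  w <- mass / sum(mass)
  structure(data.frame(requirement = mids, weight = w),
            class = c("cohort_set", "data.frame"))
}

# Core daily-stepping engine over a set of cells given as matrices
# tmin/tmax [ncell x nday]. Returns event DOYs [ncell x 5 events x ncohorts]
# and (optionally) the full per-day stage/accumulator record (for
# trajectory extraction; intended for single cells).
.run_cells <- function(tmin, tmax, params, cohorts, record_states = FALSE) {
  ncell <- nrow(tmin); nday <- ncol(tmin)
  ncoh <- nrow(cohorts)
  # degree-days per cell-day for each distinct threshold pair
  pair_key <- vapply(STAGES, function(s)
    paste0(params$thresholds[[s]]$ldt, "_", params$thresholds[[s]]$udt), "")
  upairs <- unique(pair_key)
  dd_by_pair <- lapply(upairs, function(k) {
    thr <- params$thresholds[[STAGES[match(k, pair_key)]]]
    matrix(single_triangle_dd(as.vector(tmin), as.vector(tmax), thr), ncell, nday)
  })
  names(dd_by_pair) <- upairs
  stage_pair <- match(pair_key, upairs)

  # cells with any missing day carry no predictions
  valid <- !apply(is.na(tmin) | is.na(tmax), 1, any)

  event_doy <- array(NA_real_, c(ncell, 5, ncoh),
                     dimnames = list(NULL, EVENTS, NULL))
  states <- if (record_states)
    array(NA_integer_, c(ncell, nday, ncoh)) else NULL
  acc_rec <- if (record_states)
    array(NA_real_, c(ncell, nday, ncoh)) else NULL

  for (k in seq_len(ncoh)) {
    req <- c(cohorts$requirement[k], params$stage_dd[["L"]],
             params$stage_dd[["P"]], params$stage_dd[["A"]], Inf)
    evd <- c(cohorts$requirement[k], params$event_dd[["L"]],
             params$event_dd[["P"]], params$event_dd[["A"]],
             params$event_dd[["E"]])
    stage <- ifelse(valid, 1L, 0L)   # 0 = invalid, 6 = done
    acc <- numeric(ncell)
    got <- matrix(FALSE, ncell, 5)
    for (d in seq_len(nday)) {
      active <- stage >= 1L & stage <= 5L
      if (any(active)) {
        for (s in unique(stage[active])) {
          idx <- which(stage == s)
          acc[idx] <- acc[idx] + dd_by_pair[[stage_pair[s]]][idx, d]
        }
        # record events and resolve transitions; the loop re-checks after
        # each transition so a stage crossed entirely by one day's
        # carry-over still registers its event
        repeat {
          changed <- FALSE
          for (s in 1:5) {
            hit <- which(stage == s & !got[, s] & acc >= evd[s])
            if (length(hit)) {
              event_doy[hit, s, k] <- d
              got[hit, s] <- TRUE
              changed <- TRUE
              if (s == 5L) stage[hit] <- 6L  # obligate diapause: cycle done
            }
          }
          cand <- which(stage >= 1L & stage <= 4L)
          tr <- cand[acc[cand] >= req[stage[cand]]]
          if (length(tr)) {
            acc[tr] <- acc[tr] - req[stage[tr]]  # carry excess into next stage
            stage[tr] <- stage[tr] + 1L
            changed <- TRUE
          }
          if (!changed) break
        }
      }
      if (record_states) {
        states[, d, k] <- stage
        acc_rec[, d, k] <- acc
      }
    }
  }
  list(event_doy = event_doy, states = states, acc = acc_rec, valid = valid)
}

.check_full_year <- function(grid) {
  if (format(grid$dates[1], "%m-%d") != "01-01")
    stop("annual run requires a grid starting 1 January")
  nd <- n_days(grid)
  if (!nd %in% c(365L, 366L))
    stop("annual run requires 365 or 366 day layers, got ", nd)
}

#' Run the annual cohort-structured phenology cycle
#'
#' Steps every cohort through the life cycle (overwintered egg, nymphs,
#' pre-oviposition adults, ovipositing adults, first-generation egg) in
#' every grid cell, one day at a time, accumulating single-triangle
#' degree-days under the current stage's thresholds. The overwintered egg
#' completes (egg hatch) when cumulative degree-days reach the cohort's
#' hatch requirement; later events fire when the within-stage accumulator
#' reaches the stage's event trigger. Excess degree-days on a transition
#' day carry into the next stage. After the diapausing-egg event a cohort
#' stops (obligate diapause). Events that never occur are `NA`, as is
#' every event in cells with missing climate on any day.
#'
#' @param grid A full-year [climate_grid()] starting 1 January.
#' @param params A [species_params()] object.
#' @param cohorts A [build_cohorts()] cohort set (built from `params` when
#'   omitted).
#' @return An `event_maps` object: per-event arrays `[row, col, cohort]` of
#'   1-based day-of-year, plus cohort weights and georeferencing.
#' @export
run_annual_cycle <- function(grid, params, cohorts = build_cohorts(params)) {
  stopifnot(inherits(grid, "climate_grid"), inherits(params, "species_params"))
  .check_full_year(grid)
  d <- dim(grid$tmin)
  ncell <- d[1] * d[2]
  res <- .run_cells(matrix(grid$tmin, ncell, d[3]),
                    matrix(grid$tmax, ncell, d[3]),
                    params, cohorts)
  doy <- lapply(seq_along(EVENTS), function(e)
    array(res$event_doy[, e, ], c(d[1], d[2], nrow(cohorts))))
  names(doy) <- EVENTS
  structure(list(doy = doy, weights = cohorts$weight,
                 requirements = cohorts$requirement,
                 dims = d[1:2], extent = grid$extent, crs = grid$crs,
                 year = as.integer(format(grid$dates[1], "%Y")),
                 valid = matrix(res$valid, d[1], d[2])),
            class = "event_maps")
}

#' @export
print.event_maps <- function(x, ...) {
  cat("<event_maps> ", x$dims[1], " x ", x$dims[2], " cells, ",
      length(x$weights), " cohorts, year ", x$year, "\n", sep = "")
  for (e in EVENTS) {
    first <- aggregate_cohort_events(x, e, "earliest")
    occ <- sum(!is.na(first))
    cat(sprintf("  %-16s occurs in %d/%d cells\n", e, occ, prod(x$dims)))
  }
  invisible(x)
}

#' Collapse cohort event maps to a single raster
#'
#' `earliest` takes the minimum day-of-year over cohorts (first occurrence
#' of the event in the cell); `weighted_mean` takes the cohort-weighted
#' average day-of-year over the cohorts in which the event occurred, with
#' weights renormalized over those cohorts. Cells where no cohort has the
#' event are `NA`.
#'
#' @param maps An `event_maps` object from [run_annual_cycle()].
#' @param event One of `EVENTS`.
#' @param mode `"earliest"` or `"weighted_mean"`.
#' @return A matrix `[row, col]` of day-of-year.
#' @export
aggregate_cohort_events <- function(maps, event, mode = c("earliest", "weighted_mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(maps, "event_maps"))
  if (!event %in% names(maps$doy)) stop("unknown event: ", event)
  a <- maps$doy[[event]]
  d <- dim(a)
  m <- matrix(a, d[1] * d[2], d[3])
  out <- if (mode == "earliest") {
    suppressWarnings(apply(m, 1, min, na.rm = TRUE))
  } else {
    w <- maps$weights
    apply(m, 1, function(x) {
      ok <- !is.na(x)
      if (!any(ok)) return(NA_real_)
      sum(w[ok] * x[ok]) / sum(w[ok])
    })
  }
  out[!is.finite(out)] <- NA_real_
  matrix(out, d[1], d[2])
}

#' Per-day life-stage trajectory of one grid cell
#'
#' Re-runs the engine for a single cell and returns the stage occupied and
#' the within-stage degree-day accumulator for every day and cohort. Stage
#' codes: `OE`, `L`, `P`, `A`, `E`, `done` (cycle complete), `nodata`.
#'
#' @param grid A full-year [climate_grid()].
#' @param params A [species_params()] object.
#' @param row,col Cell indices (row 1 = northernmost row).
#' @param cohorts Optional [build_cohorts()] result.
#' @return A data frame with columns `doy`, `date`, `cohort`, `stage`,
#'   `within_stage_dd`.
#' @export
cell_trajectory <- function(grid, params, row, col,
                            cohorts = build_cohorts(params)) {
  stopifnot(inherits(grid, "climate_grid"))
  .check_full_year(grid)
  nd <- n_days(grid)
  res <- .run_cells(matrix(grid$tmin[row, col, ], 1, nd),
                    matrix(grid$tmax[row, col, ], 1, nd),
                    params, cohorts, record_states = TRUE)
  ncoh <- nrow(cohorts)
  lab <- c("nodata", STAGES, "done")
  data.frame(
    doy = rep(seq_len(nd), ncoh),
    date = rep(grid$dates, ncoh),
    cohort = rep(seq_len(ncoh), each = nd),
    stage = lab[as.vector(res$states[1, , ]) + 1L],
    within_stage_dd = as.vector(res$acc[1, , ]))
}
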