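# single-band raster output: 32-bit TIFF + JSON sidecar (extent, crs,
# scaling), same packing scheme as the climate stacks
.write_raster <- function(m, path, extent, crs = "EPSG:4326") {
  rng <- if (all(is.na(m))) c(0, 1) else range(m, na.rm = TRUE)
  tiff::writeTIFF(.encode_layer(m, rng[1], rng[2]), path, bits.per.sample = 32L)
  meta <- list(extent = extent, crs = crs, scale = rng, dims = dim(m))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a single-band raster written by the pipeline
#'
#' @param path Path to a `.tif` written by [run_pipeline()] (its `.json`
#'   sidecar must sit alongside).
#' @return A list: `values` matrix, `extent`, `crs`.
#' @export
read_raster <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  r <- as.numeric(meta$scale)
  list(values = .decode_layer(tiff::readTIFF(path), r[1], r[2]),
       extent = as.numeric(meta$extent), crs = meta$crs)
}

#' Render a raster to a PNG map
#'
#' Styles: `event_doy` (continuous day-of-year ramp, annotated range),
#' `stress` (sequential ramp of stress units), `exclusion` (category
#' colors: suitable, moderate = medium gray, severe = dark gray) and
#' `year_count` (discrete count ramp). Cells that are `NA` — e.g.
#' insufficient degree-day accumulation for an event — are light gray.
#' When an `exclusion` map is supplied with an `event_doy` raster, cells
#' under moderate or severe stress are grayed over the event colors,
#' matching the map-product conventions.
#'
#' @param m Numeric matrix (row 1 = northernmost row).
#' @param style One of `"event_doy"`, `"stress"`, `"exclusion"`,
#'   `"year_count"`.
#' @param file Output PNG path.
#' @param extent `c(xmin, xmax, ymin, ymax)` for the axes.
#' @param exclusion Optional `exclusion_map` overlay (event_doy style).
#' @param title Plot title.
#' @return The file path, invisibly.
#' @export
render_map <- function(m, style = c("event_doy", "stress", "exclusion", "year_count"),
                       file, extent = c(0, ncol(m), 0, nrow(m)),
                       exclusion = NULL, title = style) {
  style <- match.arg(style)
  na_col <- "grey85"
  mod_col <- "grey55"
  sev_col <- "grey30"
  ramp_cols <- function(v, pal) {
    cols <- matrix(na_col, nrow(v), ncol(v))
    ok <- is.finite(v)
    if (any(ok)) {
      r <- range(v[ok])
      idx <- if (r[2] > r[1])
        pmin(64L, pmax(1L, 1L + floor(63.999 * (v[ok] - r[1]) / (r[2] - r[1]))))
      else rep(32L, sum(ok))
      cols[ok] <- pal[idx]
    }
    cols
  }
  legend_items <- NULL
  if (style == "event_doy") {
    pal <- grDevices::hcl.colors(64, "Viridis")
    cols <- ramp_cols(m, pal)
    if (!is.null(exclusion)) {
      cols[!is.na(exclusion$combined) & exclusion$combined == 1L] <- mod_col
      cols[!is.na(exclusion$combined) & exclusion$combined == 2L] <- sev_col
    }
    rng <- if (any(is.finite(m))) range(m[is.finite(m)]) else c(NA, NA)
    legend_items <- c(
      sprintf("DOY %s (earliest)", rng[1]), sprintf("DOY %s (latest)", rng[2]),
      if (!is.null(exclusion)) c("excl.-moderate", "excl.-severe"),
      "no event / nodata")
    legend_fill <- c(pal[1], pal[64],
                     if (!is.null(exclusion)) c(mod_col, sev_col), na_col)
  } else if (style == "stress") {
    pal <- grDevices::hcl.colors(64, "Inferno", rev = TRUE)
    cols <- ramp_cols(m, pal)
    rng <- if (any(is.finite(m))) signif(range(m[is.finite(m)]), 4) else c(NA, NA)
    legend_items <- c(sprintf("%s units", rng[1]), sprintf("%s units", rng[2]),
                      "nodata")
    legend_fill <- c(pal[1], pal[64], na_col)
  } else if (style == "exclusion") {
    cat_cols <- c("khaki1", mod_col, sev_col)
    cols <- matrix(na_col, nrow(m), ncol(m))
    ok <- is.finite(m)
    cols[ok] <- cat_cols[m[ok] + 1L]
    legend_items <- c("not excluded", "excl.-moderate", "excl.-severe", "nodata")
    legend_fill <- c(cat_cols, na_col)
  } else { # year_count
    kmax <- if (any(is.finite(m))) max(m[is.finite(m)]) else 1
    pal <- grDevices::hcl.colors(max(kmax + 1, 2), "Blue-Yellow")
    cols <- matrix(na_col, nrow(m), ncol(m))
    ok <- is.finite(m)
    cols[ok] <- pal[m[ok] + 1L]
    legend_items <- c(paste0(0:kmax, " yr"), "nodata")
    legend_fill <- c(pal[seq_len(kmax + 1)], na_col)
  }
  grDevices::png(file, width = 720, height = 560)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 3, 1))
  graphics::plot(NA, xlim = extent[1:2], ylim = extent[3:4], xlab = "x",
                 ylab = "y", main = title, asp = NA)
  graphics::rasterImage(grDevices::as.raster(cols), extent[1], extent[3],
                        extent[2], extent[4], interpolate = FALSE)
  graphics::legend("topright", legend = legend_items, fill = legend_fill,
                   bg = "white", cex = 0.8)
  invisible(file)
}

#' Run configuration for the full pipeline
#'
#' @param out_dir Output directory (created if needed).
#' @param years Integer vector of model years.
#' @param climate `"synthetic"` or a directory of climate stacks readable
#'   by [read_climate()].
#' @param spec [synthetic_climate_spec()] used when `climate =
#'   "synthetic"`; its seed is offset by the year index so each year draws
#'   independent weather.
#' @param params [species_params()] or the path of a parameter file.
#' @param aggregate_factor Optional block-mean coarsening factor.
#' @param cohort_mode Event aggregation written to map products:
#'   `"earliest"`, `"weighted_mean"`, or both.
#' @param render Write PNG renderings next to the TIFFs.
#' @param seed Base random seed for the synthetic climate.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, years, climate = "synthetic",
                       spec = synthetic_climate_spec(),
                       params = species_params(), aggregate_factor = 1,
                       cohort_mode = c("earliest", "weighted_mean"),
                       render = TRUE, seed = 1L) {
  if (length(years) < 1) stop("years must be non-empty")
  if (is.character(params)) params <- read_species_params(params)
  structure(list(out_dir = out_dir, years = as.integer(years),
                 climate = climate, spec = spec, params = params,
                 aggregate_factor = as.integer(aggregate_factor),
                 cohort_mode = match.arg(cohort_mode, several.ok = TRUE),
                 render = isTRUE(render), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full phenology + suitability pipeline
#'
#' For each configured year: obtain the daily climate (synthetic or read
#' from disk), run the annual cohort cycle, write the five phenological
#' event maps (per requested cohort aggregation), accumulate and write
#' cold/heat stress rasters and the exclusion map; across years, write the
#' potential-distribution year-count map. Every product is listed in a
#' manifest with MD5 checksums, and a log records parameters and cell
#' counts. Any stage failure aborts with the stage named.
#'
#' @param config A [run_config()].
#' @return The manifest data frame (`file`, `md5`, `bytes`), invisibly
#'   written to `manifest.csv` in the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  log_lines <- c(sprintf("run started; years: %s; climate: %s; seed: %d",
                         paste(config$years, collapse = ","), config$climate,
                         config$seed))
  at_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- character(0)
  put <- function(m, name, extent, style = NULL, exclusion = NULL) {
    p <- file.path(config$out_dir, paste0(name, ".tif"))
    .write_raster(m, p, extent)
    files <<- c(files, p, paste0(p, ".json"))
    if (config$render && !is.null(style)) {
      q <- file.path(config$out_dir, paste0(name, ".png"))
      render_map(m, style, q, extent, exclusion = exclusion, title = name)
      files <<- c(files, q)
    }
  }
  cohorts <- build_cohorts(config$params)
  excl_by_year <- list()
  last_extent <- NULL
  for (i in seq_along(config$years)) {
    yr <- config$years[i]
    grid <- at_stage("climate", {
      g <- if (identical(config$climate, "synthetic")) {
        sp <- config$spec
        sp$seed <- config$seed + i - 1L
        generate_synthetic_climate(sp, yr)
      } else read_climate(config$climate, yr)
      if (config$aggregate_factor > 1)
        g <- aggregate_resolution(g, config$aggregate_factor)
      g
    })
    events <- at_stage("phenology", run_annual_cycle(grid, config$params, cohorts))
    excl <- at_stage("suitability", exclusion_from_grid(grid, config$params$stress))
    excl_by_year[[as.character(yr)]] <- excl
    last_extent <- grid$extent
    at_stage("outputs", {
      for (ev in EVENTS) for (mode in config$cohort_mode)
        put(aggregate_cohort_events(events, ev, mode),
            sprintf("%d_%s_%s", yr, ev, mode), grid$extent,
            style = "event_doy", exclusion = excl)
      put(excl$cold_units, sprintf("%d_cold_stress_units", yr), grid$extent,
          style = "stress")
      put(excl$heat_units, sprintf("%d_heat_stress_units", yr), grid$extent,
          style = "stress")
      put(excl$combined + 0, sprintf("%d_exclusion", yr), grid$extent,
          style = "exclusion")
    })
    nvalid <- sum(events$valid)
    log_lines <- c(log_lines, sprintf(
      "year %d: %d/%d valid cells; excluded (moderate/severe): %d/%d",
      yr, nvalid, prod(events$dims),
      sum(excl$combined == 1L, na.rm = TRUE),
      sum(excl$combined == 2L, na.rm = TRUE)))
  }
  at_stage("combine", put(combine_years(excl_by_year) + 0,
                          "potential_distribution_years", last_extent,
                          style = "year_count"))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = file.size(files))
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
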