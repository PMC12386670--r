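#' Daily temperature grid
#'
#' Container for a georeferenced stack of daily minimum and maximum
#' temperatures. Days are stored along the third array dimension; row 1 is
#' the northernmost row (north-up orientation). Missing cells are `NA`.
#'
#' @param tmin,tmax Numeric arrays `[row, col, day]` of daily minimum and
#'   maximum temperature (degrees C), identical dimensions.
#' @param dates `Date` vector, one per day layer, strictly consecutive.
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` in `crs` units.
#' @param crs Coordinate reference system label (default `"EPSG:4326"`,
#'   longitude/latitude degrees).
#' @param fix_invalid If `TRUE`, cells where `tmax < tmin` are set to `NA`
#'   (count reported with a message) instead of raising an error.
#' @return An object of class `climate_grid`.
#' @export
climate_grid <- function(tmin, tmax, dates, extent, crs = "EPSG:4326",
                         fix_invalid = FALSE) {
  if (length(dim(tmin)) != 3 || !identical(dim(tmin), dim(tmax)))
    stop("tmin and tmax must be 3-d arrays [row, col, day] of identical shape")
  dates <- as.Date(dates)
  if (dim(tmin)[3] != length(dates))
    stop("number of day layers (", dim(tmin)[3], ") != number of dates (",
         length(dates), ")")
  if (length(dates) > 1 && any(diff(as.integer(dates)) != 1)) {
    gap <- dates[which(diff(as.integer(dates)) != 1)[1]]
    stop("dates are not consecutive: gap after ", format(gap))
  }
  extent <- as.numeric(extent)
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("extent must be c(xmin, xmax, ymin, ymax) with xmax > xmin, ymax > ymin")
  bad <- !is.na(tmin) & !is.na(tmax) & tmax < tmin
  if (any(bad)) {
    if (!fix_invalid)
      stop(sum(bad), " cell-day(s) violate tmax >= tmin")
    message(sum(bad), " cell-day(s) with tmax < tmin set to nodata")
    tmin[bad] <- NA_real_
    tmax[bad] <- NA_real_
  }
  # a cell missing either variable on a day is missing both
  miss <- is.na(tmin) != is.na(tmax)
  tmin[miss] <- NA_real_
  tmax[miss] <- NA_real_
  structure(list(tmin = tmin, tmax = tmax, dates = dates,
                 extent = extent, crs = crs),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  d <- dim(x$tmin)
  cat("<climate_grid> ", d[1], " x ", d[2], " cells, ", d[3], " days (",
      format(x$dates[1]), " to ", format(x$dates[length(x$dates)]), ")\n",
      "  extent: ", paste(signif(x$extent, 7), collapse = ", "),
      "  crs: ", x$crs, "\n", sep = "")
  invisible(x)
}

#' @rdname climate_grid
#' @param x A `climate_grid`.
#' @export
n_days <- function(x) dim(x$tmin)[3]

#' Cell-centre coordinates and nearest-cell lookup
#'
#' `grid_lats()`/`grid_lons()` return cell-centre y (row 1 = northernmost)
#' and x coordinates. `cell_from_xy()` maps point coordinates (in the
#' grid's CRS) to `(row, col)` of the containing cell, `NA` outside the
#' extent.
#'
#' @param grid A [climate_grid()] or any object with `$extent` and matrix
#'   dimensions `dims`.
#' @param dims Integer `c(nrow, ncol)`; defaults to the grid's dimensions.
#' @export
grid_lats <- function(grid, dims = dim(grid$tmin)[1:2]) {
  e <- grid$extent
  dy <- (e[4] - e[3]) / dims[1]
  e[4] - (seq_len(dims[1]) - 0.5) * dy
}

#' @rdname grid_lats
#' @export
grid_lons <- function(grid, dims = dim(grid$tmin)[1:2]) {
  e <- grid$extent
  dx <- (e[2] - e[1]) / dims[2]
  e[1] + (seq_len(dims[2]) - 0.5) * dx
}

#' @rdname grid_lats
#' @param x,y Point coordinates in the grid's CRS (e.g. longitude,
#'   latitude).
#' @export
cell_from_xy <- function(grid, x, y, dims = dim(grid$tmin)[1:2]) {
  e <- grid$extent
  dx <- (e[2] - e[1]) / dims[2]
  dy <- (e[4] - e[3]) / dims[1]
  col <- floor((x - e[1]) / dx) + 1
  row <- floor((e[4] - y) / dy) + 1
  # points on the max edge belong to the last cell
  col[x == e[2]] <- dims[2]
  row[y == e[3]] <- dims[1]
  out <- x < e[1] | x > e[2] | y < e[3] | y > e[4] | is.na(x) | is.na(y)
  row[out] <- NA_integer_
  col[out] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# temperature values are stored in TIFF as v -> (v - vmin)/(vmax - vmin) *
# 0.9 + 0.05; NA cells are stored as 0 and recovered as values < 0.025
.encode_layer <- function(m, vmin, vmax) {
  s <- if (vmax > vmin) (m - vmin) / (vmax - vmin) * 0.9 + 0.05 else m * 0 + 0.5
  s[is.na(m)] <- 0
  s
}

.decode_layer <- function(s, vmin, vmax) {
  m <- if (vmax > vmin) (s - 0.05) / 0.9 * (vmax - vmin) + vmin else s * 0 + vmin
  m[s < 0.025] <- NA_real_
  m
}

#' Write and read daily climate grids
#'
#' Grids are stored as one multiband 32-bit TIFF per variable and year
#' (`<prefix>_tmin_<year>.tif`, `<prefix>_tmax_<year>.tif`, one band per
#' day) together with a JSON sidecar (`<prefix>_meta_<year>.json`) holding
#' the extent, CRS, dates, and the linear scaling applied to pack
#' temperatures into TIFF samples. With `layout = "daily"` each day is
#' written to its own file (`<prefix>_tmin_<YYYY-MM-DD>.tif`).
#'
#' @param grid A [climate_grid()].
#' @param dir Directory for the files (created if needed).
#' @param prefix File name prefix.
#' @param layout `"multiband"` (default) or `"daily"`.
#' @return `write_climate()` returns the sidecar path invisibly;
#'   `read_climate()` returns a validated [climate_grid()]. Cells read with
#'   `tmax < tmin` (possible only with externally produced files) are set
#'   to nodata and counted in a message.
#' @export
write_climate <- function(grid, dir, prefix = "climate",
                          layout = c("multiband", "daily")) {
  layout <- match.arg(layout)
  stopifnot(inherits(grid, "climate_grid"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  year <- as.integer(format(grid$dates[1], "%Y"))
  rng <- function(a) if (all(is.na(a))) c(0, 1) else range(a, na.rm = TRUE)
  r1 <- rng(grid$tmin); r2 <- rng(grid$tmax)
  nd <- n_days(grid)
  enc <- function(var, r) lapply(seq_len(nd), function(d)
    .encode_layer(grid[[var]][, , d, drop = TRUE], r[1], r[2]))
  if (layout == "multiband") {
    tiff::writeTIFF(enc("tmin", r1),
                    file.path(dir, sprintf("%s_tmin_%d.tif", prefix, year)),
                    bits.per.sample = 32L)
    tiff::writeTIFF(enc("tmax", r2),
                    file.path(dir, sprintf("%s_tmax_%d.tif", prefix, year)),
                    bits.per.sample = 32L)
  } else {
    e1 <- enc("tmin", r1); e2 <- enc("tmax", r2)
    for (d in seq_len(nd)) {
      day <- format(grid$dates[d])
      tiff::writeTIFF(e1[[d]],
                      file.path(dir, sprintf("%s_tmin_%s.tif", prefix, day)),
                      bits.per.sample = 32L)
      tiff::writeTIFF(e2[[d]],
                      file.path(dir, sprintf("%s_tmax_%s.tif", prefix, day)),
                      bits.per.sample = 32L)
    }
  }
  meta <- list(extent = grid$extent, crs = grid$crs,
               dates = format(grid$dates), layout = layout,
               scale = list(tmin = r1, tmax = r2),
               dims = dim(grid$tmin)[1:2])
  meta_path <- file.path(dir, sprintf("%s_meta_%d.json", prefix, year))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(meta_path)
}

#' @rdname write_climate
#' @param year Calendar year of the grid to read.
#' @export
read_climate <- function(dir, year, prefix = "climate") {
  meta_path <- file.path(dir, sprintf("%s_meta_%d.json", prefix, year))
  if (!file.exists(meta_path)) stop("sidecar not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  dates <- as.Date(meta$dates)
  r1 <- as.numeric(meta$scale$tmin); r2 <- as.numeric(meta$scale$tmax)
  read_var <- function(var, r) {
    if (identical(meta$layout, "daily")) {
      paths <- file.path(dir, sprintf("%s_%s_%s.tif", prefix, var, format(dates)))
      miss <- !file.exists(paths)
      if (any(miss))
        stop(var, " layer missing for date(s): ",
             paste(format(dates[miss]), collapse = ", "))
      layers <- lapply(paths, function(p) tiff::readTIFF(p))
    } else {
      p <- file.path(dir, sprintf("%s_%s_%d.tif", prefix, var, year))
      if (!file.exists(p)) stop(var, " file missing: ", p)
      layers <- tiff::readTIFF(p, all = TRUE)
      if (length(layers) != length(dates))
        stop(var, ": ", length(layers), " bands but ", length(dates), " dates")
    }
    dm <- dim(layers[[1]])
    a <- array(NA_real_, c(dm[1], dm[2], length(layers)))
    for (d in seq_along(layers)) a[, , d] <- .decode_layer(layers[[d]], r[1], r[2])
    a
  }
  tmin <- read_var("tmin", r1)
  tmax <- read_var("tmax", r2)
  if (!identical(dim(tmin), dim(tmax)))
    stop("tmin and tmax rasters have different shapes")
  climate_grid(tmin, tmax, dates, as.numeric(meta$extent), meta$crs,
               fix_invalid = TRUE)
}

# block mean over f x f cells, NA-aware (all-NA block -> NA);
# trailing partial blocks are averaged over the cells they contain
.block_mean <- function(m, f) {
  rg <- ceiling(seq_len(nrow(m)) / f)
  cg <- ceiling(seq_len(ncol(m)) / f)
  v <- m
  v[is.na(v)] <- 0
  n <- (!is.na(m)) + 0
  sums <- t(rowsum(t(rowsum(v, rg)), cg))
  cnts <- t(rowsum(t(rowsum(n, rg)), cg))
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out
}

#' Aggregate a climate grid to coarser resolution
#'
#' Block-mean aggregation by an integer factor, mirroring the coarsening of
#' 1-km daily grids to a 4-km model resolution. Valid cells within each
#' `factor` x `factor` block are averaged; a block that is entirely nodata
#' stays nodata. Trailing partial blocks are averaged over the cells they
#' contain; the extent is unchanged.
#'
#' @param grid A [climate_grid()].
#' @param factor Integer aggregation factor, `>= 1`.
#' @return A coarser [climate_grid()].
#' @export
aggregate_resolution <- function(grid, factor) {
  stopifnot(inherits(grid, "climate_grid"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("factor must be an integer >= 1")
  d <- dim(grid$tmin)
  if (factor > d[1] || factor > d[2])
    stop("factor (", factor, ") exceeds grid dimension (", d[1], " x ", d[2], ")")
  if (factor == 1) return(grid)
  nd <- d[3]
  d2 <- c(ceiling(d[1] / factor), ceiling(d[2] / factor))
  tmin <- array(NA_real_, c(d2, nd))
  tmax <- array(NA_real_, c(d2, nd))
  for (day in seq_len(nd)) {
    tmin[, , day] <- .block_mean(grid$tmin[, , day, drop = TRUE], factor)
    tmax[, , day] <- .block_mean(grid$tmax[, , day, drop = TRUE], factor)
  }
  climate_grid(tmin, tmax, grid$dates, grid$extent, grid$crs)
}

#' Coldest-week Tmin / hottest-week Tmax raster
#'
#' Per cell, the extreme over the year of the 7-day rolling mean of daily
#' Tmin (coldest week) or Tmax (hottest week). Every alignment of the
#' 7-day window is considered, so the coldest rolling week bounds any
#' calendar-week value from below. A cell with any missing day is nodata.
#'
#' @param grid A full-year [climate_grid()] (at least 7 days required).
#' @param which `"coldest_week_tmin"` or `"hottest_week_tmax"`.
#' @return A matrix `[row, col]` of degrees C.
#' @export
weekly_extreme <- function(grid, which = c("coldest_week_tmin", "hottest_week_tmax")) {
  which <- match.arg(which)
  stopifnot(inherits(grid, "climate_grid"))
  nd <- n_days(grid)
  if (nd < 7) stop("grid has ", nd, " days; at least 7 required")
  a <- if (which == "coldest_week_tmin") grid$tmin else grid$tmax
  d <- dim(a)
  m <- matrix(a, nrow = d[1] * d[2], ncol = d[3])       # cells x days
  roll <- t(apply(m, 1, function(x) as.numeric(stats::filter(x, rep(1 / 7, 7), sides = 1))))
  roll <- roll[, 7:nd, drop = FALSE]                    # complete windows only
  f <- if (which == "coldest_week_tmin") function(x) min(x) else function(x) max(x)
  matrix(apply(roll, 1, f), d[1], d[2])
}

#' Synthetic daily-climate specification
#'
#' Parameters for [generate_synthetic_climate()]. The generator emulates a
#' mid-latitude gridded daily product (the model's native input): a mean
#' annual temperature at a reference latitude, a linear meridional lapse, a
#' sinusoidal seasonal cycle peaking in mid-summer, a fixed diurnal range
#' split evenly around the daily mean, and independent Gaussian noise.
#'
#' @param nrow,ncol Grid dimensions.
#' @param lat_range,lon_range Extent edges in decimal degrees.
#' @param base_temp Annual mean temperature (degrees C) at `lat_ref`.
#' @param lat_ref Reference latitude (degrees) for `base_temp`.
#' @param lapse Cooling per degree of latitude northward (degrees C / degree).
#' @param amplitude Seasonal half-range of the daily mean (degrees C).
#' @param diurnal_range Daily `tmax - tmin` (degrees C), `>= 0`.
#' @param noise_sd SD of independent cell-day noise on the daily mean
#'   (degrees C), `>= 0`.
#' @param peak_doy Day of year of the seasonal temperature peak.
#' @param seed Integer RNG seed; a fixed seed reproduces the grid exactly.
#' @return An object of class `synthetic_climate_spec`.
#' @export
synthetic_climate_spec <- function(nrow = 20, ncol = 20,
                                   lat_range = c(35, 45),
                                   lon_range = c(-85, -75),
                                   base_temp = 14, lat_ref = 40,
                                   lapse = 0.8, amplitude = 12,
                                   diurnal_range = 10, noise_sd = 2,
                                   peak_doy = 200, seed = 1L) {
  stopifnot(nrow >= 1, ncol >= 1, diurnal_range >= 0, noise_sd >= 0,
            lat_range[2] > lat_range[1], lon_range[2] > lon_range[1])
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 lat_range = as.numeric(lat_range),
                 lon_range = as.numeric(lon_range),
                 base_temp = base_temp, lat_ref = lat_ref, lapse = lapse,
                 amplitude = amplitude, diurnal_range = diurnal_range,
                 noise_sd = noise_sd, peak_doy = peak_doy,
                 seed = as.integer(seed)),
            class = "synthetic_climate_spec")
}

#' Generate a synthetic daily climate grid
#'
#' Daily mean temperature for a cell at latitude `lat` on day `d`:
#' `base_temp - lapse * (lat - lat_ref) + amplitude * cos(2 * pi * (d -
#' peak_doy) / 365) + noise`, with `tmin = mean - diurnal_range / 2` and
#' `tmax = mean + diurnal_range / 2`. With `noise_sd = 0` the grid is a
#' closed-form function of latitude and day of year.
#'
#' @param spec A [synthetic_climate_spec()].
#' @param year Calendar year (sets the number of days: 365 or 366).
#' @return A [climate_grid()]; bit-for-bit reproducible for a fixed seed.
#' @export
generate_synthetic_climate <- function(spec, year = 2023) {
  stopifnot(inherits(spec, "synthetic_climate_spec"))
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  nd <- length(dates)
  extent <- c(spec$lon_range[1], spec$lon_range[2],
              spec$lat_range[1], spec$lat_range[2])
  dy <- (spec$lat_range[2] - spec$lat_range[1]) / spec$nrow
  lats <- spec$lat_range[2] - (seq_len(spec$nrow) - 0.5) * dy  # row 1 north
  doy <- seq_len(nd)
  seasonal <- spec$amplitude * cos(2 * pi * (doy - spec$peak_doy) / 365)
  base_lat <- spec$base_temp - spec$lapse * (lats - spec$lat_ref)
  tmean <- outer(base_lat, rep(1, spec$ncol)) |>
    array(dim = c(spec$nrow, spec$ncol, nd))
  tmean <- tmean + rep(seasonal, each = spec$nrow * spec$ncol)
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(spec$seed)
    tmean <- tmean + array(stats::rnorm(length(tmean), 0, spec$noise_sd),
                           dim = dim(tmean))
  }
  climate_grid(tmean - spec$diurnal_range / 2, tmean + spec$diurnal_range / 2,
               dates, extent)
}

#' Read or write a flat `key = value` configuration file
#'
#' The format used for species parameter files and synthetic-climate /
#' run configurations: one `key = value` pair per line, `#` comments,
#' numeric values parsed as numbers, comma-separated values as vectors.
#'
#' @param path File path.
#' @return A named list.
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed line in ", path, ": ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (any(is.na(num))) parts else num
  }
  out
}

#' @rdname read_flat_config
#' @param config Named list of scalar or vector values.
#' @export
write_flat_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", paste(config[[k]], collapse = ", ")), character(1))
  writeLines(lines, path)
  invisible(path)
}
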