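# Aggregation of valid terminal points into smoothed, sea-masked 0.25-degree
# frequency grids, and the decision table combining the isotope call with the
# regions the trajectory ensemble reached.

grid_geometry <- function(bbox, cell = 0.25) {
  stopifnot(length(bbox) == 4, bbox[2] > bbox[1], bbox[4] > bbox[3])
  list(lon0 = bbox[1], lat0 = bbox[3],
       nlon = as.integer(ceiling((bbox[2] - bbox[1]) / cell - 1e-9)),
       nlat = as.integer(ceiling((bbox[4] - bbox[3]) / cell - 1e-9)))
}

#' Possible immigration dates for a trap catch
#'
#' The three days ending at the collection date are always possible
#' immigration dates (insects may linger before being trapped); with a
#' monitoring interval longer than a day, the `interval - 1` preceding
#' non-survey days are added, so the analytical period has
#' `3 + interval - 1` dates (3 for daily monitoring, 9 for 7-day intervals).
#'
#' @param collection_date a `Date`.
#' @param monitoring_interval_days trap-monitoring interval (days, >= 1).
#' @return A list of class `"analytical_period"` with the ordered `dates`,
#'   the `collection_date` and the interval.
#' @examples
#' analytical_period(as.Date("2020-05-29"), 1)$dates
#' @export
analytical_period <- function(collection_date, monitoring_interval_days = 1) {
  collection_date <- as.Date(collection_date)
  if (monitoring_interval_days < 1)
    stop("`monitoring_interval_days` must be >= 1")
  n <- 3 + monitoring_interval_days - 1
  dates <- seq(collection_date - n + 1, collection_date, by = "day")
  structure(list(dates = dates, collection_date = collection_date,
                 monitoring_interval_days = monitoring_interval_days),
            class = "analytical_period")
}

#' @export
print.analytical_period <- function(x, ...) {
  cat(sprintf("analytical period: %d dates, %s .. %s (interval %d d)\n",
              length(x$dates), min(x$dates), max(x$dates),
              x$monitoring_interval_days))
  invisible(x)
}

#' Collect valid terminal points over an analytical period
#'
#' For every possible immigration date, builds the full start ensemble
#' (24 hours x starting heights), integrates each trajectory backward, and
#' keeps the terminal point of every valid trajectory.
#'
#' @param site_lat,site_lon trap-site coordinates.
#' @param period an [analytical_period()].
#' @param field a [wind_field()] covering the period plus the maximum flight
#'   duration.
#' @param params a [flight_params()].
#' @return Data frame of terminal points: `lat`, `lon`, `time`, `temp_C`,
#'   `date`, with attribute `"n_trajectories"` (ensemble size before
#'   filtering) and `"invalid_reasons"` (a table).
#' @export
collect_terminal_points <- function(site_lat, site_lon, period, field,
                                    params = flight_params()) {
  stopifnot(inherits(period, "analytical_period"))
  t_need_lo <- as.POSIXct(min(period$dates) -
                          (if (params$duration_mode == "short") 1 else 2),
                          tz = "UTC") + params$dusk_hour_utc * 3600
  if (min(field$time) > t_need_lo ||
      max(field$time) < as.POSIXct(max(period$dates), tz = "UTC") + 23 * 3600)
    stop("wind field does not cover the analytical period plus flight duration")
  pts <- list(); reasons <- character(0); n_tot <- 0L
  for (d in seq_along(period$dates)) {
    ens <- build_start_ensemble(site_lat, site_lon, period$dates[d], params)
    n_tot <- n_tot + nrow(ens)
    for (i in seq_len(nrow(ens))) {
      tr <- integrate_backward(ens[i, ], field, params)
      if (tr$valid) {
        last <- tr$steps[nrow(tr$steps), ]
        pts[[length(pts) + 1L]] <-
          data.frame(lat = last$lat, lon = last$lon, time = last$time,
                     temp_C = last$temp_C, date = period$dates[d])
      } else {
        reasons <- c(reasons, tr$invalid_reason)
      }
    }
  }
  out <- if (length(pts)) do.call(rbind, pts)
         else data.frame(lat = numeric(0), lon = numeric(0),
                         time = as.POSIXct(character(0), tz = "UTC"),
                         temp_C = numeric(0),
                         date = as.Date(character(0)))
  attr(out, "n_trajectories") <- n_tot
  attr(out, "invalid_reasons") <- table(reasons)
  out
}

#' Count terminal points on a 0.25-degree frequency grid
#'
#' Cell membership uses half-open intervals `[west, east) x [south, north)`:
#' a point exactly on a shared edge belongs to the cell whose west/south
#' edge it lies on. Points outside the bounding box are dropped and counted
#' in the `"n_dropped"` attribute.
#'
#' @param points data frame with `lat`, `lon` (e.g. from
#'   [collect_terminal_points()]).
#' @param bbox `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param cell cell size in degrees.
#' @return A list of class `"frequency_grid"`: grid geometry, integer
#'   `counts` matrix (rows = lat cells south to north, cols = lon cells west
#'   to east), `smoothed` (filled by [smooth_grid()]), `masked` flag.
#' @export
grid_frequency <- function(points, bbox, cell = 0.25) {
  g <- grid_geometry(bbox, cell)
  counts <- matrix(0L, g$nlat, g$nlon)
  n_dropped <- 0L
  if (nrow(points)) {
    i <- floor((points$lat - g$lat0) / cell) + 1
    j <- floor((points$lon - g$lon0) / cell) + 1
    ok <- i >= 1 & i <= g$nlat & j >= 1 & j <= g$nlon
    n_dropped <- sum(!ok)
    for (k in which(ok))
      counts[i[k], j[k]] <- counts[i[k], j[k]] + 1L
  }
  structure(c(g, list(cell = cell, counts = counts, smoothed = NULL,
                      masked = FALSE, n_dropped = n_dropped)),
            class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("frequency_grid: %d x %d cells of %g deg, %d terminal points%s%s\n",
              x$nlat, x$nlon, x$cell, sum(x$counts),
              if (is.null(x$smoothed)) "" else ", smoothed",
              if (x$masked) ", sea-masked" else ""))
  invisible(x)
}

#' @export
plot.frequency_grid <- function(x, ...) {
  z <- if (!is.null(x$smoothed)) x$smoothed else x$counts
  lons <- x$lon0 + (seq_len(x$nlon) - 0.5) * x$cell
  lats <- x$lat0 + (seq_len(x$nlat) - 0.5) * x$cell
  image(lons, lats, t(z), xlab = "lon", ylab = "lat",
        col = hcl.colors(24, "YlOrRd", rev = TRUE),
        main = "terminal-point frequency", ...)
  invisible(x)
}

#' Smooth a frequency grid
#'
#' Mass-conserving 3x3 uniform kernel with edge renormalization: each cell's
#' count is spread equally over its in-bounds 3x3 neighborhood (so an
#' interior cell of count 9 leaves 1.0 in itself and each of its 8
#' neighbors). Cells adjacent to occupied cells acquire fractional values
#' below 1, reproducing the sub-unit map values around hot spots; the total
#' equals the raw terminal-point count exactly.
#'
#' @param grid a [grid_frequency()] result.
#' @return The grid with `smoothed` filled in.
#' @export
smooth_grid <- function(grid) {
  stopifnot(inherits(grid, "frequency_grid"))
  cnt <- grid$counts
  nlat <- nrow(cnt); nlon <- ncol(cnt)
  # in-bounds neighborhood size of each source cell
  ki <- ifelse(seq_len(nlat) == 1 | seq_len(nlat) == nlat, 2, 3)
  if (nlat == 1) ki[] <- 1
  kj <- ifelse(seq_len(nlon) == 1 | seq_len(nlon) == nlon, 2, 3)
  if (nlon == 1) kj[] <- 1
  k <- outer(ki, kj)
  share <- cnt / k
  sm <- matrix(0, nlat, nlon)
  for (di in -1:1) for (dj in -1:1) {
    si <- seq_len(nlat) - di
    sj <- seq_len(nlon) - dj
    oki <- si >= 1 & si <= nlat
    okj <- sj >= 1 & sj <= nlon
    sm[oki, okj] <- sm[oki, okj] + share[si[oki], sj[okj], drop = FALSE]
  }
  grid$smoothed <- sm
  grid
}

#' Remove sea cells from a smoothed frequency grid
#'
#' Terminal points over the sea cannot be take-off sources; their smoothed
#' mass is set to zero. Raw counts are kept and the `masked` flag set.
#'
#' @param grid a smoothed [grid_frequency()] result (smoothing is applied
#'   first if missing).
#' @param landmask a [gen_landmask()] mask on the same geometry.
#' @return The grid with sea cells zeroed in `smoothed` and `masked = TRUE`.
#' @export
mask_sea <- function(grid, landmask) {
  stopifnot(inherits(grid, "frequency_grid"), inherits(landmask, "land_mask"))
  same <- isTRUE(all.equal(grid$lon0, landmask$lon0)) &&
    isTRUE(all.equal(grid$lat0, landmask$lat0)) &&
    grid$nlon == landmask$nlon && grid$nlat == landmask$nlat &&
    isTRUE(all.equal(grid$cell, landmask$cell))
  if (!same) stop("land mask geometry does not match the frequency grid")
  if (is.null(grid$smoothed)) grid <- smooth_grid(grid)
  grid$smoothed[!landmask$land] <- 0
  grid$masked <- TRUE
  grid
}

#' Define a set of named origin regions
#'
#' Regions are axis-aligned lat/lon boxes labelled with an origin kind:
#' `"continental"` (the overseas source belt), `"domestic_high_ratio"`
#' (domestic districts whose isotope ratios overlap the continental range),
#' `"domestic_low_ratio"` (distant low-ratio domestic areas), or `"local"`
#' (the trap area itself). Regions may overlap.
#'
#' @param name region names.
#' @param kind region kinds (see above), recycled.
#' @param lat_min,lat_max,lon_min,lon_max box bounds, recycled.
#' @return A data frame of class `"region_set"`.
#' @export
region_set <- function(name, kind, lat_min, lat_max, lon_min, lon_max) {
  kinds <- c("continental", "domestic_high_ratio", "domestic_low_ratio",
             "local")
  if (!all(kind %in% kinds))
    stop("`kind` must be one of: ", paste(kinds, collapse = ", "))
  df <- data.frame(name = name, kind = kind, lat_min = lat_min,
                   lat_max = lat_max, lon_min = lon_min, lon_max = lon_max)
  class(df) <- c("region_set", "data.frame")
  df
}

region_mass <- function(grid, region) {
  lats <- grid$lat0 + (seq_len(grid$nlat) - 0.5) * grid$cell
  lons <- grid$lon0 + (seq_len(grid$nlon) - 0.5) * grid$cell
  ri <- which(lats >= region$lat_min & lats <= region$lat_max)
  rj <- which(lons >= region$lon_min & lons <= region$lon_max)
  if (!length(ri) || !length(rj)) return(0)
  sum(grid$smoothed[ri, rj])
}

#' Attribute a natal origin from the isotope call and the source map
#'
#' A region is "reached" when the smoothed terminal-point mass inside it
#' exceeds `threshold` (default: any positive mass). The decision table is
#' total and deterministic:
#'
#' * `above_cutoff` + continental reached, no high-ratio domestic region
#'   reached -> `"continental"`;
#' * `above_cutoff` + both continental and high-ratio domestic reached ->
#'   `"undeterminable"` (either scenario explains the high ratio);
#' * `above_cutoff` + only high-ratio domestic reached ->
#'   `"domestic_nonlocal"`;
#' * `at_or_below_cutoff` + a distant low-ratio domestic region reached ->
#'   `"domestic_nonlocal"`;
#' * `at_or_below_cutoff` + the local region reached (and no distant
#'   low-ratio region) -> `"local"`;
#' * anything else (no region reached, or regions inconsistent with the
#'   isotope call) -> `"undeterminable"`.
#'
#' @param isotope_call `"above_cutoff"` or `"at_or_below_cutoff"` (a factor
#'   level from [classify_by_cutoff()] works).
#' @param grid a smoothed (and normally sea-masked) frequency grid.
#' @param regions a [region_set()].
#' @param threshold smoothed-mass threshold above which a region counts as
#'   reached.
#' @param sample_id optional sample identifier carried into the result.
#' @return A list of class `"origin_assignment"`: `sample_id`,
#'   `isotope_call`, `regions_reached` (character), `region_mass` (named
#'   numeric), `final_call` in `c("continental", "domestic_nonlocal",
#'   "local", "undeterminable")`.
#' @export
attribute_origin <- function(isotope_call, grid, regions, threshold = 0,
                             sample_id = NA_character_) {
  stopifnot(inherits(grid, "frequency_grid"))
  if (!inherits(regions, "region_set") || nrow(regions) == 0)
    stop("`regions` must be a non-empty region_set")
  if (is.null(grid$smoothed)) grid <- smooth_grid(grid)
  isotope_call <- as.character(isotope_call)
  stopifnot(isotope_call %in% c("above_cutoff", "at_or_below_cutoff"))
  mass <- vapply(seq_len(nrow(regions)),
                 function(i) region_mass(grid, regions[i, ]), numeric(1))
  names(mass) <- regions$name
  reached <- mass > threshold
  kinds_reached <- unique(regions$kind[reached])
  cont <- "continental" %in% kinds_reached
  dhigh <- "domestic_high_ratio" %in% kinds_reached
  dlow <- "domestic_low_ratio" %in% kinds_reached
  locl <- "local" %in% kinds_reached
  final_call <- if (isotope_call == "above_cutoff") {
    if (cont && !dhigh) "continental"
    else if (cont && dhigh) "undeterminable"
    else if (dhigh) "domestic_nonlocal"
    else "undeterminable"
  } else {
    if (dlow) "domestic_nonlocal"
    else if (locl) "local"
    else "undeterminable"
  }
  structure(list(sample_id = sample_id, isotope_call = isotope_call,
                 regions_reached = regions$name[reached],
                 region_mass = mass, final_call = final_call),
            class = "origin_assignment")
}

#' @export
print.origin_assignment <- function(x, ...) {
  cat(sprintf("origin assignment%s: %s\n",
              if (is.na(x$sample_id)) "" else paste0(" [", x$sample_id, "]"),
              x$final_call))
  cat(sprintf("  isotope call: %s; regions reached: %s\n", x$isotope_call,
              if (length(x$regions_reached))
                paste(x$regions_reached, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Write / read a frequency grid
#'
#' CSV layout: one row per cell with the cell-center coordinates, the raw
#' count and the smoothed value. The NetCDF variant stores `raw` and
#' `smoothed` variables on 0.25-degree lat/lon axes (requires `ncdf4`).
#'
#' @param grid a [grid_frequency()] result.
#' @param path file path.
#' @export
write_frequency_grid_csv <- function(grid, path) {
  lats <- grid$lat0 + (seq_len(grid$nlat) - 0.5) * grid$cell
  lons <- grid$lon0 + (seq_len(grid$nlon) - 0.5) * grid$cell
  df <- expand.grid(lat = lats, lon = lons, KEEP.OUT.ATTRS = FALSE)
  df$raw <- as.vector(grid$counts)
  df$smoothed <- if (!is.null(grid$smoothed)) as.vector(grid$smoothed)
                 else NA_real_
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frequency_grid_csv
#' @export
write_frequency_grid_nc <- function(grid, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("the `ncdf4` package is required for NetCDF I/O; ",
         "use write_frequency_grid_csv() otherwise")
  lats <- grid$lat0 + (seq_len(grid$nlat) - 0.5) * grid$cell
  lons <- grid$lon0 + (seq_len(grid$nlon) - 0.5) * grid$cell
  dy <- ncdf4::ncdim_def("lat", "degrees_north", lats)
  dx <- ncdf4::ncdim_def("lon", "degrees_east", lons)
  vr <- ncdf4::ncvar_def("raw", "count", list(dx, dy), prec = "integer")
  vs <- ncdf4::ncvar_def("smoothed", "count", list(dx, dy), prec = "double")
  nc <- ncdf4::nc_create(path, list(vr, vs))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vr, t(grid$counts))
  sm <- if (!is.null(grid$smoothed)) grid$smoothed
        else matrix(NA_real_, grid$nlat, grid$nlon)
  ncdf4::ncvar_put(nc, vs, t(sm))
  invisible(path)
}
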