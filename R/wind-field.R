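# Gridded wind/temperature container and the space-time linear interpolator
# used by the trajectory integrator. Axes follow the meteorological archive
# convention the engine emulates: 3-hourly instants, height levels in m AGL,
# 1-degree lat/lon.

EARTH_RADIUS_M <- 6371000
M_PER_DEG <- EARTH_RADIUS_M * pi / 180

# the 16 corners of a 4-d cell (time, height, lat, lon), one row each
CORNERS <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1, KEEP.OUT.ATTRS = FALSE))

#' Construct a gridded wind/temperature field
#'
#' @param time POSIXct (UTC) instants, strictly increasing.
#' @param height height levels in m above ground, strictly increasing.
#' @param lat,lon axis values in degrees, strictly increasing.
#' @param u,v eastward/northward wind (m/s), 4-d arrays with dim
#'   `c(time, height, lat, lon)`.
#' @param temp air temperature (degC), same shape.
#' @param w optional vertical velocity (m/s), same shape.
#' @return A list of class `"wind_field"`.
#' @export
wind_field <- function(time, height, lat, lon, u, v, temp, w = NULL) {
  if (!inherits(time, "POSIXct")) stop("`time` must be POSIXct (UTC)")
  axes <- list(time = as.numeric(time), height = height, lat = lat, lon = lon)
  for (nm in names(axes)) {
    a <- axes[[nm]]
    if (length(a) < 1 || anyNA(a)) stop("empty or NA axis: ", nm)
    if (is.unsorted(a, strictly = TRUE)) stop("axis not strictly increasing: ", nm)
  }
  dims <- vapply(axes, length, integer(1))
  for (nm in c("u", "v", "temp")) {
    g <- get(nm)
    if (!identical(dim(g), unname(dims)))
      stop("grid `", nm, "` does not match axis shape")
  }
  if (!is.null(w) && !identical(dim(w), unname(dims)))
    stop("grid `w` does not match axis shape")
  structure(list(time = time, height = height, lat = lat, lon = lon,
                 u = u, v = v, temp = temp, w = w),
            class = "wind_field")
}

#' @export
print.wind_field <- function(x, ...) {
  cat(sprintf("wind_field: %d times x %d heights x %d lat x %d lon%s\n",
              length(x$time), length(x$height), length(x$lat), length(x$lon),
              if (is.null(x$w)) "" else " (+w)"))
  cat(sprintf("  time  %s .. %s UTC\n", format(min(x$time), tz = "UTC"),
              format(max(x$time), tz = "UTC")))
  cat(sprintf("  height %g..%g m AGL, lat %g..%g, lon %g..%g\n",
              min(x$height), max(x$height), min(x$lat), max(x$lat),
              min(x$lon), max(x$lon)))
  invisible(x)
}

# axis bracketing: index of lower node and interpolation weight
axis_locate <- function(ax, q) {
  n <- length(ax)
  if (q < ax[1] || q > ax[n]) return(NULL)
  if (n == 1L) return(list(i = 1L, wt = 0))
  i <- findInterval(q, ax, rightmost.closed = TRUE)
  if (i >= n) i <- n - 1L
  list(i = i, wt = (q - ax[i]) / (ax[i + 1] - ax[i]))
}

#' Interpolate a wind field at a point in space-time
#'
#' Linear in time and height, bilinear in lat/lon (exact at grid nodes). A
#' query outside the field's space-time hull returns `NULL`, which the
#' trajectory integrator treats as leaving the domain.
#'
#' @param field a [wind_field()].
#' @param time POSIXct or numeric seconds since epoch.
#' @param lat,lon,height query position (degrees, m AGL).
#' @return A list `u`, `v`, `temp` (and `w` if present), or `NULL` if the
#'   query is outside the hull.
#' @export
interpolate_field <- function(field, time, lat, lon, height) {
  tq <- as.numeric(time)
  lt <- axis_locate(as.numeric(field$time), tq)
  lh <- axis_locate(field$height, height)
  ly <- axis_locate(field$lat, lat)
  lx <- axis_locate(field$lon, lon)
  if (is.null(lt) || is.null(lh) || is.null(ly) || is.null(lx)) return(NULL)
  d <- c(length(field$time), length(field$height), length(field$lat),
         length(field$lon))
  # 16 corner linear indices and weights, dims ordered (time, height, lat, lon)
  i0 <- c(lt$i, lh$i, ly$i, lx$i)
  wt <- c(lt$wt, lh$wt, ly$wt, lx$wt)
  up <- pmin(i0 + 1L, d)  # collapse degenerate axes (length-1 or wt 0)
  ii <- CORNERS * rep(up - i0, each = 16L) + rep(i0, each = 16L)
  wts <- CORNERS * rep(2 * wt - 1, each = 16L) + rep(1 - wt, each = 16L)
  wprod <- wts[, 1] * wts[, 2] * wts[, 3] * wts[, 4]
  lin <- ii[, 1] + d[1] * (ii[, 2] - 1L + d[2] * (ii[, 3] - 1L +
                                                  d[3] * (ii[, 4] - 1L)))
  out <- list(u = sum(wprod * field$u[lin]),
              v = sum(wprod * field$v[lin]),
              temp = sum(wprod * field$temp[lin]))
  if (!is.null(field$w)) out$w <- sum(wprod * field$w[lin])
  out
}

#' Write / read a wind field as NetCDF
#'
#' Dimensions `time` (seconds since 1970-01-01 UTC), `height` (m AGL),
#' `lat`, `lon`; variables `u`, `v` (m/s), `T` (degC) and optionally `w`.
#' Requires the `ncdf4` package.
#'
#' @param field a [wind_field()].
#' @param path file path.
#' @return `read_wind_field_nc()` returns a [wind_field()].
#' @export
write_wind_field_nc <- function(field, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("the `ncdf4` package is required for NetCDF I/O; ",
         "use write_wind_field_csv() otherwise")
  dt <- ncdf4::ncdim_def("time", "seconds since 1970-01-01 00:00:00 UTC",
                         as.numeric(field$time))
  dh <- ncdf4::ncdim_def("height", "m", field$height)
  dy <- ncdf4::ncdim_def("lat", "degrees_north", field$lat)
  dx <- ncdf4::ncdim_def("lon", "degrees_east", field$lon)
  dims <- list(dx, dy, dh, dt)  # netcdf fastest-varying first
  vu <- ncdf4::ncvar_def("u", "m/s", dims, prec = "double")
  vv <- ncdf4::ncvar_def("v", "m/s", dims, prec = "double")
  vt <- ncdf4::ncvar_def("T", "degC", dims, prec = "double")
  vars <- list(vu, vv, vt)
  if (!is.null(field$w))
    vars <- c(vars, list(ncdf4::ncvar_def("w", "m/s", dims, prec = "double")))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  # our arrays are [time, height, lat, lon]; netcdf wants [lon, lat, height, time]
  flip <- function(g) aperm(g, c(4, 3, 2, 1))
  ncdf4::ncvar_put(nc, vu, flip(field$u))
  ncdf4::ncvar_put(nc, vv, flip(field$v))
  ncdf4::ncvar_put(nc, vt, flip(field$temp))
  if (!is.null(field$w)) ncdf4::ncvar_put(nc, "w", flip(field$w))
  invisible(path)
}

#' @rdname write_wind_field_nc
#' @export
read_wind_field_nc <- function(path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("the `ncdf4` package is required for NetCDF I/O")
  if (!file.exists(path)) stop("wind field file not found: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  gv <- function(nm) aperm(ncdf4::ncvar_get(nc, nm, collapse_degen = FALSE),
                           c(4, 3, 2, 1))
  time <- as.POSIXct(as.numeric(nc$dim$time$vals), origin = "1970-01-01",
                     tz = "UTC")
  w <- if ("w" %in% names(nc$var)) gv("w") else NULL
  wind_field(time, as.numeric(nc$dim$height$vals),
             as.numeric(nc$dim$lat$vals), as.numeric(nc$dim$lon$vals),
             gv("u"), gv("v"), gv("T"), w)
}

#' Write / read a wind field as long-format CSV
#'
#' Text fallback for the NetCDF interface: one row per grid node with
#' columns `time` (ISO 8601 UTC), `height_m`, `lat`, `lon`, `u_ms`, `v_ms`,
#' `temp_C` (and `w_ms` if present).
#'
#' @param field a [wind_field()].
#' @param path file path.
#' @return `read_wind_field_csv()` returns a [wind_field()].
#' @export
write_wind_field_csv <- function(field, path) {
  grid <- expand.grid(time = field$time, height_m = field$height,
                      lat = field$lat, lon = field$lon,
                      KEEP.OUT.ATTRS = FALSE)
  grid$time <- format(grid$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  grid$u_ms <- as.vector(field$u)
  grid$v_ms <- as.vector(field$v)
  grid$temp_C <- as.vector(field$temp)
  if (!is.null(field$w)) grid$w_ms <- as.vector(field$w)
  write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wind_field_csv
#' @export
read_wind_field_csv <- function(path) {
  if (!file.exists(path)) stop("wind field file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  time <- sort(unique(as.POSIXct(df$time, format = "%Y-%m-%dT%H:%M:%SZ",
                                 tz = "UTC")))
  height <- sort(unique(df$height_m))
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  dims <- c(length(time), length(height), length(lat), length(lon))
  o <- order(match(df$lon, lon), match(df$lat, lat),
             match(df$height_m, height),
             match(as.POSIXct(df$time, format = "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC"), time))
  shape <- function(x) array(x[o], dims)
  w <- if ("w_ms" %in% names(df)) shape(df$w_ms) else NULL
  wind_field(time, height, lat, lon,
             shape(df$u_ms), shape(df$v_ms), shape(df$temp_C), w)
}
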