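# Synthetic-data generators. They emulate the statistical structure the
# analysis assumes -- two-class Gaussian reference ratios, analytic wind
# fields with closed-form trajectories, rectangular land masks, trap series
# with an immigration peak -- so every downstream stage is testable offline.

#' Specification of a two-class reference isotope set
#'
#' Defaults are the reported class moments of the system the package
#' targets: immigration-area insects 0.70806 +/- 0.00088 (class 0) and
#' continental insects 0.71088 +/- 0.00333 (class 1).
#'
#' @param classes a list of per-class entries, each a list with `label` (0 or
#'   1), `material` (`"insect"` or `"host"`), `mean`, `sd`, `n` and
#'   `site_codes`.
#' @return A list of class `"reference_spec"`.
#' @export
reference_spec <- function(classes = list(
    list(label = 0L, material = "insect", mean = 0.70806, sd = 0.00088,
         n = 30L, site_codes = c("JA1", "JA2", "JA3")),
    list(label = 1L, material = "insect", mean = 0.71088, sd = 0.00333,
         n = 30L, site_codes = c("CN1", "CN2", "CN3")))) {
  for (cl in classes) {
    if (!cl$label %in% c(0L, 1L)) stop("labels must be 0/1")
    if (cl$sd < 0) stop("sd must be non-negative")
    if (cl$n < 1) stop("n must be at least 1")
  }
  structure(list(classes = classes), class = "reference_spec")
}

#' Generate a reference isotope set
#'
#' Draws, per class, `n` independent Normal(mean, sd) ratios, reproducibly
#' under a fixed seed. Sites are assigned cyclically from the class's site
#' codes. No site-level hierarchy is modelled: only the class moments are
#' specified by the system this emulates.
#'
#' @param spec a [reference_spec()].
#' @param seed integer seed.
#' @return Data frame with `sample_id`, `site_code`, `material`,
#'   `origin_label`, `ratio`.
#' @examples
#' head(gen_reference_set(seed = 1))
#' @export
gen_reference_set <- function(spec = reference_spec(), seed = NULL) {
  stopifnot(inherits(spec, "reference_spec"))
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_along(spec$classes), function(k) {
    cl <- spec$classes[[k]]
    data.frame(
      sample_id = sprintf("ref%0d_%04d", cl$label, seq_len(cl$n)),
      site_code = rep_len(cl$site_codes, cl$n),
      material = cl$material,
      origin_label = cl$label,
      ratio = rnorm(cl$n, cl$mean, cl$sd))
  })
  do.call(rbind, out)
}

#' Specification of an analytic wind/temperature field
#'
#' Analytic (non-stochastic) fields give the trajectory engine closed-form
#' truth. Kinds: `"uniform"` (constant `u0`, `v0`), `"rotational"`
#' (solid-body rotation of angular speed `omega` rad/s around `center`),
#' `"sheared"` (`u = u0 + shear * height`), `"layered_cold"` (uniform winds
#' with temperature `cold_T` inside a height band). Temperature elsewhere
#' follows `T0 - lapse * height + diurnal_amplitude * sin(2 pi hour / 24)`.
#' An optional seeded Gaussian perturbation supports robustness tests.
#'
#' @param kind field kind.
#' @param u0,v0 base winds (m/s).
#' @param omega angular speed (rad/s) for `"rotational"`.
#' @param center `c(lat, lon)` rotation center.
#' @param shear vertical shear ((m/s)/m) for `"sheared"`.
#' @param T0 surface temperature (degC); `lapse` (degC/m);
#'   `diurnal_amplitude` (degC).
#' @param cold_T,cold_band temperature and `c(min, max)` height band (m) for
#'   `"layered_cold"`.
#' @param lat_range,lon_range degree bounds (1-degree spacing).
#' @param heights height levels (m AGL).
#' @param time_start POSIXct UTC first instant; `n_times` 3-hourly instants.
#' @param perturb_sd standard deviation of an optional additive Gaussian
#'   perturbation of u and v; `seed` its seed.
#' @return A list of class `"wind_field_spec"`.
#' @export
wind_field_spec <- function(kind = c("uniform", "rotational", "sheared",
                                     "layered_cold"),
                            u0 = 0, v0 = 0, omega = 0,
                            center = c(35, 127), shear = 0,
                            T0 = 20, lapse = 0.0065, diurnal_amplitude = 0,
                            cold_T = 5, cold_band = c(800, 1200),
                            lat_range = c(20, 50), lon_range = c(105, 145),
                            heights = seq(0, 2000, by = 250),
                            time_start = as.POSIXct("2020-05-25 00:00:00",
                                                    tz = "UTC"),
                            n_times = 41, perturb_sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (n_times < 1 || length(heights) < 1) stop("empty grid axes")
  if (diff(lat_range) <= 0 || diff(lon_range) <= 0) stop("empty grid axes")
  structure(as.list(environment()), class = "wind_field_spec")
}

#' Generate an analytic wind/temperature field
#'
#' @param spec a [wind_field_spec()].
#' @return A [wind_field()] on a 1-degree, 3-hourly grid.
#' @examples
#' f <- gen_wind_field(wind_field_spec("uniform", u0 = 10))
#' interpolate_field(f, f$time[1], 30, 120, 500)
#' @export
gen_wind_field <- function(spec = wind_field_spec()) {
  stopifnot(inherits(spec, "wind_field_spec"))
  lat <- seq(spec$lat_range[1], spec$lat_range[2], by = 1)
  lon <- seq(spec$lon_range[1], spec$lon_range[2], by = 1)
  time <- spec$time_start + 3 * 3600 * (seq_len(spec$n_times) - 1)
  height <- spec$heights
  dims <- c(length(time), length(height), length(lat), length(lon))
  A <- function(x, along) {
    # broadcast a vector along one of the 4 dims
    aperm(array(x, dims[c(along, setdiff(1:4, along))]),
          order(c(along, setdiff(1:4, along))))
  }
  H <- A(height, 2); LAT <- A(lat, 3); LON <- A(lon, 4)
  hour <- as.numeric(format(time, "%H", tz = "UTC")) +
    as.numeric(format(time, "%M", tz = "UTC")) / 60
  HOUR <- A(hour, 1)

  u <- array(spec$u0, dims); v <- array(spec$v0, dims)
  if (spec$kind == "rotational") {
    x <- M_PER_DEG * cos(spec$center[1] * pi / 180) * (LON - spec$center[2])
    y <- M_PER_DEG * (LAT - spec$center[1])
    u <- -spec$omega * y
    v <- spec$omega * x
  } else if (spec$kind == "sheared") {
    u <- spec$u0 + spec$shear * H
  }
  temp <- spec$T0 - spec$lapse * H +
    spec$diurnal_amplitude * sin(2 * pi * HOUR / 24)
  if (spec$kind == "layered_cold") {
    band <- H >= spec$cold_band[1] & H <= spec$cold_band[2]
    temp[band] <- spec$cold_T
  }
  if (spec$perturb_sd > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    u <- u + rnorm(length(u), 0, spec$perturb_sd)
    v <- v + rnorm(length(v), 0, spec$perturb_sd)
  }
  wind_field(time, height, lat, lon, u, v, temp)
}

#' Generate a land/sea mask on the 0.25-degree grid convention
#'
#' Synthetic geography standing in for real coastlines: `"all_land"`,
#' `"all_sea"`, or `"meridian_split"` (continent in cells whose centers lie
#' west of `L0`, plus an optional island longitude band east of it).
#'
#' @param kind mask geometry.
#' @param bbox `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param L0 split longitude for `"meridian_split"`.
#' @param island_band `c(lon_min, lon_max)` island band, or `NULL`.
#' @param cell cell size in degrees.
#' @return A list of class `"land_mask"` with the logical `land` matrix
#'   (rows = lat cells, cols = lon cells) and the grid geometry.
#' @examples
#' gen_landmask("meridian_split", c(110, 140, 25, 45), L0 = 125)
#' @export
gen_landmask <- function(kind = c("meridian_split", "all_land", "all_sea"),
                         bbox, L0 = 125, island_band = c(129, 132),
                         cell = 0.25) {
  kind <- match.arg(kind)
  g <- grid_geometry(bbox, cell)
  land <- matrix(kind == "all_land", g$nlat, g$nlon)
  if (kind == "meridian_split") {
    centers_lon <- g$lon0 + (seq_len(g$nlon) - 0.5) * cell
    west <- centers_lon < L0
    isl <- if (!is.null(island_band))
      centers_lon >= island_band[1] & centers_lon <= island_band[2]
    else rep(FALSE, g$nlon)
    land <- matrix(rep(west | isl, each = g$nlat), g$nlat, g$nlon)
  }
  structure(c(g, list(cell = cell, land = land)), class = "land_mask")
}

#' Generate a trap-catch series with an immigration peak
#'
#' Poisson counts at `baseline_rate` on every date except `peak_date`, where
#' the count is exactly `peak_count` (a marked immigration peak).
#'
#' @param site site code.
#' @param dates vector of `Date`s.
#' @param baseline_rate Poisson mean of the background catch (>= 0).
#' @param peak_date the peak date (must be in `dates`).
#' @param peak_count catch on the peak date.
#' @param seed integer seed.
#' @return Data frame `site`, `date`, `count`.
#' @export
gen_trap_series <- function(site, dates, baseline_rate, peak_date,
                            peak_count, seed = NULL) {
  if (baseline_rate < 0) stop("`baseline_rate` must be non-negative")
  if (!peak_date %in% dates) stop("`peak_date` must be one of `dates`")
  if (!is.null(seed)) set.seed(seed)
  counts <- rpois(length(dates), baseline_rate)
  counts[dates == peak_date] <- as.integer(peak_count)
  data.frame(site = site, date = dates, count = counts)
}
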