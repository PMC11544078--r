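# Backward Lagrangian integration of self-powered downwind insect flight.
# Positions advance on a spherical-earth local tangent approximation with a
# two-stage (Petterssen) predictor-corrector; height is held fixed in m AGL
# by default. Validity is judged afterwards by the temperature gates.

#' Flight and integration parameters
#'
#' Defaults are the study conditions of the analysis this package
#' implements: a 3.0 m/s self-powered flight vector added along the
#' instantaneous downwind direction, a 9 degC en-route minimum and an
#' 11 degC take-off (terminal-point) minimum, 15 starting heights from 100
#' to 1500 m AGL, dusk fixed at 11:00 UTC, and a 10-minute integration step.
#'
#' @param self_speed insect airspeed added downwind (m/s).
#' @param t_enroute_min en-route minimum temperature (degC); a trajectory
#'   crossing colder air is invalid.
#' @param t_takeoff_min take-off minimum temperature (degC) at the terminal
#'   point.
#' @param start_heights starting heights (m AGL).
#' @param dusk_hour_utc terminal (take-off) hour, UTC.
#' @param duration_mode `"short"` (terminal at dusk the previous day,
#'   durations 13-36 h) or `"long"` (dusk two days before, 37-60 h).
#' @param time_step integration step (s).
#' @param calm_epsilon wind speed (m/s) below which the downwind direction
#'   is undefined and the self-speed contribution is suppressed.
#' @param vertical_advection advect height by the field's `w` (off by
#'   default; heights are held fixed in m AGL).
#' @return A list of class `"flight_params"`.
#' @export
flight_params <- function(self_speed = 3.0,
                          t_enroute_min = 9,
                          t_takeoff_min = 11,
                          start_heights = seq(100, 1500, by = 100),
                          dusk_hour_utc = 11,
                          duration_mode = c("short", "long"),
                          time_step = 600,
                          calm_epsilon = 0.1,
                          vertical_advection = FALSE) {
  duration_mode <- match.arg(duration_mode)
  stopifnot(self_speed >= 0, t_takeoff_min >= t_enroute_min,
            all(start_heights > 0), !is.unsorted(start_heights),
            time_step > 0)
  structure(list(self_speed = self_speed, t_enroute_min = t_enroute_min,
                 t_takeoff_min = t_takeoff_min, start_heights = start_heights,
                 dusk_hour_utc = dusk_hour_utc, duration_mode = duration_mode,
                 time_step = time_step, calm_epsilon = calm_epsilon,
                 vertical_advection = vertical_advection),
            class = "flight_params")
}

#' Effective flight velocity: wind plus downwind self-speed
#'
#' The insect's ground velocity is the wind vector scaled so that its speed
#' is wind speed + self speed, i.e. `(u, v) * (1 + s / |(u, v)|)`. In calm
#' air (wind speed below `epsilon`) the downwind direction is undefined and
#' the wind vector is returned unchanged.
#'
#' @param u,v wind components (m/s).
#' @param self_speed insect airspeed (m/s).
#' @param epsilon calm-wind threshold (m/s).
#' @return Named numeric `c(u, v)` of the effective velocity.
#' @examples
#' effective_velocity(10, 0, 3)   # c(13, 0)
#' effective_velocity(0, 0, 3)    # calm: c(0, 0)
#' @export
effective_velocity <- function(u, v, self_speed, epsilon = 0.1) {
  spd <- sqrt(u^2 + v^2)
  if (spd < epsilon) return(c(u = u, v = v))
  f <- 1 + self_speed / spd
  c(u = u * f, v = v * f)
}

#' Build the start ensemble for one date
#'
#' The cross product of the 24 hourly start times (00:00-23:00 UTC on the
#' date of interest) and the configured starting heights: with the default
#' 15 heights, 360 starts per date and duration mode. The scheduled terminal
#' time is dusk (11:00 UTC) on the previous day (`"short"` mode, durations
#' 13 + hour) or two days before (`"long"`, 37 + hour).
#'
#' @param site_lat,site_lon trap-site coordinates (degrees).
#' @param date the arrival `Date` of interest.
#' @param params a [flight_params()].
#' @return Data frame of start specifications: `site_lat`, `site_lon`,
#'   `date`, `start_hour_utc`, `start_height`, `duration_h`, `start_time`,
#'   `terminal_time` (POSIXct UTC).
#' @export
build_start_ensemble <- function(site_lat, site_lon, date, params = flight_params()) {
  date <- as.Date(date)
  back_days <- if (params$duration_mode == "short") 1 else 2
  g <- expand.grid(start_hour_utc = 0:23,
                   start_height = params$start_heights,
                   KEEP.OUT.ATTRS = FALSE)
  start_time <- as.POSIXct(date, tz = "UTC") + g$start_hour_utc * 3600
  terminal_time <- as.POSIXct(date - back_days, tz = "UTC") +
    params$dusk_hour_utc * 3600
  data.frame(site_lat = site_lat, site_lon = site_lon, date = date,
             start_hour_utc = g$start_hour_utc,
             start_height = g$start_height,
             duration_h = as.numeric(difftime(start_time, terminal_time,
                                              units = "hours")),
             start_time = start_time, terminal_time = terminal_time)
}

#' Integrate one backward trajectory
#'
#' Steps backward from the start time to the scheduled terminal time (dusk)
#' with a two-stage predictor-corrector: a predictor displacement with the
#' effective velocity at the current point, then a correction with the mean
#' of the velocities at the current and predicted points. Positions move on
#' the sphere via `dlat = -v dt / R`, `dlon = -u dt / (R cos lat)` (R =
#' 6371 km). Height stays at the starting level in m AGL unless
#' `vertical_advection` is enabled and the field carries `w`. The ambient
#' temperature is recorded at every step; validity is then set by
#' [apply_validity_filters()].
#'
#' @param start one row of [build_start_ensemble()] (or a list with the same
#'   fields).
#' @param field a [wind_field()].
#' @param params a [flight_params()].
#' @return A list of class `"flight_trajectory"`: `steps` (data frame
#'   `time`, `lat`, `lon`, `height`, `temp_C`, `u`, `v`, in strictly
#'   decreasing time from start to terminal), `valid`, `invalid_reason`
#'   (one of `"none"`, `"enroute_cold"`, `"takeoff_cold"`, `"left_domain"`),
#'   and the start specification.
#' @export
integrate_backward <- function(start, field, params = flight_params()) {
  t0 <- as.numeric(start$start_time)
  t_end <- as.numeric(start$terminal_time)
  stopifnot(t0 > t_end)
  dt <- params$time_step
  lat <- start$site_lat; lon <- start$site_lon; hgt <- start$start_height

  first <- interpolate_field(field, t0, lat, lon, hgt)
  if (is.null(first))
    stop("start point outside the wind field's space-time hull")

  n_steps <- ceiling((t0 - t_end) / dt - 1e-9)
  times <- lats <- lons <- hgts <- temps <- us <- vs <-
    numeric(n_steps + 1)
  cur <- first
  times[1] <- t0; lats[1] <- lat; lons[1] <- lon; hgts[1] <- hgt
  temps[1] <- cur$temp; us[1] <- cur$u; vs[1] <- cur$v
  left <- FALSE
  n_done <- 1L

  for (k in seq_len(n_steps)) {
    t_next <- max(times[n_done] - dt, t_end)
    h <- times[n_done] - t_next
    ve <- effective_velocity(cur$u, cur$v, params$self_speed,
                             params$calm_epsilon)
    w0 <- if (params$vertical_advection && !is.null(cur$w)) cur$w else 0
    # predictor
    lat_p <- lats[n_done] - ve[["v"]] * h / M_PER_DEG
    lon_p <- lons[n_done] - ve[["u"]] * h /
      (M_PER_DEG * cos(lats[n_done] * pi / 180))
    hgt_p <- max(hgts[n_done] - w0 * h, 0)
    smp <- interpolate_field(field, t_next, lat_p, lon_p, hgt_p)
    if (is.null(smp)) { left <- TRUE; break }
    vp <- effective_velocity(smp$u, smp$v, params$self_speed,
                             params$calm_epsilon)
    wp <- if (params$vertical_advection && !is.null(smp$w)) smp$w else 0
    # corrector: mean of the two velocities
    um <- (ve[["u"]] + vp[["u"]]) / 2
    vm <- (ve[["v"]] + vp[["v"]]) / 2
    wm <- (w0 + wp) / 2
    lat_n <- lats[n_done] - vm * h / M_PER_DEG
    lon_n <- lons[n_done] - um * h /
      (M_PER_DEG * cos(lats[n_done] * pi / 180))
    hgt_n <- max(hgts[n_done] - wm * h, 0)
    cur <- interpolate_field(field, t_next, lat_n, lon_n, hgt_n)
    if (is.null(cur)) { left <- TRUE; break }
    n_done <- n_done + 1L
    times[n_done] <- t_next; lats[n_done] <- lat_n; lons[n_done] <- lon_n
    hgts[n_done] <- hgt_n; temps[n_done] <- cur$temp
    us[n_done] <- cur$u; vs[n_done] <- cur$v
    if (t_next <= t_end) break
  }

  idx <- seq_len(n_done)
  steps <- data.frame(
    time = as.POSIXct(times[idx], origin = "1970-01-01", tz = "UTC"),
    lat = lats[idx], lon = lons[idx], height = hgts[idx],
    temp_C = temps[idx], u = us[idx], v = vs[idx])
  traj <- structure(list(steps = steps,
                         valid = !left,
                         invalid_reason = if (left) "left_domain" else "none",
                         start = start, params = params),
                    class = "flight_trajectory")
  if (left) traj else apply_validity_filters(traj, params)
}

#' Apply the temperature validity gates to a trajectory
#'
#' A trajectory is invalid with reason `"enroute_cold"` if any step's
#' ambient temperature is below the en-route minimum (9 degC), and with
#' reason `"takeoff_cold"` if the terminal-step temperature is below the
#' take-off minimum (11 degC); the en-route check takes precedence in the
#' recorded reason. A trajectory already marked `"left_domain"` is left
#' untouched.
#'
#' @param traj a [integrate_backward()] trajectory.
#' @param params a [flight_params()].
#' @return The trajectory with `valid` and `invalid_reason` set.
#' @export
apply_validity_filters <- function(traj, params = traj$params) {
  stopifnot(inherits(traj, "flight_trajectory"))
  if (identical(traj$invalid_reason, "left_domain")) return(traj)
  temps <- traj$steps$temp_C
  if (any(temps < params$t_enroute_min)) {
    traj$valid <- FALSE; traj$invalid_reason <- "enroute_cold"
  } else if (temps[length(temps)] < params$t_takeoff_min) {
    traj$valid <- FALSE; traj$invalid_reason <- "takeoff_cold"
  } else {
    traj$valid <- TRUE; traj$invalid_reason <- "none"
  }
  traj
}

#' @export
print.flight_trajectory <- function(x, ...) {
  n <- nrow(x$steps)
  cat(sprintf("backward trajectory: %d steps, %s -> %s UTC\n", n,
              format(x$steps$time[1], tz = "UTC"),
              format(x$steps$time[n], tz = "UTC")))
  cat(sprintf("  start (%.3f, %.3f) at %g m; terminal (%.3f, %.3f)\n",
              x$steps$lat[1], x$steps$lon[1], x$steps$height[1],
              x$steps$lat[n], x$steps$lon[n]))
  cat(sprintf("  valid: %s (%s)\n", x$valid, x$invalid_reason))
  invisible(x)
}

#' Write trajectories as delimited text
#'
#' One row per step, tab-separated, in a tdump-inspired layout with columns
#' `trajectory_id`, `step`, `timestamp` (ISO 8601 UTC), `lat`, `lon`,
#' `height_m_agl`, `temp_C`, `valid`, `invalid_reason`.
#'
#' @param trajs a list of `flight_trajectory` objects.
#' @param path output path.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "flight_trajectory")) trajs <- list(trajs)
  rows <- lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    data.frame(trajectory_id = i,
               step = seq_len(nrow(tr$steps)) - 1L,
               timestamp = format(tr$steps$time, "%Y-%m-%dT%H:%M:%SZ",
                                  tz = "UTC"),
               lat = tr$steps$lat, lon = tr$steps$lon,
               height_m_agl = tr$steps$height,
               temp_C = tr$steps$temp_C,
               valid = tr$valid, invalid_reason = tr$invalid_reason)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
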