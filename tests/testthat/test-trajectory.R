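# Trajectory engine: interpolation, effective velocity, ensemble design,
# backward integration against closed-form oracles, temperature gates.

test_that("field interpolation is exact at nodes and linear between them", {
  f <- gen_wind_field(wind_field_spec("sheared", u0 = 2, shear = 0.005,
                                      lat_range = c(30, 33),
                                      lon_range = c(128, 131),
                                      heights = c(0, 500, 1000), n_times = 3))
  # exact at a grid node
  s <- interpolate_field(f, f$time[2], f$lat[3], f$lon[2], f$height[2])
  expect_equal(s$u, f$u[2, 2, 3, 2])
  expect_equal(s$temp, f$temp[2, 2, 3, 2])
  # midpoint in height of a linear-in-height field: arithmetic mean
  m <- interpolate_field(f, f$time[1], 31, 129, 750)
  expect_equal(m$u, (f$u[1, 2, 2, 2] + f$u[1, 3, 2, 2]) / 2)
  # uniform field: same value at any interior query
  fu <- tiny_uniform_field(u0 = 7, v0 = -2, n_times = 2,
                           lat_range = c(30, 33), lon_range = c(128, 131))
  q <- interpolate_field(fu, fu$time[1] + 4000, 31.3, 129.7, 777)
  expect_equal(c(q$u, q$v), c(7, -2))
  # outside the hull: NULL
  expect_null(interpolate_field(f, f$time[1] - 1, 31, 129, 500))
  expect_null(interpolate_field(f, f$time[1], 29.9, 129, 500))
  expect_null(interpolate_field(f, f$time[1], 31, 129, 1001))
})

test_that("effective velocity adds the self speed along the wind", {
  expect_equal(effective_velocity(10, 0, 3), c(u = 13, v = 0))
  expect_equal(effective_velocity(0, 0, 3), c(u = 0, v = 0))  # calm air
  # wind (3,4): speed 5 -> 8, direction preserved
  expect_equal(effective_velocity(3, 4, 3), c(u = 4.8, v = 6.4))
  # below the calm threshold the wind is returned unchanged
  expect_equal(effective_velocity(0.05, 0, 3, epsilon = 0.1),
               c(u = 0.05, v = 0))
})

test_that("the start ensemble is 24 hours x 15 heights with the stated durations", {
  ens <- build_start_ensemble(32.6, 130.2, as.Date("2020-05-28"),
                              flight_params())
  expect_identical(nrow(ens), 360L)
  expect_identical(sort(unique(ens$start_hour_utc)), 0:23)
  expect_identical(sort(unique(ens$start_height)), seq(100, 1500, by = 100))
  expect_equal(ens$duration_h[ens$start_hour_utc == 0][1], 13)
  expect_equal(max(ens$duration_h), 36)
  long <- build_start_ensemble(32.6, 130.2, as.Date("2020-05-28"),
                               flight_params(duration_mode = "long"))
  expect_equal(range(long$duration_h), c(37, 60))
  # terminal instants are dusk (11:00 UTC) on the right day
  expect_true(all(format(ens$terminal_time, "%H", tz = "UTC") == "11"))
  expect_true(all(as.Date(ens$terminal_time, tz = "UTC") ==
                  as.Date("2020-05-27")))
  expect_true(all(as.Date(long$terminal_time, tz = "UTC") ==
                  as.Date("2020-05-26")))
})

test_that("uniform-field backward displacement matches the advection oracle", {
  f <- tiny_uniform_field(u0 = 10, v0 = 0, T0 = 20)
  fp <- flight_params()  # 3 m/s self speed, 10-min step
  ens <- build_start_ensemble(32.5, 130.0, as.Date("2020-05-28"), fp)
  st <- ens[ens$start_hour_utc == 0 & ens$start_height == 500, ]
  tr <- integrate_backward(st, f, fp)
  n <- nrow(tr$steps)
  expect_true(tr$valid)
  expect_true(all(diff(as.numeric(tr$steps$time)) < 0))
  # terminal exactly at dusk
  expect_identical(tr$steps$time[n], st$terminal_time)
  # height held fixed
  expect_true(all(tr$steps$height == 500))
  # no meridional drift, and 13 h x 13 m/s = 608.4 km of arc westward
  expect_equal(tr$steps$lat[n], 32.5, tolerance = 1e-9)
  arc_km <- abs(tr$steps$lon[n] - 130.0) * pi / 180 * 6371 * cos(32.5 * pi / 180)
  expect_equal(arc_km, 608.4, tolerance = 1e-3)
  expect_lt(tr$steps$lon[n], 130.0)  # upwind = west of the start
})

test_that("zero wind and zero self speed give a stationary trajectory", {
  f <- tiny_uniform_field(u0 = 0, v0 = 0, lat_range = c(30, 34),
                          lon_range = c(128, 132))
  fp <- flight_params(self_speed = 0)
  st <- build_start_ensemble(32, 130, as.Date("2020-05-28"), fp)[1, ]
  tr <- integrate_backward(st, f, fp)
  expect_true(all(tr$steps$lat == 32) && all(tr$steps$lon == 130))
})

test_that("solid-body rotation with period = duration closes the loop", {
  omega <- 2 * pi / (13 * 3600)
  f <- gen_wind_field(wind_field_spec("rotational", omega = omega,
                                      center = c(32.5, 130), T0 = 20,
                                      lat_range = c(28, 37),
                                      lon_range = c(125, 135)))
  fp <- flight_params(self_speed = 0, time_step = 600)
  ens <- build_start_ensemble(32.95, 130.0, as.Date("2020-05-28"), fp)
  st <- ens[ens$start_hour_utc == 0 & ens$start_height == 500, ]  # r ~ 50 km
  tr <- integrate_backward(st, f, fp)
  n <- nrow(tr$steps)
  err_m <- sqrt(((tr$steps$lat[n] - 32.95) * 111194.9)^2 +
                ((tr$steps$lon[n] - 130) * 111194.9 * cos(32.5 * pi / 180))^2)
  expect_lt(err_m, 0.02 * 0.45 * 111194.9)  # within 2% of the orbit radius
})

test_that("halving the step barely moves the terminal point", {
  f <- gen_wind_field(wind_field_spec("rotational", omega = 2 * pi / (13 * 3600),
                                      center = c(32.5, 130), T0 = 20,
                                      lat_range = c(28, 37),
                                      lon_range = c(125, 135)))
  st <- build_start_ensemble(32.95, 130.0, as.Date("2020-05-28"),
                             flight_params())[1, ]
  st$start_height <- 500
  t1 <- integrate_backward(st, f, flight_params(self_speed = 0,
                                                time_step = 600))
  t2 <- integrate_backward(st, f, flight_params(self_speed = 0,
                                                time_step = 300))
  p1 <- t1$steps[nrow(t1$steps), ]; p2 <- t2$steps[nrow(t2$steps), ]
  shift_m <- sqrt(((p1$lat - p2$lat) * 111194.9)^2 +
                  ((p1$lon - p2$lon) * 111194.9 * cos(32.5 * pi / 180))^2)
  expect_lt(shift_m, 1000)
})

test_that("forward re-integration from the terminal recovers the start", {
  f <- tiny_uniform_field(u0 = 8, v0 = 3, T0 = 20)
  fp <- flight_params()
  st <- build_start_ensemble(32.5, 130.0, as.Date("2020-05-28"), fp)[1, ]
  st$start_height <- 500
  tr <- integrate_backward(st, f, fp)
  n <- nrow(tr$steps)
  # forward integration = backward integration in the reversed field
  f_rev <- f; f_rev$u <- -f$u; f_rev$v <- -f$v
  st2 <- st
  st2$site_lat <- tr$steps$lat[n]; st2$site_lon <- tr$steps$lon[n]
  st2$start_time <- st$start_time
  st2$terminal_time <- st$start_time - (as.numeric(st$start_time) -
                                        as.numeric(st$terminal_time))
  back <- integrate_backward(st2, f_rev, fp)
  m <- nrow(back$steps)
  err_m <- sqrt(((back$steps$lat[m] - 32.5) * 111194.9)^2 +
                ((back$steps$lon[m] - 130.0) * 111194.9 *
                 cos(32.5 * pi / 180))^2)
  expect_lt(err_m, 2000)
})

test_that("temperature gates invalidate trajectories for the right reason", {
  fp <- flight_params()
  # cold layer crossing the flight height: enroute_cold
  f_cold <- gen_wind_field(wind_field_spec("layered_cold", u0 = 5, T0 = 15,
                                           lapse = 0, cold_T = 8.9,
                                           cold_band = c(400, 600),
                                           lat_range = c(28, 36),
                                           lon_range = c(122, 134)))
  st <- build_start_ensemble(32, 130, as.Date("2020-05-28"), fp)
  st <- st[st$start_hour_utc == 0 & st$start_height == 500, ]
  tr <- integrate_backward(st, f_cold, fp)
  expect_false(tr$valid)
  expect_identical(tr$invalid_reason, "enroute_cold")
  # warm en route but terminal in [9, 11): takeoff_cold
  tr2 <- structure(list(steps = data.frame(temp_C = c(15, 14, 12, 10.5)),
                        valid = TRUE, invalid_reason = "none",
                        params = fp),
                   class = "flight_trajectory")
  out2 <- apply_validity_filters(tr2, fp)
  expect_false(out2$valid)
  expect_identical(out2$invalid_reason, "takeoff_cold")
  # all steps warm: valid
  tr3 <- tr2; tr3$steps$temp_C <- c(15, 15, 15, 15)
  expect_true(apply_validity_filters(tr3, fp)$valid)
  # terminal below 9: the en-route reason takes precedence
  tr4 <- tr2; tr4$steps$temp_C <- c(15, 14, 12, 8.5)
  expect_identical(apply_validity_filters(tr4, fp)$invalid_reason,
                   "enroute_cold")
  # boundary: 8.9 degC en route is cold (strict < 9 threshold is exclusive
  # of 9 itself)
  tr5 <- tr2; tr5$steps$temp_C <- c(15, 8.9, 15, 15)
  expect_identical(apply_validity_filters(tr5, fp)$invalid_reason,
                   "enroute_cold")
  tr6 <- tr2; tr6$steps$temp_C <- c(15, 9, 15, 11)
  expect_true(apply_validity_filters(tr6, fp)$valid)
})

test_that("raising the temperature gates never recovers validity", {
  f <- gen_wind_field(wind_field_spec("uniform", u0 = 6, T0 = 13,
                                      lapse = 0.002, lat_range = c(28, 36),
                                      lon_range = c(122, 134)))
  fp0 <- small_params()
  ens <- build_start_ensemble(32, 130, as.Date("2020-05-28"), fp0)
  trajs <- lapply(seq_len(nrow(ens)), function(i)
    integrate_backward(ens[i, ], f, fp0))
  n_valid <- function(p) sum(vapply(trajs, function(tr)
    apply_validity_filters(tr, p)$valid, logical(1)))
  v1 <- n_valid(flight_params(t_enroute_min = 9, t_takeoff_min = 11))
  v2 <- n_valid(flight_params(t_enroute_min = 10, t_takeoff_min = 11))
  v3 <- n_valid(flight_params(t_enroute_min = 10, t_takeoff_min = 12))
  expect_gte(v1, v2); expect_gte(v2, v3)
})

test_that("leaving the domain truncates and marks the trajectory", {
  f <- tiny_uniform_field(u0 = 30, v0 = 0, lat_range = c(31, 34),
                          lon_range = c(129, 132))
  fp <- flight_params()
  st <- build_start_ensemble(32.5, 129.5, as.Date("2020-05-28"), fp)[1, ]
  st$start_height <- 500
  tr <- integrate_backward(st, f, fp)
  expect_false(tr$valid)
  expect_identical(tr$invalid_reason, "left_domain")
  expect_lt(nrow(tr$steps), 13 * 6 + 1)
  # start outside the hull is a rejected input
  st_bad <- st; st_bad$site_lat <- 50
  expect_error(integrate_backward(st_bad, f, fp), "outside")
})

test_that("trajectory tables are written in the documented layout", {
  f <- tiny_uniform_field(u0 = 10, lat_range = c(28, 36),
                          lon_range = c(122, 134))
  fp <- flight_params()
  st <- build_start_ensemble(32, 130, as.Date("2020-05-28"), fp)[1, ]
  tr <- integrate_backward(st, f, fp)
  tmp <- tempfile(fileext = ".tsv")
  write_trajectories(list(tr), tmp)
  tab <- read.delim(tmp)
  expect_identical(names(tab),
                   c("trajectory_id", "step", "timestamp", "lat", "lon",
                     "height_m_agl", "temp_C", "valid", "invalid_reason"))
  expect_identical(nrow(tab), nrow(tr$steps))
})
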