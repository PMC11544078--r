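# Source mapping: analytical periods, frequency gridding, smoothing,
# sea masking and the origin decision table.

test_that("analytical period follows the 3 + interval - 1 rule", {
  cd <- as.Date("2020-05-29")
  expect_length(analytical_period(cd, 1)$dates, 3)
  expect_length(analytical_period(cd, 7)$dates, 9)
  expect_length(analytical_period(cd, 3)$dates, 5)
  for (k in 1:7)
    expect_length(analytical_period(cd, k)$dates, 3 + k - 1)
  p <- analytical_period(cd, 2)
  expect_identical(max(p$dates), cd)
  expect_true(all(diff(as.numeric(p$dates)) == 1))
  expect_error(analytical_period(cd, 0), ">= 1")
})

test_that("terminal-point collection runs the full ensemble per date", {
  f <- tiny_uniform_field(u0 = 8, v0 = 1, T0 = 22,
                          time_start = as.POSIXct("2020-05-25 00:00:00",
                                                  tz = "UTC"))
  fp <- small_params()  # 24 x 2 = 48 starts per date
  per <- analytical_period(as.Date("2020-05-29"), 1)
  tps <- collect_terminal_points(32.6, 130.2, per, f, fp)
  expect_identical(attr(tps, "n_trajectories"), 3L * 48L)
  expect_identical(nrow(tps), 3L * 48L)  # warm uniform field: all valid
  # a cold layer across all heights kills every trajectory
  f_cold <- gen_wind_field(wind_field_spec("layered_cold", u0 = 8, T0 = 22,
                                           lapse = 0, cold_T = 5,
                                           cold_band = c(0, 2000),
                                           time_start = as.POSIXct(
                                             "2020-05-25 00:00:00",
                                             tz = "UTC")))
  tps0 <- collect_terminal_points(32.6, 130.2, per, f_cold, fp)
  expect_identical(nrow(tps0), 0L)
  expect_identical(sum(attr(tps0, "invalid_reasons")), 3L * 48L)
  # insufficient field coverage is a rejected input
  f_short <- tiny_uniform_field(u0 = 8, n_times = 3,
                                time_start = as.POSIXct(
                                  "2020-05-29 00:00:00", tz = "UTC"))
  expect_error(collect_terminal_points(32.6, 130.2, per, f_short, fp),
               "cover")
})

test_that("frequency gridding uses half-open 0.25-degree cells", {
  bbox <- c(120, 125, 25, 30)
  # empty input: all-zero grid
  g0 <- grid_frequency(data.frame(lat = numeric(0), lon = numeric(0)), bbox)
  expect_identical(sum(g0$counts), 0L)
  expect_identical(dim(g0$counts), c(20L, 20L))
  # one interior point: exactly one occupied cell
  g1 <- grid_frequency(data.frame(lat = 26.1, lon = 121.1), bbox)
  expect_identical(sum(g1$counts), 1L)
  expect_identical(g1$counts[floor((26.1 - 25) / 0.25) + 1,
                             floor((121.1 - 120) / 0.25) + 1], 1L)
  # a point exactly on a shared edge belongs to the cell east/north of it
  g2 <- grid_frequency(data.frame(lat = 26.25, lon = 121.50), bbox)
  expect_identical(g2$counts[6, 7], 1L)   # cell [26.25, 26.5) x [121.5, 121.75)
  # exhaustive boundary placements: every edge point lands in the half-open cell
  for (lat in c(25, 25.25, 27.5)) for (lon in c(120, 122.75)) {
    g <- grid_frequency(data.frame(lat = lat, lon = lon), bbox)
    i <- floor((lat - 25) / 0.25) + 1; j <- floor((lon - 120) / 0.25) + 1
    expect_identical(g$counts[i, j], 1L)
  }
  # points outside the bbox are dropped and counted
  g3 <- grid_frequency(data.frame(lat = c(26, 40), lon = c(121, 121)), bbox)
  expect_identical(sum(g3$counts), 1L)
  expect_identical(g3$n_dropped, 1L)
})

test_that("smoothing is the 3x3 mass-conserving kernel", {
  bbox <- c(120, 125, 25, 30)
  # single interior cell of count 9: itself and its 8 neighbors at 1.0
  pts <- data.frame(lat = rep(26.1, 9), lon = rep(121.1, 9))
  g <- smooth_grid(grid_frequency(pts, bbox))
  i <- floor((26.1 - 25) / 0.25) + 1; j <- floor((121.1 - 120) / 0.25) + 1
  expect_equal(g$smoothed[i + (-1:1), j + (-1:1)], matrix(1, 3, 3))
  expect_equal(sum(g$smoothed), 9)
  # all-zero stays all-zero
  g0 <- smooth_grid(grid_frequency(data.frame(lat = numeric(0),
                                              lon = numeric(0)), bbox))
  expect_true(all(g0$smoothed == 0))
  # conservation on random grids, including corner/edge mass
  set.seed(33)
  for (k in 1:10) {
    pts <- data.frame(lat = runif(40, 25, 30), lon = runif(40, 120, 125))
    pts$lat[1:4] <- c(25.01, 29.99, 25.01, 29.99)  # near corners
    pts$lon[1:4] <- c(120.01, 124.99, 124.99, 120.01)
    gk <- smooth_grid(grid_frequency(pts, bbox))
    expect_equal(sum(gk$smoothed), sum(gk$counts), tolerance = 1e-12)
    expect_true(all(gk$smoothed >= 0))
  }
})

test_that("sea masking removes mass and only mass", {
  bbox <- c(120, 130, 25, 30)
  set.seed(34)
  pts <- data.frame(lat = runif(60, 25, 30), lon = runif(60, 120, 130))
  g <- smooth_grid(grid_frequency(pts, bbox))
  expect_identical(mask_sea(g, gen_landmask("all_land", bbox))$smoothed,
                   g$smoothed)
  expect_true(all(mask_sea(g, gen_landmask("all_sea", bbox))$smoothed == 0))
  m <- gen_landmask("meridian_split", bbox, L0 = 125,
                    island_band = c(128, 129))
  gm <- mask_sea(g, m)
  expect_true(all(gm$smoothed[!m$land] == 0))
  expect_identical(gm$smoothed[m$land], g$smoothed[m$land])
  expect_lte(sum(gm$smoothed), sum(g$smoothed))
  expect_true(gm$masked)
  # raw counts retained
  expect_identical(gm$counts, g$counts)
  # geometry mismatch rejected
  expect_error(mask_sea(g, gen_landmask("all_land", c(120, 130, 20, 30))),
               "geometry")
})

test_that("the origin decision table is total and matches the case logic", {
  bbox <- c(105, 140, 20, 45)
  regions <- region_set(
    name = c("outbreak_belt", "west_honshu", "south_kyushu", "trap_area"),
    kind = c("continental", "domestic_high_ratio", "domestic_low_ratio",
             "local"),
    lat_min = c(30, 33, 30, 32), lat_max = c(38, 36, 32, 33.5),
    lon_min = c(105, 131, 129.5, 129.5), lon_max = c(123, 137, 132, 131))
  gr_at <- function(lat, lon)
    smooth_grid(grid_frequency(data.frame(lat = lat, lon = lon), bbox))
  # mass only over the continental belt + high isotope ratio -> continental
  a1 <- attribute_origin("above_cutoff", gr_at(34, 118), regions)
  expect_identical(a1$final_call, "continental")
  # continental AND high-ratio domestic reached -> undeterminable
  a2 <- attribute_origin("above_cutoff", gr_at(c(34, 34.5), c(118, 133)),
                         regions)
  expect_identical(a2$final_call, "undeterminable")
  # only high-ratio domestic -> domestic_nonlocal
  a3 <- attribute_origin("above_cutoff", gr_at(34.5, 133), regions)
  expect_identical(a3$final_call, "domestic_nonlocal")
  # low ratio + only a distant low-ratio region -> domestic_nonlocal
  a4 <- attribute_origin("at_or_below_cutoff", gr_at(31, 130.7), regions)
  expect_identical(a4$final_call, "domestic_nonlocal")
  # low ratio + local trap area -> local
  a5 <- attribute_origin("at_or_below_cutoff", gr_at(32.8, 130.2), regions)
  expect_identical(a5$final_call, "local")
  # nothing reached -> undeterminable (either isotope call)
  a6 <- attribute_origin("above_cutoff", gr_at(numeric(0), numeric(0)),
                         regions)
  a7 <- attribute_origin("at_or_below_cutoff", gr_at(numeric(0), numeric(0)),
                         regions)
  expect_identical(a6$final_call, "undeterminable")
  expect_identical(a7$final_call, "undeterminable")
  # determinism and totality over every (call, kind subset) combination
  kinds <- c("continental", "domestic_high_ratio", "domestic_low_ratio",
             "local")
  probe <- list(continental = c(34, 118), domestic_high_ratio = c(34.5, 133),
                domestic_low_ratio = c(31, 130.7), local = c(32.8, 130.2))
  for (call in c("above_cutoff", "at_or_below_cutoff")) {
    for (bits in 0:15) {
      sel <- kinds[bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0]
      lat <- vapply(sel, function(k) probe[[k]][1], numeric(1))
      lon <- vapply(sel, function(k) probe[[k]][2], numeric(1))
      out <- attribute_origin(call, gr_at(lat, lon), regions)
      expect_true(out$final_call %in% c("continental", "domestic_nonlocal",
                                        "local", "undeterminable"))
      again <- attribute_origin(call, gr_at(lat, lon), regions)
      expect_identical(out$final_call, again$final_call)
    }
  }
  expect_error(attribute_origin("above_cutoff", gr_at(34, 118),
                                regions[0, ]), "non-empty")
})

test_that("frequency grids round-trip through CSV and NetCDF", {
  bbox <- c(120, 123, 25, 28)
  set.seed(35)
  g <- smooth_grid(grid_frequency(
    data.frame(lat = runif(20, 25, 28), lon = runif(20, 120, 123)), bbox))
  tmp <- tempfile(fileext = ".csv")
  write_frequency_grid_csv(g, tmp)
  df <- read.csv(tmp)
  expect_equal(sum(df$raw), sum(g$counts))
  expect_equal(sum(df$smoothed), sum(g$smoothed), tolerance = 1e-9)
  tmpn <- tempfile(fileext = ".nc")
  write_frequency_grid_nc(g, tmpn)
  nc <- ncdf4::nc_open(tmpn)
  raw <- ncdf4::ncvar_get(nc, "raw")
  ncdf4::nc_close(nc)
  expect_equal(sum(raw), sum(g$counts))
})

test_that("wind fields round-trip through CSV and NetCDF", {
  f <- gen_wind_field(wind_field_spec("sheared", u0 = 2, shear = 0.005,
                                      lat_range = c(30, 33),
                                      lon_range = c(128, 132),
                                      heights = c(0, 500, 1000),
                                      n_times = 3, diurnal_amplitude = 2))
  tmp <- tempfile(fileext = ".csv")
  write_wind_field_csv(f, tmp)
  f2 <- read_wind_field_csv(tmp)
  expect_equal(f2$u, f$u); expect_equal(f2$temp, f$temp)
  expect_equal(as.numeric(f2$time), as.numeric(f$time))
  tmpn <- tempfile(fileext = ".nc")
  write_wind_field_nc(f, tmpn)
  f3 <- read_wind_field_nc(tmpn)
  expect_equal(f3$u, f$u); expect_equal(f3$v, f$v); expect_equal(f3$temp, f$temp)
  expect_equal(f3$lat, f$lat); expect_equal(as.numeric(f3$time),
                                            as.numeric(f$time))
})
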