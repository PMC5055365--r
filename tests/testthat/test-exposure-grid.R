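# Exposure grid container, nearest-centroid join, and lookups.

test_that("grid round-trips through CSV at full precision", {
  g <- toy_grid()
  path <- tempfile(fileext = ".csv")
  write_grid_csv(g, path)
  g2 <- read_grid_csv(path)
  expect_equal(g2$hmax, g$hmax, tolerance = 1e-12)
  expect_equal(g2$cells, g$cells)
  expect_equal(g2$dates, g$dates)
})

test_that("grid accepts either humidity dialect and derives the same hmax", {
  df <- data.frame(date = "2010-06-01", lat = 46, lon = -120,
                   tmax_c = 30, rh_pct = 50)
  g_rh <- exposure_grid(df)
  df2 <- data.frame(date = "2010-06-01", lat = 46, lon = -120,
                    tmax_c = 30, tdew_c = dewpoint_from_rh(30, 50))
  g_td <- exposure_grid(df2)
  expect_equal(g_rh$hmax, g_td$hmax, tolerance = 1e-12)
  expect_equal(g_rh$humidity, "rh")
  expect_equal(g_td$humidity, "dewpoint")
})

test_that("duplicate cell-days and missing humidity are rejected", {
  df <- data.frame(date = c("2010-06-01", "2010-06-01"), lat = 46,
                   lon = -120, tmax_c = c(30, 31), rh_pct = 50)
  expect_error(exposure_grid(df), "duplicate")
  expect_error(exposure_grid(df[1, c("date", "lat", "lon", "tmax_c")]),
               "humidity")
})

test_that("regular-spacing check accepts 1/16-degree lattices only", {
  ok <- expand.grid(lat = 46 + (0:3) / 16, lon = -120 + (0:3) / 16)
  ok$date <- "2010-06-01"; ok$tmax_c <- 25; ok$rh_pct <- 50
  expect_s3_class(exposure_grid(ok, check_regular = TRUE), "exposure_grid")
  bad <- ok
  bad$lat <- 46 + (0:3) / 10
  expect_error(exposure_grid(bad, check_regular = TRUE), "1/16")
})

test_that("nearest cell is exact at centroids and ties go lexicographic", {
  g <- toy_grid()
  for (i in c(1, 5, nrow(g$cells))) {
    expect_equal(nearest_cell(g$cells$lat[i], g$cells$lon[i], g),
                 g$cells$cell_id[i])
  }
  # midpoint between two lon-adjacent centroids: lexicographically smaller
  expect_equal(nearest_cell(46.0, -120.09375, g),
               g$cells$cell_id[g$cells$lat == 46.0 &
                                 g$cells$lon == -120.125])
  # midpoint in both axes: smallest (lat, lon)
  expect_equal(nearest_cell(46.03125, -120.09375, g),
               g$cells$cell_id[g$cells$lat == 46.0 &
                                 g$cells$lon == -120.125])
})

test_that("nearest cell agrees with a brute-force scan on random points", {
  set.seed(7)
  lats <- sort(runif(20, 45, 47))
  lons <- sort(runif(20, -121, -119))
  cells <- expand.grid(lat = lats, lon = lons)
  df <- data.frame(date = "2010-06-01", lat = cells$lat, lon = cells$lon,
                   tmax_c = 20, rh_pct = 50)
  g <- exposure_grid(df)
  qlat <- runif(1000, 44.5, 47.5)
  qlon <- runif(1000, -121.5, -118.5)
  got <- nearest_cell(qlat, qlon, g)
  brute <- vapply(seq_along(qlat), function(i) {
    d2 <- (g$cells$lat - qlat[i])^2 + (g$cells$lon - qlon[i])^2
    g$cells$cell_id[which.min(d2)]
  }, integer(1))
  expect_equal(got, brute)
})

test_that("nearest cell works for non-lattice centroid sets too", {
  set.seed(8)
  cells <- data.frame(lat = runif(37, 45, 47), lon = runif(37, -121, -119))
  df <- data.frame(date = "2010-06-01", lat = cells$lat, lon = cells$lon,
                   tmax_c = 20, rh_pct = 50)
  g <- exposure_grid(df)
  qlat <- runif(300, 45, 47); qlon <- runif(300, -121, -119)
  got <- nearest_cell(qlat, qlon, g)
  brute <- vapply(seq_along(qlat), function(i) {
    d2 <- (g$cells$lat - qlat[i])^2 + (g$cells$lon - qlon[i])^2
    g$cells$cell_id[which.min(d2)]
  }, integer(1))
  expect_equal(got, brute)
  expect_error(nearest_cell(46, -120,
                            structure(list(cells = g$cells[0, ]),
                                      class = "exposure_grid")), "empty")
})

test_that("hmax lookup returns the derived Humidex and errors on misses", {
  df <- data.frame(date = rep(c("2010-06-01", "2010-06-02"), each = 2),
                   lat = rep(c(46, 47), 2), lon = -120,
                   tmax_c = c(30, 30, 22, 22), rh_pct = 50)
  g <- exposure_grid(df)
  td <- dewpoint_from_rh(30, 50)
  expect_equal(daily_max_humidex(g, nearest_cell(46, -120, g), "2010-06-01"),
               humidex(30, td), tolerance = 1e-12)
  # identical meteorology in two cells gives identical hmax
  expect_equal(daily_max_humidex(g, 1L, "2010-06-01"),
               daily_max_humidex(g, 2L, "2010-06-01"))
  expect_error(daily_max_humidex(g, 1L, "2010-06-03"),
               "2010-06-03")
  expect_error(daily_max_humidex(g, 99L, "2010-06-01"), "99")
})

test_that("a synthetic grid with a closed-form field reproduces it exactly", {
  g <- toy_grid(rh = 60)
  # pick an arbitrary cell-day and recompute from the closed form
  ci <- 4L; di <- 17L
  lat <- g$cells$lat[ci]
  tm <- 20 + 0.2 * di + 10 * (lat - 46)
  expect_equal(g$tmax[ci, di], tm, tolerance = 1e-12)
  expect_equal(daily_max_humidex(g, g$cells$cell_id[ci], g$dates[di]),
               humidex(tm, dewpoint_from_rh(tm, 60)), tolerance = 1e-12)
})
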