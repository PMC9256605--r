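test_that("haversine matches closed forms and basic metric properties", {
  expect_equal(haversine(0, 0, 0, 0), 0)
  expect_equal(haversine(0, 0, 90, 0), pi * 6371 / 2, tolerance = 1e-9)
  expect_equal(haversine(0, 0, 0, 90), pi * 6371 / 2, tolerance = 1e-9)
  expect_equal(haversine(0, 0, 0, 1), 2 * pi * 6371 / 360, tolerance = 1e-9)
  expect_equal(haversine(0, 0, 0, 1), 111.195, tolerance = 1e-5)
  expect_equal(haversine(12, 34, -5, 101), haversine(-5, 101, 12, 34))
  expect_error(haversine(91, 0, 0, 0), "latitude")
})

test_that("haversine agrees with an independent geodesic implementation", {
  skip_if_not_installed("geosphere")
  set.seed(4)
  p1 <- cbind(runif(50, -180, 180), runif(50, -85, 85))
  p2 <- cbind(runif(50, -180, 180), runif(50, -85, 85))
  ref <- geosphere::distHaversine(p1, p2, r = 6371000) / 1000
  expect_equal(haversine(p1[, 2], p1[, 1], p2[, 2], p2[, 1]), ref,
               tolerance = 1e-9)
})

test_that("nearest-ocean-cell selection matches an exhaustive sort oracle", {
  g <- toy_grid(lat = seq(-4.5, 4.5), lon = seq(100.5, 109.5))
  site <- list(lat = 0.3, lon = 104.2)

  sel <- select_ocean_cells(site, g, n = 20)
  d_all <- haversine(site$lat, site$lon,
                     rep(g$lat, times = 10), rep(g$lon, each = 10))
  expect_equal(sort(sel$dist_km), sort(d_all)[1:20], tolerance = 1e-12)
  expect_equal(sel$dist_km, sort(sel$dist_km))  # ordered nearest first

  one <- select_ocean_cells(list(lat = g$lat[3], lon = g$lon[7]), g, n = 1)
  expect_equal(c(one$lat, one$lon), c(g$lat[3], g$lon[7]))
  expect_equal(one$dist_km, 0)

  expect_error(select_ocean_cells(site, g, n = 0), "at least 1")
  expect_error(select_ocean_cells(site, g, n = 101), "ocean cells")
})

test_that("distance ties break deterministically by latitude then longitude", {
  g <- toy_grid(lat = c(-1, 1), lon = c(100, 102))
  # site equidistant from all four cells
  sel <- select_ocean_cells(list(lat = 0, lon = 101), g, n = 4)
  expect_equal(sel$lat, c(-1, -1, 1, 1))
  expect_equal(sel$lon, c(100, 102, 100, 102))
})

test_that("land-window selection filters the centered block by mask", {
  all_land <- toy_grid(lat = seq(-7.75, 7.75, by = 0.5),
                       lon = seq(100.25, 115.75, by = 0.5),
                       mask = matrix(1L, 32, 32))
  w <- select_land_window(list(lat = 0.1, lon = 108), all_land, window = 11)
  expect_equal(nrow(w), 121)

  # one-cell island
  island <- matrix(0L, 32, 32); island[16, 16] <- 1L
  gi <- toy_grid(lat = all_land$lat, lon = all_land$lon, mask = island)
  wi <- select_land_window(list(lat = all_land$lat[16], lon = all_land$lon[16]),
                           gi, window = 11)
  expect_equal(nrow(wi), 1)

  # mixed mask against a brute-force filter oracle
  set.seed(12)
  mm <- matrix(rbinom(32 * 32, 1, 0.5), 32, 32)
  gm <- toy_grid(lat = all_land$lat, lon = all_land$lon, mask = mm)
  site <- list(lat = 1.3, lon = 107.1)
  got <- select_land_window(site, gm, window = 11)
  i <- which.min(abs(gm$lat - site$lat)); j <- which.min(abs(gm$lon - site$lon))
  oracle <- expand.grid(lat_idx = (i - 5):(i + 5), lon_idx = (j - 5):(j + 5))
  oracle <- oracle[mm[as.matrix(oracle)] == 1L, ]
  expect_setequal(paste(got$lat_idx, got$lon_idx),
                  paste(oracle$lat_idx, oracle$lon_idx))

  ocean_only <- toy_grid(lat = all_land$lat, lon = all_land$lon,
                         mask = matrix(0L, 32, 32))
  expect_error(select_land_window(site, ocean_only, window = 11), "no land")
  expect_error(select_land_window(site, gm, window = 10), "odd")
})

test_that("relative change reproduces hand arithmetic", {
  g <- toy_grid(lat = 0, lon = 100, hist_value = 100, fut_value = 100)
  cells <- data.frame(lat_idx = 1, lon_idx = 1)
  expect_equal(run_relative_change(g, cells), c(0, 0))

  g2 <- toy_grid(lat = 0, lon = 100, hist_value = 100, fut_value = 80)
  expect_equal(run_relative_change(g2, cells), c(-20, -20))

  # two cells: historical (100, 200), future (90, 220) -> +10/3 %
  g3 <- toy_grid(lat = c(0, 1), lon = 100, n_runs = 1)
  g3$values[1, g3$years <= 2013, , 1] <- c(100, 200)
  g3$values[1, g3$years >= 2046, , 1] <- c(90, 220)
  cells2 <- data.frame(lat_idx = c(1, 2), lon_idx = c(1, 1))
  expect_equal(run_relative_change(g3, cells2), 100 * (155 - 150) / 150,
               tolerance = 1e-12)
  expect_equal(run_relative_change(g3, cells2), 10 / 3, tolerance = 1e-12)

  # invalid historical baseline flags the run as missing
  g4 <- toy_grid(lat = 0, lon = 100, hist_value = 0, fut_value = 10)
  expect_true(all(is.na(run_relative_change(g4, cells))))
})

test_that("ensemble statistics follow the stated agreement rules", {
  x <- c(rep(-10, 12), rep(2, 4))
  s <- ensemble_stats(x)
  expect_equal(s$agreement, 12 / 16)
  expect_lt(s$mean, 0)

  s2 <- ensemble_stats(rep(-10, 5))
  expect_equal(s2[c("mean", "p25", "p75", "agreement")],
               list(mean = -10, p25 = -10, p75 = -10, agreement = 1))

  # zero-change runs agree with either direction
  s3 <- ensemble_stats(c(-4, -2, 0, 2))
  expect_equal(s3$mean, -1)
  expect_equal(s3$agreement, 3 / 4)

  # quantiles use linear interpolation
  s4 <- ensemble_stats(c(1, 2, 3, 4))
  expect_equal(c(s4$p25, s4$p75), unname(quantile(1:4, c(.25, .75))))

  expect_equal(ensemble_stats(c(-1, 0, 1))$agreement, 2 / 3)  # zero mean
  expect_error(ensemble_stats(c(1, NA, NA)), "at least 2")
  # NA runs shrink the agreement denominator
  expect_equal(ensemble_stats(c(-1, -2, NA, 3))$n_runs, 3)
})

test_that("agreement is 1 whenever all runs share the mean sign", {
  set.seed(9)
  for (i in 1:50) {
    x <- abs(rnorm(16)) * sample(c(-1, 1), 1)
    expect_equal(ensemble_stats(x)$agreement, 1)
  }
})

test_that("crop composites average and weight as specified", {
  expect_equal(crop_composite(c(rice = 9, maize = -3, cassava = -3)), 1)
  expect_equal(crop_composite(c(rice = 5, maize = NA, cassava = NA)), 5)
  expect_equal(crop_composite(c(rice = 7, maize = -2, cassava = 4),
                              weights = c(1, 0, 0)), 7)
  expect_equal(crop_composite(c(rice = 10, maize = 20, cassava = NA),
                              weights = c(1, 3, 5)), (10 + 60) / 4)
  expect_error(crop_composite(c(rice = 1, maize = NA), weights = c(0, 1)),
               "sum to 0")
  expect_error(crop_composite(c(rice = NA_real_)), "no crop")
})

test_that("the composite exposure is the sector average", {
  expect_equal(composite_exposure(10, -20), -5)
  expect_equal(composite_exposure(0, 0), 0)
  expect_equal(composite_exposure(1.2, -14.7), -6.75)
  # linear: doubling both sector exposures doubles the composite
  expect_equal(composite_exposure(2 * 1.2, 2 * -14.7),
               2 * composite_exposure(1.2, -14.7))
})

test_that("extraction is invariant to a longitude translation", {
  cfg <- small_config(seed = 13)
  g <- generate_grids(cfg)$ssp585
  site <- list(lat = 0.7, lon = 105.3)
  ex1 <- site_exposure(site, g$fisheries, g$crops)

  shift <- function(ge, dlon) { ge$lon <- ge$lon + dlon; ge }
  g2 <- list(fisheries = shift(g$fisheries, 40),
             crops = lapply(g$crops, shift, dlon = 40))
  ex2 <- site_exposure(list(lat = 0.7, lon = 145.3), g2$fisheries, g2$crops)
  expect_equal(ex1[, setdiff(names(ex1), c("lon"))],
               ex2[, setdiff(names(ex2), c("lon"))], tolerance = 1e-10)
})

test_that("per-crop changes feed a run-keyed agriculture composite", {
  cfg <- small_config(run_sd = 0, spatial_sd = 0, interannual_sd = 0,
                      scenarios = list(s = c(fisheries = -0.1, agriculture = 0.05)))
  g <- generate_grids(cfg)$s
  ex <- site_exposure(list(lat = 0.4, lon = 106.2), g$fisheries, g$crops)
  expect_equal(ex$n_runs_A, 20)  # cassava's 5 runs fold into the 20
  expect_equal(ex$E_A_rice, 5, tolerance = 1e-9)
  expect_equal(ex$E_A_cassava, 5, tolerance = 1e-9)
  expect_equal(ex$E_A, 5, tolerance = 1e-9)
  expect_equal(ex$E_AF, composite_exposure(ex$E_A, ex$E_F), tolerance = 1e-12)
})

test_that("cell-count sensitivity is flat on noise-free grids and matches the default", {
  cfg <- small_config(run_sd = 0, spatial_sd = 0, interannual_sd = 0,
                      scenarios = list(s = c(fisheries = -0.15, agriculture = 0)))
  g <- generate_grids(cfg)$s$fisheries
  site <- list(lat = 0.4, lon = 104)
  tab <- cell_count_sensitivity(site, g, counts = c(1, 3, 5, 10, 20, 50))
  expect_equal(tab$mean, rep(-15, 6), tolerance = 1e-9)
  expect_equal(tab$agreement, rep(1, 6))

  g2 <- generate_grids(small_config(seed = 23))$ssp585$fisheries
  tab2 <- cell_count_sensitivity(site, g2, counts = 20)
  ex <- site_exposure(site, g2, generate_grids(small_config(seed = 23))$ssp585$crops)
  expect_equal(tab2$mean, ex$E_F, tolerance = 1e-12)
  expect_equal(tab2$agreement, ex$agreement_F)
})

test_that("grid ensembles round-trip through CSV", {
  g <- toy_grid(lat = c(0, 1), lon = c(100, 101), n_runs = 2,
                years_hist = 2000:2001, years_fut = 2050:2051,
                mask = matrix(c(1L, 0L, 0L, 1L), 2, 2))
  g$values[] <- seq_len(length(g$values))
  path <- tempfile(fileext = ".csv")
  write_grid_csv(g, path)
  g2 <- read_grid_csv(path, scenario = g$scenario, sector = g$sector)
  expect_equal(g2$values, g$values)
  expect_equal(g2$mask, g$mask)
  expect_equal(g2$lat, g$lat)
})

test_that("grid ensembles round-trip through NetCDF", {
  skip_if_not_installed("ncdf4")
  g <- toy_grid(lat = c(0, 1, 2), lon = c(100, 101), n_runs = 3,
                years_hist = 2000:2001, years_fut = 2050:2051,
                mask = matrix(rbinom(6, 1, 0.5), 3, 2))
  g$values[] <- rnorm(length(g$values))
  path <- tempfile(fileext = ".nc")
  write_grid_ncdf(g, path)
  g2 <- read_grid_ncdf(path)
  expect_equal(g2$values, g$values, tolerance = 1e-12)
  expect_equal(g2$mask, g$mask)
  expect_equal(g2$runs$run_id, g$runs$run_id)
  expect_equal(g2$scenario, g$scenario)
})
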