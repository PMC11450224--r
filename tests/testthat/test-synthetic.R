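test_that("meteorology generator is deterministic and respects bounds", {
  g <- tiny_grid()
  m1 <- gen_meteo(g, 20, seed = 7)
  m2 <- gen_meteo(g, 20, seed = 7)
  expect_identical(m1$T, m2$T)
  expect_identical(m1$P, m2$P)
  m3 <- gen_meteo(g, 20, seed = 8)
  expect_false(identical(m1$T, m3$T))
  expect_true(all(m1$q >= 0 & m1$q <= 100))
  expect_true(all(m1$P >= 0))
  expect_true(all(m1$U >= 0))
  expect_error(gen_meteo(g, 0, seed = 1), "n_days")
})

test_that("temperature carries the southward-warm gradient", {
  g <- grid_spec(0, 10, 40, 60, 10, 10)
  m <- gen_meteo(g, 30, seed = 3)
  south <- mean(m$T[, 1, ])
  north <- mean(m$T[, 10, ])
  expect_gt(south, north)
})

test_that("streamfunction winds are divergence-free in the interior", {
  g <- grid_spec(0, 10, 45, 55, 10, 10)
  m <- gen_meteo(g, 3, seed = 5)
  u <- m$u[, , 2] - mean(m$u[, , 2]) + m$u[, , 2] * 0  # keep full field
  u <- m$u[, , 2]; v <- m$v[, , 2]
  # index-space divergence du/dx + dv/dy on interior cells
  div <- (u[3:10, 2:9] - u[1:8, 2:9]) / 2 + (v[2:9, 3:10] - v[2:9, 1:8]) / 2
  expect_lt(max(abs(div)), 1e-9 * max(abs(u)))
})

test_that("hourly mode has a diurnal cycle around the daily means", {
  g <- tiny_grid()
  mh <- gen_meteo(g, 3, seed = 2, resolution = "hourly")
  expect_equal(dim(mh$T)[3], 72)
  expect_equal(mh$dt_hours, 1)
  day1 <- mh$T[2, 2, 1:24]
  expect_gt(max(day1) - min(day1), 4)  # diurnal amplitude present
})

test_that("landscape honours the taxon latitude mask and threshold ordering", {
  g <- grid_spec(0, 10, 35, 55, 10, 20)
  birch <- taxon_params("birch")
  ls <- gen_landscape(g, birch, seed = 4)
  expect_true(all(ls$phi[, g$lat < 40] == 0))   # no birch south of 40 N
  expect_true(any(ls$phi[, g$lat > 40] > 0))
  expect_true(all(ls$H_fe - ls$H_fs > 0))
  expect_true(all(ls$phi >= 0 & ls$phi <= 1))
  # start threshold increases with latitude (row means)
  rm <- colMeans(ls$H_fs)
  expect_gt(mean(diff(rm)), 0)
  expect_identical(gen_landscape(g, birch, seed = 4)$phi, ls$phi)
  # olive has no latitude cut
  olive <- taxon_params("olive")
  lso <- gen_landscape(g, olive, seed = 4)
  expect_true(any(lso$phi[, g$lat < 40] > 0))
})

test_that("hourly-type taxa get threshold maps in K hour units", {
  g <- tiny_grid()
  alder <- taxon_params("alder")
  birch <- taxon_params("birch")
  la <- gen_landscape(g, alder, seed = 1)
  lb <- gen_landscape(g, birch, seed = 1)
  expect_equal(la$unit, "K hour")
  expect_equal(lb$unit, "K day")
  expect_equal(mean(la$H_fs) / mean(lb$H_fs), 24, tolerance = 0.01)
})

test_that("station network generation is deterministic, in-domain and flags isolation", {
  g <- grid_spec(0, 40, 35, 65, 40, 30)
  st <- gen_station_network(g, 12, seed = 5, clustering = 0)
  expect_equal(nrow(st), 12)
  expect_equal(anyDuplicated(st[, c("lon", "lat")]), 0)
  expect_true(all(st$lon > 0 & st$lon < 40 & st$lat > 35 & st$lat < 65))
  expect_identical(gen_station_network(g, 12, seed = 5, clustering = 0), st)
  st2 <- gen_station_network(g, 15, seed = 6, clustering = 0.8)
  expect_true(any(st2$isolated))
  expect_error(gen_station_network(g, 0, seed = 1), "n_stations")
  expect_error(gen_station_network(grid_spec(0, 2, 45, 47, 2, 2), 5, seed = 1),
               "more stations")
})

test_that("observations reduce to the exact operator image without noise", {
  sc <- small_scenario()
  obs0 <- gen_observations(sc$conc_truth, sc$stations, sigma = 0,
                           missing_prob = 0, seed = 1)
  truth <- sample_model(sc$conc_truth, sc$stations)
  expect_equal(obs0$value, truth$value)
  expect_true(all(obs0$valid))
  # all-missing contract
  obs1 <- gen_observations(sc$conc_truth, sc$stations, sigma = 0.5,
                           missing_prob = 1, seed = 1)
  expect_true(all(!obs1$valid))
  expect_true(all(is.na(obs1$value)))
  # reproducible noise
  a <- gen_observations(sc$conc_truth, sc$stations, sigma = 0.5,
                        missing_prob = 0.1, seed = 9)
  b <- gen_observations(sc$conc_truth, sc$stations, sigma = 0.5,
                        missing_prob = 0.1, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$value[a$valid] >= 0))
})

test_that("truth correction fields stay inside the requested range", {
  g <- tiny_grid()
  xi <- gen_truth_xi(g, 3, range = c(0.5, 2))
  expect_true(all(xi >= 0.5 & xi <= 2))
  expect_identical(gen_truth_xi(g, 3), gen_truth_xi(g, 3))
})
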