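mk_spin <- function(id, year, value, n_valid = 60, lon = 2, lat = 47) {
  data.frame(station_id = id, lon = lon, lat = lat, year = year,
             value = value, n_valid = n_valid, usable = n_valid >= 30,
             stringsAsFactors = FALSE)
}

test_that("whole-period SPIn ratio follows its defining arithmetic", {
  obs <- mk_spin("S1", 2000, 100)
  mdl <- mk_spin("S1", 2000, 200)
  r <- compute_ratio_rs(mdl, obs)
  expect_equal(r$r_s, 2)
  # identical model and observations give exactly 1
  r1 <- compute_ratio_rs(obs, obs)
  expect_equal(r1$r_s, 1)
  # multi-year: ratio of sums, not mean of ratios
  obs2 <- rbind(mk_spin("S1", 2000, 100), mk_spin("S1", 2001, 300))
  mdl2 <- rbind(mk_spin("S1", 2000, 300), mk_spin("S1", 2001, 300))
  expect_equal(compute_ratio_rs(mdl2, obs2)$r_s, 600 / 400)
})

test_that("short station-years and zero-SPIn stations are excluded", {
  obs <- rbind(mk_spin("S1", 2000, 100, n_valid = 29),
               mk_spin("S2", 2000, 100, n_valid = 45))
  mdl <- rbind(mk_spin("S1", 2000, 200), mk_spin("S2", 2000, 150))
  r <- compute_ratio_rs(mdl, obs)
  expect_equal(r$station_id, "S2")   # 29-day year disqualifies S1 entirely
  obs0 <- mk_spin("S3", 2000, 0)
  mdl0 <- mk_spin("S3", 2000, 10)
  expect_message(r0 <- compute_ratio_rs(mdl0, obs0), "zero observed")
  expect_null(r0)
})

test_that("RBF interpolation matches the reference implementation semantics", {
  # oracle values computed with the scientific python stack's thin-plate-free
  # linear-kernel RBF interpolator (constant polynomial tail) on this exact
  # configuration, frozen here
  g <- grid_spec(0, 12, 45, 55, 12, 10)
  pts <- data.frame(lon = c(2, 5.5, 9, 4, 10), lat = c(46, 48.5, 46.5, 52, 51),
                    r_s = c(1.2, 0.8, 2.0, 1.5, 0.6))
  f0 <- interpolate_rbf(pts, g, smoothing = 0)
  expect_equal(f0[1, 1], 1.26987047, tolerance = 1e-7)    # (0.5, 45.5)
  expect_equal(f0[7, 5], 0.95694661, tolerance = 1e-7)    # (6.5, 49.5)
  expect_equal(f0[12, 10], 0.79612894, tolerance = 1e-7)  # (11.5, 54.5)
  expect_equal(f0[4, 3], 1.09494946, tolerance = 1e-7)    # (3.5, 47.5)
  f10 <- interpolate_rbf(pts, g, smoothing = 10)
  expect_equal(f10[1, 1], 1.25315790, tolerance = 1e-7)
  expect_equal(f10[7, 5], 1.16587533, tolerance = 1e-7)
  expect_equal(f10[12, 10], 1.07432876, tolerance = 1e-7)
  expect_equal(f10[4, 3], 1.21477584, tolerance = 1e-7)
})

test_that("RBF degenerate contracts: constant data, single point, far field", {
  g <- grid_spec(0, 12, 45, 55, 12, 10)
  pts <- data.frame(lon = c(2, 5.5, 9), lat = c(46, 48.5, 46.5),
                    r_s = c(3.7, 3.7, 3.7))
  fc <- interpolate_rbf(pts, g, smoothing = 0)
  expect_lt(max(abs(fc - 3.7)), 1e-6)
  f1 <- interpolate_rbf(pts[1, ], g, smoothing = 0)
  expect_true(all(f1 == 3.7))
  # finite far extrapolation on a domain far from the data
  gfar <- grid_spec(100, 140, 10, 30, 8, 6)
  pts2 <- data.frame(lon = c(2, 5.5, 9), lat = c(46, 48.5, 46.5),
                     r_s = c(1, 2, 1.5))
  ff <- interpolate_rbf(pts2, gfar, smoothing = 10)
  expect_true(all(is.finite(ff)))
  expect_error(interpolate_rbf(pts2[0, ], g), "no calibration points")
})

test_that("calibration application divides, floors and validates", {
  g <- tiny_grid()
  em <- matrix(10, g$nx, g$ny)
  expect_equal(apply_calibration(em, matrix(1, g$nx, g$ny)), em)
  expect_equal(apply_calibration(em, matrix(2, g$nx, g$ny)), em / 2)
  # the floor caps extreme downscaling
  small <- matrix(1e-4, g$nx, g$ny)
  expect_equal(apply_calibration(em, small, floor = 0.1), em / 0.1)
  expect_error(apply_calibration(em, matrix(-1, g$nx, g$ny)), "non-positive")
  # emission_field objects are scaled consistently
  birch <- taxon_params("birch")
  met <- gen_meteo(g, 120, seed = 1)
  ls <- gen_landscape(g, birch, seed = 2)
  E <- compute_emission(met, ls, birch)
  E2 <- apply_calibration(E, matrix(2, g$nx, g$ny))
  expect_equal(E2$budget, E$budget / 2)
  expect_equal(E2$E, E$E / 2)
})

test_that("validation ratio uses only co-valid observed days", {
  obs <- mk_series(c(10, 20, NA, 40), valid = c(TRUE, TRUE, FALSE, TRUE))
  mdl <- mk_series(c(20, 40, 1000, 80))
  r <- validate_ratio_rst(obs, mdl)
  expect_equal(r$r_st, 0.5)       # model uniformly 2x high -> obs/mdl = 0.5
  expect_equal(r$n_days, 3)       # the invalid day contributes nothing
  r1 <- validate_ratio_rst(obs, obs)
  expect_equal(r1$r_st, 1)
  # zero model sum: station skipped
  mdl0 <- mk_series(rep(0, 4))
  expect_null(validate_ratio_rst(obs, mdl0))
})
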