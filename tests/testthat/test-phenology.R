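test_that("flowering-start and flowering-end ramps hit their endpoints", {
  expect_equal(p_start(c(0.9, 1.0, 1.1), delta_H = 0.1), c(0, 0.5, 1))
  expect_equal(p_start(0.5, 0.1), 0)
  expect_equal(p_end(c(0.5, 1.0, 1.15), delta_N = 0.1), c(1, 0.5, 0))
  # ramps are monotone
  x <- seq(0, 2, by = 0.01)
  expect_true(all(diff(p_start(x, 0.1)) >= 0))
  expect_true(all(diff(p_end(x, 0.1)) <= 0))
})

test_that("threshold factor shuts down linearly between its bounds", {
  expect_equal(threshold_factor(95, 50, 90), 0)   # humid air, birch q_high
  expect_equal(threshold_factor(40, 50, 80), 1)   # dry air
  expect_equal(threshold_factor(1, 0, 0.5), 0)    # raining above P_high
  expect_equal(threshold_factor(65, 50, 80), 0.5) # midpoint
  expect_error(threshold_factor(1, 2, 1))
})

test_that("wind factor is 1 in calm air and saturates at the max scaling", {
  birch <- taxon_params("birch")
  expect_equal(wind_factor(0, 0, birch), 1)
  expect_equal(wind_factor(1e6, 0, birch), 1.5, tolerance = 1e-12)
  u <- seq(0, 30, by = 0.5)
  expect_true(all(diff(wind_factor(u, 0, birch)) >= 0))
})

test_that("heat-sum accumulation follows the cut-off and start-day rules", {
  g <- tiny_grid()
  birch <- taxon_params("birch")
  met <- gen_meteo(g, 90, seed = 1, params = list(T_noise_sd = 0))
  # override with a controlled temperature history at one cell
  met$T[2, 2, ] <- 273.15 + 10  # constant 10 degC
  H <- accumulate_heat_sum(met, birch, cell = c(2, 2))
  start_doy <- as.integer(as.Date("2000-03-01") - as.Date("2000-01-01")) + 1
  expect_equal(H[start_doy - 1], 0)        # nothing before 1 March
  expect_equal(H[start_doy], 6.5)          # (10 - 3.5) K day per day
  expect_equal(H[start_doy + 9], 65)
  met$T[2, 2, ] <- 273.15 + 2              # below the 3.5 degC cut-off
  expect_equal(max(accumulate_heat_sum(met, birch, cell = c(2, 2))), 0)
  expect_error(accumulate_heat_sum(met, birch, c(2, 2),
                                   dates = as.Date("1999-12-01")),
               "outside")
})

test_that("ready-pollen development reproduces the direct arithmetic case", {
  # p_fs = p_fe = 1, T - T_co = 5 K, Delta_H = 100 K day, phi = 0.1,
  # S = 1e6 m2, xi * N_tot = 1e8 -> 5e11 grains/day... scaled by S phi:
  # S phi xi N_tot (T - T_co)/Delta_H = 1e6*0.1*1e8*5/100 = 5e11
  inc <- 1e6 * 0.1 * 1e8 * (5 / 100)
  expect_equal(inc, 5e11)
  # and the package's integral form reduces to that rate mid-season
  dev0 <- 0.5  # development fraction well inside p_fe = 1 territory
  dx <- 5 / 100
  got <- 1e6 * 0.1 * 1e8 * pollenvar:::p_end_integral(dev0, dev0 + dx, 0.1)
  expect_equal(got, 5e11)
})

test_that("the end-ramp integral conserves the unit seasonal total", {
  # integral of the ramp over the whole development axis is exactly 1
  expect_equal(pollenvar:::p_end_integral(0, 10, 0.1), 1)
  expect_equal(pollenvar:::p_end_integral(0, 10, 0.3), 1)
  # additivity over subintervals
  xs <- seq(0, 1.5, by = 0.07)
  pieces <- sum(pollenvar:::p_end_integral(head(xs, -1), xs[-1], 0.1))
  expect_equal(pieces, pollenvar:::p_end_integral(0, max(xs), 0.1))
})

test_that("seasonal emission budget equals S phi xi N_tot under non-limiting weather", {
  g <- tiny_grid()
  birch <- taxon_params("birch")
  met <- gen_meteo_nonlimiting(g, 160, seed = 2)
  ls <- gen_landscape(g, birch, seed = 3)
  xi <- gen_truth_xi(g, 4)
  E <- compute_emission(met, ls, birch, xi = xi)
  target <- g$area_m2 * ls$phi * xi * birch$N_tot
  rel <- abs(E$budget - target) / pmax(target, 1)
  expect_lt(max(rel[ls$phi > 0]), 0.01)
  expect_true(all(E$E >= 0))
  # released fraction never exceeds the upper uncertainty band
  expect_true(all(E$R <= 1 + birch$delta_N + 1e-12))
})

test_that("emission is exactly proportional to xi cell by cell", {
  g <- tiny_grid()
  birch <- taxon_params("birch")
  met <- gen_meteo(g, 140, seed = 5)
  ls <- gen_landscape(g, birch, seed = 6)
  xi <- gen_truth_xi(g, 7)
  E1 <- compute_emission(met, ls, birch, xi = 1)
  E2 <- compute_emission(met, ls, birch, xi = 2 * xi)
  scaled <- E1$E * array(2 * xi, dim = dim(E1$E))
  expect_equal(E2$E, scaled, tolerance = 1e-12)
})

test_that("release stops in rain and depletes fully at long steps", {
  g <- tiny_grid()
  birch <- taxon_params("birch")
  met <- gen_meteo_nonlimiting(g, 150, seed = 2)
  met$P[] <- 1  # steady rain above the 0.5 mm/hr threshold
  ls <- gen_landscape(g, birch, seed = 3)
  E <- compute_emission(met, ls, birch, xi = 1)
  expect_equal(max(E$E), 0)
  # daily step >> tau = 1 h: the whole ready stock leaves the same day,
  # so the cumulative release equals the cumulative development
  met2 <- gen_meteo_nonlimiting(g, 160, seed = 2)
  E2 <- compute_emission(met2, ls, birch, xi = 1)
  target <- g$area_m2 * ls$phi * birch$N_tot
  expect_lt(max(abs(E2$budget - target)[ls$phi > 0] /
                  target[ls$phi > 0]), 0.01)
})

test_that("xi must be strictly positive and thresholds sane", {
  g <- tiny_grid()
  birch <- taxon_params("birch")
  met <- gen_meteo(g, 40, seed = 1)
  ls <- gen_landscape(g, birch, seed = 2)
  expect_error(compute_emission(met, ls, birch, xi = 0), "positive")
  ls_bad <- ls
  ls_bad$H_fe <- ls_bad$H_fs  # zero flowering-season heat width
  expect_error(compute_emission(met, ls_bad, birch, xi = 1), "H_fe")
})
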