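test_that("background correlation follows the Gaussian distance law", {
  p <- c(10, 50)
  expect_equal(background_correlation(p, p, rho = 250), 1)
  # at distance d the correlation is exp(-d^2 / rho^2); at d = rho it is 1/e
  q <- c(10, 52.25)
  d <- gc_distance_km(p, q)
  expect_equal(background_correlation(p, q, rho = d), exp(-1))
  expect_equal(background_correlation(p, q, rho = d / 2), exp(-4))
  expect_equal(background_correlation(p, q, rho = 250), exp(-d^2 / 250^2))
  expect_error(background_correlation(p, q, rho = -1))
})

test_that("cost is zero when the model matches observations at the background", {
  sc <- small_scenario()
  # noise-free observations generated from the background model itself
  fg <- run_first_guess(sc)
  obs0 <- gen_observations(fg$conc, sc$stations, sigma = 0, missing_prob = 0,
                           seed = 1)
  prob <- da_problem(sc$transport, sc$emission_unit, obs0, sc$window)
  cg <- cost_and_gradient(rep(0, prob$ncell), prob)
  expect_equal(cg$J_bg, 0)
  expect_lt(cg$J_obs / length(prob$y), 1e-12)
  # background term is zero at zeta = 0 regardless of the observations
  prob2 <- da_problem(sc$transport, sc$emission_unit, sc$obs, sc$window)
  cg2 <- cost_and_gradient(rep(0, prob2$ncell), prob2)
  expect_equal(cg2$J_bg, 0)
  expect_gt(cg2$J_obs, 0)
})

test_that("gradient matches central finite differences on a small problem", {
  sc <- small_scenario()
  prob <- da_problem(sc$transport, sc$emission_unit, sc$obs, sc$window)
  set.seed(9)
  zeta <- stats::rnorm(prob$ncell, 0, 0.2)
  cg <- cost_and_gradient(zeta, prob)
  h <- 1e-6
  idx <- sample.int(prob$ncell, 5)
  for (k in idx) {
    zp <- zeta; zp[k] <- zp[k] + h
    zm <- zeta; zm[k] <- zm[k] - h
    fd <- (cost_and_gradient(zp, prob)$J - cost_and_gradient(zm, prob)$J) / (2 * h)
    expect_lt(abs(fd - cg$grad[k]) / max(abs(fd), 1e-8), 1e-5)
  }
})

test_that("overflowing corrections are flagged with the offending cells", {
  sc <- small_scenario()
  prob <- da_problem(sc$transport, sc$emission_unit, sc$obs, sc$window)
  z <- rep(0, prob$ncell); z[3] <- 1e4
  expect_error(cost_and_gradient(z, prob), "non-finite")
})

test_that("L-curve hyperbola fit round-trips exact generators", {
  a <- 120; b <- 40; cc <- 0.3
  x <- seq(0, 5, length.out = 12)
  pts <- data.frame(iter = seq_along(x) - 1, J_bg = x, J_obs = a + b / (x + cc))
  fit <- fit_lcurve(pts)
  expect_equal(fit$a, a, tolerance = 1e-6)
  expect_equal(fit$b, b, tolerance = 1e-6)
  expect_equal(fit$c, cc, tolerance = 1e-6)
  expect_true(fit$converged)
  # degenerate inputs: fewer than 3 points stop at the last iteration
  expect_warning(f2 <- fit_lcurve(pts[1:2, ]), "fewer than 3")
  expect_equal(f2$stop_index, 1)
  expect_false(f2$converged)
})

test_that("single-station closed form reproduces its analytic limits", {
  expect_equal(xi_opt_closed_form(10, 5, 0.8, 0.8), 2)    # perfect correlation
  expect_equal(xi_opt_closed_form(5, 5, 0, 1), 0.5)       # uncorrelated, unit var
  expect_equal(xi_opt_closed_form(7, 2, 0, 0), 3.5)       # constant series
  expect_error(xi_opt_closed_form(1, 0, 0, 0), "z_bar")
})

test_that("numerical scalar assimilation agrees with the closed form", {
  set.seed(5)
  n <- 50
  for (k in 1:25) {
    y_bar <- stats::runif(1, 5, 50); z_bar <- stats::runif(1, 5, 50)
    rho <- stats::runif(1, -0.3, 0.95)
    zm <- matrix(stats::rnorm(2 * n), n)
    mu <- 0.5 * zm[, 1]
    nu <- 0.5 * (rho * zm[, 1] + sqrt(1 - rho^2) * zm[, 2])
    mu <- pmax(mu - mean(mu), -0.9); mu <- mu - mean(mu)
    nu <- pmax(nu - mean(nu), -0.9); nu <- nu - mean(nu)
    xi_num <- assimilate_scalar(y_bar * (1 + nu), z_bar * (1 + mu))
    xi_cf <- xi_opt_closed_form(y_bar, z_bar, mean(mu * nu), mean(mu^2))
    expect_equal(xi_num, xi_cf, tolerance = 1e-6)
  }
})

test_that("assimilation returns the background when nothing can be assimilated", {
  sc <- small_scenario()
  empty_obs <- sc$obs[0, ]
  expect_warning(prob <- da_problem(sc$transport, sc$emission_unit, empty_obs,
                                    sc$window), "no valid observation")
  expect_warning(res <- minimize_truncated(prob), "background")
  expect_true(all(res$xi == 1))
  expect_equal(res$stop_index, 0L)
})

test_that("observations equal to the first guess leave xi at 1", {
  sc <- small_scenario()
  fg <- run_first_guess(sc)
  obs0 <- gen_observations(fg$conc, sc$stations, sigma = 0, missing_prob = 0,
                           seed = 1)
  prob <- da_problem(sc$transport, sc$emission_unit, obs0, sc$window)
  # with nothing to improve the minimizer stops immediately, leaving too few
  # L-curve points to fit
  expect_warning(res <- minimize_truncated(prob, max_iter = 10),
                 "fewer than 3")
  expect_lt(max(abs(res$xi - 1)), 1e-6)
})

test_that("observation term dominates the background term during minimization", {
  sc <- small_scenario()
  prob <- da_problem(sc$transport, sc$emission_unit, sc$obs, sc$window)
  res <- minimize_truncated(prob, max_iter = 10)
  d <- res$diagnostics[-1, ]  # skip iteration 0 where J_bg = 0 identically
  expect_true(all(d$J_obs >= 100 * d$J_bg))
})

test_that("truncated minimization records a coherent iteration history", {
  sc <- small_scenario()
  prob <- da_problem(sc$transport, sc$emission_unit, sc$obs, sc$window)
  res <- minimize_truncated(prob, max_iter = 12)
  d <- res$diagnostics
  expect_equal(d$iter[1], 0)
  expect_equal(d$J_bg[1], 0)                  # iteration 0 is the background
  expect_true(all(diff(d$J) < 0))             # line search enforces descent
  expect_lte(res$stop_index, max(d$iter))
  expect_equal(dim(res$xi), c(sc$grid$nx, sc$grid$ny))
  expect_true(all(res$xi > 0))                # log transform keeps xi positive
  expect_equal(length(res$xi_history), nrow(d))
  expect_equal(res$rmse_ratio_assim,
               res$rmse_assim[res$stop_index + 1] / res$rmse_assim[1])
})
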