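#' Observing-system simulation experiments
#'
#' Self-contained validation experiments exercising the package end-to-end on
#' synthetic scenarios with known truth. Each experiment builds its own
#' inputs from a seed, runs the relevant part of the pipeline, and returns
#' the summary quantities it measures. They are used by the package's test
#' suite and by `scripts/acceptance.R`, and are convenient entry points for
#' exploring the method's behaviour.
#'
#' @name experiments
NULL

#' Adjoint exactness experiment
#'
#' Random-vector dot-product identity for the transport operator:
#' `<forward(e), w> == <e, adjoint(w)>`.
#'
#' @param seed Integer seed.
#' @return List: `rel_error` (worst relative discrepancy over 3 draws).
#' @export
experiment_adjoint <- function(seed = 1) {
  g <- grid_spec(0, 8, 45, 51, 8, 6)
  met <- gen_meteo(g, 30, seed = seed)
  tr <- linear_transport(g, met, taxon_params("birch"))
  nd <- length(tr$dates)
  with_seed(seed + 1, {
    worst <- 0
    for (k in 1:3) {
      e <- array(stats::rexp(48 * nd), c(8, 6, nd))
      w <- array(stats::rnorm(48 * nd), c(8, 6, nd))
      lhs <- sum(forward_transport(tr, e)$conc * w)
      rhs <- sum(e * adjoint_transport(tr, w))
      worst <- max(worst, abs(lhs - rhs) / abs(lhs))
    }
    list(rel_error = worst)
  })
}

#' Linear-oracle equivalence experiment
#'
#' On a 10 x 10 grid with 20 stations and noise-free observations over a full
#' season, runs the variational minimization to full convergence and compares
#' the recovered correction field with the direct generalized-least-squares
#' solution built from the explicit source-receptor matrix. The scenario uses
#' uniform tree cover and light winds so every cell is comparably observed
#' and full convergence is attainable; see the methods vignette.
#'
#' @param seed Integer seed.
#' @param max_iter Quasi-Newton iterations (default 350).
#' @return List: `rmse` (RMSE between the two solutions over cells where the
#'   direct solution is positive), `n_cells`.
#' @export
experiment_linear_oracle <- function(seed = 1, max_iter = 350) {
  g <- grid_spec(0, 10, 45, 55, 10, 10)
  sc <- build_scenario(grid = g, n_days = 182, n_stations = 20,
                       clustering = 0, noise_sigma = 0, missing_prob = 0,
                       seed = seed,
                       landscape_params = list(phi_const = 0.3),
                       meteo_params = list(u_background = 1, wind_sd = 1.2))
  prob <- da_problem(sc$transport, sc$emission_unit, sc$obs, sc$window)
  res <- minimize_truncated(prob, max_iter = max_iter, gtol = 1e-12,
                            memory = 25)
  xi_full <- res$xi_history[[length(res$xi_history)]]
  gls <- direct_gls_xi(prob)
  pos <- gls$cells[gls$xi[gls$cells] > 0]
  list(rmse = sqrt(mean((xi_full[pos] - gls$xi[pos])^2)),
       n_cells = length(pos))
}

#' Single-station bias-law experiment
#'
#' Monte-Carlo verification of the analytic single-station optimum: draws
#' correlated model/observation anomaly series, assimilates a scalar
#' correction numerically with a weak background, and compares with
#' [xi_opt_closed_form()]. Includes the perfect-correlation and
#' zero-correlation limits.
#'
#' @param seed Integer seed.
#' @param n_draws Number of Monte-Carlo draws (default 200).
#' @return List: `mean_abs_rel_err`, `max_abs_rel_err`,
#'   `perfect_corr_xi` (expected `y_bar / z_bar`), `zero_corr_xi`
#'   (expected `y_bar / (2 z_bar)` at unit anomaly variance).
#' @export
experiment_bias_law <- function(seed = 1, n_draws = 200) {
  with_seed(seed + 17, {
    n <- 60
    errs <- numeric(n_draws)
    for (k in seq_len(n_draws)) {
      y_bar <- stats::runif(1, 5, 50); z_bar <- stats::runif(1, 5, 50)
      rho <- stats::runif(1, -0.5, 0.95)
      zm <- matrix(stats::rnorm(2 * n), n)
      mu <- stats::runif(1, 0.2, 0.8) * zm[, 1]
      nu <- stats::runif(1, 0.2, 0.8) *
        (rho * zm[, 1] + sqrt(1 - rho^2) * zm[, 2])
      mu <- pmax(mu - mean(mu), -0.95); mu <- mu - mean(mu)
      nu <- pmax(nu - mean(nu), -0.95); nu <- nu - mean(nu)
      xi_num <- assimilate_scalar(y_bar * (1 + nu), z_bar * (1 + mu))
      xi_cf <- xi_opt_closed_form(y_bar, z_bar, mean(mu * nu), mean(mu^2))
      errs[k] <- abs(xi_num - xi_cf) / abs(xi_cf)
    }
    # perfect correlation limit: nu = mu -> xi = y_bar / z_bar
    mu <- stats::rnorm(n, 0, 0.5)
    mu <- pmax(mu - mean(mu), -0.9); mu <- mu - mean(mu)
    xi_perf <- assimilate_scalar(10 * (1 + mu), 5 * (1 + mu))
    # zero-correlation limit at unit anomaly variance (analytic form)
    xi_zero <- xi_opt_closed_form(5, 5, 0, 1)
    list(mean_abs_rel_err = mean(errs), max_abs_rel_err = max(errs),
         perfect_corr_xi = xi_perf, zero_corr_xi = xi_zero)
  })
}

#' Parameter-recovery experiment
#'
#' Full assimilation of noisy synthetic observations of a smooth truth
#' correction field in [0.5, 2] by a 30-station network (lognormal noise
#' sigma 0.3, 5% missing days), repeated over a small ensemble of scenario
#' draws. Reports the ensemble-mean evaluation-station RMSE ratio (optimal
#' iteration vs iteration 0) and the ensemble-mean correlation between the
#' recovered and true fields inside the network's union footprint.
#'
#' @param seed Integer seed; ensemble members use `seed, seed + 1000, ...`.
#' @param n_rep Ensemble size (default 6).
#' @return List: `mean_eval_rmse_ratio`, `mean_truth_correlation`, and the
#'   per-member vectors `eval_rmse_ratio`, `truth_correlation`.
#' @export
experiment_recovery <- function(seed = 1, n_rep = 6) {
  g <- grid_spec(0, 10, 46, 54, 10, 8)
  ratios <- numeric(n_rep); corrs <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    s <- seed + (r - 1) * 1000
    sc <- build_scenario(grid = g, n_days = 182, n_stations = 30,
                         clustering = 0, noise_sigma = 0.3,
                         missing_prob = 0.05, xi_smooth = 6, seed = s)
    da <- run_da(sc, cov = cov_config(background_scale = 10), max_iter = 20)
    fp <- footprint_union(sc$transport, sc$stations, sc$window)
    msk <- fp > 0.05 * max(fp)
    ratios[r] <- da$result$rmse_ratio_eval
    corrs[r] <- stats::cor(da$result$xi[msk], sc$xi_true[msk])
  }
  list(mean_eval_rmse_ratio = mean(ratios),
       mean_truth_correlation = mean(corrs),
       eval_rmse_ratio = ratios, truth_correlation = corrs)
}

#' Truncation over-fitting protection experiment
#'
#' Sparse (6-station), noisy (lognormal sigma 0.5) scenarios where continued
#' minimization over-fits the assimilation stations: compares the
#' evaluation-station RMSE at the L-curve stop index with the RMSE at full
#' convergence, over a small ensemble.
#'
#' @param seed Integer seed.
#' @param n_rep Ensemble size (default 6).
#' @return List: `mean_eval_rmse_stop`, `mean_eval_rmse_full`, per-member
#'   vectors `eval_rmse_stop`, `eval_rmse_full`.
#' @export
experiment_truncation <- function(seed = 1, n_rep = 6) {
  g <- grid_spec(0, 12, 45, 55, 12, 10)
  stp <- c(); ful <- c()
  for (r in seq_len(n_rep)) {
    s <- seed + (r - 1) * 1000
    sc <- build_scenario(grid = g, n_days = 182, n_stations = 6,
                         clustering = 0.5, noise_sigma = 0.5,
                         missing_prob = 0.05, xi_smooth = 8, seed = s)
    da <- run_da(sc, cov = cov_config(background_scale = 10), max_iter = 30)
    re <- da$result$rmse_eval
    if (all(is.na(re))) next
    stp <- c(stp, re[da$result$stop_index + 1])
    ful <- c(ful, re[length(re)])
  }
  list(mean_eval_rmse_stop = mean(stp), mean_eval_rmse_full = mean(ful),
       eval_rmse_stop = stp, eval_rmse_full = ful)
}

#' Emission budget and linearity experiment
#'
#' Under non-limiting weather the per-cell seasonal release must equal
#' `S * phi * xi * N_tot`, and doubling the correction field must exactly
#' double every concentration.
#'
#' @param seed Integer seed.
#' @return List: `max_budget_rel_err` (over producing cells),
#'   `max_linearity_rel_dev`.
#' @export
experiment_budget_linearity <- function(seed = 1) {
  g <- grid_spec(0, 10, 45, 53, 10, 8)
  birch <- taxon_params("birch")
  met <- gen_meteo_nonlimiting(g, 182, seed = seed)
  ls <- gen_landscape(g, birch, seed = seed + 1)
  xi <- gen_truth_xi(g, seed + 2)
  E <- compute_emission(met, ls, birch, xi = xi)
  target <- g$area_m2 * ls$phi * xi * birch$N_tot
  rel <- abs(E$budget - target) / pmax(target, 1)
  tr <- linear_transport(g, met, birch)
  c1 <- forward_transport(tr, E)$conc
  E2 <- compute_emission(met, ls, birch, xi = 2 * xi)
  c2 <- forward_transport(tr, E2)$conc
  list(max_budget_rel_err = max(rel[ls$phi > 0]),
       max_linearity_rel_dev = max(abs(c2 - 2 * c1)) / max(c1))
}

#' Closed-loop calibration experiment
#'
#' Two variants of the post-assimilation bias recalibration loop: (i) a
#' noise-free scenario whose only error is a uniform factor-2 model high
#' bias, where the calibrated run must match the observations decile by
#' decile; (ii) a spatially smooth multiplicative model bias field in
#' [0.5, 2], where the post-calibration station ratios `r_st` must
#' concentrate near 1.
#'
#' @param seed Integer seed.
#' @return List: `median_rst` (smooth-bias variant),
#'   `max_decile_rel_err` (uniform-bias variant, over deciles with non-zero
#'   observed quantiles).
#' @export
experiment_calibration_loop <- function(seed = 1) {
  g <- grid_spec(0, 12, 45, 55, 12, 10)
  # uniform x2 bias, noise-free: decile agreement
  scu <- build_scenario(grid = g, n_days = 182, n_stations = 12,
                        clustering = 0.2, noise_sigma = 0, missing_prob = 0,
                        xi_true = 1, truth_scale = 0.5, seed = seed)
  fg <- run_first_guess(scu)
  cal <- run_calibration(scu, fg$series)
  fin <- run_final(scu, xi = 1, calibration = cal$map)
  w <- scu$window
  m <- merge(scu$obs[scu$obs$date >= w[1] & scu$obs$date <= w[2], ],
             fin$series, by = c("station_id", "date"),
             suffixes = c("_obs", "_mdl"))
  qt <- quantile_table(m$value_obs, m$value_mdl)
  ok <- qt$obs > 0
  dec_err <- max(abs(qt$mdl[ok] / qt$obs[ok] - 1))
  # smooth multiplicative bias field in [0.5, 2]
  beta <- gen_truth_xi(g, seed + 70, range = c(0.5, 2), smooth_cells = 8)
  scs <- build_scenario(grid = g, n_days = 182, n_stations = 20,
                        clustering = 0.2, noise_sigma = 0, missing_prob = 0,
                        xi_true = 1 / beta, seed = seed,
                        meteo_params = list(u_background = 1, wind_sd = 1.2))
  fgs <- run_first_guess(scs)
  cals <- run_calibration(scs, fgs$series)
  fins <- run_final(scs, xi = 1, calibration = cals$map)
  rst <- validate_ratio_rst(scs$obs, fins$series)
  list(median_rst = stats::median(rst$r_st), max_decile_rel_err = dec_err)
}

#' Two-day averaging correlation-gain experiment
#'
#' Monte-Carlo demonstration of the averaging rationale: for series that are
#' a shared seasonal signal plus independent daily multiplicative noise, the
#' model-observation correlation of two-day means exceeds that of daily
#' values on average.
#'
#' @param seed Integer seed.
#' @param n_rep Number of replicates (default 500).
#' @return List: `mean_gain`, `frac_improved`.
#' @export
experiment_twoday_gain <- function(seed = 1, n_rep = 500) {
  with_seed(seed + 23, {
    gains <- replicate(n_rep, {
      n <- 60
      sig <- 50 * exp(-((1:n) - 30)^2 / 200) + 5
      obs <- sig * exp(stats::rnorm(n, -0.18, 0.6))
      mdl <- sig * exp(stats::rnorm(n, -0.08, 0.4))
      d1 <- stats::cor(obs, mdl)
      d2 <- stats::cor(colMeans(matrix(obs, 2)), colMeans(matrix(mdl, 2)))
      d2 - d1
    })
    list(mean_gain = mean(gains), frac_improved = mean(gains > 0))
  })
}
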