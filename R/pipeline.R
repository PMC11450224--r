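#' Build a complete synthetic scenario
#'
#' Assembles everything one assimilation year needs: synthetic meteorology,
#' landscape, a "true" per-cell seasonal correction field, a station network,
#' the unit-correction emission history (the model's first-guess source), the
#' truth run (emission scaled by the true corrections and by `truth_scale`),
#' and noisy daily observations sampled from the truth run. All randomness is
#' funnelled through sub-seeds derived from `seed`.
#'
#' @param grid A [grid_spec()]; default 40 x 30 cells at 1 degree over
#'   Europe-like coordinates.
#' @param taxon Taxon name or [taxon_params()] (default `"birch"`).
#' @param year Scenario year (default 2000).
#' @param n_days Length of the meteorological record from 1 January
#'   (default 182, through the birch season).
#' @param n_stations Number of stations (default 20).
#' @param clustering Station clustering fraction (default 0.3).
#' @param noise_sigma Lognormal observation noise sigma (default 0.3).
#' @param missing_prob Missing-day probability (default 0.05).
#' @param xi_range Range of the true correction field (default `c(0.5, 2)`).
#' @param xi_smooth Spatial correlation scale of the true correction field,
#'   in cells (default 5).
#' @param xi_true Optional explicit truth field (matrix or scalar),
#'   overriding the random one.
#' @param truth_scale Extra uniform scaling of the truth emission relative to
#'   the model (default 1; `0.5` gives a model biased high by a factor 2 —
#'   used in calibration experiments).
#' @param seed Master seed.
#' @param meteo_params,transport_params,landscape_params Optional overrides
#'   passed to [gen_meteo()], [linear_transport()], [gen_landscape()].
#' @param nonlimiting_weather Use [gen_meteo_nonlimiting()] conditions.
#' @return A `pollen_scenario` object.
#' @export
build_scenario <- function(grid = grid_spec(0, 40, 35, 65, 40, 30),
                           taxon = "birch", year = 2000, n_days = 182,
                           n_stations = 20, clustering = 0.3,
                           noise_sigma = 0.3, missing_prob = 0.05,
                           xi_range = c(0.5, 2), xi_smooth = 5,
                           xi_true = NULL, truth_scale = 1, seed = 1,
                           meteo_params = list(), transport_params = list(),
                           landscape_params = list(),
                           nonlimiting_weather = FALSE) {
  if (is.character(taxon)) taxon <- taxon_params(taxon)
  seeds <- list(meteo = seed + 101, landscape = seed + 202, xi = seed + 303,
                stations = seed + 404, obs = seed + 505)
  meteo <- if (nonlimiting_weather) {
    gen_meteo_nonlimiting(grid, n_days, seeds$meteo, year = year)
  } else {
    gen_meteo(grid, n_days, seeds$meteo, params = meteo_params, year = year)
  }
  landscape <- gen_landscape(grid, taxon, seeds$landscape,
                             params = landscape_params)
  if (is.null(xi_true)) {
    xi_true <- gen_truth_xi(grid, seeds$xi, range = xi_range,
                            smooth_cells = xi_smooth)
  } else if (!is.matrix(xi_true)) {
    xi_true <- matrix(xi_true, grid$nx, grid$ny)
  }
  stations <- gen_station_network(grid, n_stations, seeds$stations,
                                  clustering = clustering)
  transport <- linear_transport(grid, meteo, taxon, params = transport_params)
  E1 <- compute_emission(meteo, landscape, taxon, xi = 1)
  E1mat <- emission_daily_matrix(transport, E1)
  truth_mat <- E1mat * as.vector(xi_true) * truth_scale
  conc_truth <- forward_transport(
    transport, array(truth_mat, c(grid$nx, grid$ny, ncol(truth_mat))))
  obs <- gen_observations(conc_truth, stations, sigma = noise_sigma,
                          missing_prob = missing_prob, seed = seeds$obs)
  structure(list(grid = grid, taxon = taxon, year = year,
                 window = assimilation_window(taxon, year),
                 meteo = meteo, landscape = landscape, xi_true = xi_true,
                 truth_scale = truth_scale, stations = stations,
                 transport = transport, emission_unit = E1, E1mat = E1mat,
                 conc_truth = conc_truth, obs = obs, seeds = seeds),
            class = "pollen_scenario")
}

#' @export
print.pollen_scenario <- function(x, ...) {
  cat(sprintf(
    "pollen_scenario: %s %d, %d x %d grid, %d days, %d stations, window %s to %s\n",
    x$taxon$name, x$year, x$grid$nx, x$grid$ny, length(x$transport$dates),
    nrow(x$stations), x$window[1], x$window[2]))
  invisible(x)
}

# concentration field for an arbitrary per-cell correction (model side)
scenario_concentration <- function(scenario, xi = 1, calibration = NULL) {
  xi <- if (is.matrix(xi)) as.vector(xi) else rep(xi, n_cells(scenario$grid))
  E <- scenario$E1mat * xi
  if (!is.null(calibration)) E <- E / pmax(as.vector(calibration), 0.1)
  forward_transport(scenario$transport,
                    array(E, c(scenario$grid$nx, scenario$grid$ny, ncol(E))))
}

#' First-guess (reference) run
#'
#' The unconstrained model run with `xi = 1` everywhere: the simulation
#' starts at the heat-accumulation start day and the run provides the
#' reference concentrations and station samples the assimilation must
#' outperform.
#'
#' @param scenario A [build_scenario()] object.
#' @return List: `conc` (concentration field), `series` (daily station
#'   samples).
#' @export
run_first_guess <- function(scenario) {
  conc <- scenario_concentration(scenario, xi = 1)
  list(conc = conc, series = sample_model(conc, scenario$stations))
}

#' Data-assimilation run for one scenario year
#'
#' Filters station-years against the first-guess model (completeness,
#' non-zero count, two-day correlation), splits the accepted stations 80/20
#' with isolated stations mandatorily assimilated, assembles the variational
#' problem and minimises it with the truncated-iteration watchdog. With zero
#' accepted stations the background `xi = 1` is returned (logged).
#'
#' @param scenario A [build_scenario()] object.
#' @param cov A [cov_config()].
#' @param split_seed Seed of the 80/20 split (default 1).
#' @param max_iter,slope_frac Passed to [minimize_truncated()].
#' @param first_guess Optional precomputed [run_first_guess()] output.
#' @return List: `result` (an `assimilation_result`), `audit` (filter table),
#'   `split` (assimilation/evaluation ids), `problem` (the `da_problem`).
#' @export
run_da <- function(scenario, cov = cov_config(), split_seed = 1,
                   max_iter = 40, slope_frac = 0.05, first_guess = NULL) {
  if (is.null(first_guess)) first_guess <- run_first_guess(scenario)
  audit <- filter_station_years(scenario$obs, first_guess$series,
                                scenario$window)
  accepted <- audit$station_id[audit$accept]
  if (length(accepted) == 0) {
    message("no station-years accepted: returning background xi = 1")
    xi <- matrix(1, scenario$grid$nx, scenario$grid$ny)
    return(list(result = structure(list(
      xi = xi, zeta = 0 * xi, stop_index = 0L, diagnostics = NULL,
      lcurve = NULL, rmse_assim = NA_real_, rmse_eval = NA_real_,
      rmse_ratio_assim = NA_real_, rmse_ratio_eval = NA_real_,
      xi_history = NULL), class = "assimilation_result"),
      audit = audit, split = NULL, problem = NULL))
  }
  mandatory <- intersect(accepted,
                         scenario$stations$station_id[scenario$stations$isolated])
  split <- split_assim_eval(accepted, mandatory, seed = split_seed)
  obs_a <- scenario$obs[scenario$obs$station_id %in% split$assimilation, ]
  obs_e <- scenario$obs[scenario$obs$station_id %in% split$evaluation, ]
  prob <- da_problem(scenario$transport, scenario$emission_unit, obs_a,
                     scenario$window, cov = cov)
  result <- minimize_truncated(prob, eval_obs = obs_e, max_iter = max_iter,
                               slope_frac = slope_frac)
  list(result = result, audit = audit, split = split, problem = prob)
}

#' Climatological bias calibration from a model run
#'
#' Computes per-station whole-period SPIn ratios `r_s` between a model run
#' and the observations and interpolates them over the grid with the
#' linear-kernel RBF, yielding the climatological correction map applied to
#' the emission in the final run.
#'
#' @param scenario A [build_scenario()] object (or any object carrying `grid`
#'   and `window`).
#' @param model_series Daily model station series of the run being
#'   calibrated (e.g. the DA run's output).
#' @param obs Daily observation data frame (defaults to the scenario's).
#' @param smoothing RBF smoothing parameter (default 10).
#' @param min_days Qualifying-year completeness threshold (default 30).
#' @return List: `ratios` (the `r_s` table), `map` (`nx x ny` correction
#'   matrix).
#' @export
run_calibration <- function(scenario, model_series, obs = scenario$obs,
                            smoothing = 10, min_days = 30) {
  spin_obs <- spin_table(obs, scenario$window, min_days = min_days)
  spin_mdl <- spin_table(model_series, scenario$window, min_days = 0)
  ratios <- compute_ratio_rs(spin_mdl, spin_obs, min_days = min_days)
  if (is.null(ratios) || nrow(ratios) == 0) {
    stop("no qualifying station-years for calibration")
  }
  map <- interpolate_rbf(ratios, scenario$grid, smoothing = smoothing)
  map <- pmax(map, 0.1)
  list(ratios = ratios, map = map)
}

#' Final (bias-corrected) run
#'
#' Re-runs the model with the emission scaled by the assimilated correction
#' field and divided by the climatological calibration map; the rest of the
#' setup is identical to the first guess, allowing direct comparison.
#'
#' @param scenario A [build_scenario()] object.
#' @param xi Assimilated correction field (matrix; default 1).
#' @param calibration Calibration map (matrix; default none).
#' @return List: `conc`, `series` as in [run_first_guess()].
#' @export
run_final <- function(scenario, xi = 1, calibration = NULL) {
  conc <- scenario_concentration(scenario, xi = xi, calibration = calibration)
  list(conc = conc, series = sample_model(conc, scenario$stations))
}

#' Seasonal pollen integrals of a station series table
#'
#' @param series Daily station data frame (possibly several years).
#' @param window Length-2 `Date` vector, or a named list of per-year windows.
#' @param min_days Minimum valid days for a usable station-year (default 30).
#' @return Data frame: `station_id`, `lon`, `lat`, `year`, `value`,
#'   `n_valid`, `usable`.
#' @export
spin_table <- function(series, window, min_days = 30) {
  windows <- if (is.list(window)) window else {
    yr <- format(as.Date(window[1]), "%Y")
    stats::setNames(list(as.Date(window)), yr)
  }
  rows <- list()
  for (yr in names(windows)) {
    w <- as.Date(windows[[yr]])
    for (id in unique(series$station_id)) {
      s <- series[series$station_id == id, , drop = FALSE]
      sp <- compute_spin(s, w, min_days = min_days)
      rows[[length(rows) + 1]] <- data.frame(
        station_id = id, lon = s$lon[1], lat = s$lat[1],
        year = as.integer(yr), value = sp$value, n_valid = sp$n_valid,
        usable = sp$usable, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Inter-annual SPIn correlation per station
#'
#' Pearson correlation between observed and modelled seasonal pollen
#' integrals across years, per station, restricted to stations with more
#' than `min_years - 1` valid years (default: more than 3).
#'
#' @param spin_obs,spin_mdl [spin_table()] data frames.
#' @param min_years Minimum number of valid years (default 4).
#' @return Data frame: `station_id`, `n_years`, `correlation`.
#' @export
spin_correlation_table <- function(spin_obs, spin_mdl, min_years = 4) {
  m <- merge(spin_obs[spin_obs$usable, c("station_id", "year", "value")],
             spin_mdl[, c("station_id", "year", "value")],
             by = c("station_id", "year"), suffixes = c("_obs", "_mdl"))
  ids <- unique(m$station_id)
  rows <- lapply(ids, function(id) {
    mm <- m[m$station_id == id, , drop = FALSE]
    if (nrow(mm) < min_years) return(NULL)
    data.frame(station_id = id, n_years = nrow(mm),
               correlation = suppressWarnings(
                 stats::cor(mm$value_obs, mm$value_mdl)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Quantile agreement table
#'
#' Quantiles of independently sorted observed and modelled values (their
#' temporal co-location deliberately disregarded), the desk analogue of a
#' quantile-quantile validation plot.
#'
#' @param obs_values,mdl_values Numeric vectors (e.g. co-valid daily values).
#' @param probs Quantile probabilities (default deciles).
#' @return Data frame: `prob`, `obs`, `mdl`, `ratio`.
#' @export
quantile_table <- function(obs_values, mdl_values,
                           probs = seq(0.1, 0.9, by = 0.1)) {
  qo <- stats::quantile(obs_values, probs, na.rm = TRUE, names = FALSE)
  qm <- stats::quantile(mdl_values, probs, na.rm = TRUE, names = FALSE)
  data.frame(prob = probs, obs = qo, mdl = qm,
             ratio = ifelse(qo > 0, qm / qo, NA_real_))
}

#' Union footprint of a station set
#'
#' Sum of single-station footprints over the window: the area the network's
#' observations constrain during a season.
#'
#' @param transport A [linear_transport()] object.
#' @param stations Station data frame.
#' @param window Length-2 `Date` vector; default full record.
#' @return An `nx x ny` non-negative matrix.
#' @export
footprint_union <- function(transport, stations, window = NULL) {
  out <- matrix(0, transport$grid$nx, transport$grid$ny)
  for (s in seq_len(nrow(stations))) {
    out <- out + station_footprint(transport, stations[s, ], window)
  }
  out
}

#' Validation diagnostics for the three-run protocol
#'
#' Computes the standard diagnostics comparing the unconstrained first-guess
#' run, the raw DA run and the bias-corrected final run against the
#' observations: inter-annual SPIn correlations per station (stations with
#' more than 3 valid years), a decile table of independently sorted co-valid
#' daily values, whole-period `r_st` ratios, two-day temporal correlations
#' per station-year, and (when transport and stations are given) the union
#' footprint map.
#'
#' @param obs Daily observation data frame (one or several years).
#' @param runs Named list of daily model series (e.g. `first_guess`, `da`,
#'   `final`).
#' @param windows Length-2 `Date` vector or named per-year list of windows.
#' @param transport,stations Optional, for the footprint map.
#' @return A list of class `diagnostics_bundle`: `spin_correlation` (per run),
#'   `quantiles` (per run), `r_st` (per run), `twoday_correlation` (per run),
#'   `footprint` (matrix or `NULL`).
#' @export
compute_diagnostics <- function(obs, runs, windows, transport = NULL,
                                stations = NULL) {
  spin_obs <- spin_table(obs, windows)
  win_list <- if (is.list(windows)) windows else {
    stats::setNames(list(as.Date(windows)),
                    format(as.Date(windows[1]), "%Y"))
  }
  co <- obs[obs$valid & !is.na(obs$value), c("station_id", "date", "value")]
  per_run <- lapply(runs, function(series) {
    spin_m <- spin_table(series, windows, min_days = 0)
    m <- merge(co, series[, c("station_id", "date", "value")],
               by = c("station_id", "date"), suffixes = c("_obs", "_mdl"))
    td <- lapply(names(win_list), function(yr) {
      w <- as.Date(win_list[[yr]])
      ids <- unique(obs$station_id)
      rows <- lapply(ids, function(id) {
        ob <- average_2day(obs[obs$station_id == id, ], w[1], w[2])
        mb <- average_2day(series[series$station_id == id, ], w[1], w[2])
        mm <- merge(ob, mb, by = "bin_start", suffixes = c("_obs", "_mdl"))
        cv <- mm$valid_obs & mm$valid_mdl
        if (sum(cv) < 3) return(NULL)
        data.frame(station_id = id, year = as.integer(yr),
                   correlation = suppressWarnings(
                     stats::cor(mm$value_obs[cv], mm$value_mdl[cv])),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    list(spin_correlation = spin_correlation_table(spin_obs, spin_m),
         quantiles = quantile_table(m$value_obs, m$value_mdl),
         r_st = validate_ratio_rst(obs, series),
         twoday_correlation = do.call(rbind, td))
  })
  fp <- NULL
  if (!is.null(transport) && !is.null(stations)) {
    fp <- footprint_union(transport, stations,
                          as.Date(win_list[[length(win_list)]]))
  }
  structure(list(
    spin_correlation = lapply(per_run, `[[`, "spin_correlation"),
    quantiles = lapply(per_run, `[[`, "quantiles"),
    r_st = lapply(per_run, `[[`, "r_st"),
    twoday_correlation = lapply(per_run, `[[`, "twoday_correlation"),
    footprint = fp), class = "diagnostics_bundle")
}
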