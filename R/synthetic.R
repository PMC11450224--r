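#' Synthetic gridded meteorology
#'
#' Generates the driving meteorology of the pipeline on a regular lon-lat
#' grid, emulating the statistical structure a meteorological reanalysis
#' provides: 2 m temperature with a southward-warm latitudinal gradient, a
#' seasonal warming cycle and temporally autocorrelated, spatially smooth
#' noise; a divergence-free wind field derived from a smooth random
#' streamfunction (plus a constant westerly background); a daytime convective
#' velocity scale; relative humidity clipped to `[0, 100]` %; and
#' precipitation occurring in random events. Deterministic given the seed.
#'
#' @param grid A [grid_spec()].
#' @param n_days Number of days (>= 1), starting 1 January of `year`.
#' @param seed Integer seed; same seed, same fields.
#' @param params Optional list overriding defaults: `T_winter_C`, `T_summer_C`
#'   (seasonal cycle at the reference latitude), `T_lat_grad` (K per degree
#'   latitude, cooling northwards), `T_noise_sd` (K), `T_noise_ar` (daily AR1
#'   coefficient), `u_background` (m/s), `wind_sd` (m/s, streamfunction wind
#'   scale), `wstar_max` (m/s), `q_base`, `q_sd` (%), `precip_prob`
#'   (cell-day event probability), `precip_mean` (mm/hr event mean),
#'   `smooth_cells` (spatial correlation scale, cells).
#' @param resolution `"daily"` (default) or `"hourly"`. Hourly mode adds a
#'   diurnal temperature cycle around the daily means (for hourly heat-sum
#'   taxa).
#' @param year Calendar year of the record start.
#' @return A `meteo_fields` object: arrays `T` (K), `U`, `u`, `v`, `wstar`
#'   (m/s), `q` (%), `P` (mm/hr) of dimension `nx x ny x nt`, plus `dates`
#'   (Date per step), `dt_hours` and the `grid`.
#' @export
gen_meteo <- function(grid, n_days, seed, params = list(),
                      resolution = c("daily", "hourly"), year = 2000) {
  resolution <- match.arg(resolution)
  if (n_days < 1) stop("n_days must be >= 1")
  p <- utils::modifyList(list(
    T_winter_C = 0, T_summer_C = 18, T_lat_grad = 0.6,
    T_noise_sd = 2.5, T_noise_ar = 0.7,
    u_background = 3, wind_sd = 2.5, wstar_max = 1.2,
    q_base = 60, q_sd = 15,
    precip_prob = 0.15, precip_mean = 1,
    smooth_cells = 4
  ), params)
  nx <- grid$nx; ny <- grid$ny
  lat_ref <- grid$lat_min
  with_seed(seed, {
    doy <- seq_len(n_days)
    # seasonal cycle: coldest mid-January, warmest mid-July
    seas <- (1 - cos(2 * pi * (doy - 15) / 365)) / 2
    T_day <- 273.15 + p$T_winter_C + (p$T_summer_C - p$T_winter_C) * seas
    lat_term <- -p$T_lat_grad * (grid$lat - lat_ref)        # cooler north
    Tbase <- outer(rep(1, nx), lat_term)

    Tarr <- array(0, dim = c(nx, ny, n_days))
    uarr <- array(0, dim = c(nx, ny, n_days))
    varr <- array(0, dim = c(nx, ny, n_days))
    wstar <- array(0, dim = c(nx, ny, n_days))
    qarr <- array(0, dim = c(nx, ny, n_days))
    Parr <- array(0, dim = c(nx, ny, n_days))

    ar <- p$T_noise_ar
    noise <- smooth_field(nx, ny, p$smooth_cells) * p$T_noise_sd
    psi <- smooth_field(nx, ny, p$smooth_cells)
    for (d in seq_len(n_days)) {
      noise <- ar * noise +
        sqrt(1 - ar^2) * smooth_field(nx, ny, p$smooth_cells) * p$T_noise_sd
      Tarr[, , d] <- T_day[d] + Tbase + noise

      psi <- ar * psi + sqrt(1 - ar^2) * smooth_field(nx, ny, p$smooth_cells)
      # divergence-free wind from the streamfunction (index-space gradients)
      u <- -cbind(psi[, 2] - psi[, 1],
                  (psi[, 3:ny, drop = FALSE] - psi[, 1:(ny - 2), drop = FALSE]) / 2,
                  psi[, ny] - psi[, ny - 1])
      v <- rbind(psi[2, ] - psi[1, ],
                 (psi[3:nx, , drop = FALSE] - psi[1:(nx - 2), , drop = FALSE]) / 2,
                 psi[nx, ] - psi[nx - 1, ])
      sc <- p$wind_sd / max(stats::sd(c(u, v)), 1e-12)
      uarr[, , d] <- p$u_background + u * sc
      varr[, , d] <- v * sc

      wstar[, , d] <- p$wstar_max * seas[d] *
        clip(0.5 + 0.5 * smooth_field(nx, ny, p$smooth_cells), 0, 1)
      rain <- matrix(stats::rbinom(nx * ny, 1, p$precip_prob), nx, ny)
      Parr[, , d] <- rain * stats::rexp(nx * ny, rate = 1 / p$precip_mean)
      qarr[, , d] <- clip(p$q_base + p$q_sd * smooth_field(nx, ny, p$smooth_cells) +
                            25 * rain, 0, 100)
    }

    dates <- as.Date(sprintf("%d-01-01", year)) + (doy - 1)
    if (resolution == "hourly") {
      nt <- n_days * 24
      hr <- rep(0:23, times = n_days)
      idx <- rep(seq_len(n_days), each = 24)
      diurnal <- 4 * -cos(2 * pi * (hr - 2) / 24)  # warmest mid-afternoon
      expand <- function(a) a[, , idx, drop = FALSE]
      Th <- expand(Tarr)
      for (k in seq_len(nt)) Th[, , k] <- Th[, , k] + diurnal[k]
      out <- list(T = Th, u = expand(uarr), v = expand(varr),
                  wstar = expand(wstar), q = expand(qarr), P = expand(Parr),
                  dates = dates[idx], hour = hr, dt_hours = 1)
    } else {
      out <- list(T = Tarr, u = uarr, v = varr, wstar = wstar, q = qarr,
                  P = Parr, dates = dates, hour = NULL, dt_hours = 24)
    }
    out$U <- sqrt(out$u^2 + out$v^2)
    out$grid <- grid
    class(out) <- "meteo_fields"
    out
  })
}

#' @export
print.meteo_fields <- function(x, ...) {
  cat(sprintf("meteo_fields: %d x %d grid, %d steps (%s h), %s to %s\n",
              x$grid$nx, x$grid$ny, dim(x$T)[3], x$dt_hours,
              min(x$dates), max(x$dates)))
  invisible(x)
}

#' Non-limiting weather for budget experiments
#'
#' Convenience wrapper around [gen_meteo()]: warm (no cut-off limitation),
#' dry, rain-free, lightly windy and noise-free conditions under which the
#' release stage never throttles emission, so the seasonal budget contract
#' (release = `S * phi * xi * N_tot`) can be checked exactly.
#'
#' @inheritParams gen_meteo
#' @export
gen_meteo_nonlimiting <- function(grid, n_days, seed = 1, year = 2000) {
  gen_meteo(grid, n_days, seed, params = list(
    T_winter_C = 12, T_summer_C = 20, T_lat_grad = 0.3,
    T_noise_sd = 0, precip_prob = 0, q_base = 40, q_sd = 0,
    u_background = 2, wind_sd = 0.5, wstar_max = 0.5
  ), year = year)
}

#' Synthetic landscape: tree cover and flowering thresholds
#'
#' Generates a smooth random tree-cover fraction field in `[0, 1]` (zeroed
#' south of the taxon's cut latitude where one is configured, e.g. no birch
#' south of 40 N), a flowering-start heat-sum threshold map increasing with
#' latitude (the season arrives later further north), and the flowering-end
#' map `H_fe = H_fs + delta_H_season`. Threshold maps are generated in the
#' same unit as the taxon's heat-sum accumulation (K day for daily-type
#' taxa, K hour for hourly-type).
#'
#' @param grid A [grid_spec()].
#' @param taxon A [taxon_params()] object.
#' @param seed Integer seed.
#' @param params Optional overrides: `phi_max` (max cover fraction),
#'   `phi_const` (if non-`NULL`, a spatially constant cover fraction replaces
#'   the random field — useful for controlled inversion experiments),
#'   `H_fs_base` (K day at the southern edge), `H_fs_lat_slope` (K day per
#'   degree latitude), `delta_H_season` (K day, flowering duration in heat
#'   units), `smooth_cells`.
#' @return A `landscape` object: `phi`, `H_fs`, `H_fe` (`nx x ny` matrices),
#'   heat-sum `unit`, and the `grid` (cell areas in `grid$area_m2`).
#' @export
gen_landscape <- function(grid, taxon, seed, params = list()) {
  p <- utils::modifyList(list(
    phi_max = 0.5, phi_const = NULL, H_fs_base = 60, H_fs_lat_slope = 2.5,
    delta_H_season = 60, smooth_cells = 4
  ), params)
  hourly <- taxon$heatsum_type == "hourly-mean-T"
  u <- if (hourly) 24 else 1  # K hour maps for hourly accumulation
  with_seed(seed, {
    phi <- if (!is.null(p$phi_const)) {
      matrix(p$phi_const, grid$nx, grid$ny)
    } else {
      p$phi_max * clip(0.5 + 0.6 * smooth_field(grid$nx, grid$ny,
                                                p$smooth_cells), 0, 1)
    }
    if (!is.null(taxon$cut_lat_south)) {
      phi[, grid$lat < taxon$cut_lat_south] <- 0
    }
    H_fs <- u * outer(rep(1, grid$nx),
                      p$H_fs_base + p$H_fs_lat_slope * (grid$lat - grid$lat_min))
    H_fs <- H_fs * (1 + 0.05 * smooth_field(grid$nx, grid$ny, p$smooth_cells))
    H_fs <- pmax(H_fs, u * p$H_fs_base / 2)
    structure(list(phi = phi, H_fs = H_fs, H_fe = H_fs + u * p$delta_H_season,
                   unit = if (hourly) "K hour" else "K day",
                   taxon = taxon$name, grid = grid),
              class = "landscape")
  })
}

#' Synthetic station network
#'
#' Places `n_stations` monitoring sites inside the domain. With
#' `clustering > 0` a fraction of the stations gathers around a few cluster
#' seeds (emulating dense national networks) while the rest spread uniformly;
#' stations whose nearest neighbour lies beyond `isolation_km` are flagged
#' `isolated` (such stations are mandatorily assimilated downstream). With
#' `clustering > 0` at least one isolated station is guaranteed by moving the
#' last station to the emptiest corner if necessary.
#'
#' @param grid A [grid_spec()].
#' @param n_stations Number of stations (>= 1, at most the number of cells).
#' @param seed Integer seed.
#' @param clustering Fraction in `[0, 1]` of stations drawn around cluster
#'   seeds.
#' @param isolation_km Nearest-neighbour distance (km) beyond which a station
#'   counts as spatially isolated.
#' @return A data frame with columns `station_id`, `lon`, `lat`, `isolated`.
#' @export
gen_station_network <- function(grid, n_stations, seed, clustering = 0,
                                isolation_km = 300) {
  if (n_stations < 1) stop("n_stations must be >= 1")
  if (n_stations > n_cells(grid)) stop("more stations than grid cells")
  stopifnot(clustering >= 0, clustering <= 1)
  with_seed(seed, {
    runif_lon <- function(n) stats::runif(n, grid$lon_min + 0.501 * grid$dlon,
                                          grid$lon_max - 0.501 * grid$dlon)
    runif_lat <- function(n) stats::runif(n, grid$lat_min + 0.501 * grid$dlat,
                                          grid$lat_max - 0.501 * grid$dlat)
    n_clustered <- round(clustering * n_stations)
    n_uniform <- n_stations - n_clustered
    lon <- runif_lon(n_uniform); lat <- runif_lat(n_uniform)
    if (n_clustered > 0) {
      n_seeds <- max(1, round(n_clustered / 5))
      cl <- sample.int(n_seeds, n_clustered, replace = TRUE)
      slon <- runif_lon(n_seeds); slat <- runif_lat(n_seeds)
      spread_lon <- 1.5 * grid$dlon; spread_lat <- 1.5 * grid$dlat
      lon <- c(lon, clip(slon[cl] + stats::rnorm(n_clustered, 0, spread_lon),
                         grid$lon_min + 0.501 * grid$dlon,
                         grid$lon_max - 0.501 * grid$dlon))
      lat <- c(lat, clip(slat[cl] + stats::rnorm(n_clustered, 0, spread_lat),
                         grid$lat_min + 0.501 * grid$dlat,
                         grid$lat_max - 0.501 * grid$dlat))
    }
    st <- data.frame(station_id = sprintf("ST%03d", seq_len(n_stations)),
                     lon = lon, lat = lat, stringsAsFactors = FALSE)
    st$isolated <- station_isolation(st, isolation_km)
    if (clustering > 0 && n_stations > 1 && !any(st$isolated)) {
      # plant one isolated site in the corner farthest from the network
      corners <- cbind(lon = c(grid$lon_min, grid$lon_max, grid$lon_min,
                               grid$lon_max) + c(1, -1, 1, -1) * grid$dlon,
                       lat = c(grid$lat_min, grid$lat_min, grid$lat_max,
                               grid$lat_max) + c(1, 1, -1, -1) * grid$dlat)
      d <- gc_distance_matrix_km(corners, cbind(st$lon, st$lat)[-n_stations, ,
                                                                drop = FALSE])
      k <- which.max(apply(d, 1, min))
      st$lon[n_stations] <- corners[k, 1]; st$lat[n_stations] <- corners[k, 2]
      st$isolated <- station_isolation(st, isolation_km)
    }
    st
  })
}

# nearest-neighbour isolation flags for a station table
station_isolation <- function(stations, isolation_km) {
  n <- nrow(stations)
  if (n == 1) return(TRUE)
  d <- gc_distance_matrix_km(cbind(stations$lon, stations$lat),
                             cbind(stations$lon, stations$lat))
  diag(d) <- Inf
  apply(d, 1, min) > isolation_km
}

#' Synthetic "true" seasonal release correction field
#'
#' A smooth, strictly positive per-cell correction field used as the truth of
#' observing-system simulation experiments: log-uniformly spread over
#' `range` via a smooth Gaussian field mapped through its own quantiles.
#'
#' @param grid A [grid_spec()].
#' @param seed Integer seed.
#' @param range Length-2 positive vector, the `xi` range (default `c(0.5, 2)`).
#' @param smooth_cells Spatial correlation scale in cells.
#' @return An `nx x ny` matrix of corrections in `range`.
#' @export
gen_truth_xi <- function(grid, seed, range = c(0.5, 2), smooth_cells = 5) {
  stopifnot(length(range) == 2, all(range > 0), range[2] > range[1])
  with_seed(seed, {
    f <- smooth_field(grid$nx, grid$ny, smooth_cells)
    u <- stats::pnorm(f)  # approx uniform in (0,1), spatially smooth
    exp(log(range[1]) + u * (log(range[2]) - log(range[1])))
  })
}

#' Synthetic daily station observations from a truth run
#'
#' Samples a gridded "truth" concentration field at station locations
#' (bilinear interpolation, daily means), applies multiplicative lognormal
#' noise with unit mean, and knocks out days at the configured missing-data
#' probability. With `sigma = 0` and `missing_prob = 0` the observations are
#' the exact observation-operator image of the truth run.
#'
#' @param conc A `concentration_field` (see [forward_transport()]).
#' @param stations Station data frame (`station_id`, `lon`, `lat`).
#' @param sigma Lognormal sigma of the multiplicative observation noise.
#' @param missing_prob Probability that a station-day is missing.
#' @param seed Integer seed.
#' @return A data frame (one row per station-day): `station_id`, `lon`,
#'   `lat`, `date`, `value` (grains/m3, `NA` when invalid), `valid`.
#' @export
gen_observations <- function(conc, stations, sigma = 0.3, missing_prob = 0.05,
                             seed = 1) {
  truth <- sample_model(conc, stations)
  with_seed(seed, {
    n <- nrow(truth)
    noise <- exp(stats::rnorm(n, -sigma^2 / 2, sigma))
    truth$value <- truth$value * noise
    missing <- stats::runif(n) < missing_prob
    truth$valid <- !missing
    truth$value[missing] <- NA_real_
    truth
  })
}
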