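#' Probability that flowering has started
#'
#' Piecewise-linear ramp over the heat-sum uncertainty band: 0 while the
#' accumulated heat sum is below `(1 - delta_H) * H_fs`, 1 once it exceeds
#' `(1 + delta_H) * H_fs`, linear in between. Represents the fraction of trees
#' in a cell whose individual start threshold has been crossed.
#'
#' @param h_ratio Ratio of accumulated heat sum to the start threshold,
#'   `H / H_fs` (>= 0).
#' @param delta_H Relative uncertainty of the heat-sum thresholds (e.g. 0.10).
#' @return Probability in `[0, 1]`, vectorised over `h_ratio`.
#' @examples
#' p_start(c(0.9, 1, 1.1), delta_H = 0.1)  # 0, 0.5, 1
#' @export
p_start <- function(h_ratio, delta_H) {
  stopifnot(all(h_ratio >= 0), delta_H > 0, delta_H < 1)
  clip((h_ratio - (1 - delta_H)) / (2 * delta_H), 0, 1)
}

#' Probability that flowering has not yet ended
#'
#' Piecewise-linear ramp over the seasonal-total uncertainty band: 1 while the
#' development fraction is below `1 - delta_N`, 0 once it exceeds
#' `1 + delta_N`, linear in between — the fraction of trees whose individual
#' seasonal total (uniform across the band) is not yet exhausted.
#'
#' @param frac Development fraction of the standard seasonal total (>= 0).
#' @param delta_N Relative uncertainty of the seasonal total (e.g. 0.10).
#' @return Probability in `[0, 1]`, vectorised over `frac`.
#' @examples
#' p_end(c(0.5, 1, 1.15), delta_N = 0.1)  # 1, 0.5, 0
#' @export
p_end <- function(frac, delta_N) {
  stopifnot(all(frac >= 0), delta_N > 0, delta_N < 1)
  clip(((1 + delta_N) - frac) / (2 * delta_N), 0, 1)
}

# exact integral of p_end over the development interval [x0, x1] (vectorised);
# integrating the ramp analytically (rather than sampling it once per step)
# makes the seasonal production total exactly the standard total once
# development passes the band, independent of step length.
p_end_integral <- function(x0, x1, delta_N) {
  a <- 1 - delta_N
  b <- 1 + delta_N
  # antiderivative: x below a, plus the ramp integral from a to min(x, b)
  antider <- function(x) {
    m <- pmax(pmin(x, b), a)
    pmin(pmax(x, 0), a) + ((b - a)^2 - (b - m)^2) / (2 * (b - a))
  }
  antider(x1) - antider(x0)
}

#' Threshold correction factor for humidity or precipitation
#'
#' Linear shut-down ramp: 1 at or below `v_low`, 0 at or above `v_high`,
#' linear in between. Used for relative humidity (release stops in humid air)
#' and precipitation rate (release stops in rain, with `P_low = 0`).
#'
#' @param v Value of the meteorological variable (vectorised).
#' @param v_low,v_high Lower/upper thresholds, `v_low < v_high`.
#' @return Factor in `[0, 1]`.
#' @examples
#' threshold_factor(95, 50, 90)   # humid: 0
#' threshold_factor(1, 0, 0.5)    # raining: 0
#' @export
threshold_factor <- function(v, v_low, v_high) {
  stopifnot(v_low < v_high)
  clip((v_high - v) / (v_high - v_low), 0, 1)
}

#' Wind enhancement factor for pollen release
#'
#' Saturating increase with the sum of mean wind speed and the convective
#' velocity scale: `1 + (max_scale - 1) * (1 - exp(-(U + wstar) / U_sat))`.
#' Equal to 1 in calm air and approaching the taxon's maximum wind scaling
#' (1.5 for the shipped taxa) as `(U + wstar)` grows past the saturation
#' level.
#'
#' @param U Wind speed (m/s, >= 0), vectorised.
#' @param wstar Convective velocity scale (m/s, >= 0), vectorised.
#' @param taxon A [taxon_params()] object (fields `U_sat`, `wind_max_scale`).
#' @return Factor in `[1, wind_max_scale)`.
#' @export
wind_factor <- function(U, wstar, taxon) {
  stopifnot(all(U >= 0), all(wstar >= 0))
  1 + (taxon$wind_max_scale - 1) * (1 - exp(-(U + wstar) / taxon$U_sat))
}

#' Accumulated heat sum at one grid cell
#'
#' Accumulates `max(T - T_co, 0)` per step from the taxon's start day of heat
#' accumulation. Daily-type taxa accumulate in K day on daily-mean
#' temperature; hourly-type taxa accumulate in K hour (on hourly temperature
#' when the meteorology is hourly, otherwise 24 x the daily-mean excess).
#'
#' @param meteo A `meteo_fields` object from [gen_meteo()].
#' @param taxon A [taxon_params()] object.
#' @param cell Integer vector `c(i, j)` of grid indices.
#' @param dates Optional `Date` vector at which to report the heat sum;
#'   defaults to the full meteorology record. Must lie within the record.
#' @return Numeric vector of accumulated heat sums (K day or K hour) at the
#'   requested dates.
#' @export
accumulate_heat_sum <- function(meteo, taxon, cell, dates = NULL) {
  if (is.null(dates)) dates <- unique(meteo$dates)
  if (any(dates < min(meteo$dates)) || any(dates > max(meteo$dates))) {
    stop("requested dates outside the meteorology record")
  }
  Tser <- meteo$T[cell[1], cell[2], ]
  inc <- heat_increments(Tser, meteo, taxon)
  H <- cumsum(inc)
  H[match(dates, meteo$dates)]
}

# per-step heat-sum increments for a temperature series aligned with meteo steps
heat_increments <- function(Tser, meteo, taxon) {
  year <- as.integer(format(meteo$dates[1], "%Y"))
  start <- doy_date(year, mmdd_doy(taxon$start_day, year))
  excess <- pmax(Tser - taxon$T_co, 0)
  excess[meteo$dates < start] <- 0
  if (taxon$heatsum_type == "hourly-mean-T") {
    excess * meteo$dt_hours            # K hour
  } else {
    excess * meteo$dt_hours / 24       # K day
  }
}

#' Seasonal pollen emission from phenology and meteorology
#'
#' Runs the two-stage source term over the whole meteorology record for every
#' grid cell: (1) development of ready-to-fly pollen driven by the heat sum
#' between the mapped flowering-start and flowering-end thresholds, at rate
#' `S * phi * xi * N_tot * (T - T_co)/Delta_H` gated by the start and end
#' ramps; (2) release of the ready-pollen stock modulated by wind, humidity
#' and precipitation, with exponential depletion at time constant `tau`
#' (emitted fraction capped at full depletion). The end-of-flowering ramp is
#' integrated analytically along the development coordinate, so under
#' non-limiting weather the per-cell seasonal release equals
#' `S * phi * xi * N_tot` exactly, and the whole emission history is exactly
#' proportional to `xi` cell by cell.
#'
#' @param meteo A `meteo_fields` object from [gen_meteo()].
#' @param landscape A `landscape` object from [gen_landscape()].
#' @param taxon A [taxon_params()] object.
#' @param xi Per-cell seasonal release correction: scalar or `nx x ny` matrix,
#'   strictly positive.
#' @return An object of class `emission_field`: list with `E` (array
#'   `nx x ny x nt`, grains/s per cell), `budget` (matrix, grains released per
#'   cell over the season), `R` (released fraction of the corrected seasonal
#'   total), `dates`, `dt_hours` and the `grid`.
#' @export
compute_emission <- function(meteo, landscape, taxon, xi = 1) {
  grid <- landscape$grid
  nx <- grid$nx; ny <- grid$ny
  nt <- dim(meteo$T)[3]
  if (is.matrix(xi)) stopifnot(dim(xi) == c(nx, ny)) else xi <- matrix(xi, nx, ny)
  if (any(xi <= 0)) stop("xi must be strictly positive")
  dH <- landscape$H_fe - landscape$H_fs
  producing <- landscape$phi > 0
  if (any(producing & dH <= 0)) stop("H_fe - H_fs <= 0 at a producing cell")
  dH[dH <= 0] <- 1  # inert cells; never used with phi = 0

  total <- grid$area_m2 * landscape$phi * xi * taxon$N_tot  # grains per season
  dt_s <- meteo$dt_hours * 3600
  dt_heat <- if (taxon$heatsum_type == "hourly-mean-T") meteo$dt_hours else
    meteo$dt_hours / 24

  year <- as.integer(format(meteo$dates[1], "%Y"))
  start <- doy_date(year, mmdd_doy(taxon$start_day, year))
  rel_frac_base <- 1 - exp(-dt_s / taxon$tau_s)

  H <- matrix(0, nx, ny)
  dev <- matrix(0, nx, ny)       # development coordinate (fraction of total)
  p_rdy <- matrix(0, nx, ny)
  released <- matrix(0, nx, ny)
  E <- array(0, dim = c(nx, ny, nt))

  for (t in seq_len(nt)) {
    Tt <- meteo$T[, , t]
    excess <- pmax(Tt - taxon$T_co, 0)
    if (meteo$dates[t] >= start) H <- H + excess * dt_heat

    pfs <- p_start(H / landscape$H_fs, taxon$delta_H)
    # hard stop once the released fraction overshoots the upper band edge
    active <- released < (1 + taxon$delta_N) * pmax(total, .Machine$double.xmin)
    ddev <- (excess / dH) * pfs * dt_heat * active
    prod <- total * p_end_integral(dev, dev + ddev, taxon$delta_N)
    dev <- dev + ddev
    p_rdy <- p_rdy + prod

    fw <- wind_factor(meteo$U[, , t], meteo$wstar[, , t], taxon)
    fq <- threshold_factor(meteo$q[, , t], taxon$q_low, taxon$q_high)
    fp <- threshold_factor(meteo$P[, , t], 0, taxon$P_high_mm_hr)
    frac <- pmin(1, rel_frac_base * fw * fq * fp)
    emitted <- p_rdy * frac
    p_rdy <- p_rdy - emitted
    released <- released + emitted
    E[, , t] <- emitted / dt_s
  }
  structure(list(E = E, budget = released,
                 R = released / pmax(total, .Machine$double.xmin),
                 dates = meteo$dates, dt_hours = meteo$dt_hours, grid = grid,
                 taxon = taxon$name),
            class = "emission_field")
}

#' @export
print.emission_field <- function(x, ...) {
  cat(sprintf("emission_field: %s, %d steps, total %.3g grains\n",
              x$taxon, dim(x$E)[3], sum(x$budget)))
  invisible(x)
}
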