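#' Whole-period station SPIn ratios for bias calibration
#'
#' Computes, for each station, the ratio of model to observed seasonal pollen
#' integrals summed over all qualifying years,
#' `r_s = sum(SPIn_mdl) / sum(SPIn_obs)`. A station-year qualifies when it
#' has at least `min_days` valid daily observations; no model-measurement
#' correlation threshold is applied at this stage. Stations whose observed
#' SPIn sum is zero are excluded (with a message).
#'
#' @param spin_mdl,spin_obs Data frames with `station_id`, `year`, `value`,
#'   `n_valid` (e.g. from [spin_table()]), co-located station-years.
#' @param min_days Minimum valid observation days per qualifying year
#'   (default 30).
#' @return Data frame: `station_id`, `lon`, `lat` (if present in the obs
#'   table), `r_s`, `n_years`.
#' @export
compute_ratio_rs <- function(spin_mdl, spin_obs, min_days = 30) {
  m <- merge(spin_obs, spin_mdl, by = c("station_id", "year"),
             suffixes = c("_obs", "_mdl"))
  m <- m[m$n_valid_obs >= min_days, , drop = FALSE]
  ids <- unique(m$station_id)
  rows <- lapply(ids, function(id) {
    mm <- m[m$station_id == id, , drop = FALSE]
    so <- sum(mm$value_obs); sm <- sum(mm$value_mdl)
    if (so == 0) {
      message("station ", id, " excluded from calibration: zero observed SPIn")
      return(NULL)
    }
    out <- data.frame(station_id = id, r_s = sm / so, n_years = nrow(mm),
                      stringsAsFactors = FALSE)
    if ("lon_obs" %in% names(mm)) { out$lon <- mm$lon_obs[1]; out$lat <- mm$lat_obs[1] }
    else if ("lon" %in% names(mm)) { out$lon <- mm$lon[1]; out$lat <- mm$lat[1] }
    out
  })
  do.call(rbind, rows)
}

#' Radial-basis-function interpolation of station ratios to the grid
#'
#' Interpolates/extrapolates scattered station values over the whole domain
#' with a linear-kernel RBF plus a constant polynomial tail and a smoothing
#' parameter added on the kernel diagonal (default 10). With a single point,
#' or constant data at zero smoothing, the field is exactly constant, and the
#' linear kernel keeps far-field extrapolation finite.
#'
#' @param points Data frame with `lon`, `lat` and a value column (`r_s` by
#'   default).
#' @param grid A [grid_spec()].
#' @param smoothing Smoothing parameter (default 10).
#' @param value_col Name of the value column (default `"r_s"`).
#' @return An `nx x ny` matrix of interpolated values at cell centers.
#' @export
interpolate_rbf <- function(points, grid, smoothing = 10, value_col = "r_s") {
  if (is.null(points) || nrow(points) == 0) {
    stop("no calibration points: cannot interpolate")
  }
  v <- points[[value_col]]
  X <- cbind(points$lon, points$lat)
  centers <- cell_centers(grid)
  n <- nrow(X)
  if (n == 1) return(matrix(v, grid$nx, grid$ny))
  # linear kernel phi(r) = -r, constant polynomial tail, smoothing on the
  # kernel diagonal: [K + s I, 1; 1', 0] [w; c] = [v; 0]
  K <- -as.matrix(stats::dist(X))
  A <- rbind(cbind(K + diag(smoothing, n), rep(1, n)), c(rep(1, n), 0))
  sol <- solve(A, c(v, 0))
  w <- sol[1:n]; cc <- sol[n + 1]
  d_eval <- sqrt(outer(centers[, 1], X[, 1], "-")^2 +
                   outer(centers[, 2], X[, 2], "-")^2)
  matrix(as.numeric(-d_eval %*% w + cc), grid$nx, grid$ny)
}

#' Apply a climatological calibration map to an emission field
#'
#' Divides the emission by the interpolated model-over-observation SPIn ratio
#' (`r_s > 1` means the model is biased high, so emission is reduced). The
#' correction map is clipped to a positive floor before use; a non-positive
#' correction cell is an error.
#'
#' @param emission An `emission_field` from [compute_emission()] or a numeric
#'   matrix/array to be scaled.
#' @param correction `nx x ny` matrix of `r_s` ratios (strictly positive).
#' @param floor Lower clip for the correction (default 0.1).
#' @return Object of the same kind as `emission`, scaled per cell by
#'   `1 / pmax(correction, floor)`.
#' @export
apply_calibration <- function(emission, correction, floor = 0.1) {
  if (any(correction <= 0)) stop("non-positive calibration correction cell")
  corr <- pmax(correction, floor)
  if (inherits(emission, "emission_field")) {
    nt <- dim(emission$E)[3]
    emission$E <- emission$E / array(corr, dim = c(dim(corr), nt))
    emission$budget <- emission$budget / corr
    return(emission)
  }
  if (is.array(emission) && length(dim(emission)) == 3) {
    return(emission / array(corr, dim = dim(emission)))
  }
  emission / corr
}

#' Whole-period observed-over-modelled SPIn ratio per station
#'
#' Validation ratio `r_st = sum(obs) / sum(mdl)` over all valid observed
#' daily values and the exactly co-located (same station, same day) model
#' values. Model days without a valid observation contribute nothing.
#' Stations with a zero model sum are skipped.
#'
#' @param obs,mdl Daily data frames (`station_id`, `date`, `value`, `valid`).
#' @return Data frame: `station_id`, `r_st`, `n_days`.
#' @export
validate_ratio_rst <- function(obs, mdl) {
  m <- merge(obs[obs$valid & !is.na(obs$value),
                 c("station_id", "date", "value")],
             mdl[, c("station_id", "date", "value")],
             by = c("station_id", "date"), suffixes = c("_obs", "_mdl"))
  ids <- unique(m$station_id)
  rows <- lapply(ids, function(id) {
    mm <- m[m$station_id == id, , drop = FALSE]
    sm <- sum(mm$value_mdl)
    if (sm == 0) return(NULL)
    data.frame(station_id = id, r_st = sum(mm$value_obs) / sm,
               n_days = nrow(mm), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
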