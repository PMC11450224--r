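#' Sample a concentration field at station locations
#'
#' The observation operator: bilinear interpolation of the daily near-surface
#' concentration field to each station location. Linear in the field.
#'
#' @param conc A `concentration_field` from [forward_transport()].
#' @param stations Data frame with `station_id`, `lon`, `lat` (in-domain).
#' @return Data frame of daily series: `station_id`, `lon`, `lat`, `date`,
#'   `value` (grains/m3), `valid` (all `TRUE`).
#' @export
sample_model <- function(conc, stations) {
  grid <- conc$grid
  nd <- dim(conc$conc)[3]
  cm <- matrix(conc$conc, n_cells(grid), nd)
  out <- vector("list", nrow(stations))
  for (s in seq_len(nrow(stations))) {
    if (!in_domain(grid, stations$lon[s], stations$lat[s])) {
      stop("station ", stations$station_id[s], " outside the grid domain")
    }
    bw <- bilinear_weights(grid, stations$lon[s], stations$lat[s])
    vals <- as.numeric(bw$w %*% cm[bw$idx, , drop = FALSE])
    out[[s]] <- data.frame(station_id = stations$station_id[s],
                           lon = stations$lon[s], lat = stations$lat[s],
                           date = conc$dates, value = vals, valid = TRUE,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Two-day averaging of a daily station series
#'
#' Aggregates a daily series into non-overlapping two-day bins anchored at
#' `window_start`. A bin's value is the mean of its valid days: both days
#' when both are valid, the single valid day's value otherwise; a bin is
#' invalid only when both days are invalid (or outside the series).
#'
#' @param series Daily data frame with `date`, `value`, `valid` (one station).
#' @param window_start `Date` anchoring the first bin.
#' @param window_end Optional `Date`; days after it are dropped.
#' @return Data frame with `bin_start` (`Date`), `value`, `valid`, `n_valid`.
#' @export
average_2day <- function(series, window_start, window_end = NULL) {
  window_start <- as.Date(window_start)
  keep <- series$date >= window_start
  if (!is.null(window_end)) keep <- keep & series$date <= as.Date(window_end)
  s <- series[keep, , drop = FALSE]
  if (nrow(s) == 0) {
    return(data.frame(bin_start = as.Date(character(0)), value = numeric(0),
                      valid = logical(0), n_valid = integer(0)))
  }
  bin <- as.integer(floor(as.numeric(s$date - window_start) / 2))
  ok <- s$valid & !is.na(s$value)
  starts <- window_start + 2 * sort(unique(bin))
  n_valid <- as.integer(tapply(ok, bin, sum))
  val <- as.numeric(tapply(ifelse(ok, s$value, NA_real_), bin,
                           function(x) mean(x, na.rm = TRUE)))
  val[n_valid == 0] <- NA_real_
  data.frame(bin_start = starts, value = val, valid = n_valid > 0,
             n_valid = n_valid)
}

#' Quality filter for one station-year
#'
#' Applies the observational inclusion rules of the assimilation: a station
#' year is accepted only if, inside the assimilation window, it has at least
#' `min_days` valid observation days, at least `min_nonzero` of them non-zero,
#' and the Pearson correlation between observed and modelled two-day means
#' (on co-valid bins) is strictly better than `min_corr`.
#'
#' @param obs,mdl Daily data frames (`date`, `value`, `valid`) for the same
#'   station; `mdl` is the model sampled at the station.
#' @param window Length-2 `Date` vector (assimilation window).
#' @param min_days Minimum valid observation days (default 30).
#' @param min_nonzero Minimum non-zero valid days (default 5).
#' @param min_corr Correlation threshold; strict "better than" (default 0.3).
#' @return List: `accept` (logical), `reason` (`"ok"`, `"completeness"`,
#'   `"non-zero"`, `"correlation"`, `"no co-valid data"`), `n_valid`,
#'   `n_nonzero`, `correlation`.
#' @export
station_year_passes <- function(obs, mdl, window, min_days = 30,
                                min_nonzero = 5, min_corr = 0.3) {
  window <- as.Date(window)
  o <- obs[obs$date >= window[1] & obs$date <= window[2], , drop = FALSE]
  ok <- o$valid & !is.na(o$value)
  n_valid <- sum(ok)
  n_nonzero <- sum(ok & o$value > 0)
  res <- list(accept = FALSE, reason = "ok", n_valid = n_valid,
              n_nonzero = n_nonzero, correlation = NA_real_)
  if (n_valid < min_days) { res$reason <- "completeness"; return(res) }
  if (n_nonzero < min_nonzero) { res$reason <- "non-zero"; return(res) }
  ob <- average_2day(o, window[1], window[2])
  mb <- average_2day(mdl, window[1], window[2])
  m <- merge(ob, mb, by = "bin_start", suffixes = c("_obs", "_mdl"))
  co <- m$valid_obs & m$valid_mdl
  if (sum(co) < 3) { res$reason <- "no co-valid data"; return(res) }
  r <- suppressWarnings(stats::cor(m$value_obs[co], m$value_mdl[co]))
  res$correlation <- r
  if (is.na(r) || r <= min_corr) { res$reason <- "correlation"; return(res) }
  res$accept <- TRUE
  res
}

#' Filter all station-years of an observation table
#'
#' Runs [station_year_passes()] for every station in `obs` against the
#' corresponding modelled series and returns the acceptance audit.
#'
#' @param obs,mdl Daily observation / model data frames with `station_id`.
#' @inheritParams station_year_passes
#' @return Data frame: `station_id`, `accept`, `reason`, `n_valid`,
#'   `n_nonzero`, `correlation`.
#' @export
filter_station_years <- function(obs, mdl, window, min_days = 30,
                                 min_nonzero = 5, min_corr = 0.3) {
  ids <- unique(obs$station_id)
  rows <- lapply(ids, function(id) {
    r <- station_year_passes(obs[obs$station_id == id, ],
                             mdl[mdl$station_id == id, ], window,
                             min_days, min_nonzero, min_corr)
    data.frame(station_id = id, accept = r$accept, reason = r$reason,
               n_valid = r$n_valid, n_nonzero = r$n_nonzero,
               correlation = r$correlation, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Split accepted stations into assimilation and evaluation subsets
#'
#' Semi-random 80/20 split: the mandatory (spatially isolated) stations always
#' go to assimilation; the remainder is split randomly so the assimilation set
#' holds `frac` of all stations. If `regions` are supplied and some region
#' ends up with all its stations in evaluation, the split is redrawn.
#' Deterministic given the seed.
#'
#' @param stations Character vector of accepted station ids.
#' @param mandatory Character vector, subset of `stations`.
#' @param seed Integer seed.
#' @param frac Assimilation fraction (default 0.8).
#' @param regions Optional named character vector mapping station id to a
#'   region label for the coverage re-check.
#' @param max_redraw Maximum redraws for the coverage re-check.
#' @return List with character vectors `assimilation` and `evaluation`.
#' @export
split_assim_eval <- function(stations, mandatory = character(0), seed = 1,
                             frac = 0.8, regions = NULL, max_redraw = 20) {
  stopifnot(all(mandatory %in% stations))
  rest <- setdiff(stations, mandatory)
  if (length(rest) < 2) {
    if (length(rest) > 0) {
      warning("fewer than 2 non-mandatory stations: all used for assimilation")
    }
    return(list(assimilation = stations, evaluation = character(0)))
  }
  n_target <- round(frac * length(stations))
  n_extra <- min(length(rest), max(0, n_target - length(mandatory)))
  with_seed(seed, {
    for (try in seq_len(max_redraw)) {
      extra <- sample(rest, n_extra)
      assim <- c(mandatory, extra)
      eval_ <- setdiff(stations, assim)
      if (is.null(regions) || length(eval_) == 0) break
      covered <- unique(regions[assim])
      if (all(unique(regions[stations]) %in% covered)) break
    }
    list(assimilation = assim, evaluation = eval_)
  })
}

#' Seasonal Pollen Integral (SPIn)
#'
#' Sum of the valid daily mean concentrations over a window, in
#' pollen day m-3. A station-year is flagged unusable when it has fewer than
#' `min_days` valid days in the window.
#'
#' @param series Daily data frame (`date`, `value`, `valid`) for one station.
#' @param window Length-2 `Date` vector.
#' @param min_days Minimum valid days for the value to be usable (default 30).
#' @return List: `value` (pollen day m-3), `n_valid`, `usable`.
#' @export
compute_spin <- function(series, window, min_days = 30) {
  window <- as.Date(window)
  s <- series[series$date >= window[1] & series$date <= window[2], ,
              drop = FALSE]
  ok <- s$valid & !is.na(s$value)
  list(value = sum(s$value[ok]), n_valid = sum(ok),
       usable = sum(ok) >= min_days)
}
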