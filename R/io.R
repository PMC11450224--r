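#' Write / read station series as CSV
#'
#' Plain-text exchange format for daily station series: columns
#' `station_id, lon, lat, date, value, valid_flag`.
#'
#' @param series Daily station data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_station_csv <- function(series, path) {
  out <- data.frame(station_id = series$station_id, lon = series$lon,
                    lat = series$lat, date = as.character(series$date),
                    value = series$value, valid_flag = as.integer(series$valid))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_station_csv
#' @export
read_station_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(station_id = d$station_id, lon = d$lon, lat = d$lat,
             date = as.Date(d$date), value = d$value,
             valid = d$valid_flag == 1, stringsAsFactors = FALSE)
}

#' Write a gridded field as long-format CSV
#'
#' Writes a 2-D field (`nx x ny` matrix) or 3-D field (`nx x ny x nt` array,
#' with `dates`) as `lon, lat[, date], value` rows, with the units recorded in
#' a header comment line.
#'
#' @param field Matrix or 3-D array on `grid`.
#' @param grid A [grid_spec()].
#' @param path Output file path.
#' @param units Units string stored in the header comment.
#' @param dates `Date` vector for the third dimension of a 3-D field.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(field, grid, path, units = "", dates = NULL) {
  centers <- cell_centers(grid)
  if (is.matrix(field)) {
    d <- data.frame(lon = centers[, 1], lat = centers[, 2],
                    value = as.vector(field))
  } else {
    nt <- dim(field)[3]
    if (is.null(dates)) dates <- seq_len(nt)
    d <- data.frame(lon = rep(centers[, 1], nt),
                    lat = rep(centers[, 2], nt),
                    date = rep(as.character(dates), each = nrow(centers)),
                    value = as.vector(field))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", units), con)
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}

#' Write assimilation diagnostics to CSV and JSON
#'
#' Per-iteration diagnostics go to `<stem>_iterations.csv`; the summary
#' (stop index, L-curve fit, RMSE ratios for the assimilation and evaluation
#' sets) to `<stem>_summary.json` (requires the jsonlite package).
#'
#' @param result An `assimilation_result` from [minimize_truncated()].
#' @param stem Output path stem.
#' @return Character vector of the files written, invisibly.
#' @export
write_da_diagnostics <- function(result, stem) {
  csv <- paste0(stem, "_iterations.csv")
  utils::write.csv(result$diagnostics, csv, row.names = FALSE)
  files <- csv
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    js <- paste0(stem, "_summary.json")
    jsonlite::write_json(list(
      stop_index = result$stop_index,
      rmse_ratio_assim = result$rmse_ratio_assim,
      rmse_ratio_eval = result$rmse_ratio_eval,
      lcurve = result$lcurve[c("a", "b", "c", "initial_slope", "stop_Jbg")]
    ), js, auto_unbox = TRUE, digits = NA)
    files <- c(files, js)
  }
  invisible(files)
}
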