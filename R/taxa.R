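#' Source-term parameters for a tree pollen taxon
#'
#' Loads the versioned parameter set governing heat-sum development and
#' meteorology-modulated pollen release for one tree genus. Three parameter
#' files ship with the package: `"alder"` (*Alnus*), `"birch"` (*Betula*) and
#' `"olive"` (*Olea*). Each file carries, field for field: the heat-sum type
#' (hourly vs. daily mean temperature), the heat-sum uncertainty band
#' `delta_H`, the calendar start day of heat accumulation, the cut-off
#' temperature below which no heat accumulates, the standard seasonal pollen
#' release `N_tot` (grains per m2 of crown-covered area per year) and its
#' uncertainty `delta_N`, the shortest release time `tau` (s), humidity and
#' precipitation thresholds of the release stage, the wind saturation level
#' and maximum wind scaling, injection height range, grain diameter and
#' density (used for the settling/deposition rate of the transport operator),
#' and the taxon's assimilation window.
#'
#' @param name Taxon name (`"alder"`, `"birch"`, `"olive"`) or a path to a
#'   YAML parameter file with the same schema.
#' @return An object of class `taxon_params` (a named list). Temperatures are
#'   stored in Kelvin (`T_co`), the original Celsius value is kept as
#'   `T_co_C`. Dates (`start_day`, `window_start`, `window_end`) are
#'   `"mm-dd"` strings resolved to concrete dates per scenario year.
#' @examples
#' birch <- taxon_params("birch")
#' birch$T_co_C   # 3.5 degC cut-off
#' birch$N_tot    # 1e8 grains m-2 yr-1
#' @export
taxon_params <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "taxa", paste0(name, ".yaml"), package = "pollenvar")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown taxon: ", name, " (expected alder, birch, olive or a file path)")
  }
  p <- yaml::read_yaml(path)
  p$N_tot <- as.numeric(p$N_tot)
  p$T_co <- p$T_co_C + 273.15
  stopifnot(p$q_low < p$q_high, p$P_high_mm_hr > 0, p$tau_s > 0,
            p$N_tot > 0, p$delta_H > 0, p$delta_H < 1)
  class(p) <- "taxon_params"
  p
}

#' @export
print.taxon_params <- function(x, ...) {
  cat(sprintf("taxon_params: %s (%s), %s heat sum, T_co = %g degC, N_tot = %g\n",
              x$name, x$genus, x$heatsum_type, x$T_co_C, x$N_tot))
  invisible(x)
}

# resolve an "mm-dd" string to a day-of-year in `year`
mmdd_doy <- function(mmdd, year) {
  d <- as.Date(paste0(year, "-", mmdd))
  as.integer(d - as.Date(sprintf("%d-01-01", year))) + 1L
}

#' Assimilation window of a taxon as dates
#'
#' @param taxon A [taxon_params()] object.
#' @param year Calendar year.
#' @return A length-2 `Date` vector `c(start, end)`.
#' @export
assimilation_window <- function(taxon, year) {
  c(as.Date(paste0(year, "-", taxon$window_start)),
    as.Date(paste0(year, "-", taxon$window_end)))
}
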