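# shared fixtures; expensive objects are built once per test run

tiny_grid <- function() grid_spec(0, 5, 45, 49, 5, 4)

.fix <- new.env()

# small standard scenario reused across observation/assimilation tests
small_scenario <- function() {
  if (is.null(.fix$sc)) {
    .fix$sc <- build_scenario(grid = tiny_grid(), n_days = 140, n_stations = 4,
                              clustering = 0, noise_sigma = 0.2,
                              missing_prob = 0.05, seed = 3)
  }
  .fix$sc
}

# daily series data frame helper
mk_series <- function(values, valid = rep(TRUE, length(values)),
                      start = as.Date("2000-03-10"), id = "S1",
                      lon = 2, lat = 47) {
  data.frame(station_id = id, lon = lon, lat = lat,
             date = start + seq_along(values) - 1,
             value = values, valid = valid, stringsAsFactors = FALSE)
}
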