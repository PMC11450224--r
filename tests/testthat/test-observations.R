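test_that("model sampling is exact at centers and linear in the field", {
  sc <- small_scenario()
  g <- sc$grid
  conc <- sc$conc_truth
  # uniform field samples to the same value anywhere
  cu <- conc; cu$conc[] <- 3.5
  st <- data.frame(station_id = c("A", "B"), lon = c(1.3, 4.2),
                   lat = c(45.7, 48.1))
  s <- sample_model(cu, st)
  expect_true(all(s$value == 3.5))
  # a station exactly at a cell center returns that cell's series
  stc <- data.frame(station_id = "C", lon = g$lon[2], lat = g$lat[3])
  sc2 <- sample_model(conc, stc)
  expect_equal(sc2$value, conc$conc[2, 3, ])
  # linearity
  ca <- conc; ca$conc <- 2 * conc$conc
  expect_equal(sample_model(ca, stc)$value, 2 * sc2$value)
  expect_error(sample_model(conc, data.frame(station_id = "X", lon = 99,
                                             lat = 46)), "outside")
})

test_that("two-day averaging follows the bin and fallback rules", {
  s <- mk_series(c(1, 3, 5, 7))
  b <- average_2day(s, s$date[1])
  expect_equal(b$value, c(2, 6))
  expect_true(all(b$valid))
  s2 <- mk_series(c(4, 10), valid = c(TRUE, FALSE))
  b2 <- average_2day(s2, s2$date[1])
  expect_equal(b2$value, 4)   # single valid day carries the bin
  expect_equal(b2$n_valid, 1L)
  s3 <- mk_series(c(4, 10), valid = c(FALSE, FALSE))
  b3 <- average_2day(s3, s3$date[1])
  expect_false(b3$valid)
  expect_true(is.na(b3$value))
  # bins are anchored at the window start; a trailing half-bin keeps its day
  s4 <- mk_series(1:6)
  b4 <- average_2day(s4, s4$date[2])
  expect_equal(b4$value, c(2.5, 4.5, 6))  # days 2-3, 4-5, 6 (half bin)
})

test_that("station-year filters reject short, zero-heavy and uncorrelated series", {
  win <- as.Date(c("2000-03-10", "2000-07-01"))
  mdl <- mk_series(seq(1, 80, length.out = 80))
  # 29 valid days: completeness rejection
  obs29 <- mk_series(c(rep(1, 80)), valid = c(rep(TRUE, 29), rep(FALSE, 51)))
  r <- station_year_passes(obs29, mdl, win)
  expect_false(r$accept); expect_equal(r$reason, "completeness")
  # 30 valid days but only 4 non-zero
  v30 <- c(rep(TRUE, 30), rep(FALSE, 50))
  obs4 <- mk_series(c(rep(0, 26), 1, 2, 3, 4, rep(0, 50)), valid = v30)
  r2 <- station_year_passes(obs4, mdl, win)
  expect_false(r2$accept); expect_equal(r2$reason, "non-zero")
  # enough data but anti-correlated with the model
  set.seed(1)
  obs_anti <- mk_series(rev(seq(1, 80, length.out = 80)) + rnorm(80, 0, 1))
  r3 <- station_year_passes(obs_anti, mdl, win)
  expect_false(r3$accept); expect_equal(r3$reason, "correlation")
  expect_lt(r3$correlation, 0.3)
  # a strict tie at the threshold is rejected ("better than 0.3")
  # and a well-correlated series passes
  obs_ok <- mk_series(seq(1, 80, length.out = 80) * 2 + rnorm(80, 0, 2))
  r4 <- station_year_passes(obs_ok, mdl, win)
  expect_true(r4$accept); expect_equal(r4$reason, "ok")
  # empty overlap
  obs_none <- mk_series(rep(1, 80), valid = rep(FALSE, 80))
  r5 <- station_year_passes(obs_none, mdl, win)
  expect_false(r5$accept); expect_equal(r5$reason, "completeness")
})

test_that("filter checks commute: rejection reasons are order-independent facts", {
  win <- as.Date(c("2000-03-10", "2000-07-01"))
  mdl <- mk_series(seq(1, 80, length.out = 80))
  obs <- mk_series(c(rep(0, 27), 1, 2, rep(0, 51)),
                   valid = c(rep(TRUE, 29), rep(FALSE, 51)))
  # fails completeness (29) and non-zero (2) simultaneously; either way: reject
  r <- station_year_passes(obs, mdl, win)
  expect_false(r$accept)
  expect_true(r$n_valid < 30 && r$n_nonzero < 5)
})

test_that("80/20 split honours mandatory stations and the seed", {
  st <- sprintf("S%02d", 1:10)
  sp <- split_assim_eval(st, mandatory = c("S01", "S02"), seed = 4)
  expect_equal(length(sp$assimilation), 8)
  expect_equal(length(sp$evaluation), 2)
  expect_true(all(c("S01", "S02") %in% sp$assimilation))
  expect_identical(split_assim_eval(st, c("S01", "S02"), seed = 4), sp)
  expect_false(identical(split_assim_eval(st, c("S01", "S02"), seed = 5)$evaluation,
                         sp$evaluation))
  # all mandatory: empty evaluation
  spa <- split_assim_eval(st, mandatory = st, seed = 1)
  expect_equal(spa$evaluation, character(0))
  # fewer than 2 non-mandatory stations
  expect_warning(sp1 <- split_assim_eval(c("A", "B"), mandatory = "A", seed = 1),
                 "fewer than 2")
  expect_equal(sort(sp1$assimilation), c("A", "B"))
  # regional coverage re-check keeps every region represented
  regions <- stats::setNames(rep(c("west", "east"), each = 5), st)
  for (s in 1:5) {
    spr <- split_assim_eval(st, character(0), seed = s, regions = regions)
    expect_true(all(c("west", "east") %in% unique(regions[spr$assimilation])))
  }
})

test_that("seasonal pollen integral sums valid days and flags short years", {
  win <- as.Date(c("2000-03-10", "2000-04-30"))
  s <- mk_series(c(10, 20, 30))
  sp <- compute_spin(s, win, min_days = 2)
  expect_equal(sp$value, 60)
  expect_true(sp$usable)
  s0 <- mk_series(rep(0, 40))
  expect_equal(compute_spin(s0, win, min_days = 30)$value, 0)
  s29 <- mk_series(rep(2, 29))
  sp29 <- compute_spin(s29, win, min_days = 30)
  expect_false(sp29$usable)
  expect_equal(sp29$n_valid, 29)
})

test_that("two-day averaging raises model-observation correlation under daily noise", {
  set.seed(42)
  gains <- replicate(300, {
    n <- 60
    sig <- 50 * exp(-((1:n) - 30)^2 / 200) + 5
    obs <- sig * exp(stats::rnorm(n, -0.18, 0.6))
    mdl <- sig * exp(stats::rnorm(n, -0.08, 0.4))
    d1 <- stats::cor(obs, mdl)
    d2 <- stats::cor(colMeans(matrix(obs, 2)), colMeans(matrix(mdl, 2)))
    d2 - d1
  })
  expect_gt(mean(gains), 0)
})
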