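# Ambient-series QC: drift correction, diurnal and window aggregation,
# intercomparison, enhancement ratios, paired ratios, profile filtering.

make_ambient <- function(values, hours, censored = FALSE,
                         cfc11 = 1000, cfc113 = 800, compound = "isoprene") {
  n <- length(values)
  data.frame(timestamp = ts_at_hours(hours), compound = compound,
             value_pptv = values, censored = rep(censored, length.out = n),
             cfc11_area = rep(cfc11, length.out = n),
             cfc113_area = rep(cfc113, length.out = n),
             instrument = "GC-MS", stringsAsFactors = FALSE)
}

test_that("constant reference areas make drift correction the identity", {
  x <- make_ambient(c(10, 20, 30, 40), hours = c(1, 3, 5, 7))
  out <- drift_correct(x)
  expect_equal(out$value_pptv, x$value_pptv)
  expect_equal(out$drift_factor, rep(1, 4))
})

test_that("a halved sensitivity in the second half doubles those analytes", {
  n <- 48
  hrs <- seq(1, by = 6, length.out = n)
  sens <- rep(c(1, 0.5), each = n / 2)
  x <- make_ambient(100 * sens, hours = hrs, cfc11 = 1000 * sens,
                    cfc113 = 800 * sens)
  out <- drift_correct(x, window_hours = 6)
  # second-half factors double relative to first-half factors, so the
  # corrected analyte series (constant truth) is flat again
  expect_equal(out$drift_factor[n] / out$drift_factor[1], 2, tolerance = 1e-12)
  expect_true(all(abs(out$value_pptv - out$value_pptv[1]) < 1e-9))
})

test_that("a planted linear sensitivity decay is removed (slope CI covers zero)", {
  p <- generator_params(seed = 12, noise_cv = 0.1, t_amplitude = 0)
  amb <- gen_ambient_timeseries(n_days = 30, params = p, drift_total = 0.2)
  acn <- amb[amb$compound == "acetonitrile", ] # constant planted truth
  days <- as.numeric(difftime(acn$timestamp, acn$timestamp[1], units = "days"))

  raw_fit <- lm(value_pptv ~ days, data = acn)
  expect_lt(confint(raw_fit)["days", 2], 0) # drift visible before correction

  cor_fit <- lm(value_pptv ~ days, data = drift_correct(acn))
  ci <- confint(cor_fit)["days", ]
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)

  # idempotence up to smoothing: correcting twice changes little
  once <- drift_correct(acn)
  twice <- drift_correct(once)
  expect_equal(twice$value_pptv, once$value_pptv, tolerance = 0.05)
})

test_that("non-positive reference areas leave samples flagged and uncorrected", {
  x <- make_ambient(c(10, 20, 30), hours = c(1, 3, 5))
  x$cfc11_area[2] <- 0
  out <- drift_correct(x)
  expect_true(out$drift_uncorrected[2])
  expect_equal(out$value_pptv[2], 20)
})

test_that("diurnal cycle conserves the overall mean and finds planted peaks", {
  hrs <- rep(seq(0.5, 23.5, by = 1), times = 10)
  x <- make_ambient(10 + 5 * cos(2 * pi * (hrs - 14) / 24) +
                      rnorm(length(hrs), 0, 0.1), hours = hrs)
  cyc <- diurnal_cycle(x)
  expect_equal(cyc$hour, 0:23)
  expect_equal(sum(cyc$n * cyc$mean) / sum(cyc$n), mean(x$value_pptv),
               tolerance = 1e-12)
  expect_equal(cyc$hour[which.max(cyc$mean)], 14)
  # constant series: flat cycle
  flat <- diurnal_cycle(make_ambient(rep(7, 24), hours = 0:23 + 0.25))
  expect_true(all(flat$mean == 7))
})

test_that("window means follow the Table-3 windows with midnight wrap", {
  x <- make_ambient(c(1, 2, 3), hours = c(23.5, 4.5, 22.5))
  w <- window_means(x, value_col = "value_pptv")
  night <- w[w$window == "nighttime", ]
  expect_equal(night$n, 2L) # 23:30 and 04:30 in, 22:30 out
  expect_equal(night$mean, 1.5)
  day <- w[w$window == "daytime", ]
  expect_equal(day$n, 0L)
  expect_true(is.na(day$mean))

  # all data at noon: daytime and midday populated, nighttime missing
  noon <- window_means(make_ambient(c(5, 7), hours = c(12, 12.5)),
                       value_col = "value_pptv")
  expect_equal(noon$n[noon$window %in% c("daytime", "midday")], c(2L, 2L))
  expect_equal(noon$n[noon$window == "nighttime"], 0L)
})

test_that("window means agree with count-weighted diurnal means and grouping works", {
  sc <- enclosure_scenario(n_enclosures = 4, duration_days = 5,
                           params = generator_params(seed = 77))
  er <- emission_rates(gen_enclosure_timeseries(sc))
  w <- window_means(er, value_col = "value", by = "vegetation_class")
  cyc <- diurnal_cycle(er, value_col = "value")
  day_hours <- cyc$hour >= 10 & cyc$hour < 20
  expect_equal(w$mean[w$window == "daytime"],
               sum(cyc$n[day_hours] * cyc$mean[day_hours]) /
                 sum(cyc$n[day_hours]),
               tolerance = 1e-12)
  # planted diurnal temperature dependence orders the windows
  expect_gt(w$mean[w$window == "midday"], w$mean[w$window == "daytime"])
  expect_gt(w$mean[w$window == "daytime"], w$mean[w$window == "nighttime"])
  expect_gt(w$mean_temp[w$window == "midday"],
            w$mean_temp[w$window == "nighttime"])
})

test_that("intercomparison recovers planted proportionality", {
  hrs <- seq(0, 500, by = 1)
  a <- make_ambient(50 + 10 * sin(hrs / 10), hours = hrs)
  expect_equal(intercompare(a, a)$slope, 1, tolerance = 1e-12)
  expect_equal(intercompare(a, a)$r, 1, tolerance = 1e-12)

  b <- a
  b$value_pptv <- 0.85 * a$value_pptv
  ic <- intercompare(a, b)
  expect_equal(ic$slope, 0.85, tolerance = 1e-12)
  expect_equal(ic$r, 1, tolerance = 1e-12)

  # proportionality 0.85 with independent 20% noise on both instruments
  set.seed(500)
  n <- 500
  hrs <- seq(0, by = 2, length.out = n)
  truth <- rlnorm(n, log(50), 0.6)
  a2 <- make_ambient(truth * rlnorm(n, 0, 0.2), hours = hrs)
  b2 <- make_ambient(0.85 * truth * rlnorm(n, 0, 0.2), hours = hrs + 0.1)
  ic2 <- intercompare(a2, b2)
  expect_gt(ic2$slope, 0.7)
  expect_lt(ic2$slope, 1.0)
  expect_gt(ic2$r, 0.8) # 20% noise on both sides attenuates correlation
  expect_equal(ic2$n_pairs, n)
  # pairing respects the tolerance
  far <- b2
  far$timestamp <- far$timestamp + 3600
  expect_error(intercompare(a2[1:5, ], far[1:5, ], tolerance_min = 15),
               "paired")
})

test_that("enhancement ratios divide event means by background means", {
  hrs <- seq(0, 47, by = 1)
  v <- rep(24, 48)
  v[hrs >= 24 & hrs < 30] <- 505
  x <- make_ambient(v, hours = hrs)
  ev <- ts_at_hours(c(24, 30))
  bg <- ts_at_hours(c(0, 24))
  expect_equal(enhancement_ratio(x, ev, bg), 505 / 24, tolerance = 1e-12)
  expect_equal(enhancement_ratio(x, bg, ts_at_hours(c(30, 48))), 1)
  expect_error(enhancement_ratio(x, ts_at_hours(c(0, 30)), bg), "overlap")

  # planted x4 acetonitrile event in fully synthetic data
  p <- generator_params(seed = 21, noise_cv = 0.1, t_amplitude = 0)
  amb <- gen_ambient_timeseries(n_days = 30, params = p, drift_total = 0,
                                event = list(start_day = 14, end_day = 16))
  acn <- amb[amb$compound == "acetonitrile", ]
  t0 <- as.POSIXct("2019-06-01", tz = ast_timezone())
  r <- enhancement_ratio(acn, t0 + c(14, 16) * 86400, t0 + c(0, 14) * 86400)
  expect_lt(abs(r - 4), 0.4)
})

test_that("paired ratio means require both members above threshold", {
  x <- c(10, 20, 1, 30)
  expect_equal(ratio_mean(x, x)$ratio_mean, 1)
  expect_equal(ratio_mean(2.7 * x, x)$ratio_mean, 2.7, tolerance = 1e-12)
  r <- ratio_mean(c(10, 1, 20), c(5, 10, 2), threshold = 2)
  expect_equal(r$n_pairs, 2L)
  expect_error(ratio_mean(c(1, 1), c(1, 1), threshold = 2), "qualifying")

  # planted MVK = 2.7 MACR with noise: mean ratio near 2.7 (lognormal
  # ratio bias is positive and small at this CV)
  amb <- gen_ambient_timeseries(n_days = 60,
                                params = generator_params(seed = 6,
                                                          noise_cv = 0.15),
                                drift_total = 0)
  mvk <- amb$value_pptv[amb$compound == "methyl-vinyl-ketone"]
  macr <- amb$value_pptv[amb$compound == "methacrolein"]
  rr <- ratio_mean(mvk, macr)
  expect_lt(abs(rr$ratio_mean - 2.7), 0.15)
})

test_that("profile filtering drops only sub-blank samples and keeps structure", {
  pr <- data.frame(flight_id = "f1", nominal_altitude = c(0, 30, 100),
                   mixing_ratio = c(10, 15, 15), blank_value = 15)
  out <- profile_filter(pr, quiet = TRUE)
  expect_equal(nrow(out), 2L) # 10 < blank dropped; equal-to-blank retained
  expect_equal(attr(out, "n_removed"), 1L)

  noiseless <- gen_profile_samples(n_flights = 4, noise_cv = 0,
                                   blank_mean = 1, seed = 3)
  kept <- profile_filter(noiseless, quiet = TRUE)
  for (f in unique(kept$flight_id)) {
    v <- kept$mixing_ratio[kept$flight_id == f]
    expect_true(all(diff(v) < 0)) # surface maximum preserved
  }
})
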