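# Synthetic-data generator: planted truth, determinism, structure.

test_that("planted emission truth has the stated closed form", {
  p <- generator_params()
  expect_equal(true_emission(20, 1000, p), p$e20)
  expect_equal(true_emission(23, 1000, p), oracle$warming_3c_percent / 100 * p$e20,
               tolerance = 1e-12)
  # full darkness with light dependence on: zero emission
  expect_equal(true_emission(25, 0, p, light_dependence = TRUE), 0)
  expect_gt(true_emission(25, 0, p, light_dependence = FALSE), 0)
})

test_that("generated enclosure records obey the noiseless mass balance", {
  sc <- enclosure_scenario(n_enclosures = 10, duration_days = 5,
                           params = generator_params(noise_cv = 0, seed = 9))
  rec <- gen_enclosure_timeseries(sc)
  expect_equal(nrow(rec), 10 * 60)
  expect_true(all(rec$c_out >= rec$c_in))
  er_back <- (rec$c_out - rec$c_in) * rec$q / rec$s
  expect_equal(er_back, rec$er_true, tolerance = 1e-10)
})

test_that("a fixed seed reproduces the series exactly", {
  sc <- enclosure_scenario(params = generator_params(seed = 42))
  expect_identical(gen_enclosure_timeseries(sc), gen_enclosure_timeseries(sc))
  amb <- gen_ambient_timeseries(n_days = 5,
                                params = generator_params(seed = 42))
  amb2 <- gen_ambient_timeseries(n_days = 5,
                                 params = generator_params(seed = 42))
  expect_identical(amb, amb2)
  expect_false(identical(
    gen_enclosure_timeseries(sc),
    gen_enclosure_timeseries(enclosure_scenario(
      params = generator_params(seed = 43)))))
})

test_that("diurnal models peak at 14:00 with a nocturnal midnight-sun PAR floor", {
  p <- generator_params()
  h <- seq(0, 23.5, by = 0.5)
  temp <- diurnal_temperature(h, p)
  par <- diurnal_par(h, p)
  expect_equal(h[which.max(temp)], 14)
  expect_equal(max(temp), p$t_mean + p$t_amplitude)
  expect_true(all(par >= p$par_floor_frac * p$par_max))
  expect_equal(max(par), p$par_max)
})

test_that("ambient generator plants drift, event factors and censoring", {
  ev <- list(start_day = 10, end_day = 12)
  amb <- gen_ambient_timeseries(n_days = 30,
                                params = generator_params(seed = 5,
                                                          noise_cv = 0.1),
                                drift_total = 0.2, event = ev)
  truth <- attr(amb, "truth")
  expect_equal(truth$factor_isoprene, 21)
  expect_equal(truth$factor_acetonitrile, 4)
  expect_equal(range(truth$drift), c(0.8, 1))
  expect_setequal(unique(amb$compound),
                  c("isoprene", "acetonitrile", "methacrolein",
                    "methyl-vinyl-ketone"))
  expect_true(all(amb$censored == (amb$value_pptv < truth$loq)))
  # timestamps strictly increasing within a compound
  iso <- amb[amb$compound == "isoprene", ]
  expect_true(all(diff(as.numeric(iso$timestamp)) > 0))
})

test_that("censoring frequency matches the planted lognormal rate", {
  # flat, noisy background near the LOQ: P(value < loq) is analytic
  p <- generator_params(seed = 8, noise_cv = 0.5, t_amplitude = 0,
                        c_in_background = 3)
  amb <- gen_ambient_timeseries(n_days = 120, params = p, drift_total = 0,
                                loq = 2)
  iso <- amb[amb$compound == "isoprene", ]
  # log(value) = log(bg) + 0.1 * N(0, 1.5^2) [temperature term]
  #            + N(-s2/2, s2)               [measurement noise]
  s2 <- log(1 + p$noise_cv^2)
  p_cens <- pnorm(log(2 / 3), mean = -s2 / 2,
                  sd = sqrt(s2 + (0.1 * 1.5)^2))
  n <- nrow(iso)
  expect_lt(abs(mean(iso$censored) - p_cens),
            3 * sqrt(p_cens * (1 - p_cens) / n) + 0.01)
})

test_that("profile generator produces a surface-maximum decay with blanks", {
  pr <- gen_profile_samples(n_flights = 8, noise_cv = 0, seed = 2)
  expect_equal(nrow(pr), 40)
  for (f in unique(pr$flight_id)) {
    v <- pr$mixing_ratio[pr$flight_id == f]
    expect_true(all(diff(v) < 0)) # noiseless: monotone decrease with altitude
  }
  expect_true(all(pr$blank_value > 0))
})
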