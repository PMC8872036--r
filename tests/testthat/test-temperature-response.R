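# Enclosure-wise normalization, temperature binning, exponential fit,
# warming percentages, and the MEGAN comparison table.

test_that("normalization sets each enclosure's reference-bin mean to one", {
  rec <- make_exact_enclosure(e20 = c(50, 120, 7))
  er <- emission_rates(rec)
  nn <- normalize_by_reference(er)
  for (e in unique(nn$enclosure_id)) {
    i <- nn$enclosure_id == e & nn$t_enclosure >= 19 & nn$t_enclosure < 21
    expect_equal(mean(nn$value_norm[i]), 1, tolerance = 1e-12)
  }
  # constant-emission enclosure: all normalized values are 1
  const <- er
  const$value <- 50
  nc <- normalize_by_reference(const)
  expect_true(all(nc$value_norm == 1))
  # simple division: reference mean 50, record 100 -> 2
  expect_equal((100 / 50), 2)
  expect_equal(nn$value_norm[nn$enclosure_id == "enc01"],
               exp(0.1935 * (rec$t_enclosure[1:6] - 20)), tolerance = 1e-12)
})

test_that("normalization is idempotent and drops uncovered enclosures with a warning", {
  rec <- make_exact_enclosure(e20 = c(50, 120))
  er <- emission_rates(rec)
  nn <- normalize_by_reference(er)
  renn <- nn
  renn$value <- renn$value_norm
  renn2 <- normalize_by_reference(renn)
  expect_equal(renn2$value_norm, nn$value_norm, tolerance = 1e-12)

  # an enclosure with no record near 20 degC cannot be normalized
  cold <- er[er$enclosure_id == "enc01" & er$t_enclosure < 18, ]
  cold$enclosure_id <- "enc99"
  expect_warning(nn3 <- normalize_by_reference(rbind(er, cold)), "enc99")
  expect_false("enc99" %in% nn3$enclosure_id)
  expect_equal(attr(nn3, "dropped_enclosures"), "enc99")
})

test_that("temperature bins are half-open and centered on multiples of the width", {
  d <- data.frame(t_enclosure = c(20.0, 18.9, 19.1), value_norm = 1)
  b <- bin_by_temperature(d, bin_width = 2)
  expect_equal(b$bin_center, c(18, 20))
  expect_equal(b$n, c(1L, 2L))
  # 18.9 and 19.1 land in different bins under [center-1, center+1)
  expect_equal(bin_by_temperature(d[2:3, ], 2)$n, c(1L, 1L))
  # uniform coverage gives near-equal interior bin counts
  set.seed(20)
  u <- data.frame(t_enclosure = runif(6000, 2, 32), value_norm = 1)
  bu <- bin_by_temperature(u, 2)
  interior <- bu[bu$bin_center > 3 & bu$bin_center < 31, ]
  expect_true(all(abs(interior$n - 400) < 5 * sqrt(400)))
  expect_equal(sum(bu$n), 6000L)
})

test_that("noiseless exponential truth is recovered exactly", {
  rec <- make_exact_enclosure(a = 0.1935, e20 = c(50, 120),
                              temps = c(2, 8, 14, 20, 26, 32))
  nn <- normalize_by_reference(emission_rates(rec))
  fit <- fit_temperature_response(nn)
  expect_equal(fit$a_hat, 0.1935, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(sum(fit$bins$n), fit$n)
  expect_true(fit$ci95[["lower"]] <= fit$a_hat &&
              fit$a_hat <= fit$ci95[["upper"]])

  # flat data: zero temperature coefficient
  flat <- nn
  flat$value_norm <- 1
  expect_equal(fit_temperature_response(flat)$a_hat, 0, tolerance = 1e-12)
})

test_that("noisy recovery lands near the planted coefficient", {
  sc <- enclosure_scenario(n_enclosures = 10, temperature_model = "uniform",
                           params = generator_params(noise_cv = 0.15,
                                                     seed = 31))
  fit <- fit_temperature_response(
    normalize_by_reference(emission_rates(gen_enclosure_timeseries(sc))))
  expect_lt(abs(fit$a_hat - oracle$a_true_default), 0.02)
  expect_equal(fit$n, 600)
})

test_that("the fit refuses insufficient data and counts non-positive exclusions", {
  rec <- make_exact_enclosure()
  nn <- normalize_by_reference(emission_rates(rec))
  expect_error(fit_temperature_response(nn[1:4, ]), "insufficient")
  nn$value_norm[1] <- -0.5
  fit <- fit_temperature_response(nn, min_records = 5)
  expect_equal(fit$n_excluded_nonpositive, 1)
})

test_that("warming percentages compose multiplicatively and match the closed form", {
  fit <- list(a_hat = 0.1935)
  class(fit) <- "bvoc_tresp"
  expect_equal(warming_percent(fit, 0), 100)
  expect_equal(warming_percent(fit, 3), oracle$warming_3c_percent,
               tolerance = 1e-12)
  expect_equal(warming_percent(fit, 4), oracle$warming_4c_percent,
               tolerance = 1e-12)
  # exponential semigroup: w(d1 + d2) = w(d1) w(d2) / 100
  for (d in list(c(1, 2), c(0.5, 3.1), c(2, 2))) {
    expect_equal(warming_percent(fit, sum(d)),
                 warming_percent(fit, d[1]) * warming_percent(fit, d[2]) / 100,
                 tolerance = 1e-12)
  }
})

test_that("the MEGAN comparison table shares the reference normalization", {
  rec <- make_exact_enclosure(temps = c(5, 10, 15, 20, 25, 30))
  fit <- fit_temperature_response(
    normalize_by_reference(emission_rates(rec)))
  cmp <- compare_to_megan(fit, t10_k = 287, grid_c = seq(0, 40, by = 1))
  at20 <- cmp[cmp$t_c == 20, ]
  expect_equal(at20$observed_fit_norm, 1)
  expect_equal(at20$megan_gamma_norm, 1)
  # the MEGAN column peaks at T_opt
  t_opt_c <- megan_t_opt(287) - 273.15
  expect_equal(cmp$t_c[which.max(cmp$megan_gamma_norm)],
               round(t_opt_c))
  # both curves increase monotonically over 0-30 degC at this t10
  sub <- cmp[cmp$t_c <= 30, ]
  expect_true(all(diff(sub$observed_fit_norm) > 0))
  expect_true(all(diff(sub$megan_gamma_norm) > 0))
})

test_that("fit methods expose coefficients, intervals and predictions", {
  rec <- make_exact_enclosure(temps = c(5, 10, 15, 20, 25, 30))
  fit <- fit_temperature_response(normalize_by_reference(emission_rates(rec)))
  expect_named(coef(fit), c("intercept", "a"))
  ci <- confint(fit)
  expect_lt(ci[["lower"]], fit$a_hat)
  expect_gt(ci[["upper"]], fit$a_hat)
  expect_equal(predict(fit, 20), 1, tolerance = 1e-10)
  expect_equal(predict(fit, c(23, 24)),
               exp(fit$intercept + fit$a_hat * c(3, 4)), tolerance = 1e-12)
  expect_length(residuals(fit), fit$n)
  expect_output(print(fit), "a = ")
  expect_output(summary(fit), "Per-bin")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, megan_t10_k = 287))
})
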