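# Emission-temperature response analysis.
#
# Daytime emission rates from different enclosures are made comparable by
# dividing each enclosure's records by that enclosure's mean emission in a
# reference temperature bin (20 +/- 1 degC by default -- a reference suited
# to cold growth environments where 30 degC is rarely reached). The pooled
# normalized emissions are then fit with an exponential temperature
# response, ln(E_norm) = b + a (T - T_ref), and the fitted coefficient a
# converts directly into warming-scenario emission ratios 100 * exp(a * dT).

#' Normalize emission rates by an enclosure-specific reference bin
#'
#' Divides every record's emission value by its enclosure's mean daytime
#' emission at the reference temperature (within `reference_temp +/-
#' reference_halfwidth`, half-open on the right). This removes differences
#' in total biomass and species composition between enclosures, putting all
#' enclosures on a common dimensionless scale where the reference-bin mean
#' is exactly 1. Enclosures with no positive daytime record in the
#' reference bin cannot be normalized and are dropped with a warning.
#'
#' @param rates Emission-rate data.frame (see [emission_rates()]) with
#'   `value`, `t_enclosure`, `enclosure_id` columns and either a
#'   `timestamp` column (for the daytime filter) or a logical
#'   `daytime_flag`.
#' @param reference_temp Reference temperature, degC (default 20).
#' @param reference_halfwidth Bin half-width, degC (default 1).
#' @param daytime_window Local-time window treated as daytime, hours
#'   (default 10-20, half-open).
#' @return data.frame with columns `enclosure_id`, `t_enclosure`,
#'   `value_norm`, `daytime_flag` plus carried-through columns; dropped
#'   enclosures are listed in attribute `"dropped_enclosures"`.
#' @export
normalize_by_reference <- function(rates, reference_temp = 20,
                                   reference_halfwidth = 1,
                                   daytime_window = c(10, 20)) {
  stopifnot(is.data.frame(rates),
            all(c("value", "t_enclosure", "enclosure_id") %in% names(rates)))
  if (is.null(rates$daytime_flag)) {
    if (is.null(rates$timestamp)) {
      stop("need a timestamp or daytime_flag column", call. = FALSE)
    }
    rates$daytime_flag <- in_window(hour_of_day(rates$timestamp),
                                    daytime_window[1], daytime_window[2])
  }
  lo <- reference_temp - reference_halfwidth
  hi <- reference_temp + reference_halfwidth
  in_ref <- rates$t_enclosure >= lo & rates$t_enclosure < hi

  ref_means <- vapply(split(seq_len(nrow(rates)), rates$enclosure_id),
                      function(i) {
    j <- i[in_ref[i] & rates$daytime_flag[i] & rates$value[i] > 0]
    if (length(j) == 0) NA_real_ else mean(rates$value[j])
  }, numeric(1))

  bad <- names(ref_means)[is.na(ref_means) | ref_means <= 0]
  if (length(bad) > 0) {
    warning("dropping enclosure(s) without positive daytime reference-bin ",
            sprintf("coverage at %g +/- %g degC: ", reference_temp,
                    reference_halfwidth),
            paste(bad, collapse = ", "), call. = FALSE)
  }
  keep <- !(rates$enclosure_id %in% bad)
  out <- rates[keep, , drop = FALSE]
  out$value_norm <- out$value / ref_means[match(out$enclosure_id,
                                                names(ref_means))]
  rownames(out) <- NULL
  attr(out, "dropped_enclosures") <- bad
  attr(out, "reference_temp") <- reference_temp
  attr(out, "reference_halfwidth") <- reference_halfwidth
  out
}

#' Bin normalized emissions by temperature
#'
#' Bins centered on multiples of `bin_width` with half-open intervals
#' `[center - w/2, center + w/2)`, covering the observed temperature range.
#'
#' @param normalized Output of [normalize_by_reference()] (or any data.frame
#'   with `t_enclosure` and the value column).
#' @param bin_width Bin width, degC (> 0). Default 2 (the 20 +/- 1 degC
#'   reference bin is then one of the bins).
#' @param value_col Column to summarize (default `"value_norm"`).
#' @return data.frame with `bin_center`, `bin_lo`, `bin_hi`, `mean`, `sd`,
#'   `n` per nonempty bin.
#' @export
bin_by_temperature <- function(normalized, bin_width = 2,
                               value_col = "value_norm") {
  stopifnot(bin_width > 0, is.data.frame(normalized))
  if (nrow(normalized) == 0) {
    return(data.frame(bin_center = numeric(), bin_lo = numeric(),
                      bin_hi = numeric(), mean = numeric(), sd = numeric(),
                      n = integer()))
  }
  t <- normalized$t_enclosure
  v <- normalized[[value_col]]
  center <- bin_width * floor(t / bin_width + 0.5)
  agg <- lapply(split(v, center), function(x) {
    c(mean = mean(x), sd = stats::sd(x), n = length(x))
  })
  centers <- as.numeric(names(agg))
  o <- order(centers)
  data.frame(
    bin_center = centers[o],
    bin_lo = centers[o] - bin_width / 2,
    bin_hi = centers[o] + bin_width / 2,
    mean = vapply(agg, `[[`, numeric(1), "mean")[o],
    sd = vapply(agg, `[[`, numeric(1), "sd")[o],
    n = as.integer(vapply(agg, `[[`, numeric(1), "n")[o]),
    row.names = NULL
  )
}

#' Fit an exponential emission-temperature response
#'
#' Least-squares fit of `ln(value_norm)` on `(T - reference_temp)` over the
#' (by default daytime-only) normalized records. Non-positive normalized
#' values cannot enter the log fit; they are excluded and counted. The
#' intercept is retained as a diagnostic -- enclosure-wise normalization
#' makes it approximately zero. The fit is performed on the raw normalized
#' records, not on binned means; the temperature binning is reported for
#' display counts only.
#'
#' @param normalized Output of [normalize_by_reference()].
#' @param daytime_only Restrict the fit to daytime records (default TRUE).
#' @param bin_width Bin width for the reported per-bin counts, degC.
#' @param reference_temp Reference temperature of the normalization, degC.
#' @param min_records Minimum number of usable records (default 10).
#' @return Object of class `bvoc_tresp`: list with `a_hat` (degC^-1),
#'   `ci95`, `intercept`, `r_squared`, `n`, `n_excluded_nonpositive`,
#'   `bins` (binned means and counts), `bin_width`, `reference_temp`, and
#'   the underlying `lm` fit as `model`.
#' @seealso [warming_percent()], [compare_to_megan()], and the
#'   `print`/`summary`/`coef`/`confint`/`predict`/`plot` methods.
#' @export
fit_temperature_response <- function(normalized, daytime_only = TRUE,
                                     bin_width = 2, reference_temp = 20,
                                     min_records = 10) {
  stopifnot(is.data.frame(normalized), "value_norm" %in% names(normalized))
  d <- normalized
  if (daytime_only && !is.null(d$daytime_flag)) d <- d[d$daytime_flag, ]
  if (!is.null(d$qc_flags)) d <- d[!has_flag(d$qc_flags, "deposition_or_noise"), ]
  pos <- d$value_norm > 0
  n_excl <- sum(!pos)
  d <- d[pos, , drop = FALSE]
  if (nrow(d) < min_records) {
    stop("insufficient data for exponential fit: ", nrow(d),
         " usable records (need >= ", min_records, ")", call. = FALSE)
  }
  dt <- d$t_enclosure - reference_temp
  model <- stats::lm(log(value_norm) ~ dt, data = cbind(d, dt = dt))
  # noiseless data triggers lm's "essentially perfect fit" warning; the
  # exact-recovery case is legitimate here
  ci <- suppressWarnings(stats::confint(model, "dt", level = 0.95))
  fit <- list(
    a_hat = unname(stats::coef(model)[["dt"]]),
    ci95 = c(lower = ci[1], upper = ci[2]),
    intercept = unname(stats::coef(model)[["(Intercept)"]]),
    r_squared = suppressWarnings(summary(model)$r.squared),
    n = nrow(d),
    n_excluded_nonpositive = n_excl,
    bins = bin_by_temperature(d, bin_width),
    bin_width = bin_width,
    reference_temp = reference_temp,
    model = model
  )
  class(fit) <- "bvoc_tresp"
  fit
}

#' @export
print.bvoc_tresp <- function(x, digits = 4, ...) {
  cat("Exponential emission-temperature response\n")
  cat(sprintf("  ln(E_norm) = %s + a (T - %g degC)\n",
              format(x$intercept, digits = digits), x$reference_temp))
  cat(sprintf("  a = %s degC^-1  (95%% CI %s to %s), r^2 = %s, n = %d\n",
              format(x$a_hat, digits = digits),
              format(x$ci95[["lower"]], digits = digits),
              format(x$ci95[["upper"]], digits = digits),
              format(x$r_squared, digits = digits), x$n))
  cat(sprintf("  emission at +3 degC: %.1f%% of baseline; at +4 degC: %.1f%%\n",
              warming_percent(x, 3), warming_percent(x, 4)))
  if (x$n_excluded_nonpositive > 0) {
    cat(sprintf("  (%d non-positive normalized records excluded from the log fit)\n",
                x$n_excluded_nonpositive))
  }
  invisible(x)
}

#' @export
summary.bvoc_tresp <- function(object, ...) {
  print(object)
  cat("\nPer-bin record counts:\n")
  print(object$bins, row.names = FALSE)
  invisible(object)
}

#' @export
coef.bvoc_tresp <- function(object, ...) {
  c(intercept = object$intercept, a = object$a_hat)
}

#' @export
confint.bvoc_tresp <- function(object, parm = "a", level = 0.95, ...) {
  ci <- suppressWarnings(stats::confint(object$model, "dt", level = level))
  c(lower = ci[1], upper = ci[2])
}

#' Predicted normalized emission at new temperatures
#'
#' @param object A `bvoc_tresp` fit.
#' @param newdata Numeric temperatures (degC) or a data.frame with a
#'   `t_enclosure` column. Default: the fitted temperatures.
#' @param ... Unused.
#' @return Predicted normalized emissions, `exp(b + a (T - T_ref))`.
#' @export
predict.bvoc_tresp <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(exp(stats::fitted(object$model)))
  t_c <- if (is.data.frame(newdata)) newdata$t_enclosure else newdata
  exp(object$intercept + object$a_hat * (t_c - object$reference_temp))
}

#' @export
residuals.bvoc_tresp <- function(object, ...) {
  stats::residuals(object$model)
}

#' Plot a temperature-response fit
#'
#' Binned mean normalized emissions with the exponential fit curve, and
#' optionally the MEGAN temperature activity curve normalized to the same
#' reference, on base graphics.
#'
#' @param x A `bvoc_tresp` fit.
#' @param megan_t10_k If non-`NULL`, overlay the MEGAN gamma_T curve for
#'   this 10-day mean temperature (K).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bvoc_tresp <- function(x, megan_t10_k = NULL, ...) {
  b <- x$bins
  grid <- seq(min(b$bin_lo), max(b$bin_hi), length.out = 200)
  graphics::plot(b$bin_center, b$mean, pch = 16,
                 xlab = "Enclosure temperature (degC)",
                 ylab = sprintf("Normalized emission (1 at %g degC)",
                                x$reference_temp), ...)
  graphics::lines(grid, predict(x, grid), col = "blue", lwd = 2)
  if (!is.null(megan_t10_k)) {
    g <- megan_gamma_t(grid + 273.15, megan_t10_k)
    g_ref <- megan_gamma_t(x$reference_temp + 273.15, megan_t10_k)
    graphics::lines(grid, g / g_ref, col = "darkgreen", lwd = 2, lty = 2)
    graphics::legend("topleft", legend = c("exponential fit", "MEGAN2.1"),
                     col = c("blue", "darkgreen"), lty = c(1, 2), lwd = 2,
                     bty = "n")
  }
  invisible(x)
}

#' Warming-scenario emission percentage
#'
#' Emission after a `delta` degC warming as a percentage of baseline,
#' `100 * exp(a * delta)`. For an exponential response this is independent
#' of the baseline temperature, and composes multiplicatively:
#' `warming_percent(f, d1 + d2) = warming_percent(f, d1) *
#' warming_percent(f, d2) / 100`.
#'
#' @param fit A `bvoc_tresp` fit, or a numeric exponential coefficient
#'   (degC^-1).
#' @param delta Warming, degC (>= 0).
#' @return Percent of baseline emission.
#' @export
warming_percent <- function(fit, delta) {
  stopifnot(all(delta >= 0))
  a <- if (inherits(fit, "bvoc_tresp")) fit$a_hat else fit
  100 * exp(a * delta)
}

#' Compare a fitted response with the MEGAN temperature curve
#'
#' Tabulates the fitted exponential response and the MEGAN gamma_T curve
#' over a temperature grid, both normalized to 1 at the fit's reference
#' temperature, for plotting or side-by-side inspection.
#'
#' @param fit A `bvoc_tresp` fit.
#' @param t10_k 10-day mean temperature for the MEGAN curve, K.
#' @param grid_c Temperature grid, degC.
#' @return data.frame with `t_c`, `observed_fit_norm`, `megan_gamma_norm`.
#' @export
compare_to_megan <- function(fit, t10_k = 287, grid_c = seq(0, 40, by = 1)) {
  stopifnot(inherits(fit, "bvoc_tresp"))
  obs <- exp(fit$a_hat * (grid_c - fit$reference_temp))
  g <- megan_gamma_t(grid_c + 273.15, t10_k)
  g_ref <- megan_gamma_t(fit$reference_temp + 273.15, t10_k)
  data.frame(t_c = grid_c, observed_fit_norm = obs,
             megan_gamma_norm = g / g_ref)
}
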