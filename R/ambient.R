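# Ambient time-series QC and aggregation: internal-reference drift
# correction, diurnal cycles, local-time window means, instrument
# intercomparison, event enhancement ratios, oxidation-product ratios,
# and vertical-profile blank filtering.

# LOQ/2 substitution for censored entries (the reporting convention used
# by all aggregations here).
substitute_censored <- function(values, censored = NULL, loq = 2) {
  if (is.null(censored)) return(values)
  ifelse(censored, loq / 2, values)
}

#' Internal-reference (CFC) drift correction
#'
#' Long-lived chlorofluorocarbons (CFC-11, CFC-113) are ubiquitous and
#' nearly constant in ambient air, so trends in their detector peak areas
#' track instrument sensitivity drift rather than the atmosphere. Each
#' analyte response is multiplied by (campaign reference area)/(smoothed
#' sample area), where the reference is the campaign median and the sample
#' area is the geometric mean of the two CFC channels (neither is given
#' precedence), smoothed with a running median over a configurable time
#' window. The CFC areas themselves are rescaled by the same factor, so
#' applying the correction twice is the identity up to smoothing.
#'
#' @param samples Ambient data.frame with `timestamp`, `value_pptv`,
#'   `cfc11_area`, `cfc113_area` columns (long format over compounds is
#'   fine; areas are per-sample).
#' @param window_hours Running-median smoothing window, hours (default 24).
#' @return `samples` with `value_pptv` and the CFC areas corrected, the
#'   original values in `value_pptv_raw`, and the applied factor in
#'   `drift_factor`. Samples with non-positive CFC areas are flagged in a
#'   logical `drift_uncorrected` column and left unchanged.
#' @export
drift_correct <- function(samples, window_hours = 24) {
  stopifnot(is.data.frame(samples),
            all(c("timestamp", "value_pptv", "cfc11_area", "cfc113_area")
                %in% names(samples)))
  bad <- !(samples$cfc11_area > 0 & samples$cfc113_area > 0)
  bad[is.na(bad)] <- TRUE

  ut <- sort(unique(samples$timestamp[!bad]))
  i <- match(ut, samples$timestamp)
  g <- sqrt((samples$cfc11_area[i] / stats::median(samples$cfc11_area[i])) *
            (samples$cfc113_area[i] / stats::median(samples$cfc113_area[i])))
  half <- window_hours * 3600 / 2
  tnum <- as.numeric(ut)
  g_smooth <- vapply(tnum, function(t0) {
    stats::median(g[tnum >= t0 - half & tnum <= t0 + half])
  }, numeric(1))
  factor <- 1 / g_smooth

  f <- factor[match(samples$timestamp, ut)]
  f[bad] <- 1
  out <- samples
  out$value_pptv_raw <- samples$value_pptv
  out$value_pptv <- samples$value_pptv * f
  out$cfc11_area <- samples$cfc11_area * f
  out$cfc113_area <- samples$cfc113_area * f
  out$drift_factor <- f
  out$drift_uncorrected <- bad
  out
}

#' Mean diurnal cycle
#'
#' Hour-of-day means, standard deviations and counts in the series' local
#' time zone. The count-weighted mean over hours equals the overall mean
#' exactly.
#'
#' @param x data.frame with a `timestamp` column.
#' @param value_col Value column name (default `"value_pptv"`).
#' @param loq LOQ (pptv) for LOQ/2 substitution where a logical `censored`
#'   column is present.
#' @return data.frame with `hour` (0-23), `mean`, `sd`, `n`.
#' @export
diurnal_cycle <- function(x, value_col = "value_pptv", loq = 2) {
  stopifnot(is.data.frame(x), "timestamp" %in% names(x),
            value_col %in% names(x))
  v <- substitute_censored(x[[value_col]], x$censored, loq)
  hr <- floor(hour_of_day(x$timestamp))
  out <- do.call(rbind, lapply(split(v, hr), function(vv) {
    data.frame(mean = mean(vv), sd = stats::sd(vv), n = length(vv))
  }))
  out <- cbind(hour = as.integer(rownames(out)), out)
  rownames(out) <- NULL
  out[order(out$hour), ]
}

#' Default local-time aggregation windows
#'
#' Daytime 10:00-20:00, midday 11:00-14:00, nighttime 23:00-05:00 (all
#' half-open, local AST; nighttime wraps midnight).
#'
#' @return Named list of `c(start_hour, end_hour)` windows.
#' @export
default_windows <- function() {
  list(daytime = c(10, 20), midday = c(11, 14), nighttime = c(23, 5))
}

#' Local-time window means
#'
#' Per-window mean, standard deviation and count of a value column,
#' optionally grouped (e.g. by vegetation class and compound), with the
#' mean enclosure temperature over the same records when a temperature
#' column is present. Windows are half-open `[start, end)` local-time hour
#' intervals; a window whose end precedes its start wraps midnight.
#'
#' @param x data.frame with a `timestamp` column.
#' @param value_col Value column name (default `"value"`).
#' @param windows Named list of hour windows; see [default_windows()].
#' @param by Character vector of grouping columns (optional).
#' @param temp_col Temperature column to average alongside (default
#'   `"t_enclosure"` when present).
#' @param loq LOQ for LOQ/2 substitution where a `censored` column exists.
#' @return data.frame with grouping columns, `window`, `mean`, `sd`, `n`,
#'   and `mean_temp` when available; windows with no data are reported with
#'   `n = 0` and `NA` statistics.
#' @export
window_means <- function(x, value_col = "value", windows = default_windows(),
                         by = NULL, temp_col = "t_enclosure", loq = 2) {
  stopifnot(is.data.frame(x), "timestamp" %in% names(x),
            value_col %in% names(x))
  v <- substitute_censored(x[[value_col]], x$censored, loq)
  hr <- hour_of_day(x$timestamp)
  has_temp <- temp_col %in% names(x)
  groups <- if (is.null(by)) {
    list(all = seq_len(nrow(x)))
  } else {
    split(seq_len(nrow(x)), interaction(x[by], drop = TRUE, sep = "/"))
  }
  rows <- list()
  for (gname in names(groups)) {
    gi <- groups[[gname]]
    for (wname in names(windows)) {
      w <- windows[[wname]]
      i <- gi[in_window(hr[gi], w[1], w[2])]
      row <- data.frame(
        group = gname, window = wname,
        mean = if (length(i)) mean(v[i]) else NA_real_,
        sd = if (length(i) > 1) stats::sd(v[i]) else NA_real_,
        n = length(i),
        stringsAsFactors = FALSE
      )
      if (has_temp) {
        row$mean_temp <- if (length(i)) mean(x[[temp_col]][i]) else NA_real_
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(by)) out$group <- NULL
  rownames(out) <- NULL
  out
}

#' Instrument intercomparison
#'
#' Pairs two time series by nearest-neighbor timestamp matching within a
#' tolerance, then reports the ordinary least-squares regression of B on A
#' and the Pearson correlation.
#'
#' @param series_a,series_b data.frames with `timestamp` and a value
#'   column.
#' @param value_col Value column name (default `"value_pptv"`).
#' @param tolerance_min Maximum pairing offset, minutes (default 15).
#' @return List with `slope`, `intercept`, `r`, `n_pairs`.
#' @export
intercompare <- function(series_a, series_b, value_col = "value_pptv",
                         tolerance_min = 15) {
  stopifnot(is.data.frame(series_a), is.data.frame(series_b))
  ta <- as.numeric(series_a$timestamp)
  tb <- as.numeric(series_b$timestamp)
  j <- vapply(ta, function(t0) {
    k <- which.min(abs(tb - t0))
    if (abs(tb[k] - t0) <= tolerance_min * 60) k else NA_integer_
  }, integer(1))
  ok <- !is.na(j)
  a <- series_a[[value_col]][ok]
  b <- series_b[[value_col]][j[ok]]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) stop("fewer than 3 paired samples", call. = FALSE)
  fit <- stats::lm(b ~ a)
  list(slope = unname(stats::coef(fit)[["a"]]),
       intercept = unname(stats::coef(fit)[["(Intercept)"]]),
       r = stats::cor(a, b),
       n_pairs = length(a))
}

#' Event enhancement ratio
#'
#' Ratio of the mean mixing ratio inside an event window to the mean over
#' a background window (e.g. a wildfire-influenced episode against the
#' surrounding campaign background).
#'
#' @param x data.frame with `timestamp` and a value column.
#' @param event_window,background_window Length-2 POSIXct vectors
#'   `c(start, end)` (half-open); must not overlap.
#' @param value_col Value column name (default `"value_pptv"`).
#' @param loq LOQ for LOQ/2 substitution where a `censored` column exists.
#' @return Enhancement factor (event mean / background mean).
#' @export
enhancement_ratio <- function(x, event_window, background_window,
                              value_col = "value_pptv", loq = 2) {
  stopifnot(is.data.frame(x), "timestamp" %in% names(x))
  if (event_window[1] < background_window[2] &&
      background_window[1] < event_window[2]) {
    stop("event and background windows overlap", call. = FALSE)
  }
  v <- substitute_censored(x[[value_col]], x$censored, loq)
  in_ev <- x$timestamp >= event_window[1] & x$timestamp < event_window[2]
  in_bg <- x$timestamp >= background_window[1] & x$timestamp < background_window[2]
  if (!any(in_ev) || !any(in_bg)) {
    stop("event and background windows must each contain samples",
         call. = FALSE)
  }
  bg <- mean(v[in_bg])
  if (!is.finite(bg) || bg <= 0) {
    stop("undefined enhancement: background mean is not positive",
         call. = FALSE)
  }
  mean(v[in_ev]) / bg
}

#' Mean ratio of two paired series
#'
#' Mean of the per-sample ratio x/y over pairs where both values are at or
#' above the quantification threshold (censored values cannot support a
#' meaningful ratio). Note the mean of a ratio of noisy positive series is
#' slightly biased high relative to the ratio of the means.
#'
#' @param x,y Numeric vectors of paired mixing ratios (same length).
#' @param threshold Minimum value (pptv) for a sample to qualify; default 2.
#' @return List with `ratio_mean` and `n_pairs`.
#' @export
ratio_mean <- function(x, y, threshold = 2) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y) & x >= threshold & y >= threshold
  if (!any(ok)) stop("no qualifying pairs above threshold", call. = FALSE)
  list(ratio_mean = mean(x[ok] / y[ok]), n_pairs = sum(ok))
}

#' Blank-filter vertical profile samples
#'
#' Discards profile samples whose mixing ratio is strictly below the
#' flight's field-blank value (such samples are indistinguishable from
#' sampling artifacts); samples equal to the blank are retained.
#'
#' @param profiles data.frame with `mixing_ratio` and `blank_value`
#'   columns (e.g. from [gen_profile_samples()]).
#' @param quiet Suppress the removal-count message?
#' @return Filtered data.frame; removal count in attribute `"n_removed"`.
#' @export
profile_filter <- function(profiles, quiet = FALSE) {
  stopifnot(is.data.frame(profiles),
            all(c("mixing_ratio", "blank_value") %in% names(profiles)))
  drop <- profiles$mixing_ratio < profiles$blank_value
  if (!quiet) {
    message(sum(drop), " of ", nrow(profiles),
            " profile samples below blank discarded")
  }
  out <- profiles[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  out
}
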