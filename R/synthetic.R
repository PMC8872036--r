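# Synthetic enclosure, ambient and vertical-profile data with planted truth.
#
# The generator emulates the statistical structure the analysis assumes:
# midnight-sun diurnal temperature/PAR cycles, an exponential-in-temperature
# isoprene emission truth, low near-constant monoterpene emissions, the
# chamber mass balance C_out = C_in + ER * S / Q, multiplicative lognormal
# measurement noise, ambient background with temperature-driven enhancements,
# detector sensitivity drift on internal-reference peak areas, and censoring
# at the limit of quantification. Every generated table carries its planted
# truth so downstream stages can be tested against a known answer.

#' Parameters of the synthetic-data generator
#'
#' @param e20 True isoprene emission at 20 degC and PAR 1000,
#'   ugC m^-2 h^-1 (> 0). Default 100 (a willow-dominated surface).
#' @param a_true Exponential temperature coefficient of the planted isoprene
#'   emission truth, degC^-1. Default 0.1935 (a 179%/217% emission ratio for
#'   +3/+4 degC warming).
#' @param beta_mt Monoterpene temperature coefficient, degC^-1. Default 0.09.
#' @param mt_e20 True monoterpene emission at 20 degC, ugC m^-2 h^-1.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (>= 0). Default 0.15, matching typical analytic
#'   uncertainty of 15-25%.
#' @param t_mean,t_amplitude Diurnal temperature model, degC: temperature is
#'   `t_mean + t_amplitude * cos(2 pi (h - 14) / 24)` (peak at 14:00 local
#'   solar time).
#' @param par_max Peak PAR, umol m^-2 s^-1.
#' @param par_floor_frac Nocturnal PAR floor as a fraction of `par_max`
#'   (midnight sun: PAR never reaches zero). Default 0.02.
#' @param q Purge-air flow, L h^-1 (> 0). Default 1500 (25 L min^-1).
#' @param s Surface-chamber footprint, m^2 (> 0). Default 0.04909 (circular
#'   base of 25 cm diameter).
#' @param m_dry Dry leaf mass for branch chambers, g.
#' @param c_in_background Background (inlet) isoprene mixing ratio, pptv.
#' @param greenhouse_offset Constant enclosure-minus-ambient temperature
#'   offset, degC (chamber greenhouse heating). Default 0.
#' @param pressure_kpa Station pressure for pptv <-> ugC conversions.
#' @param seed Integer RNG seed; one generator stream per scenario.
#' @return List of class `generator_params`.
#' @export
generator_params <- function(e20 = 100, a_true = 0.1935, beta_mt = 0.09,
                             mt_e20 = 0.5, noise_cv = 0.15,
                             t_mean = 12, t_amplitude = 10,
                             par_max = 1000, par_floor_frac = 0.02,
                             q = 1500, s = 0.04909, m_dry = 5,
                             c_in_background = 20, greenhouse_offset = 0,
                             pressure_kpa = 96, seed = 1L) {
  stopifnot(e20 > 0, noise_cv >= 0, q > 0, s > 0, m_dry > 0,
            par_max > 0, c_in_background >= 0)
  p <- as.list(environment())
  class(p) <- "generator_params"
  p
}

#' Synthetic enclosure scenario
#'
#' @param n_enclosures Number of enclosures.
#' @param vegetation_class One of `"salix"`, `"betula"`, `"miscellaneous"`.
#' @param kind `"surface"` or `"branch"` chambers.
#' @param duration_days Days of operation per enclosure.
#' @param sampling_interval_h Hours between time-integrated samples
#'   (timestamps mark the end of each integration period).
#' @param temperature_model `"diurnal"` (temperature and PAR follow the
#'   diurnal model) or `"uniform"` (enclosure temperatures drawn uniformly
#'   from `t_range` at daytime sampling hours under saturating constant
#'   light -- the design used for temperature-response recovery studies).
#' @param t_range Temperature range for the `"uniform"` model, degC.
#' @param light_dependence Should the planted isoprene truth include the
#'   light activity term (zero emission in full darkness)?
#' @param include_monoterpenes Also generate monoterpene records?
#' @param start Campaign start (date or POSIXct, local AST).
#' @param params [generator_params()].
#' @return List of class `enclosure_scenario`.
#' @export
enclosure_scenario <- function(n_enclosures = 10,
                               vegetation_class = c("salix", "betula",
                                                    "miscellaneous"),
                               kind = c("surface", "branch"),
                               duration_days = 5, sampling_interval_h = 2,
                               temperature_model = c("diurnal", "uniform"),
                               t_range = c(2, 32),
                               light_dependence = TRUE,
                               include_monoterpenes = FALSE,
                               start = "2019-06-10",
                               params = generator_params()) {
  stopifnot(sampling_interval_h > 0,
            duration_days * 24 >= sampling_interval_h,
            n_enclosures >= 1)
  sc <- list(n_enclosures = n_enclosures,
             vegetation_class = match.arg(vegetation_class),
             kind = match.arg(kind),
             duration_days = duration_days,
             sampling_interval_h = sampling_interval_h,
             temperature_model = match.arg(temperature_model),
             t_range = t_range,
             light_dependence = light_dependence,
             include_monoterpenes = include_monoterpenes,
             start = start,
             params = params)
  class(sc) <- "enclosure_scenario"
  sc
}

#' Diurnal temperature and PAR models
#'
#' Temperature peaks at 14:00 (local solar noon); PAR follows the same
#' phase with a nonzero nocturnal floor representing midnight-sun
#' conditions at high latitude.
#'
#' @param hour Fractional hour of day (0-24).
#' @param params [generator_params()].
#' @return Temperature (degC) or PAR (umol m^-2 s^-1).
#' @export
diurnal_temperature <- function(hour, params = generator_params()) {
  params$t_mean + params$t_amplitude * cos(2 * pi * (hour - 14) / 24)
}

#' @rdname diurnal_temperature
#' @export
diurnal_par <- function(hour, params = generator_params()) {
  params$par_max * pmax(params$par_floor_frac, cos(2 * pi * (hour - 14) / 24))
}

#' Planted emission truth
#'
#' The true emission at temperature T and light PAR:
#' `e20 * exp(a_true * (T - 20)) * CL(PAR)/CL(1000)` with CL the light
#' activity factor (see [cl_light()]); the light term is dropped when
#' `light_dependence = FALSE` (monoterpene-style pool emission uses
#' `mt_e20 * exp(beta_mt * (T - 20))`, see [gen_enclosure_timeseries()]).
#'
#' @param t_c Temperature, degC.
#' @param par PAR, umol m^-2 s^-1 (>= 0).
#' @param params [generator_params()].
#' @param light_dependence Include the light activity ratio?
#' @return True emission rate(s), ugC m^-2 h^-1.
#' @export
true_emission <- function(t_c, par, params = generator_params(),
                          light_dependence = TRUE) {
  stopifnot(all(par >= 0))
  e <- params$e20 * exp(params$a_true * (t_c - 20))
  if (light_dependence) e <- e * cl_light(par) / cl_light(1000)
  e
}

# Lognormal multiplicative noise with mean 1 and coefficient of variation cv.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic enclosure time series
#'
#' Produces enclosure records obeying the chamber mass balance
#' `c_out = c_in + ER_true * S / Q * eps` with `eps` multiplicative
#' lognormal noise of CV `noise_cv` (so the recovered emission rate is
#' lognormal around the planted truth), and inlet concentrations jittered
#' around the background with the same CV. With `noise_cv = 0` the mass
#' balance applied to the records recovers the planted emission exactly.
#' Records carry the truth in an `er_true` column.
#'
#' @param scenario An [enclosure_scenario()].
#' @return data.frame of enclosure records (see [emission_rates()] for the
#'   schema) with planted-truth column `er_true`; the scenario is attached
#'   as attribute `"scenario"`.
#' @export
gen_enclosure_timeseries <- function(scenario = enclosure_scenario()) {
  stopifnot(inherits(scenario, "enclosure_scenario"))
  p <- scenario$params
  if (!is.null(p$seed)) set.seed(p$seed)
  t0 <- as.POSIXct(paste(scenario$start, "00:00:00"), tz = ast_timezone())
  n_per <- floor(scenario$duration_days * 24 / scenario$sampling_interval_h)

  one_enclosure <- function(eid) {
    if (scenario$temperature_model == "diurnal") {
      hrs <- seq(scenario$sampling_interval_h,
                 by = scenario$sampling_interval_h, length.out = n_per)
      hod <- hrs %% 24
      t_c <- diurnal_temperature(hod, p) + p$greenhouse_offset
      par <- diurnal_par(hod, p)
    } else {
      # daytime sampling hours (10:00-20:00), temperatures uniform on t_range
      day <- sort(sample(rep(seq_len(scenario$duration_days), length.out = n_per)))
      hod <- stats::runif(n_per, 10, 20)
      hrs <- (day - 1) * 24 + hod
      t_c <- stats::runif(n_per, scenario$t_range[1], scenario$t_range[2])
      # saturating constant light: isolates the temperature response
      par <- rep(p$par_max, n_per)
    }
    er_true <- true_emission(t_c, par, p, scenario$light_dependence)
    denom <- if (scenario$kind == "surface") p$s else p$m_dry
    bg_ugc_l <- mixing_ratio_to_carbon_conc(
      p$c_in_background, "isoprene",
      temperature_k = t_c + 273.15, pressure_kpa = p$pressure_kpa) / 1000
    c_in <- bg_ugc_l * lognormal_noise(n_per, p$noise_cv)
    c_out <- c_in + er_true * denom / p$q * lognormal_noise(n_per, p$noise_cv)
    rec <- data.frame(
      timestamp = t0 + hrs * 3600,
      enclosure_id = sprintf("enc%02d", eid),
      kind = scenario$kind,
      vegetation_class = scenario$vegetation_class,
      compound = "isoprene",
      c_in = c_in, c_out = c_out,
      q = p$q,
      s = if (scenario$kind == "surface") p$s else NA_real_,
      m_dry = if (scenario$kind == "branch") p$m_dry else NA_real_,
      t_enclosure = t_c,
      rh = 70,
      par = par,
      er_true = er_true,
      stringsAsFactors = FALSE
    )
    if (scenario$include_monoterpenes) {
      mt_true <- p$mt_e20 * exp(p$beta_mt * (t_c - 20))
      mt <- rec
      mt$compound <- "alpha-pinene"
      mt$er_true <- mt_true
      mt$c_in <- 0
      mt$c_out <- mt_true * denom / p$q * lognormal_noise(n_per, p$noise_cv)
      rec <- rbind(rec, mt)
    }
    rec
  }

  out <- do.call(rbind, lapply(seq_len(scenario$n_enclosures), one_enclosure))
  rownames(out) <- NULL
  attr(out, "scenario") <- scenario
  out
}

#' Generate a synthetic ambient time series
#'
#' Emulates an ambient monitoring record: isoprene background with
#' temperature-driven enhancement, acetonitrile and isoprene-oxidation-
#' product channels, a planted multiplicative detector sensitivity drift
#' that scales both the analyte responses and the CFC internal-reference
#' peak areas, censoring at the limit of quantification, and an optional
#' wildfire-style event window multiplying isoprene and acetonitrile by
#' known factors.
#'
#' The planted truth (pre-drift, pre-noise values, the drift profile, and
#' the event specification) is attached as attribute `"truth"`.
#'
#' @param n_days Campaign length, days.
#' @param interval_h Sampling interval, hours.
#' @param params [generator_params()]; `c_in_background` is the isoprene
#'   background (pptv) and `noise_cv` the measurement noise.
#' @param loq Limit of quantification, pptv.
#' @param drift_total Total fractional sensitivity loss across the campaign
#'   (0.2 = linear decay to 80% of initial sensitivity). 0 disables drift.
#' @param event `NULL`, or a list with `start_day`, `end_day`,
#'   `factor_isoprene` (default 21) and `factor_acetonitrile` (default 4).
#' @param mvk_macr_ratio Planted ratio of MVK to MACR (default 2.7).
#' @param start Campaign start date (local AST).
#' @return Long-format data.frame: `timestamp`, `compound`, `value_pptv`,
#'   `censored`, `cfc11_area`, `cfc113_area`, `instrument`.
#' @export
gen_ambient_timeseries <- function(n_days = 30, interval_h = 2,
                                   params = generator_params(),
                                   loq = 2, drift_total = 0.2,
                                   event = NULL, mvk_macr_ratio = 2.7,
                                   start = "2019-06-01") {
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = ast_timezone())
  hrs <- seq(interval_h, n_days * 24, by = interval_h)
  n <- length(hrs)
  ts <- t0 + hrs * 3600
  hod <- hrs %% 24
  t_c <- diurnal_temperature(hod, p) + stats::rnorm(n, 0, 1.5)

  frac <- (hrs - hrs[1]) / (hrs[n] - hrs[1])
  drift <- 1 - drift_total * frac

  iso_true <- p$c_in_background * exp(0.10 * (t_c - p$t_mean))
  acn_true <- rep(100, n)
  macr_true <- 10 * exp(0.05 * (t_c - p$t_mean))
  mvk_true <- mvk_macr_ratio * macr_true
  if (!is.null(event)) {
    f_iso <- if (is.null(event$factor_isoprene)) 21 else event$factor_isoprene
    f_acn <- if (is.null(event$factor_acetonitrile)) 4 else event$factor_acetonitrile
    in_ev <- hrs >= event$start_day * 24 & hrs < event$end_day * 24
    iso_true[in_ev] <- iso_true[in_ev] * f_iso
    acn_true[in_ev] <- acn_true[in_ev] * f_acn
  } else {
    in_ev <- rep(FALSE, n)
  }

  cfc11 <- 1000 * drift * lognormal_noise(n, 0.02)
  cfc113 <- 800 * drift * lognormal_noise(n, 0.02)

  measure <- function(true) true * drift * lognormal_noise(n, p$noise_cv)
  compounds <- list(
    isoprene = measure(iso_true),
    acetonitrile = measure(acn_true),
    methacrolein = measure(macr_true),
    `methyl-vinyl-ketone` = measure(mvk_true)
  )
  out <- do.call(rbind, lapply(names(compounds), function(cmp) {
    v <- compounds[[cmp]]
    data.frame(timestamp = ts, compound = cmp,
               value_pptv = v, censored = v < loq,
               cfc11_area = cfc11, cfc113_area = cfc113,
               instrument = "GC-MS", stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    drift = drift, event_window = in_ev,
    factor_isoprene = if (is.null(event)) NA else f_iso,
    factor_acetonitrile = if (is.null(event)) NA else f_acn,
    mvk_macr_ratio = mvk_macr_ratio,
    iso_true = iso_true, params = p, loq = loq
  )
  out
}

#' Generate synthetic vertical-profile samples
#'
#' Tethered-balloon style profiles with a surface source: mixing ratios
#' decay exponentially with altitude around a per-flight surface value,
#' with multiplicative noise and per-flight blank values.
#'
#' @param n_flights Number of flights.
#' @param altitudes Nominal sampling altitudes, m a.g.l.
#' @param surface_value Mean surface mixing ratio, pptv.
#' @param scale_height e-folding altitude of the profile, m.
#' @param blank_mean Mean field-blank value, pptv.
#' @param noise_cv Multiplicative noise CV.
#' @param seed RNG seed.
#' @return data.frame: `flight_id`, `nominal_altitude`, `mixing_ratio`,
#'   `blank_value`.
#' @export
gen_profile_samples <- function(n_flights = 8,
                                altitudes = c(0, 30, 100, 170, 240),
                                surface_value = 50, scale_height = 150,
                                blank_mean = 5, noise_cv = 0.2, seed = 1L) {
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(n_flights), function(f) {
    sv <- surface_value * lognormal_noise(1, 0.3)
    blank <- blank_mean * lognormal_noise(1, 0.2)
    v <- sv * exp(-altitudes / scale_height) * lognormal_noise(length(altitudes),
                                                              noise_cv)
    data.frame(flight_id = sprintf("flight%02d", f),
               nominal_altitude = altitudes,
               mixing_ratio = v, blank_value = blank,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
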