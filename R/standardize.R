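# Standardization of observed emission rates to reference conditions
# (30 degC, PAR 1000 umol m^-2 s^-1) with the canonical leaf-level
# light (CL) and temperature (CT) activity algorithms, and the simple
# exponential temperature response used for monoterpenes.

#' Constants of the leaf-level standardization algorithms
#'
#' The published constants of the canonical isoprene light/temperature
#' activity algorithms and the monoterpene exponential temperature
#' coefficient. All exposed so site-specific re-fits can be swapped in.
#'
#' @param alpha Empirical light coefficient, (umol m^-2 s^-1)^-1.
#' @param c_l1 Light-term asymptote, dimensionless.
#' @param c_t1,c_t2 Temperature-term energies, J mol^-1.
#' @param t_m High-temperature rolloff point, K.
#' @param t_s Standard leaf temperature of the algorithm, K (30 degC).
#' @param r Gas constant, J mol^-1 K^-1.
#' @param beta_mt Monoterpene exponential temperature coefficient, K^-1.
#' @return List of class `std_constants`.
#' @export
standardization_constants <- function(alpha = 0.0027, c_l1 = 1.066,
                                      c_t1 = 95000, c_t2 = 230000,
                                      t_m = 314, t_s = 303.15,
                                      r = 8.314, beta_mt = 0.09) {
  k <- list(alpha = alpha, c_l1 = c_l1, c_t1 = c_t1, c_t2 = c_t2,
            t_m = t_m, t_s = t_s, r = r, beta_mt = beta_mt)
  if (any(unlist(k) <= 0)) stop("all standardization constants must be positive",
                                call. = FALSE)
  if (t_m <= t_s) stop("t_m must exceed t_s", call. = FALSE)
  class(k) <- "std_constants"
  k
}

#' Light activity factor CL
#'
#' `CL = alpha * c_l1 * PAR / sqrt(1 + alpha^2 * PAR^2)`: zero in darkness,
#' strictly increasing, bounded above by `c_l1` (1.066). At PAR = 1000
#' umol m^-2 s^-1 it equals 0.99964, i.e. effectively unity at the
#' standardization reference.
#'
#' @param par Photosynthetically active radiation, umol m^-2 s^-1 (>= 0).
#' @param k Constants from [standardization_constants()].
#' @return Dimensionless activity factor(s).
#' @export
cl_light <- function(par, k = standardization_constants()) {
  stopifnot(all(par >= 0, na.rm = TRUE))
  k$alpha * k$c_l1 * par / sqrt(1 + k$alpha^2 * par^2)
}

#' Temperature activity factor CT
#'
#' `CT = exp(c_t1 (T - t_s) / (R t_s T)) / (1 + exp(c_t2 (T - t_m) / (R t_s T)))`.
#' Increases roughly exponentially below the optimum and rolls off above
#' `t_m`.
#'
#' @param temperature_k Leaf/enclosure temperature, K (> 0).
#' @param k Constants from [standardization_constants()].
#' @return Dimensionless activity factor(s).
#' @export
ct_temperature <- function(temperature_k, k = standardization_constants()) {
  stopifnot(all(temperature_k > 0, na.rm = TRUE))
  num <- exp(k$c_t1 * (temperature_k - k$t_s) / (k$r * k$t_s * temperature_k))
  den <- 1 + exp(k$c_t2 * (temperature_k - k$t_m) / (k$r * k$t_s * temperature_k))
  num / den
}

#' Isoprene standardization factor
#'
#' Multiplicative factor taking an observation at (T, PAR) to the reference
#' conditions (default 30 degC, 1000 umol m^-2 s^-1), in ratio form:
#' `[CT(T_ref) CL(PAR_ref)] / [CT(T_obs) CL(PAR_obs)]`. An observation
#' already at reference conditions is therefore unchanged regardless of
#' whether CT and CL are exactly 1 there.
#'
#' @param t_c Observed enclosure temperature, degC.
#' @param par Observed PAR, umol m^-2 s^-1 (> 0: standardization is
#'   undefined in darkness).
#' @param k Constants from [standardization_constants()].
#' @param t_ref_c Reference temperature, degC (default 30).
#' @param par_ref Reference PAR (default 1000).
#' @return Dimensionless factor(s); `NA` where `par == 0`.
#' @export
isoprene_std_factor <- function(t_c, par, k = standardization_constants(),
                                t_ref_c = 30, par_ref = 1000) {
  ref <- ct_temperature(t_ref_c + 273.15, k) * cl_light(par_ref, k)
  obs <- ct_temperature(t_c + 273.15, k) * cl_light(par, k)
  factor <- ref / obs
  factor[par == 0] <- NA_real_
  factor
}

#' Standardize isoprene emission rates to reference conditions
#'
#' Applies the ratio-form standardization to an emission-rate table
#' (see [emission_rates()]): adds columns `value_std_30C_1000PAR` and
#' `standardization_basis`. Records with PAR = 0 cannot be standardized;
#' they get `NA` and the QC flag `no_light_standardization`.
#'
#' @param rates Emission-rate data.frame with `value`, `t_enclosure` (degC)
#'   and `par` columns.
#' @param k Constants from [standardization_constants()].
#' @param t_ref_c,par_ref Reference conditions.
#' @return `rates` with standardized-value columns added.
#' @seealso [destandardize_isoprene()] for the inverse.
#' @export
standardize_isoprene <- function(rates, k = standardization_constants(),
                                 t_ref_c = 30, par_ref = 1000) {
  stopifnot(is.data.frame(rates),
            all(c("value", "t_enclosure", "par") %in% names(rates)))
  f <- isoprene_std_factor(rates$t_enclosure, rates$par, k, t_ref_c, par_ref)
  rates$value_std_30C_1000PAR <- rates$value * f
  rates$standardization_basis <- sprintf("CT_CL_ratio_%gC_%gPAR", t_ref_c, par_ref)
  if (!is.null(rates$qc_flags)) {
    dark <- !is.na(rates$par) & rates$par == 0
    rates$qc_flags[dark] <- add_flag(rates$qc_flags[dark],
                                     "no_light_standardization")
  }
  rates
}

#' Invert the isoprene standardization
#'
#' Recovers the observed-condition value from the standardized one;
#' `destandardize_isoprene(standardize_isoprene(x))` is the identity where
#' standardization was defined.
#'
#' @inheritParams standardize_isoprene
#' @return `rates` with a `value_destd` column.
#' @export
destandardize_isoprene <- function(rates, k = standardization_constants(),
                                   t_ref_c = 30, par_ref = 1000) {
  stopifnot(is.data.frame(rates), "value_std_30C_1000PAR" %in% names(rates))
  f <- isoprene_std_factor(rates$t_enclosure, rates$par, k, t_ref_c, par_ref)
  rates$value_destd <- rates$value_std_30C_1000PAR / f
  rates
}

#' Standardize monoterpene emission rates to a reference temperature
#'
#' Monoterpene emission is treated as pool (temperature-only) release:
#' `value_std = value * exp(beta_mt * (T_ref - T_obs))` with `beta_mt` in
#' K^-1 and temperatures in K (differences equal those in degC).
#'
#' @inheritParams standardize_isoprene
#' @return `rates` with `value_std_30C_1000PAR` and `standardization_basis`
#'   columns added.
#' @export
standardize_monoterpene <- function(rates, k = standardization_constants(),
                                    t_ref_c = 30) {
  stopifnot(is.data.frame(rates),
            all(c("value", "t_enclosure") %in% names(rates)))
  rates$value_std_30C_1000PAR <-
    rates$value * exp(k$beta_mt * (t_ref_c - rates$t_enclosure))
  rates$standardization_basis <- sprintf("exp_beta_%gC", t_ref_c)
  rates
}

#' Invert the monoterpene standardization
#'
#' @inheritParams standardize_monoterpene
#' @return `rates` with a `value_destd` column.
#' @export
destandardize_monoterpene <- function(rates, k = standardization_constants(),
                                      t_ref_c = 30) {
  stopifnot(is.data.frame(rates), "value_std_30C_1000PAR" %in% names(rates))
  rates$value_destd <-
    rates$value_std_30C_1000PAR / exp(k$beta_mt * (t_ref_c - rates$t_enclosure))
  rates
}
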