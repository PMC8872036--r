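# MEGAN2.1 temperature-only emission prediction: the temperature activity
# factor gamma_T and its optimum structure, canopy-coefficient calibration,
# and warming-scenario ratios. Temperatures are Kelvin throughout; the
# constant 0.00831 is the gas constant in kJ mol^-1 K^-1.

#' MEGAN optimum temperature
#'
#' `T_opt = 313 + 0.6 (T10 - 297)`: the temperature (K) at which the
#' activity factor peaks, shifted by the 10-day mean temperature T10 to
#' represent thermal acclimation.
#'
#' @param t10_k 10-day mean air temperature, K.
#' @return Optimum temperature, K.
#' @export
megan_t_opt <- function(t10_k) {
  313 + 0.6 * (t10_k - 297)
}

#' MEGAN optimum activity
#'
#' `E_opt = 2 exp(0.08 (T10 - 297))`: the peak value of the activity
#' factor, again a function of the 10-day mean temperature.
#'
#' @param t10_k 10-day mean air temperature, K.
#' @return Dimensionless peak activity.
#' @export
megan_e_opt <- function(t10_k) {
  2 * exp(0.08 * (t10_k - 297))
}

#' MEGAN temperature activity factor
#'
#' The dimensionless multiplier describing the isoprene emission response
#' to the current temperature T and the 10-day mean T10:
#' \deqn{x = (1/T_{opt} - 1/T) / 0.00831}
#' \deqn{\gamma_T = E_{opt} \cdot 200 e^{95x} / (200 - 95(1 - e^{200x}))}
#' The denominator simplifies to `105 + 95 exp(200 x)`, the form used here;
#' for extreme arguments the asymptotic form `E_opt (200/95) exp(-105 x)`
#' is substituted to avoid overflow. gamma_T is unimodal in T with its
#' maximum exactly E_opt at T = T_opt.
#'
#' @param t_k Current (enclosure ambient) air temperature, K. Vectorized.
#' @param t10_k 10-day mean air temperature, K.
#' @return Dimensionless activity factor(s).
#' @seealso [megan_intermediates()] to retrieve x, E_opt and T_opt as well.
#' @export
megan_gamma_t <- function(t_k, t10_k) {
  stopifnot(all(t_k > 200 & t_k < 330, na.rm = TRUE),
            all(t10_k > 200 & t10_k < 330, na.rm = TRUE))
  t_opt <- megan_t_opt(t10_k)
  e_opt <- megan_e_opt(t10_k)
  x <- (1 / t_opt - 1 / t_k) / 0.00831
  g <- e_opt * 200 * exp(95 * x) / (105 + 95 * exp(200 * x))
  big <- is.finite(x) & (200 * x > 700)
  if (any(big)) {
    # exp(200 x) overflows; gamma -> E_opt (200/95) exp(-105 x)
    g[big] <- (e_opt * (200 / 95) * exp(-105 * x))[big]
  }
  g[is.finite(x) & (95 * x < -700)] <- 0
  g
}

#' MEGAN temperature-response intermediates
#'
#' @inheritParams megan_gamma_t
#' @return data.frame with `t`, `t10`, `x`, `e_opt`, `t_opt`, `gamma_t`.
#' @export
megan_intermediates <- function(t_k, t10_k) {
  n <- max(length(t_k), length(t10_k))
  t_k <- rep_len(t_k, n); t10_k <- rep_len(t10_k, n)
  t_opt <- megan_t_opt(t10_k)
  data.frame(
    t = t_k, t10 = t10_k,
    x = (1 / t_opt - 1 / t_k) / 0.00831,
    e_opt = megan_e_opt(t10_k),
    t_opt = t_opt,
    gamma_t = megan_gamma_t(t_k, t10_k)
  )
}

#' MEGAN configuration for landscape emission prediction
#'
#' Holds the landscape emission-capacity sum (Sum_j kappa_j epsilon_j,
#' the areal-coverage-weighted emission factors of the vegetation types in
#' the grid cell) and the standard conditions at which the canopy
#' environment coefficient C_CE is calibrated. `c_ce` starts unset; call
#' [calibrate_cce()] before [megan_flux()].
#'
#' @param sum_kappa_eps Emission-capacity sum, ug m^-2 h^-1 (> 0).
#'   Default 2766, the 1 km emission-factor product for the study site.
#' @param t_standard,t10_standard Standard conditions, K.
#' @param c_ce Canopy environment coefficient; normally left `NULL` and
#'   set by calibration.
#' @return List of class `megan_config`.
#' @export
megan_config <- function(sum_kappa_eps = 2766, t_standard = 303,
                         t10_standard = 297, c_ce = NULL) {
  stopifnot(sum_kappa_eps > 0)
  cfg <- list(sum_kappa_eps = sum_kappa_eps, t_standard = t_standard,
              t10_standard = t10_standard, c_ce = c_ce)
  class(cfg) <- "megan_config"
  cfg
}

#' Calibrate the canopy environment coefficient
#'
#' Sets `c_ce = 1 / gamma_T(t_standard, t10_standard)` so that the activity
#' product `c_ce * gamma_T` is exactly 1 under standard conditions, making
#' the predicted flux equal the emission-capacity sum there.
#'
#' @param config A [megan_config()].
#' @return The config with `c_ce` set.
#' @export
calibrate_cce <- function(config) {
  stopifnot(inherits(config, "megan_config"))
  g <- megan_gamma_t(config$t_standard, config$t10_standard)
  if (!is.finite(g) || g <= 0) {
    stop("calibration error: gamma_T at standard conditions is not positive",
         call. = FALSE)
  }
  config$c_ce <- 1 / g
  config
}

#' MEGAN temperature-driven emission flux
#'
#' `F_T = C_CE * gamma_T(T, T10) * Sum_j kappa_j epsilon_j`, in
#' ug m^-2 h^-1.
#'
#' @inheritParams megan_gamma_t
#' @param config A calibrated [megan_config()].
#' @return Predicted flux(es), ug m^-2 h^-1.
#' @export
megan_flux <- function(t_k, t10_k, config) {
  stopifnot(inherits(config, "megan_config"))
  if (is.null(config$c_ce)) {
    stop("megan_config is not calibrated; call calibrate_cce() first",
         call. = FALSE)
  }
  config$c_ce * megan_gamma_t(t_k, t10_k) * config$sum_kappa_eps
}

#' Warming-scenario emission ratio under MEGAN
#'
#' Emission at `t_base + delta` as a percentage of emission at `t_base`,
#' `100 * gamma_T(t_base + delta, T10') / gamma_T(t_base, T10)`. Under the
#' `"tracking"` policy the 10-day mean warms with the scenario
#' (T10' = T10 + delta, sustained warming); under `"fixed"` it does not
#' (a transient heat event). Independent of C_CE and the capacity sum,
#' which cancel.
#'
#' @param t_base_k Baseline temperature, K.
#' @param t10_k Baseline 10-day mean temperature, K.
#' @param delta Warming, degC (>= 0).
#' @param t10_policy `"tracking"` or `"fixed"`.
#' @return Percent of baseline emission.
#' @export
megan_warming_ratio <- function(t_base_k, t10_k, delta,
                                t10_policy = c("tracking", "fixed")) {
  stopifnot(all(delta >= 0))
  t10_policy <- match.arg(t10_policy)
  t10_new <- if (t10_policy == "tracking") t10_k + delta else t10_k
  100 * megan_gamma_t(t_base_k + delta, t10_new) / megan_gamma_t(t_base_k, t10_k)
}

#' Tabulate gamma_T over a temperature grid
#'
#' @param t_grid_c Temperatures, degC.
#' @param t10_k 10-day mean temperature, K.
#' @return data.frame with `t_c`, `t_k`, `gamma_t`.
#' @export
megan_gamma_table <- function(t_grid_c = seq(0, 40, by = 1), t10_k = 287) {
  data.frame(
    t_c = t_grid_c,
    t_k = t_grid_c + 273.15,
    gamma_t = megan_gamma_t(t_grid_c + 273.15, t10_k)
  )
}
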