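# Emission rates from dynamic (flow-through) enclosure records.
#
# A dynamic enclosure is purged at flow Q (L h^-1); the emission rate is
# inferred from the inlet/outlet concentration difference (ugC L^-1):
#   surface chambers:  ER = (C_out - C_in) * Q / S      [ugC m^-2 h^-1]
#   branch chambers:   ER = (C_out - C_in) * Q / m_dry  [ugC g^-1  h^-1]

.ENCLOSURE_COLS <- c("timestamp", "enclosure_id", "kind", "compound",
                     "c_in", "c_out", "q", "t_enclosure", "par")

validate_enclosure <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.ENCLOSURE_COLS, names(records))
  if (length(missing_cols) > 0) {
    stop("enclosure records missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(records$kind %in% c("surface", "branch"))) {
    stop("kind must be 'surface' or 'branch'", call. = FALSE)
  }
  if (any(records$q <= 0, na.rm = TRUE)) {
    stop("purge flow q must be positive", call. = FALSE)
  }
  if (any(records$c_in < 0 | records$c_out < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  surf <- records$kind == "surface"
  if (any(surf) && (is.null(records$s) || any(is.na(records$s[surf])) ||
                    any(records$s[surf] <= 0))) {
    stop("geometry error: surface records require footprint area s > 0",
         call. = FALSE)
  }
  if (any(!surf) && (is.null(records$m_dry) || any(is.na(records$m_dry[!surf])) ||
                     any(records$m_dry[!surf] <= 0))) {
    stop("geometry error: branch records require dry leaf mass m_dry > 0",
         call. = FALSE)
  }
  invisible(records)
}

#' Emission rates from enclosure records
#'
#' Computes per-record emission rates from a table of dynamic-enclosure
#' observations. Surface records (per-area basis) use the chamber footprint
#' `s` (m^2); branch records (per-dry-mass basis) use the dried leaf mass
#' `m_dry` (g). Negative rates (outlet below inlet) are retained -- they may
#' represent deposition or measurement noise -- and flagged
#' `"deposition_or_noise"` so downstream aggregations can exclude them.
#'
#' @param records data.frame of enclosure observations with columns
#'   `timestamp`, `enclosure_id`, `kind` (`"surface"`/`"branch"`),
#'   `compound`, `c_in`, `c_out` (ugC L^-1), `q` (L h^-1), `s` (m^2,
#'   surface) or `m_dry` (g, branch), `t_enclosure` (degC), `par`
#'   (umol m^-2 s^-1); optional `vegetation_class`, `rh`.
#' @param acclimation_hours Leading hours dropped per enclosure to let the
#'   vegetation acclimate after installation (default 0: assume the input
#'   already excludes the acclimation period).
#' @param loss_correction Optional multiplicative correction factor applied
#'   to the computed rates (e.g. 1/0.75 to undo a known 25% chamber loss of
#'   monoterpenes/sesquiterpenes). Default 1 (off): reported rates are
#'   uncorrected and possibly biased low for those classes.
#' @return data.frame of emission-rate records: `timestamp`, `enclosure_id`,
#'   `compound`, `value`, `basis` (`"per_area"`/`"per_dry_mass"`),
#'   `t_enclosure`, `par`, `qc_flags` (semicolon-joined labels), plus
#'   `vegetation_class` and any `er_true` planted-truth column carried
#'   through from synthetic records.
#' @export
emission_rates <- function(records, acclimation_hours = 0,
                           loss_correction = 1) {
  validate_enclosure(records)
  if (acclimation_hours > 0) {
    keep <- unlist(lapply(split(seq_len(nrow(records)), records$enclosure_id),
                          function(i) {
      t0 <- min(records$timestamp[i])
      i[as.numeric(difftime(records$timestamp[i], t0, units = "hours")) >=
          acclimation_hours]
    }), use.names = FALSE)
    records <- records[sort(keep), , drop = FALSE]
  }
  surf <- records$kind == "surface"
  denom <- ifelse(surf, records$s, records$m_dry)
  value <- (records$c_out - records$c_in) * records$q / denom * loss_correction
  flags <- character(nrow(records))
  flags[value < 0] <- "deposition_or_noise"
  out <- data.frame(
    timestamp = records$timestamp,
    enclosure_id = records$enclosure_id,
    compound = records$compound,
    value = value,
    basis = ifelse(surf, "per_area", "per_dry_mass"),
    t_enclosure = records$t_enclosure,
    par = records$par,
    qc_flags = flags,
    stringsAsFactors = FALSE
  )
  for (extra in c("vegetation_class", "er_true")) {
    if (!is.null(records[[extra]])) out[[extra]] <- records[[extra]]
  }
  out
}

#' Surface-chamber emission rate
#'
#' Scalar/vector form of the per-area mass balance
#' `ER = (c_out - c_in) * q / s`.
#'
#' @param c_in,c_out Inlet and outlet concentrations, ugC L^-1.
#' @param q Purge-air flow, L h^-1.
#' @param s Chamber footprint area, m^2 (> 0).
#' @return Emission rate(s), ugC m^-2 h^-1.
#' @export
surface_emission_rate <- function(c_in, c_out, q, s) {
  if (any(is.na(s)) || any(s <= 0)) {
    stop("geometry error: footprint area s must be > 0", call. = FALSE)
  }
  (c_out - c_in) * q / s
}

#' Branch-chamber emission rate
#'
#' Scalar/vector form of the per-dry-mass mass balance
#' `ER = (c_out - c_in) * q / m_dry`.
#'
#' @param c_in,c_out Inlet and outlet concentrations, ugC L^-1.
#' @param q Purge-air flow, L h^-1.
#' @param m_dry Dried leaf mass in the chamber, g (> 0).
#' @return Emission rate(s), ugC g^-1 h^-1.
#' @export
branch_emission_rate <- function(c_in, c_out, q, m_dry) {
  if (any(is.na(m_dry)) || any(m_dry <= 0)) {
    stop("geometry error: dry leaf mass m_dry must be > 0", call. = FALSE)
  }
  (c_out - c_in) * q / m_dry
}

#' Internal-standard recovery
#'
#' Percent recovery of pre-loaded internal-standard compounds, used to flag
#' analyte losses during cartridge transport, storage and analysis.
#'
#' @param measured Recovered mass(es).
#' @param loaded Loaded mass(es) (> 0).
#' @param window Acceptable recovery window, percent (default 70-130).
#' @return data.frame with `recovery_percent` and logical `flagged`.
#' @export
internal_standard_recovery <- function(measured, loaded, window = c(70, 130)) {
  if (any(loaded <= 0)) stop("loaded mass must be positive", call. = FALSE)
  rec <- 100 * measured / loaded
  data.frame(recovery_percent = rec,
             flagged = rec < window[1] | rec > window[2])
}

#' Cartridge breakthrough check
#'
#' For cartridges sampled in series, the fraction of total analyte found on
#' the back cartridge. A fraction strictly above the threshold indicates
#' breakthrough of the front adsorbent bed.
#'
#' @param front,back Analyte masses on the front and back cartridges (>= 0,
#'   not both zero).
#' @param threshold Flagging threshold on the back fraction (default 0.05;
#'   the boundary value itself is not flagged).
#' @return data.frame with `fraction` and logical `flagged`.
#' @export
breakthrough_check <- function(front, back, threshold = 0.05) {
  if (any(front < 0 | back < 0)) stop("masses must be non-negative", call. = FALSE)
  if (any(front + back == 0)) {
    stop("undefined ratio: front and back both zero", call. = FALSE)
  }
  frac <- back / (front + back)
  data.frame(fraction = frac, flagged = frac > threshold)
}
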