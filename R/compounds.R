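# Compound registry and carbon-basis unit conversions.
#
# All emission rates in this package are expressed on a carbon-mass basis
# (ugC), so every conversion between volume mixing ratio (pptv) and mass
# concentration runs through the carbon fraction of the compound.

# IUPAC 2021 standard atomic weights, rounded as used throughout.
.ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007, S = 32.06)

# Universal gas constant, J mol^-1 K^-1.
.R_GAS <- 8.314

#' Parse a simple elemental formula
#'
#' Accepts formulas of the form `C5H8`, `C10H18O`, `C2H3N` (element symbol
#' followed by an optional count). No parentheses or hydrates.
#'
#' @param formula Character scalar, e.g. `"C5H8"`.
#' @return Named integer vector of element counts.
#' @keywords internal
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (paste(tokens, collapse = "") != formula) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  elems <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(elems, names(.ATOMIC_MASS))
  if (length(unknown) > 0) {
    stop("unknown element(s) in formula: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tapply(counts, factor(elems, levels = unique(elems)), sum)
}

#' Molar mass from an elemental formula
#'
#' @param formula Character scalar elemental formula.
#' @return Molar mass in g mol^-1.
#' @examples
#' molar_mass("C5H8") # isoprene, 68.119
#' @export
molar_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(.ATOMIC_MASS[names(counts)] * counts)
}

#' Packaged compound registry
#'
#' Returns the registry of compounds known to the package (terpenoids,
#' isoprene oxidation products, tracers), with molar mass, carbon count and
#' carbon fraction computed from the elemental formula. Extend by passing
#' extra rows with `name`, `formula`, and optionally `class`,
#' `default_loq_pptv` columns.
#'
#' @param extra Optional data.frame of additional compounds (`name`,
#'   `formula` columns required).
#' @return data.frame with columns `name`, `formula`, `class`,
#'   `default_loq_pptv`, `molar_mass`, `n_carbon`, `carbon_fraction`.
#' @export
bvoc_compounds <- function(extra = NULL) {
  path <- system.file("extdata", "compounds.csv", package = "tundrabvoc")
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot(is.data.frame(extra), all(c("name", "formula") %in% names(extra)))
    if (is.null(extra$class)) extra$class <- "user"
    if (is.null(extra$default_loq_pptv)) extra$default_loq_pptv <- 2
    reg <- rbind(reg, extra[, names(reg)])
  }
  reg$molar_mass <- vapply(reg$formula, molar_mass, numeric(1), USE.NAMES = FALSE)
  reg$n_carbon <- vapply(reg$formula, function(f) {
    counts <- parse_formula(f)
    as.numeric(if ("C" %in% names(counts)) counts[["C"]] else 0)
  }, numeric(1), USE.NAMES = FALSE)
  reg$carbon_fraction <- .ATOMIC_MASS[["C"]] * reg$n_carbon / reg$molar_mass
  reg
}

#' Look up one compound
#'
#' @param name Compound name as in the registry (e.g. `"isoprene"`,
#'   `"alpha-pinene"`).
#' @param registry Registry data.frame, by default [bvoc_compounds()].
#' @return One-row data.frame of class `compound_spec`.
#' @export
compound_spec <- function(name, registry = bvoc_compounds()) {
  if (is.data.frame(name)) return(name) # already a spec
  i <- match(name, registry$name)
  if (is.na(i)) {
    stop("unknown compound: ", name,
         " (see bvoc_compounds() for the registry)", call. = FALSE)
  }
  spec <- registry[i, , drop = FALSE]
  if (spec$molar_mass <= 0) stop("invalid compound: non-positive molar mass",
                                 call. = FALSE)
  class(spec) <- c("compound_spec", "data.frame")
  spec
}

#' Carbon mass fraction of a compound
#'
#' The fraction of molecular mass contributed by carbon,
#' `12.011 * n_carbon / molar_mass`. Isoprene (C5H8) and all pure
#' (C5H8)n terpenoids share the value 0.8816.
#'
#' @param compound Compound name or `compound_spec`.
#' @return Dimensionless fraction in (0, 1].
#' @examples
#' carbon_fraction("isoprene")
#' @export
carbon_fraction <- function(compound) {
  spec <- compound_spec(compound)
  if (spec$molar_mass <= 0) stop("invalid compound: non-positive molar mass",
                                 call. = FALSE)
  if (spec$n_carbon < 1) stop("invalid compound: no carbon atoms", call. = FALSE)
  .ATOMIC_MASS[["C"]] * spec$n_carbon / spec$molar_mass
}

#' Convert mixing ratio to carbon mass concentration
#'
#' Ideal-gas conversion from volume mixing ratio (pptv) to carbon mass
#' concentration (ugC m^-3):
#' `x * 1e-12 * P/(R*T) * M * f_C`, with P in Pa, M in g mol^-1 and the
#' result scaled to micrograms. Station defaults (96 kPa, 298.15 K) are
#' configurable; pass the measured air temperature when available.
#'
#' @param x_pptv Mixing ratio(s), pptv. Must be non-negative.
#' @param compound Compound name or `compound_spec`.
#' @param temperature_k Air temperature, K.
#' @param pressure_kpa Station pressure, kPa.
#' @return Carbon mass concentration(s), ugC m^-3.
#' @seealso [carbon_conc_to_mixing_ratio()] for the inverse.
#' @export
mixing_ratio_to_carbon_conc <- function(x_pptv, compound,
                                        temperature_k = 298.15,
                                        pressure_kpa = 96) {
  stopifnot(all(temperature_k > 0), all(pressure_kpa > 0))
  if (any(x_pptv < 0, na.rm = TRUE)) {
    stop("negative mixing ratio", call. = FALSE)
  }
  spec <- compound_spec(compound)
  mol_per_m3 <- pressure_kpa * 1000 / (.R_GAS * temperature_k)
  # g/mol * mol/m3 * 1e-12 (pptv) * 1e6 (g -> ug)
  x_pptv * 1e-12 * mol_per_m3 * spec$molar_mass * carbon_fraction(spec) * 1e6
}

#' Convert carbon mass concentration to mixing ratio
#'
#' Inverse of [mixing_ratio_to_carbon_conc()].
#'
#' @param conc_ugc_m3 Carbon mass concentration(s), ugC m^-3.
#' @inheritParams mixing_ratio_to_carbon_conc
#' @return Mixing ratio(s), pptv.
#' @export
carbon_conc_to_mixing_ratio <- function(conc_ugc_m3, compound,
                                        temperature_k = 298.15,
                                        pressure_kpa = 96) {
  stopifnot(all(temperature_k > 0), all(pressure_kpa > 0))
  spec <- compound_spec(compound)
  mol_per_m3 <- pressure_kpa * 1000 / (.R_GAS * temperature_k)
  conc_ugc_m3 / (1e-12 * mol_per_m3 * spec$molar_mass * carbon_fraction(spec) * 1e6)
}
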