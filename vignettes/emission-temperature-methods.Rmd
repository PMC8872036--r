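---
title: "Methods: enclosure fluxes, standardization, and the emission-temperature response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enclosure fluxes, standardization, and the emission-temperature response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tundrabvoc)
```

## Scope and model

This package implements the computational chain for quantifying terpenoid
emissions from tundra vegetation with dynamic (flow-through) enclosures,
and for the associated ambient time-series quality control. The pieces are:

1. **Chamber mass balance.** A dynamic enclosure purged at flow $Q$
   (L h$^{-1}$) reaches a quasi-steady state in which the emission rate is
   $\mathrm{ER} = (C_\mathrm{out} - C_\mathrm{in})\,Q/S$ per footprint area
   $S$ (m$^2$), or $(C_\mathrm{out} - C_\mathrm{in})\,Q/m_\mathrm{dry}$ per
   dry leaf mass. Concentrations are carried on a carbon-mass basis
   (µgC L$^{-1}$), which makes rates comparable across terpenoids: all pure
   (C$_5$H$_8$)$_n$ species share the carbon fraction
   $12.011\,n_C/M = 0.8816$. The steady-state assumption means the 2 h
   integrated samples must be long relative to the chamber residence time;
   residence-time dynamics are not modelled.

2. **Standardization.** Isoprene emission is light- and
   temperature-dependent; observed rates are referred to 30 °C and PAR
   1000 µmol m$^{-2}$ s$^{-1}$ with the canonical leaf-level activity
   factors
   $C_L = \alpha c_{L1} \mathrm{PAR}/\sqrt{1+\alpha^2\mathrm{PAR}^2}$ and
   $C_T(T) = e^{c_{T1}(T-T_s)/(R T_s T)} / (1 + e^{c_{T2}(T-T_M)/(R T_s T)})$.
   We use the *ratio form* — multiply by
   $C_T(T_\mathrm{ref})C_L(\mathrm{PAR}_\mathrm{ref}) / C_T(T)C_L(\mathrm{PAR})$
   — so that an observation already at reference conditions is unchanged
   even though $C_T(303.15\,\mathrm{K}) \ne 1$ exactly, and the operation
   inverts exactly. Standardization is undefined in full darkness
   ($C_L(0)=0$); such records are flagged, not guessed. Monoterpene release
   is treated as temperature-driven pool emission,
   $\mathrm{ER}_\mathrm{std} = \mathrm{ER}\,e^{\beta(303.15-T)}$ with
   $\beta = 0.09$ K$^{-1}$.

3. **MEGAN2.1 temperature activity.** The temperature-only emission
   prediction is $F_T = C_{CE}\,\gamma_T\,\sum_j \kappa_j\varepsilon_j$ with
   $$\gamma_T = E_\mathrm{opt}\frac{200\,e^{95x}}{200 - 95(1-e^{200x})},
   \qquad x = \frac{1/T_\mathrm{opt} - 1/T}{0.00831},$$
   $T_\mathrm{opt} = 313 + 0.6(T_{10}-297)$ and
   $E_\mathrm{opt} = 2e^{0.08(T_{10}-297)}$, all temperatures in Kelvin
   ($0.00831$ is the gas constant in kJ mol$^{-1}$ K$^{-1}$; 297 and 313 are
   Kelvin anchors). We simplify the denominator algebraically to
   $105 + 95e^{200x}$, which is exactly equivalent and numerically benign;
   for extreme arguments the asymptotic form
   $E_\mathrm{opt}(200/95)e^{-105x}$ is substituted. $\gamma_T$ is unimodal
   with its maximum exactly $E_\mathrm{opt}$ at $T=T_\mathrm{opt}$. The
   canopy environment coefficient is calibrated as
   $C_{CE} = 1/\gamma_T(T_\mathrm{std}, T_{10,\mathrm{std}})$ so the
   standard-condition activity is exactly one; flux prediction refuses to
   run uncalibrated rather than assuming a default.

4. **Emission-temperature response.** Different enclosures hold different
   biomass and species mixes, so daytime rates are first divided by the
   enclosure-specific mean emission at the 20 ± 1 °C reference (a reference
   suited to cold growth environments). The pooled normalized emissions are
   fit by ordinary least squares on the log scale,
   $\ln E_\mathrm{norm} = b + a(T-20)$, and the warming response is
   reported as $100\,e^{a\,\Delta T}$ percent of baseline. The multiplicative
   reading of "X % increase" (final = X % of baseline) is used throughout:
   it is the only reading under which a single exponential coefficient is
   consistent across $\Delta T$ values.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| LOQ | 2 | pptv | instrumental quantification limit; configurable per compound |
| station pressure | 96 | kPa | ~720 m elevation site; used for pptv ↔ µgC m⁻³ |
| purge flow $Q$ | 1500 | L h⁻¹ | 25 L min⁻¹ chamber purge |
| footprint $S$ | 0.04909 | m² | circular 25 cm base read as diameter |
| $\alpha, c_{L1}$ | 0.0027, 1.066 | –, – | published light-algorithm constants |
| $c_{T1}, c_{T2}$ | 95000, 230000 | J mol⁻¹ | published temperature-algorithm constants |
| $T_M, T_s$ | 314, 303.15 | K | rolloff point; standard temperature (30 °C) |
| $\beta$ (monoterpene) | 0.09 | K⁻¹ | canonical pool-emission coefficient |
| $\sum\kappa\varepsilon$ | 2766 | µg m⁻² h⁻¹ | landscape emission capacity at the study site |
| MEGAN standard | $T=303$, $T_{10}=297$ | K | convention for $C_{CE}$ calibration; configurable |
| reference bin | 20 ± 1 | °C | normalization reference, half-open $[19,21)$ |
| bin width | 2 | °C | display bins $[c-1, c+1)$ centered on even degrees |
| daytime window | 10:00–20:00 | AST | half-open; midday 11:00–14:00, nighttime 23:00–05:00 (wraps) |

The standard temperature is 303.15 K (= 30 °C as stated) rather than the
algorithm's 303 K; with the ratio-form standardization the difference
cancels to well below 0.1 %.

## The synthetic-data generator

The generator plants a known truth and pushes it through the same physical
relations the analysis inverts:

- diurnal temperature $T(h) = \bar T + A\cos(2\pi(h-14)/24)$ peaking at
  14:00 (local solar noon, AST) and PAR with the same phase and a 2 %
  nocturnal floor, emulating midnight sun (PAR never reaches zero, but is
  very low at night);
- isoprene truth $E(T) = E_{20}e^{a(T-20)}\,C_L(\mathrm{PAR})/C_L(1000)$
  with defaults $E_{20} = 100$ µgC m⁻² h⁻¹ (a willow-dominated surface,
  consistent with observed daytime means once the exponential response is
  applied) and $a = 0.1935$ °C⁻¹ (which gives 178.7 % / 216.8 % of baseline
  at +3 / +4 °C); near-constant low monoterpene emission
  $0.5\,e^{0.09(T-20)}$ µgC m⁻² h⁻¹;
- the chamber mass balance
  $C_\mathrm{out} = C_\mathrm{in} + E\,S/Q\cdot\varepsilon$, with
  $\varepsilon$ multiplicative lognormal noise of mean 1 and CV 0.15
  (matching 15–25 % analytic uncertainty; concentrations stay positive).
  Placing the noise on the emission term makes the recovered rate lognormal
  around the truth with the stated CV, which is what the
  parameter-recovery analysis presumes. With CV = 0 the mass balance
  inverts the truth exactly (to float rounding), which is the package's
  strongest internal oracle;
- ambient series with temperature-driven isoprene enhancement over a 20
  pptv background, MVK = 2.7 × MACR, constant acetonitrile, a planted
  linear detector-sensitivity decay applied to both analytes and
  CFC-11/CFC-113 reference areas, censoring below the LOQ, and an optional
  event window multiplying isoprene (×21) and acetonitrile (×4);
- vertical profiles decaying exponentially from a surface source, with
  per-flight blanks.

Two sampling designs are provided. The *diurnal* design mimics a field
campaign (2 h integrated samples around the clock; timestamps mark the end
of each integration period). The *uniform* design draws enclosure
temperatures uniformly on 2–32 °C at daytime hours under saturating
constant light; it isolates the temperature response and is the design used
for coefficient-recovery studies and the reproduction script.

What the generator does **not** emulate: leaf-vs-air temperature
decoupling, chamber micro-climate and radiative transfer (greenhouse
heating is available only as a constant offset), adsorbent losses of
monoterpenes/sesquiterpenes (an optional multiplicative correction exists,
default off, so rates mirror the uncorrected-measurement convention),
autocorrelated weather, and instrument breakdown gaps. Passing tests
therefore demonstrate the correctness of the computational chain under the
assumed error structure, not the field validity of those assumptions.

## Numerical and convention choices

- **Normalization exactness.** Each enclosure's reference-bin mean of
  normalized values is 1 by construction, so the pooled reference-bin mean
  is exactly 1 — a useful invariant. The fitted intercept is a diagnostic:
  it is near, not exactly, zero, because the reference-bin mean of
  $e^{a(T-20)}$ over the sampled bin temperatures is not exactly
  $e^{0}$.
- **Fit on records, not bins.** The exponential is fit to raw normalized
  records; temperature bins are reported for display counts only. Binned
  fits weight sparse temperature extremes differently and were rejected.
- **Non-positive values.** Negative fluxes (deposition or noise) are
  retained and flagged rather than clipped; they are excluded from the log
  fit with an explicit count.
- **Censored statistics.** Below-LOQ values enter means and standard
  deviations as LOQ/2 (the substitution convention); the quantification
  frequency is reported alongside. The standard deviation after
  substitution is a convention, not an unbiased estimate.
- **Drift correction.** Neither CFC channel is given precedence: the
  correction uses the geometric mean of the two median-normalized areas,
  smoothed by a 24 h running median; the correction also rescales the areas
  so that re-applying it is the identity up to smoothing. The campaign
  median defines the reference sensitivity.
- **Windows and bins are half-open** ($[start, end)$), and the nighttime
  window wraps midnight. The boundary convention matters at exact-boundary
  timestamps and is tested.
- **Breakthrough threshold** is strict (a back-fraction exactly at 0.05 is
  not flagged); internal-standard recovery flags outside 70–130 %.
- **Acclimation.** A configurable leading-record drop per enclosure
  (default off) implements the 24 h acclimation exclusion.

## Design decisions taken where the design was open

- The pressure/temperature basis of pptv ↔ µgC conversions is exposed as
  configuration (96 kPa, measured temperature when available, else
  298.15 K) rather than hard-coded.
- The chamber base "25 cm width" is read as a diameter
  ($S = 0.04909$ m²); both $S$ and $Q$ are per-record inputs, so other
  geometries need no code change.
- Leaf-level activity factors are used for standardization, with the MEGAN
  $\gamma_T$ available separately for comparison rather than conflated with
  it.
- The MEGAN warming ratio exposes a $T_{10}$ policy: *tracking* (sustained
  warming shifts the 10-day mean with the scenario) or *fixed* (transient
  heat event). No single published procedure pins this down, so both are
  available and none is asserted as canonical.
- This is an analysis library: the interface is the exported functions, the
  `run_pipeline()` runner with CSV/JSON artifacts, and this vignette.

## Problem sizes

The bundled analyses run at desk scale by choice: recovery studies use 10
enclosures × 60 daytime samples (n = 600) per seed and 50 seeds for
coverage checks; ambient QC demonstrations use 30–120 day campaigns at 2 h
resolution. All complete in seconds on one CPU.

## Known limitations

- Air temperature stands in for leaf temperature throughout; in tundra the
  two can decouple, and the emission-temperature coefficient inherits that
  caveat.
- The exponential fit is linear least squares on the log scale; lognormal
  noise makes this the maximum-likelihood estimator, but heavy-tailed
  contamination would call for robust alternatives not implemented here.
- No correction is applied for chamber losses of monoterpenes and
  sesquiterpenes; reported MT/SQT rates are conservative (biased low by
  roughly 20–30 % in comparable systems).
- Above ~30 °C the exponential and MEGAN curves diverge; with few hot
  records a leveling-off cannot be distinguished from continued exponential
  growth, and the package deliberately tabulates rather than tests that
  comparison.
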