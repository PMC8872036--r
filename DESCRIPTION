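Package: tundrabvoc
Title: Terpenoid Emission Rates and Ambient Mixing Ratios in Arctic Tundra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying biogenic volatile organic compound (BVOC)
    emissions from Arctic tundra vegetation and for quality control of ambient
    terpenoid time series. Computes emission rates from dynamic (flow-through)
    enclosure measurements on a per-area or per-dry-mass basis, standardizes
    isoprene and monoterpene emissions to reference temperature and light
    conditions using the canonical leaf-level algorithms, implements the
    MEGAN2.1 temperature activity factor with canopy-coefficient calibration,
    fits exponential emission-temperature responses with enclosure-wise
    normalization and reports warming-scenario emission ratios, and provides
    censored (below-quantification-limit) summary statistics, internal-reference
    drift correction, diurnal and time-window aggregation, instrument
    intercomparison, and vertical-profile blank filtering. A synthetic-data
    generator with planted emission truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
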