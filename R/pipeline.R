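# End-to-end pipeline runner: simulate -> enclosure flux -> standardize ->
# temperature response, with on-disk CSV artifacts and a JSON run manifest.
# Every stage is a thin call into the library functions; no analysis logic
# lives here.

#' Pipeline configuration
#'
#' Bundles and validates everything a pipeline run needs. Can be built
#' directly or loaded from a YAML/JSON file with [read_pipeline_config()].
#'
#' @param seed Integer RNG seed (required: the simulate stage is
#'   stochastic).
#' @param loq_pptv Limit of quantification, pptv (> 0).
#' @param pressure_kpa Station pressure, kPa (> 0).
#' @param bin_width Temperature bin width, degC (> 0).
#' @param reference_temp Normalization reference temperature, degC.
#' @param windows Aggregation windows ([default_windows()]).
#' @param constants [standardization_constants()].
#' @param megan A [megan_config()] (calibrated automatically if not).
#' @param scenario An [enclosure_scenario()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, loq_pptv = 2, pressure_kpa = 96,
                            bin_width = 2, reference_temp = 20,
                            windows = default_windows(),
                            constants = standardization_constants(),
                            megan = megan_config(),
                            scenario = enclosure_scenario()) {
  if (is.null(seed) || is.na(seed)) stop("seed is required", call. = FALSE)
  stopifnot(loq_pptv > 0, pressure_kpa > 0, bin_width > 0)
  if (is.null(megan$c_ce)) megan <- calibrate_cce(megan)
  scenario$params$seed <- as.integer(seed)
  cfg <- list(seed = as.integer(seed), loq_pptv = loq_pptv,
              pressure_kpa = pressure_kpa, bin_width = bin_width,
              reference_temp = reference_temp, windows = windows,
              constants = constants, megan = megan, scenario = scenario)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Scalar fields of [pipeline_config()] can be overridden from a config
#' file; nested sections `params` and `scenario` override the generator
#' parameters and scenario fields by name.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  params <- do.call(generator_params, as.list(raw$params))
  sc_args <- as.list(raw$scenario)
  sc_args$params <- params
  scenario <- do.call(enclosure_scenario, sc_args)
  top <- raw[intersect(names(raw), c("seed", "loq_pptv", "pressure_kpa",
                                     "bin_width", "reference_temp"))]
  do.call(pipeline_config, c(top, list(scenario = scenario)))
}

#' Run the emission-analysis pipeline
#'
#' Executes the requested stages in order, writing each stage's artifact as
#' CSV under `output_dir` together with a JSON run manifest (seed, stage
#' list, key fit numbers). Deterministic given (config, seed).
#'
#' Stages: `"simulate"` (synthetic enclosure records; skipped when
#' `input` provides measured records), `"flux"` (mass-balance emission
#' rates), `"standardize"` (values at 30 degC / PAR 1000),
#' `"temp_response"` (normalization, exponential fit, MEGAN comparison).
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of the stages above.
#' @param output_dir Output directory (created if missing).
#' @param input Optional path to an enclosure CSV replacing the simulate
#'   stage.
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with the stage outputs (`records`, `rates`,
#'   `fit`, ...) and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "flux", "standardize",
                                    "temp_response"),
                         output_dir = tempfile("bvoc_run_"),
                         input = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  out <- list()

  if (!is.null(input)) {
    say("reading enclosure records from ", input)
    out$records <- read_enclosure_csv(input)
  } else if ("simulate" %in% stages) {
    say("simulating enclosure records (seed ", config$seed, ")")
    out$records <- gen_enclosure_timeseries(config$scenario)
    write_enclosure_csv(out$records, file.path(output_dir, "enclosure.csv"))
  }

  if ("flux" %in% stages) {
    stopifnot(!is.null(out$records))
    out$rates <- emission_rates(out$records)
    n_neg <- sum(has_flag(out$rates$qc_flags, "deposition_or_noise"))
    say("computed ", nrow(out$rates), " emission rates (", n_neg,
        " negative, flagged)")
    write_emission_csv(out$rates, file.path(output_dir, "emission_rates.csv"))
  }

  if ("standardize" %in% stages) {
    stopifnot(!is.null(out$rates))
    out$rates <- standardize_isoprene(out$rates, config$constants)
    write_emission_csv(out$rates,
                       file.path(output_dir, "emission_rates_std.csv"))
  }

  if ("temp_response" %in% stages) {
    stopifnot(!is.null(out$rates))
    iso <- out$rates[out$rates$compound == "isoprene", ]
    out$normalized <- normalize_by_reference(
      iso, reference_temp = config$reference_temp)
    out$fit <- fit_temperature_response(
      out$normalized, bin_width = config$bin_width,
      reference_temp = config$reference_temp)
    out$megan_comparison <- compare_to_megan(out$fit)
    say(sprintf("exponential fit: a = %.4f degC^-1 (r^2 = %.3f, n = %d)",
                out$fit$a_hat, out$fit$r_squared, out$fit$n))
    utils::write.csv(out$fit$bins,
                     file.path(output_dir, "temperature_bins.csv"),
                     row.names = FALSE)
    utils::write.csv(out$megan_comparison,
                     file.path(output_dir, "megan_comparison.csv"),
                     row.names = FALSE)
    fit_df <- data.frame(a_hat = out$fit$a_hat,
                         ci_lower = out$fit$ci95[["lower"]],
                         ci_upper = out$fit$ci95[["upper"]],
                         intercept = out$fit$intercept,
                         r_squared = out$fit$r_squared,
                         n = out$fit$n,
                         warming_3c_percent = warming_percent(out$fit, 3),
                         warming_4c_percent = warming_percent(out$fit, 4))
    utils::write.csv(fit_df, file.path(output_dir, "fit.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package = "tundrabvoc",
    version = as.character(utils::packageVersion("tundrabvoc")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    stages = stages,
    n_records = if (is.null(out$records)) NA else nrow(out$records),
    a_hat = if (is.null(out$fit)) NA else out$fit$a_hat
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  out$output_dir <- output_dir
  invisible(out)
}
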