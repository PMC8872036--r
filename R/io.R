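# CSV schemas binding the pipeline stages together. All files are UTF-8
# CSV with a header row; timestamps are ISO-8601 local time with explicit
# numeric offset; missing values are empty cells; censored values are
# marked in a dedicated logical column, never by sentinel numbers.

.TS_FORMAT <- "%Y-%m-%dT%H:%M:%S%z"

format_timestamp <- function(ts) format(ts, .TS_FORMAT)

parse_timestamp <- function(x, tz = ast_timezone()) {
  x <- as.character(x)
  out <- as.POSIXct(x, format = .TS_FORMAT, tz = tz)
  if (any(is.na(out) & !is.na(x) & nzchar(x))) {
    stop("unparseable ISO-8601 timestamp(s), e.g. ",
         x[which(is.na(out) & nzchar(x))[1]], call. = FALSE)
  }
  out
}

check_columns <- function(df, required, what, path) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("invalid ", what, " file ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Read and write enclosure-record CSV files
#'
#' Schema: `timestamp` (ISO-8601 with offset), `enclosure_id`, `kind`,
#' `vegetation_class`, `compound`, `c_in`, `c_out` (ugC L^-1), `q`
#' (L h^-1), `s` (m^2), `m_dry` (g), `t_enclosure` (degC), `rh` (%),
#' `par` (umol m^-2 s^-1); optional planted-truth `er_true`.
#'
#' @param path File path.
#' @param tz Time zone for parsed timestamps.
#' @return data.frame of enclosure records.
#' @export
read_enclosure_csv <- function(path, tz = ast_timezone()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, .ENCLOSURE_COLS, "enclosure", path)
  df$timestamp <- parse_timestamp(df$timestamp, tz)
  validate_enclosure(df)
  df
}

#' @rdname read_enclosure_csv
#' @param records data.frame of enclosure records.
#' @export
write_enclosure_csv <- function(records, path) {
  records$timestamp <- format_timestamp(records$timestamp)
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write emission-rate CSV files
#'
#' Schema as produced by [emission_rates()]; `qc_flags` is a
#' semicolon-joined label string.
#'
#' @param path File path.
#' @param tz Time zone for parsed timestamps.
#' @return data.frame of emission-rate records.
#' @export
read_emission_csv <- function(path, tz = ast_timezone()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("timestamp", "enclosure_id", "compound", "value",
                      "basis", "t_enclosure", "par", "qc_flags"),
                "emission-rate", path)
  df$timestamp <- parse_timestamp(df$timestamp, tz)
  df$qc_flags[is.na(df$qc_flags)] <- ""
  df
}

#' @rdname read_emission_csv
#' @param rates data.frame of emission-rate records.
#' @export
write_emission_csv <- function(rates, path) {
  rates$timestamp <- format_timestamp(rates$timestamp)
  utils::write.csv(rates, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write ambient-sample CSV files
#'
#' Schema: `timestamp`, `compound`, `value_pptv`, `censored` (written as
#' `"<LOQ"` in a dedicated flag column, empty when quantified),
#' `cfc11_area`, `cfc113_area`, `instrument`.
#'
#' @param path File path.
#' @param tz Time zone for parsed timestamps.
#' @return data.frame of ambient samples (`censored` as logical).
#' @export
read_ambient_csv <- function(path, tz = ast_timezone()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("timestamp", "compound", "value_pptv", "censored",
                      "cfc11_area", "cfc113_area", "instrument"),
                "ambient", path)
  df$timestamp <- parse_timestamp(df$timestamp, tz)
  # censored is "<LOQ" / empty on disk; an all-empty column reads as logical
  df$censored <- if (is.logical(df$censored)) {
    !is.na(df$censored) & df$censored
  } else {
    !is.na(df$censored) & df$censored == "<LOQ"
  }
  df
}

#' @rdname read_ambient_csv
#' @param samples data.frame of ambient samples.
#' @export
write_ambient_csv <- function(samples, path) {
  samples$timestamp <- format_timestamp(samples$timestamp)
  samples$censored <- ifelse(samples$censored, "<LOQ", "")
  utils::write.csv(samples, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write vertical-profile CSV files
#'
#' Schema: `flight_id`, `nominal_altitude` (m a.g.l.), `mixing_ratio`
#' (pptv), `blank_value` (pptv).
#'
#' @param path File path.
#' @return data.frame of profile samples.
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("flight_id", "nominal_altitude", "mixing_ratio",
                      "blank_value"), "profile", path)
  if (any(df$nominal_altitude < 0)) {
    stop("invalid profile file ", path, ": negative altitude", call. = FALSE)
  }
  df
}

#' @rdname read_profile_csv
#' @param profiles data.frame of profile samples.
#' @export
write_profile_csv <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE, na = "")
  invisible(path)
}
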