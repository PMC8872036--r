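# Small shared helpers.

# Append a QC flag label to semicolon-joined flag strings.
add_flag <- function(flags, label) {
  flags <- ifelse(is.na(flags) | flags == "", label,
                  paste(flags, label, sep = ";"))
  flags
}

has_flag <- function(flags, label) {
  flags <- as.character(flags)
  flags[is.na(flags)] <- ""
  vapply(strsplit(flags, ";", fixed = TRUE),
         function(f) label %in% f, logical(1))
}

# Fractional hour of day in the series' local time zone.
hour_of_day <- function(timestamp) {
  lt <- as.POSIXlt(timestamp)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

# Is a fractional hour inside the half-open local-time window [start, end)?
# Windows with end <= start wrap midnight (e.g. nighttime 23:00-05:00).
in_window <- function(hour, start, end) {
  if (end > start) hour >= start & hour < end
  else hour >= start | hour < end
}

#' Alaska standard time zone of the study
#'
#' All diurnal windows in this package are defined in Alaska standard time
#' (AST, UTC-9, no daylight saving). This returns the corresponding Olson
#' name, `"Etc/GMT+9"` (POSIX sign convention: GMT+9 means UTC-9).
#'
#' @return Time zone string.
#' @export
ast_timezone <- function() "Etc/GMT+9"
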