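# Internal helpers shared across modules.

# Parse timestamp strings under a set of admissible formats, returning POSIXct
# (NA where no format applies). Formats tried in order; first that yields a
# non-NA value wins, per element.
parse_timestamps <- function(x, formats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                            "%m/%d/%Y %H:%M:%S")) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = .ipplog_tz)
  pending <- !is.na(x) & nzchar(x)
  for (fmt in formats) {
    if (!any(pending)) break
    parsed <- as.POSIXct(x[pending], format = fmt, tz = .ipplog_tz)
    ok <- !is.na(parsed)
    idx <- which(pending)[ok]
    out[idx] <- parsed[ok]
    pending[idx] <- FALSE
  }
  out
}

format_timestamp <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = .ipplog_tz)

stop_missing_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Multi-valued fields (source encounter ids, hospital account ids, diagnosis
# codes) are carried as ";"-joined strings so every table stays CSV-safe.
join_ids <- function(x) vapply(x, function(v) paste(sort(unique(v[!is.na(v) & nzchar(v)])),
                                                    collapse = ";"), character(1))
split_ids <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_epoch <- function(x) as.numeric(x)

epoch_to_ts <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = .ipplog_tz)
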