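#' Shared table schemas
#'
#' The pipeline passes plain \code{data.table}s between stages. Each table kind
#' has a fixed column set and column order, used by the readers, by
#' \code{\link{write_table}}, and by the internal validators:
#'
#' \describe{
#'   \item{audit}{\code{patient_id}, \code{action}, \code{extended_info},
#'     \code{timestamp}. One row per raw audit-log event: the de-identified
#'     study id standing in for the MRN, the raw activity code (UA-TYPE), the
#'     optional extended-info code, and a second-resolution timestamp.}
#'   \item{adt}{\code{patient_id}, \code{encounter_id} (contact serial
#'     number), \code{hospital_account_id}, \code{admit}, \code{discharge},
#'     \code{encounter_class} (one of \code{inpatient}, \code{outpatient},
#'     \code{emergency}).}
#'   \item{charges}{\code{hospital_account_id}, \code{patient_id},
#'     \code{admit}, \code{discharge}, \code{diagnosis_codes} (";"-joined),
#'     \code{encounter_class}.}
#'   \item{admissions}{\code{patient_id}, \code{admission_id}, \code{start},
#'     \code{end}, \code{source_encounter_ids} (";"-joined),
#'     \code{hospital_account_ids} (";"-joined). A consolidated
#'     continuous-care interval built from one or more raw ADT encounters.}
#'   \item{events}{classified events: the audit columns plus \code{fn}
#'     (function label, one of the nine portal functions or
#'     \code{Administrative}), \code{active}, and after linkage
#'     \code{admission_id}, \code{provision_day}, \code{session_id}.}
#'   \item{sessions}{\code{session_id}, \code{patient_id},
#'     \code{admission_id}, \code{start}, \code{end}, \code{event_count},
#'     \code{n_active_tasks} (active tasks outside Administrative),
#'     \code{zero_time}.}
#'   \item{metrics}{\code{level}, \code{unit_id}, \code{patient_id}, one
#'     \code{freq_*} column per portal function, \code{n_active_admin},
#'     \code{comprehensiveness}, \code{pct_functions}, \code{n_sessions}.}
#' }
#'
#' @param kind one of the table kinds above.
#' @return character vector of column names for that kind.
#' @export
table_schema <- function(kind) {
  switch(match.arg(kind, names(.schemas)), .schemas[[kind]])
}

.schemas <- list(
  audit      = c("patient_id", "action", "extended_info", "timestamp"),
  adt        = c("patient_id", "encounter_id", "hospital_account_id",
                 "admit", "discharge", "encounter_class"),
  charges    = c("hospital_account_id", "patient_id", "admit", "discharge",
                 "diagnosis_codes", "encounter_class"),
  admissions = c("patient_id", "admission_id", "start", "end",
                 "source_encounter_ids", "hospital_account_ids"),
  events     = c("patient_id", "action", "extended_info", "timestamp",
                 "fn", "active", "admission_id", "provision_day", "session_id"),
  sessions   = c("session_id", "patient_id", "admission_id", "start", "end",
                 "event_count", "n_active_tasks", "zero_time"),
  metrics    = NULL  # filled in metrics.R (depends on function keys)
)

.timestamp_cols <- c(timestamp = NA, admit = NA, discharge = NA, start = NA, end = NA)

# columns that are character-typed in every schema; read_table() restores
# them when a CSV round trip degrades an all-NA column to logical
.character_cols <- c("patient_id", "action", "extended_info", "encounter_id",
                     "hospital_account_id", "hospital_account_ids",
                     "admission_id", "session_id", "source_encounter_ids",
                     "diagnosis_codes", "encounter_class", "fn", "unit_id",
                     "level", "drop_class")

#' Default column-name mapping for site CSV extracts
#'
#' Epic extract headers vary by site, so each reader takes a schema config:
#' a named list mapping the package's canonical column names to the column
#' names found in the file, plus an optional \code{timestamp_formats}
#' character vector (strptime formats, tried in order; the defaults accept
#' ISO-8601 and the US "MDY HMS" style). Configs can be stored in YAML and
#' loaded with \code{\link{read_schema_config}}.
#'
#' @return named list with identity column mapping and default formats.
#' @export
default_schema_config <- function() {
  list(
    columns = list(),   # canonical name -> file header; empty = identity
    timestamp_formats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                          "%m/%d/%Y %H:%M:%S"),
    max_reject_fraction = 0.10
  )
}

#' Read a schema config from a YAML file
#' @param path YAML file with optional keys \code{columns},
#'   \code{timestamp_formats}, \code{max_reject_fraction}.
#' @return schema config list as in \code{\link{default_schema_config}}.
#' @export
read_schema_config <- function(path) {
  cfg <- default_schema_config()
  user <- yaml::read_yaml(path)
  for (k in names(user)) cfg[[k]] <- user[[k]]
  cfg$timestamp_formats <- as.character(unlist(cfg$timestamp_formats))
  cfg
}

# Shared reader core: rename site columns to canonical, parse timestamps,
# reject rows whose mandatory timestamps do not parse, build a load report.
read_table_kind <- function(path, kind, schema_config, required, ts_cols) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  cfg <- schema_config %||% default_schema_config()
  raw <- data.table::fread(path, colClasses = "character", na.strings = c("", "NA"))
  colmap <- cfg$columns %||% list()
  for (canon in names(colmap)) {
    site <- colmap[[canon]]
    if (!site %in% names(raw)) {
      stop(sprintf("%s: configured column '%s' (for '%s') not in header",
                   path, site, canon), call. = FALSE)
    }
    data.table::setnames(raw, site, canon)
  }
  stop_missing_cols(raw, required, path)
  extra_ok <- setdiff(.schemas[[kind]], names(raw))
  for (col in extra_ok) raw[, (col) := NA_character_]
  n_in <- nrow(raw)
  bad <- rep(FALSE, n_in)
  for (tc in intersect(ts_cols, names(raw))) {
    parsed <- parse_timestamps(raw[[tc]], cfg$timestamp_formats)
    bad <- bad | is.na(parsed)
    raw[, (tc) := parsed]
  }
  # empty patient ids are rejected alongside unparseable timestamps
  if ("patient_id" %in% names(raw)) bad <- bad | is.na(raw$patient_id) | !nzchar(raw$patient_id)
  out <- raw[!bad]
  report <- list(file = path, kind = kind, rows_in = n_in,
                 accepted = nrow(out), rejected = sum(bad))
  max_frac <- cfg$max_reject_fraction %||% 0.10
  if (n_in > 0 && report$rejected / n_in > max_frac) {
    stop(sprintf("%s: %d/%d rows rejected (limit %.0f%%)", path,
                 report$rejected, n_in, 100 * max_frac), call. = FALSE)
  }
  data.table::setcolorder(out, intersect(.schemas[[kind]], names(out)))
  data.table::setattr(out, "load_report", report)
  out[]
}

#' Read an audit-log CSV
#'
#' Reads the raw audit-log extract: one row per logged event with the
#' de-identified patient id, the raw activity code, the optional extended-info
#' code, and a timestamp. Rows with unparseable timestamps or empty patient
#' ids are rejected and counted in the load report (attached as attribute
#' \code{"load_report"} and retrievable with \code{\link{load_report}}); a
#' reject fraction above \code{max_reject_fraction} aborts.
#'
#' @param path CSV file path.
#' @param schema_config see \code{\link{default_schema_config}}.
#' @return \code{data.table} with the \code{audit} schema.
#' @export
read_audit_log <- function(path, schema_config = NULL) {
  read_table_kind(path, "audit", schema_config,
                  required = c("patient_id", "action", "timestamp"),
                  ts_cols = "timestamp")
}

#' Read a raw ADT (admission/discharge/transfer) CSV
#' @inheritParams read_audit_log
#' @return \code{data.table} with the \code{adt} schema.
#' @export
read_adt <- function(path, schema_config = NULL) {
  read_table_kind(path, "adt", schema_config,
                  required = c("patient_id", "encounter_id", "admit",
                               "discharge", "encounter_class"),
                  ts_cols = c("admit", "discharge"))
}

#' Read a hospital-charges CSV
#' @inheritParams read_audit_log
#' @return \code{data.table} with the \code{charges} schema.
#' @export
read_charges <- function(path, schema_config = NULL) {
  read_table_kind(path, "charges", schema_config,
                  required = c("hospital_account_id", "patient_id",
                               "admit", "discharge", "encounter_class"),
                  ts_cols = c("admit", "discharge"))
}

#' Retrieve the load report attached by a reader
#' @param x table returned by one of the readers.
#' @return list with \code{rows_in}, \code{accepted}, \code{rejected}.
#' @export
load_report <- function(x) attr(x, "load_report")

#' Write a pipeline table to CSV
#'
#' Writes any pipeline table with deterministic column order and ISO-8601
#' timestamps, so that write-then-read is the identity on field values
#' (timestamps to the second).
#'
#' @param records a pipeline \code{data.frame}/\code{data.table}.
#' @param path output CSV path.
#' @return (invisibly) the number of data rows written.
#' @export
write_table <- function(records, path) {
  df <- data.table::as.data.table(records)
  for (col in names(df)) {
    if (inherits(df[[col]], "POSIXct")) df[, (col) := format_timestamp(.SD[[1L]]), .SDcols = col]
    if (inherits(df[[col]], "Date")) df[, (col) := format(.SD[[1L]], "%Y-%m-%d"), .SDcols = col]
  }
  data.table::fwrite(df, path, quote = TRUE, na = "NA")
  invisible(nrow(df))
}

#' Read back a table written by \code{write_table}
#'
#' @param path CSV path.
#' @param timestamp_cols columns to parse as timestamps (default: the
#'   package's standard timestamp column names present in the file).
#' @return \code{data.table}.
#' @export
read_table <- function(path, timestamp_cols = NULL) {
  df <- data.table::fread(path, na.strings = c("NA"))
  ts_cols <- timestamp_cols %||% intersect(names(.timestamp_cols), names(df))
  for (tc in ts_cols) {
    if (is.character(df[[tc]]) || inherits(df[[tc]], "POSIXct")) {
      df[, (tc) := parse_timestamps(as.character(.SD[[1L]])), .SDcols = tc]
    }
  }
  for (cc in intersect(.character_cols, names(df))) {
    if (is.logical(df[[cc]]) && all(is.na(df[[cc]]))) {
      df[, (cc) := as.character(.SD[[1L]]), .SDcols = cc]
    }
  }
  df[]
}

#' Write a JSON report sidecar
#' @param report a list (load report, cleaning report, manifest, ...).
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
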