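#' Restrict charges to inpatient encounters
#'
#' The portal is an inpatient tool, so hospital-charge records from
#' outpatient or emergency visits are excluded before diagnoses are attached
#' to admissions. Dropped counts by encounter class are attached as attribute
#' \code{"report"}.
#'
#' @param charges \code{charges}-schema table.
#' @param strict_class if \code{TRUE}, an encounter class other than
#'   inpatient/outpatient/emergency is an error; otherwise such rows are
#'   dropped with a warning.
#' @return inpatient-only \code{charges} \code{data.table}.
#' @export
filter_inpatient <- function(charges, strict_class = FALSE) {
  ch <- data.table::as.data.table(charges)
  stop_missing_cols(ch, c("hospital_account_id", "encounter_class"), "charges")
  known <- c("inpatient", "outpatient", "emergency")
  unknown <- setdiff(unique(ch$encounter_class), known)
  if (length(unknown)) {
    msg <- sprintf("unknown encounter class(es): %s", paste(unknown, collapse = ", "))
    if (strict_class) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  dropped <- ch[encounter_class != "inpatient" | is.na(encounter_class)]
  out <- ch[encounter_class == "inpatient"]
  report <- list(rows_in = nrow(ch), retained = nrow(out),
                 dropped_by_class = as.list(table(dropped$encounter_class)))
  data.table::setattr(out, "report", report)
  out[]
}

#' Collapse duplicate hospital account ids
#'
#' Because one hospital charge may cover multiple encounters, the raw charge
#' extract can carry the same hospital account id several times with
#' different admission/discharge times. One record per account id is
#' retained (the one with the earliest admit; ties broken by discharge then
#' patient id), after validating that the diagnosis payload agrees across
#' the duplicates. Disagreeing duplicates are still collapsed the same way
#' but are flagged in the consistency report rather than silently resolved.
#'
#' @param charges inpatient-only \code{charges} table
#'   (\code{\link{filter_inpatient}} output).
#' @return \code{charges} \code{data.table} with unique
#'   \code{hospital_account_id}; consistency report in attribute
#'   \code{"report"} (fields \code{rows_in}, \code{retained},
#'   \code{collapsed}, \code{conflicts}, \code{conflict_account_ids}).
#' @export
dedupe_hospital_accounts <- function(charges) {
  ch <- data.table::as.data.table(charges)
  stop_missing_cols(ch, c("hospital_account_id", "admit"), "charges")
  if (any(is.na(ch$hospital_account_id) | !nzchar(ch$hospital_account_id))) {
    stop("empty hospital_account_id in charges", call. = FALSE)
  }
  data.table::setorder(ch, hospital_account_id, admit, discharge, patient_id)
  conflicts <- ch[, .(n = .N, n_diag = data.table::uniqueN(diagnosis_codes)),
                  by = hospital_account_id][n > 1L & n_diag > 1L, hospital_account_id]
  out <- ch[, .SD[1L], by = hospital_account_id]
  data.table::setcolorder(out, intersect(.schemas$charges, names(out)))
  report <- list(rows_in = nrow(ch), retained = nrow(out),
                 collapsed = nrow(ch) - nrow(out),
                 conflicts = length(conflicts),
                 conflict_account_ids = as.character(conflicts))
  data.table::setattr(out, "report", report)
  out[]
}
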