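#' Link classified events to admissions
#'
#' The study id (de-identified MRN) is the only join key between the audit
#' log and the ADT-derived admissions, so each event is attached to the
#' admission of the same patient whose interval contains its timestamp.
#' Intervals are closed on both ends: an event at the admission start or at
#' the discharge second is in-encounter. Containment is unambiguous because
#' consolidated admissions are disjoint within patient.
#'
#' Events falling outside every admission of their patient are dropped and
#' classified \code{near} (within \code{near_window_hours} of some admission
#' boundary) or \code{far} (anything beyond — portal use can surface days or
#' even years after a patient leaves any encounter). Events of patients with
#' no admissions at all are \code{far}.
#'
#' @param events cleaned \code{events}-schema table
#'   (\code{\link{clean_events}} output).
#' @param admissions consolidated \code{admissions} table.
#' @param near_window_hours diagnostic near/far boundary in hours
#'   (default 24).
#' @return list with \code{events} (linked rows, \code{admission_id} set),
#'   \code{dropped} (unlinked rows with a \code{drop_class} column), and
#'   \code{report} (\code{rows_in}, \code{linked}, \code{near}, \code{far}).
#' @export
link_events <- function(events, admissions, near_window_hours = 24) {
  ev <- data.table::as.data.table(events)
  adm <- data.table::as.data.table(admissions)
  stop_missing_cols(ev, c("patient_id", "timestamp"), "events")
  stop_missing_cols(adm, c("patient_id", "admission_id", "start", "end"), "admissions")
  if ("admission_id" %in% names(ev)) ev[, admission_id := NULL]
  ev[, ts := as_epoch(timestamp)]
  win <- adm[, .(patient_id, admission_id, lo = as_epoch(start), hi = as_epoch(end))]
  hit <- win[ev, on = .(patient_id, lo <= ts, hi >= ts),
             .(admission_id = x.admission_id[1L]), by = .EACHI]
  ev[, admission_id := hit$admission_id]

  linked <- ev[!is.na(admission_id)]
  dropped <- ev[is.na(admission_id)]
  if (nrow(dropped)) {
    # distance (seconds) to the nearest admission interval of the same patient
    dropped[, rn := .I]
    d <- win[dropped, on = "patient_id", allow.cartesian = TRUE]
    d[, dist := pmax(lo - ts, ts - hi, 0)]
    mind <- d[, .(dist = if (all(is.na(admission_id)))
                    Inf else min(dist, na.rm = TRUE)), by = rn]
    dropped[mind$rn, min_dist := mind$dist]
    dropped[, drop_class := ifelse(min_dist <= near_window_hours * 3600, "near", "far")]
    dropped[, c("rn", "min_dist") := NULL]
  } else {
    dropped[, drop_class := character(0)]
  }
  linked[, ts := NULL]
  dropped[, ts := NULL]
  data.table::setcolorder(linked, .schemas$events)
  report <- list(rows_in = nrow(ev), linked = nrow(linked),
                 near = sum(dropped$drop_class == "near"),
                 far = sum(dropped$drop_class == "far"),
                 near_window_hours = near_window_hours)
  list(events = linked[], dropped = dropped[], report = report)
}

#' Attach charge diagnoses to admissions
#'
#' Joins deduplicated charge records to admissions via the hospital account
#' id(s) carried through consolidation. An admission whose merged encounters
#' span several account ids receives the union of the matching charge
#' records' diagnosis codes. Admissions without a matching charge are
#' flagged (\code{has_charges == FALSE}), never dropped; orphan charges
#' (no admission) are counted in the report.
#'
#' @param admissions consolidated \code{admissions} table.
#' @param charges deduplicated inpatient \code{charges} table.
#' @return \code{admissions} \code{data.table} with \code{diagnosis_codes}
#'   and \code{has_charges} columns; report in attribute \code{"report"}.
#' @export
attach_charges <- function(admissions, charges) {
  adm <- data.table::as.data.table(admissions)
  ch <- data.table::as.data.table(charges)
  stop_missing_cols(adm, c("admission_id", "hospital_account_ids"), "admissions")
  stop_missing_cols(ch, c("hospital_account_id", "diagnosis_codes"), "charges")
  long <- adm[, .(hospital_account_id = unlist(split_ids(hospital_account_ids))),
              by = admission_id]
  m <- merge(long, ch[, .(hospital_account_id, diagnosis_codes)],
             by = "hospital_account_id")
  diag <- m[, .(diagnosis_codes = paste(sort(unique(unlist(split_ids(diagnosis_codes)))),
                                        collapse = ";")), by = admission_id]
  if ("diagnosis_codes" %in% names(adm)) adm[, diagnosis_codes := NULL]
  out <- merge(adm, diag, by = "admission_id", all.x = TRUE)
  out[is.na(diagnosis_codes), diagnosis_codes := ""]
  out[, has_charges := nzchar(diagnosis_codes)]
  orphan <- setdiff(ch$hospital_account_id, long$hospital_account_id)
  data.table::setorder(out, patient_id, start)
  report <- list(admissions = nrow(out),
                 with_charges = sum(out$has_charges),
                 without_charges = sum(!out$has_charges),
                 orphan_charges = length(orphan))
  data.table::setattr(out, "report", report)
  out[]
}
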