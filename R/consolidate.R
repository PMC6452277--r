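#' Deterministic admission identifier
#'
#' Admissions are identified by the patient id plus the admission start
#' instant, so re-runs on the same inputs always produce the same ids.
#'
#' @param patient_id character vector.
#' @param start POSIXct vector of admission starts.
#' @return character vector of admission ids.
#' @export
make_admission_id <- function(patient_id, start) {
  paste(patient_id, format(start, "%Y%m%dT%H%M%S", tz = .ipplog_tz), sep = "_")
}

# Core interval-merging sweep shared by the overlap and adjacency passes:
# within each patient, sort by interval start and open a new component
# whenever the start exceeds the running max end by more than `gap_sec`.
# gap_sec = 0 merges exactly the connected components of the interval-overlap
# graph (touching endpoints overlap); gap_sec = 4*3600 additionally merges
# near-adjacent intervals.
merge_intervals <- function(dt, gap_sec) {
  dt <- data.table::copy(dt)
  data.table::setorder(dt, patient_id, lo, hi)
  dt[, comp := {
    run_hi <- cummax(data.table::shift(cummax(hi), fill = -Inf))
    cumsum(lo > run_hi + gap_sec)
  }, by = patient_id]
  dt
}

adt_to_intervals <- function(encounters) {
  enc <- data.table::as.data.table(encounters)
  stop_missing_cols(enc, c("patient_id", "encounter_id", "admit", "discharge"),
                    "encounters")
  if (any(enc$admit > enc$discharge)) {
    stop("encounter with admit > discharge", call. = FALSE)
  }
  enc[, `:=`(lo = as_epoch(admit), hi = as_epoch(discharge))]
  enc
}

intervals_to_admissions <- function(dt) {
  has_hai <- "hospital_account_id" %in% names(dt)
  adm <- dt[, .(
    start = epoch_to_ts(min(lo)),
    end = epoch_to_ts(max(hi)),
    source_encounter_ids = join_ids(list(encounter_id)),
    hospital_account_ids = if (has_hai) join_ids(list(hospital_account_id)) else ""
  ), by = .(patient_id, comp)]
  adm[, admission_id := make_admission_id(patient_id, start)]
  adm[, comp := NULL]
  data.table::setcolorder(adm, .schemas$admissions)
  data.table::setorder(adm, patient_id, start)
  adm[]
}

#' Merge overlapping raw encounters into admissions
#'
#' A patient can accumulate several raw ADT encounters for one continuous
#' stay (for example an inpatient admission plus a procedure admission at a
#' sister facility, yielding multiple admissions but a single discharge).
#' This pass merges the connected components of the interval-overlap graph:
#' each output admission spans \code{min(admit)} to \code{max(discharge)} of
#' its component, and every encounter id appears in exactly one admission.
#'
#' @param encounters \code{adt}-schema table (any number of patients).
#' @return \code{admissions}-schema \code{data.table}.
#' @export
merge_overlapping <- function(encounters) {
  intervals_to_admissions(merge_intervals(adt_to_intervals(encounters), gap_sec = 0))
}

#' Merge near-adjacent admissions
#'
#' Transfers between facilities surface as a discharge followed by a new
#' admission a short time later. Consecutive admissions whose gap
#' (next start minus previous end) is at most \code{gap_hours} are merged,
#' applied transitively to a fixed point; a gap of exactly \code{gap_hours}
#' merges (inclusive reading of "within"). Source encounter ids and hospital
#' account ids are unioned.
#'
#' @param admissions \code{admissions}-schema table, pairwise non-overlapping
#'   within patient.
#' @param gap_hours non-negative merge threshold in hours (default 4).
#' @return \code{admissions}-schema \code{data.table}.
#' @export
merge_adjacent <- function(admissions, gap_hours = 4) {
  if (gap_hours < 0) stop("gap_hours must be non-negative", call. = FALSE)
  adm <- data.table::as.data.table(admissions)
  stop_missing_cols(adm, c("patient_id", "start", "end", "source_encounter_ids"),
                    "admissions")
  if (!"hospital_account_ids" %in% names(adm)) adm[, hospital_account_ids := ""]
  dt <- adm[, .(patient_id,
                encounter_id = split_ids(source_encounter_ids),
                hospital_account_id = split_ids(hospital_account_ids),
                lo = as_epoch(start), hi = as_epoch(end))]
  merged <- merge_intervals(dt, gap_sec = gap_hours * 3600)
  # re-flatten the id list-columns before aggregating
  out <- merged[, .(
    start = epoch_to_ts(min(lo)),
    end = epoch_to_ts(max(hi)),
    source_encounter_ids = paste(sort(unique(unlist(encounter_id))), collapse = ";"),
    hospital_account_ids = {
      v <- unlist(hospital_account_id)
      paste(sort(unique(v[nzchar(v)])), collapse = ";")
    }
  ), by = .(patient_id, comp)]
  out[, admission_id := make_admission_id(patient_id, start)]
  out[, comp := NULL]
  data.table::setcolorder(out, .schemas$admissions)
  data.table::setorder(out, patient_id, start)
  out[]
}

#' Consolidate raw ADT encounters into admissions
#'
#' Composition of \code{\link{merge_overlapping}} then
#' \code{\link{merge_adjacent}}: the result is a set of per-patient disjoint
#' continuous-care intervals in which every within-patient gap strictly
#' exceeds \code{gap_hours}. Idempotent, and conserves the multiset of
#' encounter ids. A consolidation report (input/output counts and the number
#' of encounters merged away) is attached as attribute \code{"report"}.
#'
#' @inheritParams merge_overlapping
#' @inheritParams merge_adjacent
#' @return \code{admissions}-schema \code{data.table}.
#' @export
consolidate_encounters <- function(encounters, gap_hours = 4) {
  if (gap_hours < 0) stop("gap_hours must be non-negative", call. = FALSE)
  # single sweep at the adjacency threshold: connected components of the
  # "overlapping or within gap_hours" relation, identical to
  # merge_adjacent(merge_overlapping(x)) but in one pass
  adm <- intervals_to_admissions(
    merge_intervals(adt_to_intervals(encounters), gap_sec = gap_hours * 3600))
  n_in <- nrow(data.table::as.data.table(encounters))
  report <- list(encounters_in = n_in, admissions_out = nrow(adm),
                 merged_away = n_in - nrow(adm), gap_hours = gap_hours)
  data.table::setattr(adm, "report", report)
  adm
}
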