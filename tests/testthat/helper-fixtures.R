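# Shared fixtures and independent oracles for the test suite.

ts <- function(x) as.POSIXct(x, tz = "UTC")

fcols <- paste0("freq_", c("education", "notes", "msg_check", "happening_soon",
                           "would_like", "mychart", "care_team", "vitals",
                           "msg_send"))

make_audit <- function(patient_id, action, timestamp, extended_info = NA_character_) {
  n <- max(length(patient_id), length(action), length(timestamp))
  data.frame(patient_id = rep(patient_id, length.out = n),
             action = rep(action, length.out = n),
             extended_info = rep(extended_info, length.out = n),
             timestamp = ts(rep(timestamp, length.out = n)),
             stringsAsFactors = FALSE)
}

make_adt <- function(patient_id, encounter_id, admit, discharge,
                     hospital_account_id = NA_character_,
                     encounter_class = "inpatient") {
  data.frame(patient_id = patient_id, encounter_id = encounter_id,
             hospital_account_id = hospital_account_id,
             admit = ts(admit), discharge = ts(discharge),
             encounter_class = encounter_class, stringsAsFactors = FALSE)
}

make_charges <- function(hospital_account_id, patient_id, admit, discharge,
                         diagnosis_codes = "I10", encounter_class = "inpatient") {
  data.frame(hospital_account_id = hospital_account_id, patient_id = patient_id,
             admit = ts(admit), discharge = ts(discharge),
             diagnosis_codes = diagnosis_codes,
             encounter_class = encounter_class, stringsAsFactors = FALSE)
}

# O(n^2) union-find oracle for interval consolidation: two raw encounters
# belong to one admission iff connected through pairwise
# overlap-or-gap-at-most-`gap_sec` relations.
brute_consolidate <- function(lo, hi, gap_sec) {
  n <- length(lo)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        gap <- max(lo[i], lo[j]) - min(hi[i], hi[j])
        if (gap <= gap_sec) parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), comp)
  out <- t(vapply(comps, function(idx) c(min(lo[idx]), max(hi[idx])), numeric(2)))
  out[order(out[, 1]), , drop = FALSE]
}

# O(n^2)-style brute-force sessionizer: scan sorted times and cut wherever
# the gap strictly exceeds the threshold.
brute_sessionize <- function(times, gap_sec) {
  tt <- sort(as.numeric(times))
  if (!length(tt)) return(integer(0))
  sess <- integer(length(tt))
  sess[1] <- 1L
  for (i in seq_along(tt)[-1]) {
    sess[i] <- sess[i - 1] + as.integer(tt[i] - tt[i - 1] > gap_sec)
  }
  sess
}

# Compare pipeline metrics at all three levels against the generator's
# ground truth, exactly. Returns character(0) when everything matches.
compare_to_truth <- function(res, truth) {
  bad <- character(0)
  eq <- function(a, b) identical(as.integer(a), as.integer(b))
  check_lvl <- function(p, t, label, extra = "n_sessions") {
    if (nrow(p) != nrow(t)) return(sprintf("%s: %d vs %d units", label, nrow(p), nrow(t)))
    out <- character(0)
    for (f in c(fcols, "comprehensiveness", extra)) {
      if (!eq(p[[paste0(f, ".p")]], p[[paste0(f, ".t")]]))
        out <- c(out, sprintf("%s: %s mismatch", label, f))
    }
    out
  }
  pm <- merge(as.data.frame(res$metrics$patient), truth$metrics$patient,
              by = "unit_id", suffixes = c(".p", ".t"))
  bad <- c(bad, check_lvl(pm, truth$metrics$patient, "patient"))
  am <- merge(as.data.frame(res$metrics$admission), truth$metrics$admission,
              by = "unit_id", suffixes = c(".p", ".t"))
  bad <- c(bad, check_lvl(am, truth$metrics$admission, "admission"))
  ps <- as.data.frame(res$metrics$session)
  ss <- as.data.frame(res$sessions)
  ps$start <- ss$start[match(ps$unit_id, ss$session_id)]
  ps$admission_id <- ss$admission_id[match(ps$unit_id, ss$session_id)]
  sm <- merge(ps, truth$metrics$session, by = c("admission_id", "start"),
              suffixes = c(".p", ".t"))
  bad <- c(bad, check_lvl(sm, truth$metrics$session, "session", extra = character(0)))
  bad
}

run_clean_pipeline <- function(audit, adt, charges = NULL, ...) {
  run_pipeline(audit, adt, charges,
               options = list(los_cap = Inf, min_group_size = 1, ...))
}
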