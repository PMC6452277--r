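#' Partition linked events into sessions
#'
#' A session is a maximal run of a patient's portal events with no
#' inactivity gap exceeding \code{gap_minutes}: within each
#' (patient, admission), a new session starts at the first event and
#' whenever the gap to the previous event strictly exceeds the threshold
#' (a gap of exactly \code{gap_minutes} stays in-session). The threshold
#' default of 15 minutes is a conservative reading of the institution's
#' 10-minute auto-logout, whose log markers are not reliable; login/logout
#' events therefore extend sessions but are never session delimiters by
#' themselves. Sessions never span admissions.
#'
#' A session's \code{zero_time} flag is \code{TRUE} iff it contains no
#' active task outside the Administrative category — the user logged in and
#' activated no function. Session duration is a diagnostic only
#' (\code{\link{session_diagnostics}}) and is never an engagement measure,
#' because zero-time sessions bias any duration-based metric.
#'
#' @param events linked \code{events}-schema table
#'   (\code{link_events()$events}).
#' @param gap_minutes non-negative inactivity threshold (default 15).
#' @return list with \code{sessions} (\code{sessions}-schema table) and
#'   \code{events} (input rows with \code{session_id} filled in).
#' @export
build_sessions <- function(events, gap_minutes = 15) {
  if (gap_minutes < 0) stop("gap_minutes must be non-negative", call. = FALSE)
  ev <- data.table::as.data.table(events)
  stop_missing_cols(ev, c("patient_id", "admission_id", "timestamp", "fn", "active"),
                    "events")
  data.table::setorder(ev, patient_id, admission_id, timestamp, action)
  gap_sec <- gap_minutes * 60
  ev[, new_sess := {
    gap <- as_epoch(timestamp) - data.table::shift(as_epoch(timestamp))
    is.na(gap) | gap > gap_sec
  }, by = .(patient_id, admission_id)]
  ev[, sess_seq := cumsum(new_sess), by = .(patient_id, admission_id)]
  ev[, session_id := sprintf("%s_s%03d", admission_id, sess_seq)]
  sessions <- ev[, .(
    patient_id = patient_id[1L],
    admission_id = admission_id[1L],
    start = min(timestamp),
    end = max(timestamp),
    event_count = .N,
    n_active_tasks = sum(active & fn != "Administrative")
  ), by = session_id]
  sessions[, zero_time := n_active_tasks == 0L]
  data.table::setcolorder(sessions, .schemas$sessions)
  data.table::setorder(sessions, patient_id, start)
  ev[, c("new_sess", "sess_seq") := NULL]
  data.table::setcolorder(ev, .schemas$events)
  list(sessions = sessions[], events = ev[])
}

#' Session-length diagnostics
#'
#' Histogram tables of session duration and per-session event counts, the
#' diagnostic used to visualize how retaining the 5-minute wallpaper
#' refresh artificially chains sessions (refreshes every 5 minutes can
#' never trip a 15-minute inactivity gap, so retaining them merges — never
#' splits — sessions). Compute it once on sessions built from cleaned
#' events and once with cleaning disabled to reproduce the contrast.
#'
#' @param sessions \code{sessions}-schema table.
#' @param duration_breaks_minutes bin edges in minutes for the duration
#'   histogram (right-open bins; last bin catches everything above).
#' @return list of two \code{data.table}s: \code{duration} (bin, count)
#'   and \code{events_per_session} (event count, sessions).
#' @export
session_diagnostics <- function(sessions,
                                duration_breaks_minutes = c(0, 1, 5, 10, 15, 30,
                                                            60, 120, 240, Inf)) {
  s <- data.table::as.data.table(sessions)
  if (!nrow(s)) {
    return(list(duration = data.table::data.table(bin = character(0), count = integer(0)),
                events_per_session = data.table::data.table(event_count = integer(0),
                                                            sessions = integer(0))))
  }
  dur_min <- (as_epoch(s$end) - as_epoch(s$start)) / 60
  bins <- cut(dur_min, breaks = duration_breaks_minutes, right = FALSE,
              include.lowest = TRUE)
  duration <- data.table::as.data.table(table(bin = bins))
  data.table::setnames(duration, c("bin", "count"))
  eps <- s[, .(sessions = .N), by = .(event_count)][order(event_count)]
  list(duration = duration[], events_per_session = eps[])
}
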