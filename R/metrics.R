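#' Calendar-day length of stay
#'
#' LOS is the calendar-date difference between discharge and admission, not
#' an hourly calculation: a patient admitted and discharged on the same
#' calendar day has LOS 0, and admission at 23:00 with discharge at 01:00
#' the next day has LOS 1.
#'
#' @param admissions \code{admissions}-schema table (or any table with
#'   \code{start} and \code{end} timestamps).
#' @return integer vector of LOS in days, one per admission.
#' @export
compute_los <- function(admissions) {
  adm <- data.table::as.data.table(admissions)
  stop_missing_cols(adm, c("start", "end"), "admissions")
  as.integer(as.Date(adm$end, tz = .ipplog_tz) - as.Date(adm$start, tz = .ipplog_tz))
}

#' Data-driven LOS cap from an a-priori minimum group size
#'
#' Long-stay outliers distort descriptive statistics, so the analysis keeps
#' only LOS values backed by enough patients: the cap is the largest
#' observed LOS \code{L} such that every observed LOS value up to \code{L}
#' has at least \code{min_group_size} admissions. Returns \code{-1} when
#' even the smallest observed LOS is under-populated (nothing passes the
#' filter). With \code{min_group_size = 1} the cap is the maximum observed
#' LOS.
#'
#' @param los integer vector of LOS values (one per admission), or an
#'   \code{admissions} table (LOS computed via \code{\link{compute_los}}).
#' @param min_group_size a-priori minimum patients per LOS value
#'   (default 30).
#' @return integer cap in days.
#' @export
compute_los_cap <- function(los, min_group_size = 30) {
  if (min_group_size < 1) stop("min_group_size must be >= 1", call. = FALSE)
  if (is.data.frame(los)) los <- compute_los(los)
  if (!length(los)) stop("no LOS values supplied", call. = FALSE)
  counts <- table(los)
  vals <- as.integer(names(counts))
  ok <- as.integer(counts) >= min_group_size
  first_bad <- which(!ok)[1L]
  if (is.na(first_bad)) return(max(vals))
  if (first_bad == 1L) return(-1L)
  vals[first_bad - 1L]
}

#' Assign provision days to linked events
#'
#' Tablets are provisioned after admission, so engagement is measured on
#' provision days rather than stay days. The extract has no provisioning
#' table; the provision date is inferred as the calendar date of the
#' admission's earliest audit event. An event's \code{provision_day} is its
#' calendar date minus the provision date (0-based); the admission's
#' \code{provisioning_day} is provision date minus admission date.
#'
#' @param events linked \code{events}-schema table.
#' @param admissions consolidated \code{admissions} table.
#' @return list with \code{events} (\code{provision_day} filled in),
#'   \code{contexts} (one row per admission with events: \code{admission_id},
#'   \code{patient_id}, \code{provision_date}, \code{los_days},
#'   \code{provisioning_day}), and \code{no_event_admissions} (ids of
#'   admissions without any linked event, which yield no context).
#' @export
assign_provision_days <- function(events, admissions) {
  ev <- data.table::as.data.table(events)
  adm <- data.table::as.data.table(admissions)
  stop_missing_cols(ev, c("admission_id", "timestamp"), "events")
  stop_missing_cols(adm, c("admission_id", "start", "end"), "admissions")
  prov <- ev[!is.na(admission_id),
             .(provision_date = min(as.Date(timestamp, tz = .ipplog_tz))),
             by = admission_id]
  ev[, provision_day := {
    pd <- prov$provision_date[match(admission_id, prov$admission_id)]
    as.integer(as.Date(timestamp, tz = .ipplog_tz) - pd)
  }]
  ctx <- merge(prov,
               adm[, .(admission_id, patient_id,
                       admit_date = as.Date(start, tz = .ipplog_tz),
                       los_days = compute_los(adm))],
               by = "admission_id")
  ctx[, provisioning_day := as.integer(provision_date - admit_date)]
  ctx[, admit_date := NULL]
  data.table::setcolorder(ctx, c("admission_id", "patient_id", "provision_date",
                                 "los_days", "provisioning_day"))
  list(events = ev[], contexts = ctx[],
       no_event_admissions = setdiff(adm$admission_id, prov$admission_id))
}

#' Column names of a metrics table
#' @return character vector: level, unit_id, patient_id, the nine
#'   \code{freq_*} columns, n_active_admin, comprehensiveness,
#'   pct_functions, n_sessions.
#' @export
metrics_schema <- function() {
  c("level", "unit_id", "patient_id", paste0("freq_", unname(.fn_keys)),
    "n_active_admin", "comprehensiveness", "pct_functions", "n_sessions")
}

#' Frequency and comprehensiveness of portal use
#'
#' For each unit at the chosen level of analysis (session, admission, or
#' patient — the patient level aggregates all use across that patient's
#' admissions), computes per-function \emph{frequency}: the count of active
#' tasks in each of the nine portal functions, restricted to the unit's
#' first \code{max_provision_day + 1} provision days (the main reporting
#' restriction uses the first 10 provision days of an admission; the
#' provision-day filter always applies per admission), and
#' \emph{comprehensiveness}: the number of the nine functions with
#' frequency > 0. Active Administrative tasks are tallied separately
#' (\code{n_active_admin}) and never count toward either measure.
#' \code{pct_functions} (= comprehensiveness / 9 * 100) and
#' \code{n_sessions} are carried as auxiliary columns.
#'
#' Units with no qualifying active tasks appear with all-zero frequencies,
#' so every session/admission/patient present in \code{sessions} is
#' represented.
#'
#' @param sessions \code{sessions}-schema table.
#' @param events session-annotated events (\code{build_sessions()$events})
#'   with \code{provision_day} assigned.
#' @param level \code{"session"}, \code{"admission"}, or \code{"patient"}.
#' @param max_provision_day last provision day (0-based) included
#'   (default 9, i.e. the first 10 provision days); \code{Inf} disables the
#'   restriction.
#' @return \code{data.table}, one row per unit, columns per
#'   \code{metrics_schema()}.
#' @export
compute_metrics <- function(sessions, events, level = c("session", "admission", "patient"),
                            max_provision_day = 9) {
  level <- match.arg(level)
  s <- data.table::as.data.table(sessions)
  ev <- data.table::as.data.table(events)
  stop_missing_cols(ev, c("session_id", "admission_id", "patient_id", "fn",
                          "active", "provision_day"), "events")
  key <- switch(level, session = "session_id", admission = "admission_id",
                patient = "patient_id")
  units <- s[, .(unit_id = get(key), patient_id, session_id)]
  units <- units[, .(n_sessions = data.table::uniqueN(session_id),
                     patient_id = patient_id[1L]), by = unit_id]
  act <- ev[active == TRUE & provision_day <= max_provision_day]
  act[, unit_id := get(key)]
  nonadmin <- act[fn != "Administrative"]
  freq <- if (nrow(nonadmin)) {
    data.table::dcast(nonadmin, unit_id ~ fn, value.var = "fn",
                      fun.aggregate = length)
  } else data.table::data.table(unit_id = character(0))
  admin <- act[fn == "Administrative", .(n_active_admin = .N), by = unit_id]
  out <- merge(units, freq, by = "unit_id", all.x = TRUE)
  out <- merge(out, admin, by = "unit_id", all.x = TRUE)
  for (f in .portal_functions) {
    col <- paste0("freq_", .fn_keys[[f]])
    if (f %in% names(out)) data.table::setnames(out, f, col) else out[, (col) := 0L]
    out[is.na(get(col)), (col) := 0L]
  }
  out[is.na(n_active_admin), n_active_admin := 0L]
  fcols <- paste0("freq_", unname(.fn_keys))
  out[, comprehensiveness := as.integer(rowSums(.SD > 0)), .SDcols = fcols]
  out[, pct_functions := comprehensiveness / 9 * 100]
  out[, level := level]
  data.table::setcolorder(out, metrics_schema())
  data.table::setorder(out, unit_id)
  out[]
}

#' Provisioning-delay by length-of-stay heatmap
#'
#' Cross-tabulates admissions by LOS (columns) and day of provisioning
#' (rows): cell counts plus percentages normalized within each LOS column.
#' If every patient were provisioned on the admission day, only the
#' provisioning-day-0 row would be populated; in practice provisioning lags
#' admission, which is why provision days — not stay days — anchor the
#' engagement measures.
#'
#' @param contexts provision contexts (\code{assign_provision_days()$contexts}).
#' @param max_los largest LOS column shown (default 10); admissions with
#'   larger LOS are excluded from the display.
#' @return list with matrices \code{counts} and \code{percent}
#'   (rows = provisioning day 0..max, cols = LOS 0..max_los).
#' @export
provisioning_heatmap <- function(contexts, max_los = 10) {
  ctx <- data.table::as.data.table(contexts)
  stop_missing_cols(ctx, c("los_days", "provisioning_day"), "contexts")
  ctx <- ctx[los_days <= max_los]
  days <- 0:max(c(ctx$provisioning_day, 0))
  los <- 0:max_los
  counts <- matrix(0L, nrow = length(days), ncol = length(los),
                   dimnames = list(provisioning_day = days, los = los))
  if (nrow(ctx)) {
    tab <- ctx[, .N, by = .(provisioning_day, los_days)]
    counts[cbind(match(tab$provisioning_day, days), match(tab$los_days, los))] <- tab$N
  }
  colsum <- colSums(counts)
  percent <- sweep(counts, 2, pmax(colsum, 1), "/") * 100
  percent[, colsum == 0] <- 0
  list(counts = counts, percent = percent)
}
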