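#' Default pipeline options
#'
#' All analysis thresholds live in one block so sensitivity re-runs are a
#' single override away: the encounter-merge gap (hours), the session
#' inactivity gap (minutes), the near/far diagnostic window (hours), the
#' provision-day restriction (0-based last day), the hard LOS cap (days)
#' and the a-priori minimum group size behind the data-driven LOS cap
#' (the stricter of the two caps wins).
#'
#' @return named list of defaults.
#' @export
pipeline_options <- function() {
  list(gap_hours = 4, session_gap_minutes = 15, near_window_hours = 24,
       max_provision_day = 9, los_cap = 30, min_group_size = 30,
       strict = FALSE, quantile_type = 7)
}

#' Run the full audit-log processing pipeline
#'
#' Executes the six stages in order: (1) consolidate raw ADT encounters
#' into admissions; (2) restrict and deduplicate hospital charges;
#' (3) clean and classify audit events; (4) link events to admissions and
#' attach charges; (5) sessionize; (6) assign provision days, apply the LOS
#' cap, and compute frequency/comprehensiveness at the session, admission,
#' and patient levels, plus summary tables and the provisioning heatmap.
#' Every stage's drop/merge/dedup counts are collected into a run manifest
#' that reconciles end-to-end conservation:
#' \code{rows_in = linked + near + far + removed + collapsed_logins + deduped}.
#'
#' @param audit audit table (\code{data.frame}) or CSV path.
#' @param adt ADT table or CSV path.
#' @param charges charges table, CSV path, or \code{NULL} to skip diagnosis
#'   attachment.
#' @param options list of thresholds overriding
#'   \code{\link{pipeline_options}} entries.
#' @param taxonomy,external_map overrides passed to
#'   \code{\link{clean_events}}.
#' @param schema_config reader schema config for CSV inputs.
#' @param out_dir if non-\code{NULL}, write all output tables and the
#'   manifest there.
#' @return list with \code{admissions}, \code{events} (linked, sessionized,
#'   provision days assigned), \code{sessions}, \code{contexts},
#'   \code{metrics} (list \code{session}/\code{admission}/\code{patient}),
#'   \code{summaries} (frequency and comprehensiveness tables per level),
#'   \code{heatmap}, \code{los_cap_applied}, and \code{manifest}.
#' @export
run_pipeline <- function(audit, adt, charges = NULL, options = list(),
                         taxonomy = NULL, external_map = NULL,
                         schema_config = NULL, out_dir = NULL) {
  opt <- pipeline_options()
  opt[names(options)] <- options
  stage <- "read inputs"
  res <- tryCatch({
    if (is.character(audit)) audit <- read_audit_log(audit, schema_config)
    if (is.character(adt)) adt <- read_adt(adt, schema_config)
    if (is.character(charges)) charges <- read_charges(charges, schema_config)

    stage <- "1: consolidate encounters"
    admissions <- consolidate_encounters(adt, gap_hours = opt$gap_hours)
    rep_consolidate <- attr(admissions, "report")

    stage <- "2: process charges"
    rep_charges <- NULL
    if (!is.null(charges)) {
      inpt <- filter_inpatient(charges, strict_class = opt$strict)
      ded <- dedupe_hospital_accounts(inpt)
      rep_charges <- list(filter = attr(inpt, "report"), dedupe = attr(ded, "report"))
      admissions <- attach_charges(admissions, ded)
      rep_charges$attach <- attr(admissions, "report")
    }

    stage <- "3: clean and classify events"
    cleaned <- clean_events(audit, taxonomy = taxonomy, external_map = external_map,
                            strict = opt$strict)
    rep_clean <- attr(cleaned, "report")

    stage <- "4: link events to admissions"
    linked <- link_events(cleaned, admissions, near_window_hours = opt$near_window_hours)

    stage <- "5: sessionize"
    built <- build_sessions(linked$events, gap_minutes = opt$session_gap_minutes)

    stage <- "6: provision days, LOS cap, metrics"
    prov <- assign_provision_days(built$events, admissions)
    events <- prov$events
    contexts <- prov$contexts
    los <- compute_los(admissions)
    data_cap <- if (nrow(admissions)) compute_los_cap(los, opt$min_group_size) else -1L
    # the data-driven cap targets the under-populated upper tail; if even the
    # smallest observed LOS is under-populated the rule is inapplicable and
    # only the hard cap binds (noted in the manifest)
    cap <- if (data_cap < 0) opt$los_cap else min(opt$los_cap, data_cap)
    keep_adm <- admissions$admission_id[los <= cap]
    sessions_kept <- built$sessions[admission_id %in% keep_adm]
    events_kept <- events[admission_id %in% keep_adm]
    contexts_kept <- contexts[admission_id %in% keep_adm]
    metrics <- lapply(setNames(nm = c("session", "admission", "patient")),
                      function(lv) compute_metrics(sessions_kept, events_kept, lv,
                                                   max_provision_day = opt$max_provision_day))
    summaries <- if (nrow(sessions_kept)) {
      list(
        frequency = lapply(metrics, summarize_frequency, quantile_type = opt$quantile_type),
        comprehensiveness = lapply(metrics, summarize_comprehensiveness)
      )
    }
    heatmap <- provisioning_heatmap(contexts_kept, max_los = max(min(cap, 10), 0))

    conservation <- list(
      rows_in = rep_clean$rows_in,
      removed = rep_clean$removed,
      collapsed_logins = rep_clean$collapsed_logins,
      deduped = rep_clean$deduped,
      linked = linked$report$linked,
      near_dropped = linked$report$near,
      far_dropped = linked$report$far,
      reconciled = rep_clean$rows_in ==
        linked$report$linked + linked$report$near + linked$report$far +
        rep_clean$removed + rep_clean$collapsed_logins + rep_clean$deduped
    )
    manifest <- list(
      options = opt,
      quantile_rule = sprintf("linear interpolation (R quantile type %d)", opt$quantile_type),
      stages = list(consolidate = rep_consolidate, charges = rep_charges,
                    clean = rep_clean, link = linked$report),
      los_cap = list(hard_cap = opt$los_cap, data_driven_cap = data_cap,
                     applied = cap,
                     admissions_excluded = sum(los > cap)),
      no_event_admissions = length(prov$no_event_admissions),
      conservation = conservation,
      n = list(admissions = nrow(admissions), sessions = nrow(built$sessions),
               sessions_analyzed = nrow(sessions_kept),
               patients = data.table::uniqueN(sessions_kept$patient_id))
    )
    manifest$config_hash <- hash_object(list(opt, manifest$n, conservation))

    list(admissions = admissions, events = events_kept, sessions = sessions_kept,
         all_sessions = built$sessions, contexts = contexts_kept,
         dropped_events = linked$dropped, metrics = metrics,
         summaries = summaries, heatmap = heatmap, los_cap_applied = cap,
         manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage [%s]: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(res$admissions, file.path(out_dir, "admissions.csv"))
    write_table(res$sessions, file.path(out_dir, "sessions.csv"))
    write_table(res$events, file.path(out_dir, "events.csv"))
    write_table(res$contexts, file.path(out_dir, "provision_contexts.csv"))
    for (lv in names(res$metrics)) {
      write_table(res$metrics[[lv]], file.path(out_dir, sprintf("metrics_%s.csv", lv)))
      if (!is.null(res$summaries)) {
        write_table(res$summaries$frequency[[lv]],
                    file.path(out_dir, sprintf("summary_frequency_%s.csv", lv)))
        write_table(res$summaries$comprehensiveness[[lv]],
                    file.path(out_dir, sprintf("summary_comprehensiveness_%s.csv", lv)))
      }
    }
    write.csv(res$heatmap$counts, file.path(out_dir, "heatmap_counts.csv"))
    write.csv(res$heatmap$percent, file.path(out_dir, "heatmap_percent.csv"))
    write_report(res$manifest, file.path(out_dir, "manifest.json"))
  }
  res
}

# Stable content hash for the run manifest: serialize to canonical JSON and
# md5 the bytes (via a temp file; tools::md5sum is file-based).
hash_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Frequency summary table (median / IQR / min / max per function)
#'
#' One row per portal function with the median, first and third quartiles,
#' IQR (Q3 - Q1), minimum and maximum of per-unit frequency at the metrics
#' table's level. Quartiles use R's linear-interpolation rule
#' (\code{quantile} type 7) by default; the rule is recorded in the run
#' manifest.
#'
#' @param metrics output of \code{\link{compute_metrics}}.
#' @param quantile_type passed to \code{\link[stats]{quantile}}.
#' @return \code{data.table}: function, median, q1, q3, iqr, min, max.
#' @export
summarize_frequency <- function(metrics, quantile_type = 7) {
  m <- data.table::as.data.table(metrics)
  if (!nrow(m)) stop("empty metrics table", call. = FALSE)
  rows <- lapply(.portal_functions, function(f) {
    v <- m[[paste0("freq_", .fn_keys[[f]])]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = quantile_type, names = FALSE)
    data.table::data.table(fn = f, median = q[2], q1 = q[1], q3 = q[3],
                           iqr = q[3] - q[1], min = min(v), max = max(v))
  })
  data.table::rbindlist(rows)
}

#' Comprehensiveness distribution table
#'
#' Counts and percentages of units by number of distinct portal functions
#' used (0-9). Percentages sum to 100 within rounding.
#'
#' @param metrics output of \code{\link{compute_metrics}}.
#' @return \code{data.table}: n_functions (0-9), count, pct.
#' @export
summarize_comprehensiveness <- function(metrics) {
  m <- data.table::as.data.table(metrics)
  counts <- table(factor(m$comprehensiveness, levels = 0:9))
  out <- data.table::data.table(
    n_functions = 0:9,
    count = as.integer(counts),
    pct = if (nrow(m)) as.numeric(counts) / nrow(m) * 100 else rep(0, 10)
  )
  out[]
}
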