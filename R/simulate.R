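#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults describe a
#' plausible inpatient-portal cohort: log-normal stay durations (median ~4
#' days), provisioning usually on the admission day or the day after,
#' negative-binomial daily session counts, and a function-use profile in
#' which care-team viewing and the daily schedule dominate while secure
#' messages are rarely sent. Artifact rates are all zero by default
#' (\code{\link{corrupt_tables}} injects them separately).
#'
#' @param n_patients number of patients (>= 1).
#' @param seed integer seed; all generator randomness derives from it.
#' @param los_meanlog,los_sdlog log-normal parameters of the continuous
#'   stay duration in days.
#' @param multi_admission_prob probability a patient has a second admission.
#' @param provisioning_delay_probs named probability vector over delay days
#'   (names "0","1",...) from admission to tablet provisioning.
#' @param sessions_per_day_size,sessions_per_day_mu negative-binomial
#'   (size, mu) for sessions per provision day (capped at 8/day; at least
#'   one session is forced on the provision day).
#' @param events_per_session_lambda Poisson mean of task events per session
#'   beyond the opening login (capped at 8).
#' @param function_use_probs named probability vector over the nine portal
#'   functions plus \code{Administrative}, used to draw each task event.
#' @param artifact_rates named rates in [0,1] for
#'   \code{wallpaper}, \code{sequential_login}, \code{dup_timestamp},
#'   \code{stray_event}, \code{transfer_split}, \code{dup_account}.
#' @param max_provision_day provision-day restriction used for the
#'   ground-truth metrics (default 9).
#' @return validated config list of class \code{ipplog_sim_config}.
#' @export
sim_config <- function(n_patients = 500,
                       seed = 1,
                       los_meanlog = log(4),
                       los_sdlog = 0.6,
                       multi_admission_prob = 0.15,
                       provisioning_delay_probs = c("0" = 0.55, "1" = 0.25,
                                                    "2" = 0.10, "3" = 0.06,
                                                    "4" = 0.04),
                       sessions_per_day_size = 1.5,
                       sessions_per_day_mu = 2,
                       events_per_session_lambda = 3,
                       function_use_probs = c(
                         "Review current care team"      = 0.20,
                         "Happening soon"                = 0.20,
                         "Review vitals and lab results" = 0.12,
                         "Check secure messages"         = 0.10,
                         "Access educational materials"  = 0.10,
                         "Access personal notes"         = 0.07,
                         "I would like"                  = 0.06,
                         "MyChart Ambulatory"            = 0.05,
                         "Send a secure message"         = 0.02,
                         "Administrative"                = 0.08),
                       artifact_rates = c(wallpaper = 0, sequential_login = 0,
                                          dup_timestamp = 0, stray_event = 0,
                                          transfer_split = 0, dup_account = 0),
                       max_provision_day = 9) {
  stopifnot(n_patients >= 1, los_sdlog > 0,
            abs(sum(provisioning_delay_probs) - 1) < 1e-8,
            abs(sum(function_use_probs) - 1) < 1e-8,
            all(artifact_rates >= 0 & artifact_rates <= 1))
  if (!all(names(function_use_probs) %in% .all_functions)) {
    stop("function_use_probs names must be portal functions or Administrative",
         call. = FALSE)
  }
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              los_meanlog = los_meanlog, los_sdlog = los_sdlog,
              multi_admission_prob = multi_admission_prob,
              provisioning_delay_probs = provisioning_delay_probs,
              sessions_per_day_size = sessions_per_day_size,
              sessions_per_day_mu = sessions_per_day_mu,
              events_per_session_lambda = events_per_session_lambda,
              function_use_probs = function_use_probs,
              artifact_rates = artifact_rates,
              max_provision_day = max_provision_day)
  class(cfg) <- "ipplog_sim_config"
  cfg
}

# Drawable task actions: keep-disposition rows of the default taxonomy,
# excluding Login/logout (opening logins are generated explicitly, and a
# randomly drawn mid-run login would itself constitute the sequential-login
# artifact the clean path must not contain).
.sim_action_pool <- function() {
  tax <- default_taxonomy()
  tax[disposition == "keep" & raw_action != "Login/logout"]
}

#' Simulate a raw inpatient-portal extract with ground truth
#'
#' Generates the three raw input tables (audit log, ADT, charges) for a
#' seeded synthetic cohort, together with the ground truth the pipeline
#' should recover: true admissions, true session boundaries, and true
#' frequency/comprehensiveness at the session, admission, and patient
#' levels. With all artifact rates zero the generated tables are clean:
#' one ADT encounter and one charge row per admission, strictly increasing
#' within-patient event times, intra-session gaps of 10-90 s and
#' inter-session gaps over an hour, so the 15-minute session boundary is
#' unambiguous. Artifacts are injected afterwards by
#' \code{\link{corrupt_tables}}.
#'
#' Ground-truth metrics are tallied directly from the generator's internal
#' per-event labels (true session membership is known by construction)
#' using base-R aggregation — an independent path from the pipeline's.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{audit}, \code{adt}, \code{charges} tables and
#'   \code{truth} (list: \code{admissions}, \code{sessions}, \code{events},
#'   \code{metrics} at the three levels, \code{config}).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "ipplog_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  pool <- .sim_action_pool()
  fn_probs <- config$function_use_probs

  patients <- sprintf("P%05d", seq_len(n))
  n_adm <- 1L + stats::rbinom(n, 1L, config$multi_admission_prob)
  adm <- data.table::data.table(
    patient_id = rep(patients, n_adm),
    adm_idx = sequence(n_adm)
  )
  # first admissions anchored on random 2014-2015 dates at ~08:00
  first <- adm$adm_idx == 1L
  base_date <- as.Date("2014-01-15") + sample(0:640, n, replace = TRUE)
  jitter1 <- sample(0:1800, n, replace = TRUE)
  los_cont <- stats::rlnorm(nrow(adm), config$los_meanlog, config$los_sdlog)
  admit <- rep(epoch_to_ts(NA_real_), nrow(adm))
  admit[first] <- as.POSIXct(paste(base_date, "08:00:00"), tz = .ipplog_tz) + jitter1
  # second resolution throughout: stays are rounded down to whole seconds
  discharge <- admit + floor(los_cont * 86400)
  # second admissions start 10-60 days after the first discharge
  second <- which(adm$adm_idx == 2L)
  if (length(second)) {
    prev <- match(adm$patient_id[second], adm$patient_id)  # first admission row
    gap_days <- sample(10:60, length(second), replace = TRUE)
    jitter2 <- sample(0:1800, length(second), replace = TRUE)
    admit[second] <- as.POSIXct(paste(as.Date(discharge[prev], tz = .ipplog_tz) + gap_days,
                                      "08:00:00"), tz = .ipplog_tz) + jitter2
    discharge[second] <- admit[second] + floor(los_cont[second] * 86400)
  }
  adm[, `:=`(admit = admit, discharge = discharge,
             encounter_id = sprintf("E%06d", .I),
             hospital_account_id = sprintf("H%06d", .I))]
  adm[, admission_id := make_admission_id(patient_id, admit)]

  # provisioning delay, clamped into the stay
  los_cal <- as.integer(as.Date(adm$discharge, tz = .ipplog_tz) -
                          as.Date(adm$admit, tz = .ipplog_tz))
  delay <- sample(as.integer(names(config$provisioning_delay_probs)), nrow(adm),
                  replace = TRUE, prob = config$provisioning_delay_probs)
  adm[, provision_date := as.Date(admit, tz = .ipplog_tz) + pmin(delay, los_cal)]

  # provision-day expansion and per-day session counts
  days <- adm[, .(day = 0:(as.integer(as.Date(discharge, tz = .ipplog_tz) -
                                        provision_date))),
              by = .(patient_id, admission_id, provision_date, admit, discharge)]
  days[, n_sess := pmin(stats::rnbinom(.N, size = config$sessions_per_day_size,
                                       mu = config$sessions_per_day_mu), 8L)]
  days[day == 0L, n_sess := pmax(n_sess, 1L)]
  days <- days[n_sess > 0L]

  # session slots: an 80-minute grid from 08:30 with up to 5 min of jitter,
  # so inter-session gaps are always > 60 min and the 15-min rule is clean
  sess <- days[, .(slot = sort(sample(0:7, n_sess))),
               by = .(patient_id, admission_id, provision_date, admit, discharge, day)]
  sess[, start := as.POSIXct(paste(provision_date + day, "08:30:00"), tz = .ipplog_tz) +
         slot * 4800 + sample(0:300, .N, replace = TRUE)]
  # sessions must fit inside the admission (longest session is under 15 min)
  sess <- sess[start >= admit + 60 & start + 900 <= discharge]
  sess[, session_uid := sprintf("%s_t%04d", admission_id, seq_len(.N)), by = admission_id]

  # events: an opening login plus task events with 10-90 s gaps. Every clean
  # session carries at least one task: a pure-login session is byte-for-byte
  # the sequential-login artifact, which only corrupt_tables() may inject.
  # Zero-time sessions still arise whenever all drawn tasks are inactive.
  sess[, n_tasks := 1L + pmin(stats::rpois(.N, config$events_per_session_lambda), 7L)]
  tasks <- sess[rep(seq_len(.N), n_tasks)]
  if (nrow(tasks)) {
    tasks[, gap := sample(10:90, .N, replace = TRUE)]
    tasks[, ts := start + cumsum(gap), by = session_uid]
    drawn_fn <- sample(names(fn_probs), nrow(tasks), replace = TRUE, prob = fn_probs)
    tasks[, fn := drawn_fn]
    tasks[, action := {
      acts <- pool[fn == .BY$fn, raw_action]
      acts[sample.int(length(acts), .N, replace = TRUE)]
    }, by = fn]
    tasks[, active := pool$active[match(action, pool$raw_action)]]
  }
  logins <- sess[, .(patient_id, admission_id, session_uid, ts = start,
                     action = "Login/logout", fn = "Administrative", active = FALSE)]
  events <- data.table::rbindlist(list(
    logins,
    if (nrow(tasks)) tasks[, .(patient_id, admission_id, session_uid, ts,
                               action, fn, active)]
  ), use.names = TRUE)
  data.table::setorder(events, patient_id, ts, action)

  audit <- events[, .(patient_id, action, extended_info = NA_character_,
                      timestamp = ts)]
  adt <- adm[, .(patient_id, encounter_id, hospital_account_id,
                 admit, discharge, encounter_class = "inpatient")]
  diag_pool <- c("I10", "E11.9", "J18.9", "N39.0", "K35.80", "O80", "I21.4")
  charges <- adm[, .(hospital_account_id, patient_id, admit, discharge,
                     diagnosis_codes = vapply(seq_len(.N), function(i)
                       paste(sort(sample(diag_pool, sample(1:3, 1))), collapse = ";"),
                       character(1)),
                     encounter_class = "inpatient")]

  truth <- build_ground_truth(adm, events, config)
  list(audit = audit[], adt = adt[], charges = charges[], truth = truth)
}

# Ground truth tallied with base-R aggregation over the generator's internal
# labels; unit keys are (admission_id, start) for sessions, admission_id, and
# patient_id, so pipeline output can be joined back without sharing id logic
# beyond the deterministic admission id.
build_ground_truth <- function(adm, events, config) {
  ev <- as.data.frame(events)
  ev$date <- as.Date(ev$ts, tz = .ipplog_tz)
  # provision date := date of the admission's earliest surviving event
  prov <- aggregate(date ~ admission_id, ev, min)
  names(prov)[2] <- "provision_date"
  ev$provision_date <- prov$provision_date[match(ev$admission_id, prov$admission_id)]
  ev$provision_day <- as.integer(ev$date - ev$provision_date)

  sess_start <- aggregate(ts ~ session_uid, ev, min)
  sess_end <- aggregate(ts ~ session_uid, ev, max)
  sess_n <- aggregate(cbind(n = ts) ~ session_uid, ev, length)
  key <- ev[!duplicated(ev$session_uid),
            c("session_uid", "patient_id", "admission_id")]
  sessions <- Reduce(function(a, b) merge(a, b, by = "session_uid"),
                     list(key, sess_start, sess_end, sess_n))
  names(sessions)[match(c("ts.x", "ts.y", "n"), names(sessions))] <-
    c("start", "end", "event_count")
  act_nonadmin <- ev$active & ev$fn != "Administrative"
  n_active <- tapply(act_nonadmin, ev$session_uid, sum)
  sessions$n_active_tasks <- as.integer(n_active[sessions$session_uid])
  sessions$zero_time <- sessions$n_active_tasks == 0L
  sessions <- sessions[order(sessions$patient_id, sessions$start), ]

  keep <- act_nonadmin & ev$provision_day <= config$max_provision_day
  fe <- ev[keep, ]
  tally <- function(all_units, fe_units) {
    m <- matrix(0L, nrow = length(all_units), ncol = 9,
                dimnames = list(all_units, .portal_functions))
    if (nrow(fe)) {
      t0 <- table(fe_units, factor(fe$fn, levels = .portal_functions))
      m[rownames(t0), ] <- as.integer(t0)
    }
    df <- data.frame(unit_id = all_units, m, check.names = FALSE)
    colnames(df) <- c("unit_id", paste0("freq_", unname(.fn_keys[.portal_functions])))
    df$comprehensiveness <- as.integer(rowSums(m > 0))
    df
  }
  sm <- tally(sessions$session_uid, fe$session_uid)
  sm$admission_id <- sessions$admission_id[match(sm$unit_id, sessions$session_uid)]
  sm$start <- sessions$start[match(sm$unit_id, sessions$session_uid)]
  sm$n_sessions <- 1L
  am <- tally(sort(unique(sessions$admission_id)), fe$admission_id)
  am$patient_id <- sessions$patient_id[match(am$unit_id, sessions$admission_id)]
  am$n_sessions <- as.integer(table(sessions$admission_id)[am$unit_id])
  pm <- tally(sort(unique(sessions$patient_id)), fe$patient_id)
  pm$n_sessions <- as.integer(table(sessions$patient_id)[pm$unit_id])

  admissions <- adm[, .(patient_id, admission_id, start = admit, end = discharge,
                        encounter_id, hospital_account_id, provision_date)]
  list(admissions = admissions[], sessions = sessions, events = ev,
       metrics = list(session = sm, admission = am, patient = pm),
       config = config)
}
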