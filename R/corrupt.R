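#' Inject documented logging artifacts into a clean simulated extract
#'
#' Separates generation from corruption so each artifact type can be tested
#' in isolation. Given the output of \code{\link{simulate_cohort}} and a set
#' of rates, injects:
#' \describe{
#'   \item{wallpaper}{per selected admission, \emph{Get Wallpaper Data}
#'     page-refresh events at an exact 5-minute (300 s) cadence from the
#'     first session's start to the last session's end — spanning the real
#'     inter-session gaps, which is what chains sessions together when the
#'     action is not removed.}
#'   \item{sequential_login}{per selected session, 1-2 extra login events
#'     within seconds of the opening login, before any task event.}
#'   \item{dup_timestamp}{exact duplicates of selected non-login events
#'     (same patient, action, timestamp).}
#'   \item{stray_event}{out-of-encounter events per selected patient: a
#'     \emph{near} stray within 24 h after the last discharge and a
#'     \emph{far} stray more than 30 days after it.}
#'   \item{transfer_split}{selected ADT encounters split in two at an
#'     interior cut, either overlapping or separated by a gap under 4 h, as
#'     transfers between facilities appear in raw ADT.}
#'   \item{dup_account}{duplicate charge rows with the same hospital account
#'     id and diagnoses but shifted admission/discharge times.}
#' }
#' Every injected row is recorded in the returned ledger so cleaning and
#' drop reports can be reconciled against it exactly.
#'
#' @param sim output of \code{\link{simulate_cohort}}.
#' @param artifact_rates named rates in [0,1]; missing names default to 0.
#' @param seed seed for the injection randomness.
#' @return list with \code{audit}, \code{adt}, \code{charges} (corrupted)
#'   and \code{ledger} (named injection counts plus per-type detail).
#' @export
corrupt_tables <- function(sim, artifact_rates, seed = 1) {
  rates <- c(wallpaper = 0, sequential_login = 0, dup_timestamp = 0,
             stray_event = 0, transfer_split = 0, dup_account = 0)
  rates[names(artifact_rates)] <- artifact_rates
  stopifnot(all(rates >= 0 & rates <= 1))
  set.seed(seed)
  audit <- data.table::copy(data.table::as.data.table(sim$audit))
  adt <- data.table::copy(data.table::as.data.table(sim$adt))
  charges <- data.table::copy(data.table::as.data.table(sim$charges))
  sessions <- sim$truth$sessions
  ledger <- list()

  # wallpaper: 300-s cadence spanning the admission's whole active span
  if (rates[["wallpaper"]] > 0 && nrow(sessions)) {
    span <- data.table::as.data.table(sessions)[, .(
      lo = min(as_epoch(start)), hi = max(as_epoch(end))
    ), by = .(patient_id, admission_id)]
    pick <- span[runif(.N) < rates[["wallpaper"]]]
    wp <- pick[, .(timestamp = epoch_to_ts(seq(lo, hi, by = 300))),
               by = .(patient_id, admission_id)]
    ledger$wallpaper <- nrow(wp)
    if (nrow(wp)) {
      audit <- rbind(audit, wp[, .(patient_id, action = "Get Wallpaper Data",
                                   extended_info = NA_character_, timestamp)])
    }
  } else ledger$wallpaper <- 0L

  # sequential logins: extras 2-9 s after the opening login (generator task
  # gaps are >= 10 s, so extras always precede the first task event)
  if (rates[["sequential_login"]] > 0 && nrow(sessions)) {
    sel <- sessions[runif(nrow(sessions)) < rates[["sequential_login"]], ]
    if (nrow(sel)) {
      m <- sample(1:2, nrow(sel), replace = TRUE)
      extra <- data.table::data.table(
        patient_id = rep(sel$patient_id, m),
        start = rep(sel$start, m),
        off = unlist(lapply(m, function(k) cumsum(sample(2:4, k, replace = TRUE))))
      )
      ledger$sequential_login <- nrow(extra)
      audit <- rbind(audit, extra[, .(patient_id, action = "Login/logout",
                                      extended_info = NA_character_,
                                      timestamp = start + off)])
    } else ledger$sequential_login <- 0L
  } else ledger$sequential_login <- 0L

  # duplicate timestamps: exact copies of non-login rows
  if (rates[["dup_timestamp"]] > 0) {
    cand <- which(audit$action != "Login/logout")
    dup <- cand[runif(length(cand)) < rates[["dup_timestamp"]]]
    ledger$dup_timestamp <- length(dup)
    if (length(dup)) audit <- rbind(audit, audit[dup])
  } else ledger$dup_timestamp <- 0L

  # strays: relative to each selected patient's last discharge
  if (rates[["stray_event"]] > 0) {
    last <- data.table::as.data.table(sim$truth$admissions)[, .(
      last_end = max(as_epoch(end))), by = patient_id]
    near_sel <- last[runif(.N) < rates[["stray_event"]]]
    far_sel <- last[runif(.N) < rates[["stray_event"]]]
    near <- near_sel[, .(patient_id,
                         timestamp = epoch_to_ts(last_end +
                           sample(7200:72000, .N, replace = TRUE)))]
    far <- far_sel[, .(patient_id,
                       timestamp = epoch_to_ts(last_end + 86400 *
                         sample(31:300, .N, replace = TRUE)))]
    ledger$stray_near <- nrow(near)
    ledger$stray_far <- nrow(far)
    stray <- rbind(near, far)
    if (nrow(stray)) {
      audit <- rbind(audit, stray[, .(patient_id, action = "Get Care Team",
                                      extended_info = NA_character_, timestamp)])
    }
  } else {
    ledger$stray_near <- 0L
    ledger$stray_far <- 0L
  }

  # transfer splits: replace one encounter with two covering the same stay
  if (rates[["transfer_split"]] > 0) {
    elig <- which(as_epoch(adt$discharge) - as_epoch(adt$admit) > 6 * 3600)
    sel <- elig[runif(length(elig)) < rates[["transfer_split"]]]
    ledger$transfer_split <- length(sel)
    if (length(sel)) {
      lo <- as_epoch(adt$admit[sel]); hi <- as_epoch(adt$discharge[sel])
      cut <- lo + (0.2 + 0.6 * runif(length(sel))) * (hi - lo)
      overlap <- runif(length(sel)) < 0.5
      start2 <- ifelse(overlap, cut - 3600,
                       pmin(cut + sample(600:10800, length(sel), replace = TRUE),
                            hi - 60))
      part1 <- adt[sel][, `:=`(discharge = epoch_to_ts(cut),
                               encounter_id = paste0(encounter_id, "a"))]
      part2 <- adt[sel][, `:=`(admit = epoch_to_ts(start2),
                               encounter_id = paste0(encounter_id, "b"))]
      adt <- rbind(adt[-sel], part1, part2)
    }
  } else ledger$transfer_split <- 0L

  # duplicate hospital accounts: same id and diagnoses, shifted times
  if (rates[["dup_account"]] > 0) {
    dup <- which(runif(nrow(charges)) < rates[["dup_account"]])
    ledger$dup_account <- length(dup)
    if (length(dup)) {
      extra <- data.table::copy(charges[dup])
      shift <- sample(3600:172800, length(dup), replace = TRUE)
      extra[, `:=`(admit = admit + shift, discharge = discharge + shift)]
      charges <- rbind(charges, extra)
    }
  } else ledger$dup_account <- 0L

  data.table::setorder(audit, patient_id, timestamp, action)
  data.table::setorder(adt, patient_id, admit)
  data.table::setorder(charges, hospital_account_id, admit)
  list(audit = audit[], adt = adt[], charges = charges[], ledger = ledger)
}
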