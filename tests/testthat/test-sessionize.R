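# Build linked, classified events at given times inside one long admission.
linked_fixture <- function(times, patient = "P1", action = "Get Care Team") {
  adm <- consolidate_encounters(make_adt(patient, "E1", "2014-01-01 00:00:00",
                                         "2014-12-31 23:59:59"))
  ev <- clean_events(make_audit(patient, action, times))
  link_events(ev, adm)$events
}

test_that("a gap over 15 minutes splits a session; exactly 15 minutes does not", {
  ev <- linked_fixture(c("2014-01-01 10:00:00", "2014-01-01 10:10:00",
                         "2014-01-01 10:40:00"))
  out <- build_sessions(ev)
  expect_equal(nrow(out$sessions), 2L)
  expect_equal(sort(out$sessions$event_count), c(1L, 2L))
  # boundary: exactly 15:00 stays in-session, 15:01 splits
  ev2 <- linked_fixture(c("2014-01-01 10:00:00", "2014-01-01 10:15:00"))
  expect_equal(nrow(build_sessions(ev2)$sessions), 1L)
  ev3 <- linked_fixture(c("2014-01-01 10:00:00", "2014-01-01 10:15:01"))
  expect_equal(nrow(build_sessions(ev3)$sessions), 2L)
  expect_error(build_sessions(ev, gap_minutes = -2), "non-negative")
})

test_that("session boundaries match a brute-force gap scan on random streams", {
  set.seed(55)
  for (rep in 1:40) {
    n <- sample(2:200, 1)
    times <- ts("2014-02-01 00:00:00") + sort(sample(0:(3 * 86400), n))
    ev <- linked_fixture(format(times))
    out <- build_sessions(ev)
    oracle <- brute_sessionize(unique(times), 15 * 60)  # dedup collapses ties
    expect_equal(nrow(out$sessions), max(oracle))
    # per-session event counts agree with the oracle partition
    expect_equal(sort(out$sessions$event_count),
                 sort(unname(as.integer(table(oracle)))))
  }
})

test_that("sessions partition linked events and respect gap structure", {
  sim <- simulate_cohort(sim_config(n_patients = 50, seed = 12))
  res <- run_clean_pipeline(sim$audit, sim$adt, sim$charges)
  s <- res$sessions
  ev <- res$events
  expect_equal(sum(s$event_count), nrow(ev))
  expect_false(any(is.na(ev$session_id)))
  # within sessions gaps <= 15 min, between consecutive sessions > 15 min
  evdt <- data.table::as.data.table(ev)
  gaps_within <- evdt[, diff(as.numeric(sort(timestamp))), by = session_id]$V1
  if (length(gaps_within)) expect_true(all(gaps_within <= 900))
  sdt <- data.table::as.data.table(s)
  data.table::setorder(sdt, admission_id, start)
  btw <- sdt[, as.numeric(start[-1]) - as.numeric(end[-.N]), by = admission_id]$V1
  if (length(btw)) expect_true(all(btw > 900))
  # sessions never span admissions
  adm_of_sess <- evdt[, data.table::uniqueN(admission_id), by = session_id]$V1
  expect_true(all(adm_of_sess == 1L))
})

test_that("lowering the inactivity gap never decreases the session count", {
  sim <- simulate_cohort(sim_config(n_patients = 20, seed = 8))
  res <- run_clean_pipeline(sim$audit, sim$adt, sim$charges)
  counts <- vapply(c(60, 30, 15, 5, 1), function(g)
    nrow(build_sessions(res$events, gap_minutes = g)$sessions), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("zero-time sessions are exactly those without an active non-administrative task", {
  adm <- consolidate_encounters(make_adt("P1", "E1", "2014-01-01 00:00:00",
                                         "2014-01-10 00:00:00"))
  ev <- clean_events(make_audit(
    "P1",
    c("Login/logout", "Get health metrics",      # inactive only -> zero-time
      "Login/logout", "Get Care Team",           # active task   -> not zero-time
      "Login/logout", "Send MyChart email"),     # active Administrative -> zero-time
    c("2014-01-02 10:00:00", "2014-01-02 10:01:00",
      "2014-01-03 10:00:00", "2014-01-03 10:01:00",
      "2014-01-04 10:00:00", "2014-01-04 10:01:00")))
  out <- build_sessions(link_events(ev, adm)$events)
  s <- out$sessions[order(out$sessions$start)]
  expect_equal(s$zero_time, c(TRUE, FALSE, TRUE))
  expect_equal(s$n_active_tasks, c(0L, 1L, 0L))
})

test_that("retaining wallpaper refreshes merges sessions but never splits them", {
  sim <- simulate_cohort(sim_config(n_patients = 30, seed = 44))
  co <- corrupt_tables(sim, c(wallpaper = 0.6), seed = 6)
  keep_tax <- default_taxonomy()
  keep_tax[keep_tax$raw_action == "Get Wallpaper Data",
           c("fn", "active", "disposition")] <- list("Administrative", FALSE, "keep")
  cleaned <- run_clean_pipeline(co$audit, co$adt, co$charges)
  retained <- run_pipeline(co$audit, co$adt, co$charges,
                           options = list(los_cap = Inf, min_group_size = 1),
                           taxonomy = keep_tax)
  expect_lt(nrow(retained$sessions), nrow(cleaned$sessions))
  # the retained variant has strictly more long sessions
  dur <- function(s) as.numeric(s$end) - as.numeric(s$start)
  expect_gt(sum(dur(retained$sessions) > 3600), sum(dur(cleaned$sessions) > 3600))
})

test_that("session diagnostics bin durations and event counts, including degenerate input", {
  sim <- simulate_cohort(sim_config(n_patients = 10, seed = 2))
  res <- run_clean_pipeline(sim$audit, sim$adt, sim$charges)
  d <- session_diagnostics(res$sessions)
  expect_equal(sum(d$duration$count), nrow(res$sessions))
  expect_equal(sum(d$events_per_session$sessions), nrow(res$sessions))
  empty <- session_diagnostics(res$sessions[0, ])
  expect_equal(nrow(empty$events_per_session), 0L)
  one <- build_sessions(linked_fixture("2014-01-01 10:00:00"))
  d1 <- session_diagnostics(one$sessions)
  expect_equal(d1$duration$count[d1$duration$bin == "[0,1)"], 1L)
})
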