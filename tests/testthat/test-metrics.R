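test_that("length of stay is a calendar-day difference, never hourly", {
  adm <- data.frame(start = ts(c("2014-01-01 23:00:00", "2014-01-07 08:00:00",
                                 "2014-01-01 09:00:00")),
                    end = ts(c("2014-01-02 01:00:00", "2014-01-07 19:00:00",
                               "2014-01-04 07:00:00")))
  expect_equal(compute_los(adm), c(1L, 0L, 3L))
})

test_that("LOS cap follows the a-priori minimum group size", {
  # constructed count table {0:100, 1:80, 2:40, 3:10}
  los <- rep(c(0L, 1L, 2L, 3L), c(100, 80, 40, 10))
  expect_equal(compute_los_cap(los, min_group_size = 30), 2L)
  # brute-force check over every candidate cap
  brute <- max(Filter(function(L) {
    vals <- unique(los[los <= L])
    all(vapply(vals, function(v) sum(los == v), integer(1)) >= 30)
  }, sort(unique(los))))
  expect_equal(brute, 2L)
  expect_equal(compute_los_cap(los, min_group_size = 1), max(los))
  expect_equal(compute_los_cap(rep(0:5, each = 50), 30), 5L)
  expect_equal(compute_los_cap(rep(2L, 5), 30), -1L)
  expect_error(compute_los_cap(los, min_group_size = 0), ">= 1")
})

test_that("provision dates come from the first audit event, provision days are calendar offsets", {
  adm <- consolidate_encounters(make_adt("P1", "E1", "2014-01-01 07:00:00",
                                         "2014-01-09 12:00:00"))
  ev <- clean_events(make_audit("P1", "Get Care Team",
                                c("2014-01-03 22:00:00", "2014-01-05 03:00:00")))
  linked <- link_events(ev, adm)$events
  out <- assign_provision_days(linked, adm)
  ctx <- out$contexts
  expect_equal(ctx$provision_date, as.Date("2014-01-03"))
  expect_equal(ctx$provisioning_day, 2L)   # provisioned on the third day
  expect_equal(ctx$los_days, 8L)
  expect_equal(out$events$provision_day, c(0L, 2L))
  # admission without events yields no context but is flagged
  adm2 <- rbind(adm, consolidate_encounters(make_adt("P2", "E2",
                                                     "2014-02-01 08:00:00",
                                                     "2014-02-02 08:00:00")))
  out2 <- assign_provision_days(linked, adm2)
  expect_equal(length(out2$no_event_admissions), 1L)
})

test_that("frequency counts active non-administrative tasks and comprehensiveness counts functions", {
  adm <- consolidate_encounters(make_adt("P1", "E1", "2014-01-01 07:00:00",
                                         "2014-01-20 12:00:00"))
  ev <- clean_events(make_audit(
    "P1",
    c("Login/logout", "Get Care Team", "Get Care Team", "Get Care Team",
      "Get Menu Items", "Get health metrics", "Send MyChart email"),
    paste0("2014-01-02 10:0", 0:6, ":00")))
  linked <- link_events(ev, adm)$events
  built <- build_sessions(linked)
  evp <- assign_provision_days(built$events, adm)$events
  m <- compute_metrics(built$sessions, evp, "session")
  expect_equal(nrow(m), 1L)
  expect_equal(m$freq_care_team, 3L)
  expect_equal(sum(m[, setdiff(fcols, "freq_care_team"), with = FALSE]), 0L)
  expect_equal(m$comprehensiveness, 1L)
  # active Administrative tallied separately, inactive loads not at all
  expect_equal(m$n_active_admin, 1L)
  # a session of only logins and inactive loads scores zero everywhere
  ev0 <- clean_events(make_audit("P1", c("Login/logout", "Get health metrics"),
                                 c("2014-01-05 10:00:00", "2014-01-05 10:01:00")))
  l0 <- build_sessions(link_events(ev0, adm)$events)
  m0 <- compute_metrics(l0$sessions, assign_provision_days(l0$events, adm)$events,
                        "session")
  expect_equal(m0$comprehensiveness, 0L)
  expect_equal(sum(m0[, fcols, with = FALSE]), 0L)
})

test_that("patient comprehensiveness is the union over admissions", {
  # two admissions using disjoint function sets of sizes 2 and 3
  adm <- consolidate_encounters(make_adt(
    "P1", c("E1", "E2"), c("2014-01-01 07:00:00", "2014-03-01 07:00:00"),
    c("2014-01-05 12:00:00", "2014-03-05 12:00:00")))
  ev <- clean_events(make_audit(
    "P1",
    c("Get Care Team", "Load schedule",                        # admission 1
      "Get messages", "Save message", "Get lab result comments"), # admission 2
    c("2014-01-02 10:00:00", "2014-01-02 10:01:00",
      "2014-03-02 10:00:00", "2014-03-02 10:01:00", "2014-03-02 10:02:00")))
  built <- build_sessions(link_events(ev, adm)$events)
  evp <- assign_provision_days(built$events, adm)$events
  am <- compute_metrics(built$sessions, evp, "admission")
  pm <- compute_metrics(built$sessions, evp, "patient")
  expect_equal(sort(am$comprehensiveness), c(2L, 3L))
  expect_equal(pm$comprehensiveness, 5L)
  expect_equal(pm$n_sessions, 2L)
  # additivity: patient frequency = sum of admission frequencies
  expect_equal(unlist(pm[, fcols, with = FALSE]),
               colSums(am[, fcols, with = FALSE]), ignore_attr = TRUE)
})

test_that("the provision-day filter is monotone and bounded", {
  sim <- simulate_cohort(sim_config(n_patients = 60, seed = 17))
  res <- run_clean_pipeline(sim$audit, sim$adt, sim$charges)
  prev_total <- -1
  for (mpd in c(0, 2, 9, 29, Inf)) {
    m <- compute_metrics(res$sessions, res$events, "patient", max_provision_day = mpd)
    total <- sum(m[, fcols, with = FALSE])
    expect_gte(total, prev_total)
    prev_total <- total
    expect_true(all(m$comprehensiveness >= 0 & m$comprehensiveness <= 9))
  }
  # patient-level comprehensiveness >= max admission-level comprehensiveness
  am <- compute_metrics(res$sessions, res$events, "admission")
  pm <- compute_metrics(res$sessions, res$events, "patient")
  max_adm <- tapply(am$comprehensiveness, am$patient_id, max)
  expect_true(all(pm$comprehensiveness >= max_adm[pm$unit_id]))
})

test_that("the provisioning heatmap conserves counts and normalizes within LOS", {
  ctx <- data.frame(admission_id = sprintf("A%d", 1:6), patient_id = sprintf("P%d", 1:6),
                    provision_date = as.Date("2014-01-03"),
                    los_days = c(3L, 3L, 3L, 5L, 5L, 12L),
                    provisioning_day = c(0L, 1L, 1L, 0L, 2L, 0L))
  hm <- provisioning_heatmap(ctx, max_los = 10)
  expect_equal(sum(hm$counts), 5L)  # LOS 12 excluded by max_los
  expect_equal(unname(colSums(hm$counts)[c("3", "5")]), c(3L, 2L))
  expect_equal(unname(hm$percent["1", "3"]), 2 / 3 * 100)
  expect_true(all(abs(colSums(hm$percent)[colSums(hm$counts) > 0] - 100) < 1e-9))
  # everyone provisioned on admission day populates only row 0
  ctx0 <- transform(ctx, provisioning_day = 0L)
  hm0 <- provisioning_heatmap(ctx0, max_los = 10)
  expect_equal(sum(hm0$counts["0", ]), 5L)
  expect_equal(sum(hm0$counts) - sum(hm0$counts["0", ]), 0L)
  # single patient -> single 100% cell
  hm1 <- provisioning_heatmap(ctx[1, ], max_los = 10)
  expect_equal(sum(hm1$counts), 1L)
  expect_equal(max(hm1$percent), 100)
})
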