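test_that("the default taxonomy reproduces the published function/activity table", {
  tax <- default_taxonomy()
  lookup <- function(a) tax[tax$raw_action == a, ]
  expect_equal(lookup("Save message")$fn, "Send a secure message")
  expect_true(lookup("Save message")$active)
  expect_equal(lookup("Get patient notes")$fn, "Access personal notes")
  expect_false(lookup("Get patient notes")$active)
  expect_equal(lookup("Get Wallpaper Data")$disposition, "remove")
  expect_equal(lookup("Get Menu Items")$disposition, "remove")
  expect_equal(lookup("Get Provider")$disposition, "remove")
  expect_equal(lookup("Media/Web content")$disposition, "remap")
  expect_equal(lookup("Login/logout")$fn, "Administrative")
  expect_false(lookup("Login/logout")$active)
  expect_equal(lookup("Get Care Team")$fn, "Review current care team")
  # nine functions plus Administrative, every kept action classified
  kept <- tax[tax$disposition == "keep", ]
  expect_setequal(unique(kept$fn), c(portal_functions(), "Administrative"))
  expect_equal(length(portal_functions()), 9L)
  expect_false(anyDuplicated(tax$raw_action) > 0)
  # active/inactive split of the published table: 23 active, 13 inactive
  expect_equal(sum(kept$active), 23L)
  expect_equal(sum(!kept$active), 13L)
})

test_that("taxonomy configs load from CSV and reject duplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_table(default_taxonomy(), f)
  expect_equal(as.data.frame(load_taxonomy(f)), as.data.frame(default_taxonomy()))
  bad <- rbind(default_taxonomy(), default_taxonomy()[1, ])
  expect_error(load_taxonomy(bad), "duplicate")
})

test_that("system noise is removed and counted", {
  ev <- make_audit("P1",
                   c("Get Wallpaper Data", "Get Care Team", "Get Provider",
                     "Get Provider", "Get Menu Items", "Get messages"),
                   paste0("2014-01-01 10:0", 0:5, ":00"))
  out <- clean_events(ev)
  rep <- attr(out, "report")
  expect_equal(nrow(out), 2L)
  expect_equal(rep$removed, 4L)
  expect_equal(rep$removed_by_action$`Get Provider`, 2L)
  expect_false(any(out$action %in% c("Get Menu Items", "Get Provider",
                                     "Get Wallpaper Data")))
  expect_equal(sort(out$fn), c("Check secure messages", "Review current care team"))
})

test_that("a 5-minute wallpaper stream around sparse real actions cleans to the real actions", {
  wall_ts <- ts("2014-01-01 09:00:00") + seq(0, 3600, by = 300)
  real_ts <- ts("2014-01-01 09:07:00") + c(0, 600, 1800)
  ev <- rbind(
    make_audit("P1", "Get Wallpaper Data", format(wall_ts)),
    make_audit("P1", c("Get Care Team", "Get messages", "Save message"),
               format(real_ts))
  )
  out <- clean_events(ev)
  expect_equal(nrow(out), 3L)
  expect_equal(attr(out, "report")$removed, length(wall_ts))
})

test_that("sequential logins collapse to the earliest; separated logins survive", {
  ev <- make_audit("P1",
                   c("Login/logout", "Login/logout", "Login/logout",
                     "Get Care Team", "Login/logout"),
                   c("2014-01-01 10:00:00", "2014-01-01 10:00:30",
                     "2014-01-01 10:01:00", "2014-01-01 10:02:00",
                     "2014-01-01 10:03:00"))
  out <- clean_events(ev)
  rep <- attr(out, "report")
  expect_equal(nrow(out), 3L)  # first login + care team + later login
  expect_equal(rep$collapsed_logins, 2L)
  expect_equal(out$timestamp[1], ts("2014-01-01 10:00:00"))  # earliest kept
  expect_equal(rep$survivors + rep$removed + rep$collapsed_logins + rep$deduped,
               rep$rows_in)
})

test_that("identical (patient, action, timestamp) events reduce to one", {
  ev <- make_audit(c("P1", "P1", "P1", "P2"),
                   c("Get messages", "Get messages", "Get messages", "Get messages"),
                   c("2014-01-01 10:00:00", "2014-01-01 10:00:00",
                     "2014-01-01 10:00:05", "2014-01-01 10:00:00"))
  out <- clean_events(ev)
  expect_equal(nrow(out), 3L)  # same second for P2 is a different patient
  expect_equal(attr(out, "report")$deduped, 1L)
})

test_that("external Media/Web content is remapped through the extended-info code", {
  ev <- make_audit("P1",
                   c("Media/Web content", "Media/Web content", "Media/Web content"),
                   c("2014-01-01 10:00:00", "2014-01-01 10:01:00", "2014-01-01 10:02:00"),
                   extended_info = c("Welcome video", "Dining on demand", "UNKNOWN-CODE"))
  expect_warning(out <- clean_events(ev), "unmapped extended info")
  expect_equal(out$fn[out$action == "Welcome video"], "Access educational materials")
  expect_true(out$active[out$action == "Welcome video"])
  expect_equal(out$fn[out$action == "Dining on demand"], "Administrative")
  expect_true(out$active[out$action == "Dining on demand"])
  # unknown code routed to Administrative/inactive, or error under strict
  expect_equal(sum(out$fn == "Administrative" & !out$active), 1L)
  expect_error(clean_events(ev, strict = TRUE), "unmapped")
})

test_that("unmapped raw actions warn and route to Administrative (or fail under strict)", {
  ev <- make_audit("P1", c("Mystery Action", "Get Care Team"),
                   c("2014-01-01 10:00:00", "2014-01-01 10:01:00"))
  expect_warning(out <- clean_events(ev), "Mystery Action")
  expect_equal(out$fn[out$action == "Mystery Action"], "Administrative")
  expect_false(out$active[out$action == "Mystery Action"])
  expect_error(clean_events(ev, strict = TRUE), "Mystery Action")
})

test_that("cleaning output is independent of input row order", {
  set.seed(9)
  sim <- simulate_cohort(sim_config(n_patients = 20, seed = 21))
  co <- corrupt_tables(sim, c(dup_timestamp = 0.2, sequential_login = 0.3), seed = 4)
  a <- clean_events(co$audit)
  b <- clean_events(co$audit[sample(nrow(co$audit)), ])
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
})
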