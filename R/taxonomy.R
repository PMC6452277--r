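#' The nine portal functions
#'
#' Canonical names of the nine MyChart Bedside functions used for frequency
#' and comprehensiveness. \code{Administrative} is a tenth category for
#' system/navigational actions; it never counts toward either measure.
#'
#' @return character vector of length 9.
#' @export
portal_functions <- function() .portal_functions

.portal_functions <- c(
  "Access educational materials",
  "Access personal notes",
  "Check secure messages",
  "Happening soon",
  "I would like",
  "MyChart Ambulatory",
  "Review current care team",
  "Review vitals and lab results",
  "Send a secure message"
)

.all_functions <- c(.portal_functions, "Administrative")

# Short column-safe keys for the nine functions, used in wide metric tables.
.fn_keys <- c(
  "Access educational materials"  = "education",
  "Access personal notes"         = "notes",
  "Check secure messages"         = "msg_check",
  "Happening soon"                = "happening_soon",
  "I would like"                  = "would_like",
  "MyChart Ambulatory"            = "mychart",
  "Review current care team"      = "care_team",
  "Review vitals and lab results" = "vitals",
  "Send a secure message"         = "msg_send"
)

#' Default action taxonomy
#'
#' Maps every known raw audit-log action to a portal function, an
#' active/inactive flag, and a disposition:
#' \itemize{
#'   \item \code{keep}: a real user or background action, classified into one
#'     of the nine functions or Administrative, flagged active (intentionally
#'     initiated by the patient) or inactive (background load/refresh).
#'   \item \code{remove}: system-generated noise dropped outright —
#'     \emph{Get Menu Items} (pure navigation), \emph{Get Provider} (emitted
#'     once per care-team member every time the care team is viewed), and
#'     \emph{Get Wallpaper Data} (a page refresh firing every 5 minutes).
#'   \item \code{remap}: \emph{Media/Web content}, the catch-all the software
#'     logs for any remote internet call; re-labelled per event via the
#'     extended-info code and the external-action map.
#' }
#' Login/logout is retained as an inactive Administrative event: logins
#' extend sessions but never count as active tasks, since the log's
#' login/logout markers are not reliable delimiters of contiguous use.
#'
#' @return \code{data.table} with columns \code{raw_action}, \code{fn},
#'   \code{active}, \code{disposition}.
#' @export
default_taxonomy <- function() {
  e <- function(action, fn, active) list(action, fn, active, "keep")
  rows <- list(
    e("Get 1 patient-prescribed education title", "Access educational materials", TRUE),
    e("Update education status",                  "Access educational materials", TRUE),
    e("Get patient-prescribed education titles",  "Access educational materials", FALSE),
    e("Create patient note",   "Access personal notes", TRUE),
    e("Delete patient media",  "Access personal notes", TRUE),
    e("Delete patient note",   "Access personal notes", TRUE),
    e("Update patient note",   "Access personal notes", TRUE),
    e("Get patient notes",     "Access personal notes", FALSE),
    e("Identify user with lock",     "Administrative", TRUE),
    e("Make Bedside link",           "Administrative", TRUE),
    e("Send MyChart email",          "Administrative", TRUE),
    e("Accept terms and conditions", "Administrative", FALSE),
    e("Handshake",                   "Administrative", FALSE),
    e("Load terms and conditions",   "Administrative", FALSE),
    e("Set lock for user",           "Administrative", FALSE),
    e("Update photo for user",       "Administrative", FALSE),
    e("Login/logout",                "Administrative", FALSE),
    e("Get messages", "Check secure messages", TRUE),
    e("Create user-created event",             "Happening soon", TRUE),
    e("Delete user-created event",             "Happening soon", TRUE),
    e("Get appointment event detail",          "Happening soon", TRUE),
    e("Get medication administration details", "Happening soon", TRUE),
    e("Get surgery event detail",              "Happening soon", TRUE),
    e("Load schedule",                         "Happening soon", TRUE),
    e("Delete patient request", "I would like", TRUE),
    e("Save patient request",   "I would like", TRUE),
    e("Get patient requests",   "I would like", FALSE),
    e("Create MyChart account",    "MyChart Ambulatory", TRUE),
    e("Load MyChart info",         "MyChart Ambulatory", TRUE),
    e("Validate MyChart login",    "MyChart Ambulatory", FALSE),
    e("Validate MyChart password", "MyChart Ambulatory", FALSE),
    e("Get Care Team", "Review current care team", TRUE),
    e("Get lab result comments", "Review vitals and lab results", TRUE),
    e("Get health metrics",      "Review vitals and lab results", FALSE),
    e("Switch bedside admission","Review vitals and lab results", FALSE),
    e("Save message", "Send a secure message", TRUE),
    list("Get Menu Items",     NA_character_, NA, "remove"),
    list("Get Provider",       NA_character_, NA, "remove"),
    list("Get Wallpaper Data", NA_character_, NA, "remove"),
    list("Media/Web content",  NA_character_, NA, "remap")
  )
  tax <- data.table::rbindlist(lapply(rows, function(r) {
    data.table::data.table(raw_action = r[[1]], fn = r[[2]],
                           active = r[[3]], disposition = r[[4]])
  }))
  validate_taxonomy(tax)
}

validate_taxonomy <- function(tax) {
  tax <- data.table::as.data.table(tax)
  stop_missing_cols(tax, c("raw_action", "fn", "active", "disposition"), "taxonomy")
  if (anyDuplicated(tax$raw_action)) {
    stop("duplicate raw_action in taxonomy", call. = FALSE)
  }
  bad <- tax[disposition == "keep" & !(fn %in% .all_functions)]
  if (nrow(bad)) {
    stop(sprintf("taxonomy maps action(s) to unknown function: %s",
                 paste(bad$raw_action, collapse = ", ")), call. = FALSE)
  }
  if (!all(tax$disposition %in% c("keep", "remove", "remap"))) {
    stop("taxonomy disposition must be keep/remove/remap", call. = FALSE)
  }
  tax[]
}

#' Load an action taxonomy
#'
#' @param config \code{NULL} for the built-in default, or a CSV/YAML path
#'   with columns/fields \code{raw_action}, \code{fn}, \code{active},
#'   \code{disposition}.
#' @return validated taxonomy \code{data.table}.
#' @export
load_taxonomy <- function(config = NULL) {
  if (is.null(config)) return(default_taxonomy())
  if (is.data.frame(config)) return(validate_taxonomy(config))
  if (grepl("\\.ya?ml$", config)) {
    rows <- yaml::read_yaml(config)
    tax <- data.table::rbindlist(lapply(rows, data.table::as.data.table),
                                 fill = TRUE)
  } else {
    tax <- data.table::fread(config)
  }
  if ("active" %in% names(tax)) tax[, active := as.logical(active)]
  validate_taxonomy(tax)
}

#' Default external-action map
#'
#' The hospital exposes external tools (meal ordering, orientation videos,
#' tutorials) through the portal; the log records all of them as
#' \emph{Media/Web content}, distinguished only by the extended-info code.
#' Such events are re-labelled as specific active tasks. By default the four
#' educational items map to active tasks under \emph{Access educational
#' materials} and meal ordering (\emph{Dining on demand}) to an active
#' Administrative task; extended-info codes default to the label strings
#' themselves, and real site-specific codes can be supplied via
#' \code{\link{load_external_map}}.
#'
#' @return \code{data.table} with columns \code{extended_info_code},
#'   \code{label}, \code{mapped_action}, \code{mapped_fn}, \code{active}.
#' @export
default_external_map <- function() {
  labels <- c("Dining on demand", "Welcome video", "Getting started",
              "MCB patients' rights and responsibilities",
              "MCB patients' tutorial")
  fns <- c("Administrative", rep("Access educational materials", 4))
  data.table::data.table(
    extended_info_code = labels,
    label = labels,
    mapped_action = labels,
    mapped_fn = fns,
    active = TRUE
  )
}

#' Load an external-action map
#' @param config \code{NULL} for the default, a data.frame, or a CSV path
#'   with the columns of \code{\link{default_external_map}}.
#' @return validated \code{data.table}.
#' @export
load_external_map <- function(config = NULL) {
  if (is.null(config)) return(default_external_map())
  m <- if (is.data.frame(config)) data.table::as.data.table(config)
       else data.table::fread(config)
  stop_missing_cols(m, c("extended_info_code", "mapped_action", "mapped_fn",
                         "active"), "external map")
  if (anyDuplicated(m$extended_info_code)) {
    stop("duplicate extended_info_code in external map", call. = FALSE)
  }
  m[, active := as.logical(active)]
  m[]
}

#' Clean and classify raw audit-log events
#'
#' Applies the artifact-removal and classification rules, in order:
#' \enumerate{
#'   \item drop actions with disposition \code{remove} (menu navigation,
#'     per-care-team-member provider replication, 5-minute wallpaper
#'     refreshes);
#'   \item re-label \emph{Media/Web content} events via their extended-info
#'     code and the external-action map;
#'   \item collapse runs of consecutive login events for a patient with no
#'     intervening action to the earliest login of the run;
#'   \item reduce events identical in (patient, action, timestamp) to one;
#'   \item attach the function label and active flag to every survivor.
#' }
#' Events are first put in a canonical order (patient, timestamp, action,
#' extended info), so the output is independent of input row order. The
#' cleaning report (attribute \code{"report"}) conserves counts:
#' \code{survivors + removed + collapsed_logins + deduped = rows_in}.
#'
#' @param events \code{audit}-schema table.
#' @param taxonomy taxonomy table (default \code{\link{default_taxonomy}}).
#' @param external_map external-action map (default
#'   \code{\link{default_external_map}}).
#' @param login_action raw action string marking logins (default
#'   \code{"Login/logout"}).
#' @param strict if \code{TRUE}, an unmapped raw action or unmapped
#'   extended-info code is an error; otherwise such events are routed to
#'   Administrative/inactive with a warning and counted in the report.
#' @return \code{events}-schema \code{data.table} (admission/session columns
#'   still \code{NA}), with the cleaning report attached.
#' @export
clean_events <- function(events, taxonomy = NULL, external_map = NULL,
                         login_action = "Login/logout", strict = FALSE) {
  tax <- load_taxonomy(taxonomy)
  emap <- load_external_map(external_map)
  ev <- data.table::as.data.table(events)
  stop_missing_cols(ev, c("patient_id", "action", "timestamp"), "events")
  if (!"extended_info" %in% names(ev)) ev[, extended_info := NA_character_]
  ev <- ev[, .(patient_id, action, extended_info, timestamp)]
  data.table::setorder(ev, patient_id, timestamp, action, extended_info, na.last = TRUE)
  n_in <- nrow(ev)

  # (a) removals
  remove_actions <- tax[disposition == "remove", raw_action]
  removed_tab <- table(ev$action[ev$action %in% remove_actions])
  ev <- ev[!action %in% remove_actions]
  n_removed <- n_in - nrow(ev)

  # (b) external remap via extended info
  remap_actions <- tax[disposition == "remap", raw_action]
  ev[, `:=`(fn = NA_character_, active = NA)]
  is_remap <- ev$action %in% remap_actions
  n_unmapped_ext <- 0L
  if (any(is_remap)) {
    idx <- which(is_remap)
    m <- match(ev$extended_info[idx], emap$extended_info_code)
    hit <- !is.na(m)
    ev[idx[hit], `:=`(action = emap$mapped_action[m[hit]],
                      fn = emap$mapped_fn[m[hit]],
                      active = emap$active[m[hit]])]
    n_unmapped_ext <- sum(!hit)
    if (n_unmapped_ext > 0) {
      msg <- sprintf("%d external (Media/Web content) event(s) with unmapped extended info",
                     n_unmapped_ext)
      if (strict) stop(msg, call. = FALSE)
      warning(paste(msg, "- routed to Administrative/inactive"), call. = FALSE)
      ev[idx[!hit], `:=`(fn = "Administrative", active = FALSE)]
    }
  }
  n_remapped <- sum(is_remap) - n_unmapped_ext

  # (c) collapse sequential login runs (keep earliest of each run)
  ev[, is_login := action == login_action]
  ev[, login_run := {
    r <- rle(is_login)
    rep(seq_along(r$lengths), r$lengths)
  }, by = patient_id]
  keep <- ev[, .I[!is_login | seq_len(.N) == 1L], by = .(patient_id, login_run)]$V1
  n_collapsed <- nrow(ev) - length(keep)
  ev <- ev[sort(keep)]

  # (d) same-timestamp duplicate removal
  dup <- duplicated(ev, by = c("patient_id", "action", "timestamp"))
  n_deduped <- sum(dup)
  ev <- ev[!dup]

  # (e) classification of survivors not already labelled by the remap
  m <- match(ev$action, tax$raw_action)
  needs <- is.na(ev$fn)
  ev[needs & !is.na(m), `:=`(fn = tax$fn[m[needs & !is.na(m)]],
                             active = tax$active[m[needs & !is.na(m)]])]
  unmapped <- is.na(ev$fn)
  unmapped_actions <- sort(unique(ev$action[unmapped]))
  if (any(unmapped)) {
    msg <- sprintf("unmapped raw action(s): %s", paste(unmapped_actions, collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(paste(msg, "- routed to Administrative/inactive"), call. = FALSE)
    ev[unmapped, `:=`(fn = "Administrative", active = FALSE)]
  }

  ev[, `:=`(is_login = NULL, login_run = NULL,
            admission_id = NA_character_, provision_day = NA_integer_,
            session_id = NA_character_)]
  data.table::setcolorder(ev, .schemas$events)
  report <- list(rows_in = n_in, survivors = nrow(ev), removed = n_removed,
                 removed_by_action = as.list(removed_tab),
                 remapped = n_remapped, collapsed_logins = n_collapsed,
                 deduped = n_deduped,
                 unmapped_events = sum(unmapped) + n_unmapped_ext,
                 unmapped_actions = as.character(unmapped_actions))
  data.table::setattr(ev, "report", report)
  ev[]
}
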