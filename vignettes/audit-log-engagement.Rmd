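---
title: "From raw inpatient-portal audit logs to engagement metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw inpatient-portal audit logs to engagement metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipplog)
```

## The problem

Inpatient portals (bedside tablets offering schedules, lab results, care-team
information, secure messaging, education) log every user and system action
server-side as a triad: a de-identified patient id, an activity code, and a
second-resolution timestamp, optionally augmented by an extended-info code.
These logs were built for operations, and measuring patient engagement from
them requires undoing a catalogue of artifacts before any statistic is
meaningful. `ipplog` implements that path as six auditable stages and pairs it
with a generator that can fabricate cohorts — with or without each artifact —
whose true engagement is known exactly.

## Data model

Three levels of analysis nest naturally: a **session** (one continuous use of
the tablet), an **admission** (one continuous-care interval, possibly merged
from several raw ADT encounters), and a **patient** (all use across
admissions). Two measures are computed at every level:

* **frequency** — the count of *active tasks* (actions intentionally initiated
  by the patient) per portal function;
* **comprehensiveness** — the number of distinct portal functions used, 0–9.

Nine functions carry the measures: accessing educational materials, personal
notes, checking secure messages, the daily schedule ("Happening soon"),
service requests ("I would like"), the ambulatory-portal bridge, care-team
review, vitals/lab review, and sending a secure message. A tenth
*Administrative* category (logins, handshakes, lock management, and similar)
never counts toward either measure, even for its few active actions (such as
sending a MyChart enrollment email), which are tallied separately.

Duration is deliberately **not** a measure. Many sessions consist of a login
and background loads only — *zero-time sessions* — so any duration-based
metric is systematically biased; the package computes duration solely for
histogram diagnostics (`session_diagnostics()`).

## Thresholds and their rationale

All tunables live in `pipeline_options()`:

| parameter | default | units | why |
|---|---|---|---|
| `gap_hours` | 4 | hours | discharge-to-admission gaps up to 4 h are treated as transfers and merged; exactly 4 h merges (inclusive reading of "within") |
| `session_gap_minutes` | 15 | minutes | conservative bound above the institution's nominal 10-minute auto-logout, whose log markers are unreliable; exactly 15 min stays in-session |
| `near_window_hours` | 24 | hours | diagnostic split of out-of-encounter events into near (boundary noise) vs far (stale device use); the cut is a package convention |
| `max_provision_day` | 9 | days (0-based) | engagement is reported on the first 10 provision days; provisioning lags admission, so stay days would bias comparisons |
| `los_cap` | 30 | days | hard cap on length of stay |
| `min_group_size` | 30 | patients | data-driven cap: the largest LOS such that every observed LOS value up to it has at least this many admissions; the stricter of the two caps wins |

Boundary conventions are closed everywhere: an event at the admission start or
at the discharge second is in-encounter; a gap of exactly the threshold never
splits or separates.

Two noteworthy resolutions of underdetermined corners:

* **Zero-time flag.** A session is zero-time iff it contains no active task
  outside Administrative — regardless of its duration. A one-event session
  consisting of a single active function task is therefore *not* zero-time.
* **Data-driven LOS cap at the low end.** The group-size rule targets the
  sparse upper tail. If even the smallest observed LOS is under-populated the
  rule would exclude everything; `run_pipeline()` then treats it as
  inapplicable and applies only the hard cap, recording the decision in the
  manifest. `compute_los_cap()` itself returns `-1` in that case.
* **Provision date.** Extracts carry no provisioning table, so the provision
  date is inferred as the calendar date of the admission's first audit event.
  Admissions without any linked event produce no provision context and are
  flagged.
* **Provision-day filter at the patient level** applies per admission (each
  admission contributes its own first 10 provision days), which keeps
  admission-level frequencies exactly additive into patient-level ones.

## Cleaning rules

Cleaning is order-sensitive and runs before sessionization, so removed
artifacts can never extend a session:

1. remove `Get Menu Items` (navigation), `Get Provider` (replicated once per
   care-team member on every care-team view) and `Get Wallpaper Data` (a page
   refresh on an exact 5-minute timer);
2. re-label `Media/Web content` through the extended-info code: by default the
   four orientation/education items map to active educational tasks and meal
   ordering to an active Administrative task; the map is config-overridable
   because the codes are site-specific;
3. collapse each run of consecutive logins with no intervening action to its
   earliest login (preserving the session start);
4. drop exact (patient, action, timestamp) duplicates, keeping the first row
   after a canonical sort — such ties may be real or artifactual, so the count
   is always reported;
5. classify survivors; unmapped actions go to Administrative/inactive with a
   warning (or abort under `strict`).

The cleaning report conserves counts exactly:
`survivors + removed + collapsed + deduped = rows_in`, and the pipeline
manifest extends the identity through linkage.

## The synthetic cohort generator

`simulate_cohort()` draws, per patient: admission anchors in 2014–2015 with a
15% chance of a second admission 10–60 days later; a continuous log-normal
stay duration (`meanlog = log 4`, `sdlog = 0.6`, i.e. a median stay of ~4
days — the shape of observed inpatient LOS distributions); a provisioning
delay of 0–4 days (mostly 0–1); negative-binomial daily session counts with at
least one session on the provision day; and per-session action sequences drawn
from a function-use profile in which care-team review and the schedule
dominate and secure-message sending is rarest. The profile echoes reported
usage patterns qualitatively without claiming any institution's magnitudes.

Timing margins make the 15-minute rule unambiguous by construction: sessions
sit on an 80-minute grid (inter-session gaps > 60 min) and intra-session gaps
are 10–90 s. Boundary behaviour is exercised by separate explicit fixtures at
exactly 15 min and 15 min + 1 s, not by the generator. Two generator-design
constraints are worth noting:

* every clean session contains at least one task event, because a pure-login
  session is indistinguishable from the sequential-login artifact that
  cleaning must collapse;
* stays are rounded down to whole seconds (the package's timestamp
  resolution), so goodness-of-fit for the stay distribution is assessed on
  the continuous duration `discharge − admit`, not on calendar-day LOS, which
  is its discretization.

`corrupt_tables()` injects each documented artifact independently at a given
rate — wallpaper refreshes at an exact 300 s cadence spanning a whole
admission's sessions, sequential-login stutters, duplicate timestamps,
near/far out-of-encounter strays, transfer-split encounters (overlapping or
gapped < 4 h), and duplicated hospital-account charge rows — and records every
injected row in a ledger. Because the artifacts are precisely the phenomena
the cleaning stages target, the pipeline must recover the clean cohort's
ground truth *exactly* under each single-artifact corruption, and each
cleaning/drop report must match the ledger count. The test suite asserts both,
plus the qualitative session-chaining phenomenon: retaining wallpaper events
merges sessions across real gaps (5 min < 15 min), so disabling the removal
strictly lowers the session count.

Ground truth is tallied at generation time from the generator's internal
labels using plain base-R aggregation — an independent code path from the
data.table machinery the pipeline uses.

## What passing tests do and do not show

The generator reproduces the *structural* artifacts of real audit logs, not
their full messiness: it has a single clock, no mid-session device handoffs,
no site-specific action vocabulary beyond the built-in taxonomy, and
clean-margin session spacing. Exact recovery on synthetic cohorts therefore
validates the pipeline's logic — boundary conventions, conservation,
invertibility of each cleaning rule — but says nothing about whether the
15-minute gap or the 4-hour merge window is *right* for a given institution.
Those remain analytic choices to be sensitivity-checked with the config block.

## Numerical and scale choices

Quartiles use R's linear-interpolation rule (`quantile` type 7), recorded in
the run manifest. Admission ids are deterministic (patient id + start
instant), so re-runs are byte-reproducible; the manifest carries an md5 hash
over options and counts to make identical runs evident. Test and acceptance
cohorts use 1000 patients (≈ 50k events), which exercises every code path at
interactive speeds; the generator and pipeline are vectorized and scale
linearly well beyond that.

## Limitations

* The provision date is a proxy; if a tablet was provisioned but never
  touched, the admission is invisible to the metrics.
* Same-timestamp deduplication cannot distinguish genuine simultaneous
  actions from replays; the dropped count is surfaced for exactly that
  reason.
* Hospital account ids are required input columns; the package does not
  reconstruct them from charge line items.
* No clustering or user-typology layer is included; the metrics tables are
  deliberately the stable substrate such analyses would consume.
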