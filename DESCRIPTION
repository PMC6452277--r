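Package: ipplog
Title: Inpatient-Portal Audit-Log Sessionization and Engagement Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes raw inpatient-portal (e.g. Epic MyChart Bedside) audit
    logs together with admission/discharge/transfer (ADT) records and hospital
    charges into cleaned, sessionized engagement measures. Consolidates
    overlapping and near-adjacent encounters into admissions, removes
    system-generated log artifacts (page-refresh polling, per-care-team-member
    replication, duplicate timestamps, sequential logins), maps raw user
    actions onto a nine-function taxonomy with active/inactive flags, links
    events to admissions, reconstructs sessions with an inactivity-gap rule,
    and computes frequency and comprehensiveness of portal use at the session,
    admission, and patient levels. Includes a seeded synthetic-data generator
    that reproduces the documented logging artifacts so the full pipeline is
    testable without protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table (>= 1.14),
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
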