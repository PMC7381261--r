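Package: microengage
Title: Micro-Level Engagement Analytics for Unguided Web-Based Health
    Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs usage sessions from raw page-visit logs of an
    unguided web-based psychoeducational program using login events and a
    configurable inactivity timeout, computes per-user monthly engagement
    metrics (login frequency, lower-bound duration, total and unique
    component views), classifies users into adherence statuses and
    frequency/activity tiers, detects automated usage-prompt trigger
    points, and provides the inferential layer (within-subject ANOVA
    across study months, paired contrasts, Pearson correlations with
    psychosocial change scores). Includes a seeded synthetic-cohort
    generator producing clickstreams and psychosocial trajectories with
    known ground truth so that every pipeline stage is testable without
    access to real user data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
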