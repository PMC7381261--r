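---
title: "Micro-level engagement analytics: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-level engagement analytics: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microengage)
```

## The problem

Unguided web-based psychoeducational programs are used by patients on
their own, with no coach steering them. Whether such a program can work
depends first on whether and how people actually use it, so the
measurable, moment-to-moment record of use — logins, time on the site,
which components were opened and reopened — is the primary observable.
This package implements that measurement chain for programs whose
analytics layer records one row per *page visit*: user id, a
whole-second timestamp, a login flag, and the component viewed.

The motivating setting is a distress self-management program for women
newly diagnosed with breast cancer, offered for a 12-week access window,
with a component inventory of 5 learning modules divided into 17 topical
section pages, 20 cognitive-behavioral exercises, 90 video vignettes and
13 resource pages — 140 countable components. Three introductory pages
and the personalized home page are navigational and never counted toward
activity. `default_catalog()` ships this inventory; `build_catalog()`
constructs arbitrary ones, and the activity denominator is always
recomputed from the stored component list.

## Session reconstruction

A *session* is a set of consecutive page visits starting with a login
event and ending with a logout or a period of inactivity. Because users
may simply close the browser, the log has no reliable end-of-visit
marker; the dwell on a visit is therefore the difference between its
timestamp and the next visit's timestamp within the same session, and
the last visit of a session contributes zero. All durations are **lower
bounds** on true time-on-site.

`sessionize()` starts a new session at:

* every login event, and
* every visit whose gap from the previous visit is at least the
  inactivity timeout (default **30 minutes**, configurable).

Three boundary decisions were genuinely open and are fixed as follows:

* **A gap exactly equal to the timeout splits the session** (`>=`, not
  `>`): a 30-minute inactivity period is treated as expiry. The boundary
  is covered by tests so the choice stays explicit.
* **A timeout-initiated session does not increment the login count.**
  Activity resuming after expiry opens a new session
  (`started_by_login = FALSE`), but only genuine login events are
  logins. Cohorts report more sessions than logins precisely because
  one login can span several sessions; treating resumptions as logins
  would collapse that distinction.
* **Visits with no component (the login landing page) carry dwell** that
  extends session duration but is attributed to no component.

Explicit logout button presses are not modeled separately: ending
sessions at the next login or a timeout gap subsumes them, at the cost
of conflating a deliberate logout with inactivity.

```{r}
v <- tibble::tibble(
  user_id = "u1",
  timestamp = as.POSIXct("2024-01-01 09:00:00", tz = "UTC") +
    c(0, 4, 35, 40) * 60,
  is_login = c(TRUE, FALSE, FALSE, FALSE),
  component_id = c(NA, "sec_001", "sec_002", "vid_001")
)
session_table(sessionize(v))[, c("session_id", "n_visits",
  "started_by_login", "duration_seconds")]
```

## Monthly metrics

Study months are **28-day blocks from each user's access start**
(12 weeks = 3 x 28 days). The published description alternates between
"12 weeks" and "3 months"; equal 28-day blocks keep windows disjoint,
cover the 84-day access period exactly, and align per user. A session
straddling a boundary is credited wholly to the month of its first
visit, because sessions are the atomic frequency unit. Visits before the
access start are an error (the log would precede the credentials);
visits after day 84 are dropped with a warning.

`summarize_usage()` reports per user and month: logins, sessions,
minutes (lower-bound), and total/unique views per countable category;
and overall: the same sums plus repeat views (total minus unique) and
the count of distinct components ever opened. A component seen in two
months is unique once overall, so overall unique counts are at most the
sum of the monthly ones.

## Classification rules

* **Status.** *Non-user*: at most one login **and** zero recorded
  minutes (both conditions; several zero-duration single-page sessions
  do not make a non-user). *Continuous*: at least one session in every
  study month. Everyone else is *intermittent*. A user active in months
  2-3 but not month 1 falls outside the usual intermittent pattern;
  such users are classified intermittent and flagged
  (`unusual_pattern`).
* **Frequency tier** (total logins): low 1-12 (half or less of the
  suggested minimum of 24 = 2/week x 12 weeks), moderate 13-24, high 25
  or more.
* **Activity tier** (proportion of the denominator ever opened): low up
  to 25%, moderate above 25% up to 50%, high above 50%. Proportions are
  used rather than the pre-rounded integer cutoffs of the 140-component
  program, so the rule generalizes to any catalog; with 140 components
  the boundaries land on 35 and 70 unique views.
* **Cross group**: matching tiers give `low_low`, `mod_mod`,
  `high_high`; otherwise `mixed`. Tiering counts logins, not sessions,
  mirroring how the frequency bands were defined.

## Prompt triggers

Two automated prompts are detected (no mail is sent): a congratulatory
prompt after every two hours of accumulated lower-bound use, with the
trigger instant interpolated inside the dwell interval that crosses each
120-minute multiple; and an informative prompt per cognitive-behavioral
exercise once a single visit's dwell on that exercise reaches two
minutes. The exercise rule is deliberately per-visit (one continuous
viewing episode), not cumulative across visits, and fires at most once
per user-exercise pair — these were pre-written one-shot messages.
Whether the original system's two-hour counter used wall-clock time is
unknowable from the log; lower-bound dwell is used for internal
consistency, making trigger counts equal to
`floor(total_minutes / 120)`.

## Inferential layer

`rm_anova()` is the sphericity-naive one-way within-subject ANOVA:
subject means removed, `F = MS_condition / MS_error`, `df = (k-1,
(k-1)(n-1))` — (2, 104) for 53 users over 3 months, and (1, 52) for
`paired_contrast()`, which is the squared paired t-test.
`pearson_cor()` is the product-moment correlation with the two-sided
t-based p-value. No sphericity correction and no multiplicity adjustment
are applied, matching how attrition analyses of this kind are reported;
`usage_outcome_correlations()` records the number of tests it ran in an
attribute so a reader can judge the multiplicity. Degenerate inputs are
handled explicitly: identical ANOVA columns give F = 0, p = 1;
zero-variance paired differences give a missing p-value; constant
vectors are a correlation error rather than a silent `NA`.

## The synthetic cohort generator

No real user data are distributed, so `generate_cohort()` stands in for
them. Its defaults are the study conditions: 53 users, an 84-day window,
a 70/28/2 continuous/intermittent/non-user mix, and month multipliers
(1, 0.60, 0.55) for session rate and (1, 0.75, 0.60) for dwell, placing
the sharpest attrition between months 1 and 2. Sessions draw a
geometric number of visits (mean ~6) with log-normal dwell (median 90 s,
`sdlog` 0.9) capped below the timeout so sessions split only where the
generator plants an inactivity gap (probability 0.08 per session).
Category preference weights (modules 0.30, exercises 0.25, videos 0.30,
resources 0.15) drive which components are opened, and revisit affinity
(exercises 3.5, modules 3.0, resources 1.8, videos 1.0) concentrates
repeat views on exercises and written content, as observed in practice.
Where the published account gives no value (dwell distribution, visit
counts per session, revisit affinities), parameters were chosen once as
field-plausible and are documented here rather than revisited.

Generation is **archetype-conditional**: labels and tier targets are
drawn first, then the log is generated to match them exactly — every
planned login is emitted as a login event, and the set of distinct
components opened equals the target. Tier target bands sit strictly
inside the classification bands (logins 4-10 / 15-22 / 26-34; activity
proportions 0.08-0.20 / 0.30-0.45 / 0.55-0.75), so classifier recovery
of the ground truth is exact by construction; with boundary-straddling
bands recovery would degrade, which is documented rather than asserted.
The top-ranked user of each frequency tier is forced to a matching
activity tier so all three matched cross groups are populated under the
defaults.

Psychosocial trajectories couple to usage through a single latent
distress variable $z \sim N(0,1)$ with additive Gaussian noise — the
simplest structure that reproduces weak (|r| ~ 0.3-0.6) correlations in
the directions observed: (a) per-visit dwell scales with
$e^{0.35z}$ and the intrusive/avoidant (IES) baseline loads on $z$, so
high-IES users accumulate more minutes; (b) frequency-tier placement
ranks on $z$ and the depressive (CES-D) baseline loads on $z$, so
high-CES-D users log in more; (c) the IES decline to month 3 steepens by
0.6 points per unique exercise view, giving the negative change-score
correlation. All three coupling strengths are configurable and zero in
`null_config()`.

**The null harness.** `null_cohort()` equalizes the month multipliers
and zeroes the couplings. It also sets the archetype mix to
all-continuous: intermittent and non-user archetypes are month-1-heavy
*by definition*, so leaving them in would re-introduce a real month
effect into a harness meant to have none. Monthly login counts are
multinomial with symmetric probabilities, and the minimum-one-per-month
fix-up draws its donor month at random among the maxima, keeping months
exchangeable; the within-subject ANOVA on the resulting login matrix
rejects at close to the nominal 5%.

## What the synthetic data do and do not show

The generator emulates attrition, archetype heterogeneity, repeat-view
structure and weak usage-psychosocial coupling; it does not emulate
calendar effects (weekday/holiday rhythms), treatment-phase bursts,
item-level instrument structure, demographic covariates, or the
particular means and SDs of any real cohort — those depend on data that
are not distributed, and matching them is a non-goal. Passing tests
therefore demonstrate that the pipeline measures, classifies and tests
correctly on logs with known structure, not that any clinical finding
replicates.

## Problem sizes and numerics

The test suite and the acceptance script use cohorts of 53 users
(hundreds of sessions, a few thousand visits), 1000 randomized logs for
the sessionizer-oracle comparison, 100 cohort replicates for
correlation-sign recovery and 2000 for the null type-I rate — sizes
chosen so the whole suite completes in minutes on one CPU while keeping
Monte-Carlo error well inside the asserted bands (the type-I standard
error at 2000 replicates is about 0.5 percentage points). Timestamps are
whole seconds throughout; activity-tier boundaries are compared with a
square-root-of-machine-epsilon tolerance so exact 25%/50% proportions
land in the lower tier; ANOVA sums of squares are clipped at zero to
absorb floating-point cancellation; ties at equal timestamps keep file
order (stable sorts everywhere).

## Known limitations

Durations are lower bounds and systematically undercount single-page
sessions; the 30-minute timeout is a convention, and although shrinking
it can only increase session counts (a tested monotonicity), absolute
session numbers are timeout-relative; classification of users whose logs
contain visits but no login events yields an undefined frequency tier
(flagged, not guessed); and the month-2-vs-3 comparisons inherit the
generator's stabilization of attrition after month 2, so their p-values
are not calibrated quantities of any real study.
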