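# microengage

Micro-level engagement analytics for unguided, web-based health
interventions.

Self-directed psychoeducational web programs — no therapist, no coach —
stand or fall on whether patients actually use them. The observable
record of that use is a clickstream: one row per page visit with a user
id, a whole-second timestamp, a login flag and the component viewed.
`microengage` turns such logs into the standard micro-level engagement
measures and the inferential analyses built on them. It is written for
researchers running or re-analyzing eHealth intervention studies.

The package implements, end to end:

* **Sessionization.** A session is a maximal run of consecutive page
  visits starting at a login and ending at the next login or an
  inactivity gap of at least *T* minutes (default *T* = 30). Dwell on a
  visit is the time to the next visit in the session; the last visit
  contributes 0, so session durations are lower bounds. Resumption
  after a timeout opens a new session but is not a login — hence
  cohorts have more sessions than logins.
* **Monthly metrics.** Per user and 28-day study month (12 weeks =
  3 x 28 days from each user's access start): logins, sessions,
  minutes, total and unique views per component category; overall:
  repeat views and the count of distinct components opened.
* **Classification.** Status (non-user: ≤1 login *and* 0 minutes;
  continuous: ≥1 session every month; else intermittent), frequency
  tier (1–12 / 13–24 / ≥25 total logins), activity tier (≤25% /
  ≤50% / >50% of the program's countable components opened; 140 in the
  built-in catalog), and the matched cross groups low-low / mod-mod /
  high-high.
* **Prompt triggers.** Congratulatory prompts at every 120 minutes of
  accumulated use (instants interpolated within the crossing dwell
  interval) and per-exercise prompts at the first visit with ≥120 s
  dwell on that exercise.
* **Statistics.** One-way within-subject ANOVA across months
  (F = MS_cond/MS_err on (k−1, (k−1)(n−1)) df — (2, 104) for n = 53,
  k = 3), paired contrasts (t² on (1, n−1) df), Pearson correlations of
  usage metrics with baseline and change scores of psychosocial
  instruments (distress thermometer, CES-D, IES, social constraints).
* **Synthetic cohorts.** A seeded generator producing clickstreams and
  psychosocial trajectories with known ground truth (archetype labels,
  tier targets, latent couplings, true session exit times), so every
  stage is testable without access to real user data.

## Worked example

```r
library(microengage)

co <- generate_cohort(cohort_config(), seed = 42)  # 53 simulated users
s  <- summarize_usage(co$visits, access = co$access)

dplyr::filter(cohort_table(s), metric == "logins")
#>   month metric  mean    sd     n
#> 1     1 logins  6.87  5.24    53
#> 2     2 logins  3.91  3.89    53
#> 3     3 logins  3.21  3.19    53

cl <- classify_users(s)
table(cl$status)
#>   continuous intermittent     non_user
#>           37           15            1

rm_anova(usage_matrix(s, "logins"))
#>   statistic   df1   df2  p.value
#> 1      35.4     2   104 1.85e-12

association_estimates(co)
#>   association                   estimate expected_sign
#> 1 ies_baseline_vs_minutes          0.541             1
#> 2 cesd_baseline_vs_logins          0.401             1
#> 3 ies_change_vs_unique_exercise   -0.662            -1
```

Reading: mean logins fall from 6.9 in study month 1 to 3.2 in month 3
and the within-subject ANOVA confirms the attrition (F(2,104) = 35.4);
the cohort splits 37/15/1 into continuous/intermittent/non-users; and
the three couplings the generator imposes — more baseline intrusive
thinking → more minutes, more baseline depressive symptoms → more
logins, more unique exercise views → steeper intrusive-thought decline —
are recovered with the configured signs.

`run_pipeline(visits_csv, out_dir, ...)` performs the whole chain on a
visit log on disk and writes a CSV/plain-text report bundle
(per-session, per-user and cohort tables, classification and cross-tab,
attrition tests, trigger lists, correlation table). Re-running it
reproduces every file bit for bit.

The methods, boundary conventions and generator design are documented
in `vignettes/engagement-analytics.Rmd`.

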