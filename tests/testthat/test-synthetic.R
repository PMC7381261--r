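test_that("generation is deterministic under a fixed seed", {
  a <- generate_cohort(cohort_config(n_users = 10), seed = 99)
  b <- generate_cohort(cohort_config(n_users = 10), seed = 99)
  expect_identical(a$visits, b$visits)
  expect_identical(a$psychosocial, b$psychosocial)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cohort_config(n_users = 10), seed = 100)
  expect_false(identical(a$visits, c$visits))
})

test_that("generated logs satisfy the event-model invariants", {
  co <- generate_cohort(cohort_config(n_users = 15), seed = 8)
  v <- co$visits
  # whole-second timestamps
  expect_true(all(as.numeric(v$timestamp) %% 1 == 0))
  # sorted within user
  expect_true(all(tapply(
    as.numeric(v$timestamp), v$user_id,
    function(x) !is.unsorted(x)
  )))
  # every referenced component exists in the catalog
  known <- default_catalog()$component_id
  expect_true(all(is.na(v$component_id) | v$component_id %in% known))
  # all visits inside the access window
  expect_silent(
    m <- assign_study_month(v$timestamp, co$config$access_start)
  )
  expect_false(anyNA(m))
  # psychosocial records validate and cover four timepoints per user
  expect_silent(microengage:::validate_psychosocial(co$psychosocial))
  expect_equal(nrow(co$psychosocial), 15 * 4)
})

test_that("an all-non-user mix yields no recorded minutes", {
  cfg <- cohort_config(
    n_users = 6,
    archetype_mix = c(continuous = 0, intermittent = 0, non_user = 1)
  )
  co <- generate_cohort(cfg, seed = 3)
  s <- summarize_usage(co$visits, access = co$access)
  expect_true(all(s$overall$minutes == 0))
  expect_true(all(s$overall$logins <= 1))
  cl <- classify_users(s)
  expect_true(all(cl$status == "non_user"))
})

test_that("an all-intermittent mix lapses in month 2 and/or 3", {
  cfg <- cohort_config(
    n_users = 12,
    archetype_mix = c(continuous = 0, intermittent = 1, non_user = 0)
  )
  co <- generate_cohort(cfg, seed = 14)
  s <- summarize_usage(co$visits, access = co$access)
  m <- usage_matrix(s, "sessions")
  expect_true(all(m[, 1] >= 1))
  expect_true(all(m[, 2] == 0 | m[, 3] == 0))
  expect_true(all(classify_users(s)$status == "intermittent"))
})

test_that("generated targets sit inside the classification bands", {
  co <- generate_cohort(cohort_config(), seed = 25)
  tr <- co$truth$users
  users <- tr$archetype != "non_user"
  expect_equal(freq_tier(tr$logins_target[users]),
    tr$freq_tier_target[users]
  )
  expect_equal(activity_tier(tr$unique_target[users], 140),
    tr$activity_tier_target[users]
  )
})

test_that("default cohorts populate all three matched cross groups", {
  for (seed in c(1, 6, 19)) {
    co <- generate_cohort(cohort_config(), seed = seed)
    s <- summarize_usage(co$visits, access = co$access)
    cl <- classify_users(s)
    expect_true(
      all(c("low_low", "mod_mod", "high_high") %in% cl$cross_group),
      info = seed
    )
  }
})

test_that("null cohorts carry no month effect and no couplings", {
  co <- null_cohort(seed = 41)
  expect_true(all(co$truth$users$dwell_scale == 1))
  expect_true(all(co$truth$users$archetype == "continuous"))
  # mean monthly logins roughly equal across months over replicates
  means <- colMeans(do.call(rbind, lapply(42:51, function(s) {
    colMeans(monthly_login_matrix(null_cohort(seed = s)))
  })))
  expect_lt(max(means) / min(means), 1.1)
})

test_that("attrition multipliers produce declining monthly means", {
  means <- colMeans(do.call(rbind, lapply(1:5, function(s) {
    colMeans(monthly_login_matrix(generate_cohort(seed = s)))
  })))
  expect_gt(means[1], means[2])
  expect_gte(means[2], means[3] * 0.9)
})

test_that("infeasible configurations are rejected", {
  expect_error(
    cohort_config(activity_bands = list(
      low = c(0.1, 0.2), moderate = c(0.3, 0.4), high = c(0.6, 1.4)
    )),
    "activity bands"
  )
  expect_error(
    cohort_config(archetype_mix = c(
      continuous = 0.5, intermittent = 0.2, non_user = 0.2
    )),
    "sum to 1"
  )
  expect_error(cohort_config(month_multipliers = c(1, 0, 0.5)), "positive")
})

test_that("association signs match the generator's configured couplings", {
  signs <- sapply(61:75, function(s) {
    est <- association_estimates(generate_cohort(seed = s))
    sign(est$estimate) == est$expected_sign
  })
  # each of the three associations recovers its sign in nearly all replicates
  expect_true(all(rowMeans(signs) >= 14 / 15))
})

test_that("cohort files round trip through write_cohort", {
  co <- generate_cohort(cohort_config(n_users = 5), seed = 55)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_identical(
    as.data.frame(read_visits(paths$visits)),
    as.data.frame(co$visits)
  )
  expect_identical(
    as.data.frame(read_psychosocial(paths$psychosocial)),
    as.data.frame(co$psychosocial)
  )
  truth <- jsonlite::fromJSON(paths$truth)
  expect_equal(truth$seed, 55)
  expect_equal(nrow(truth$users), 5)
})
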