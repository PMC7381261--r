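test_that("study-month assignment uses 28-day blocks with half-open bounds", {
  start <- T0
  day <- function(d) start + d * 86400
  expect_equal(assign_study_month(day(0), start), 1L)
  expect_equal(assign_study_month(day(27), start), 1L)
  expect_equal(assign_study_month(day(28), start), 2L)
  expect_equal(assign_study_month(day(55), start), 2L)
  expect_equal(assign_study_month(day(56), start), 3L)
  expect_equal(assign_study_month(day(83), start), 3L)
  expect_true(is.na(assign_study_month(day(84), start)))
  expect_error(assign_study_month(day(-1), start), "precedes")
})

test_that("a month-1-only user has zero metrics in months 2 and 3", {
  s <- summarize_usage(fig2_visits(),
    access = access_windows("u1", T0)
  )
  m <- s$monthly
  expect_equal(m$logins, c(1L, 0L, 0L))
  expect_equal(m$sessions, c(2L, 0L, 0L))
  expect_equal(m$minutes > 0, c(TRUE, FALSE, FALSE))
  expect_equal(s$overall$logins, 1L)
  expect_equal(s$overall$sessions, 2L)
})

test_that("total, unique and repeat views follow their definitions", {
  v <- mk_visits(
    0:5,
    logins = c(TRUE, rep(FALSE, 5)),
    comps = c(NA, rep("ex_001", 5))
  )
  s <- summarize_usage(v, access = access_windows("u1", T0))
  ov <- s$overall
  expect_equal(ov$total_views_exercise, 5L)
  expect_equal(ov$unique_views_exercise, 1L)
  expect_equal(ov$repeat_views_exercise, 4L)
  expect_equal(ov$overall_unique_components, 1L)
  # duplicating an already-seen component never changes unique counts
  v2 <- dplyr::bind_rows(v, mk_visits(6, logins = FALSE, comps = "ex_001"))
  s2 <- summarize_usage(v2, access = access_windows("u1", T0))
  expect_equal(s2$overall$unique_views_exercise, 1L)
  expect_equal(s2$overall$total_views_exercise, 6L)
})

test_that("visits after the access window are dropped with a warning", {
  v <- mk_visits(c(0, 84 * 24 * 60),
    logins = c(TRUE, TRUE)
  )
  expect_warning(
    s <- summarize_usage(v, access = access_windows("u1", T0)),
    "after the access window"
  )
  expect_equal(s$overall$logins, 1L)
})

test_that("monthly metrics equal a naive per-window recount on random cohorts", {
  catalog <- default_catalog()
  for (seed in c(3, 9)) {
    co <- generate_cohort(cohort_config(n_users = 8), seed = seed)
    s <- summarize_usage(co$visits, access = co$access)
    for (uid in co$access$user_id) {
      vu <- co$visits[co$visits$user_id == uid, ]
      start <- co$access$access_start[co$access$user_id == uid]
      want <- oracle_user_monthly(vu, start, catalog)
      got <- as.data.frame(s$monthly[s$monthly$user_id == uid, ])
      for (col in setdiff(names(want), "month")) {
        expect_equal(got[[col]], want[[col]],
          info = paste(seed, uid, col)
        )
      }
      expect_equal(
        s$overall$overall_unique_components[s$overall$user_id == uid],
        oracle_overall_unique(vu, start, catalog),
        info = paste(seed, uid)
      )
    }
  }
})

test_that("overall metrics are consistent with monthly metrics", {
  co <- generate_cohort(cohort_config(n_users = 15), seed = 21)
  s <- summarize_usage(co$visits, access = co$access)
  cats <- countable_categories()
  sums <- s$monthly |>
    dplyr::group_by(user_id) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(c(
        "logins", "sessions", "minutes", paste0("total_views_", cats)
      )), sum
    ))
  ov <- s$overall[match(sums$user_id, s$overall$user_id), ]
  for (col in setdiff(names(sums), "user_id")) {
    expect_equal(ov[[col]], sums[[col]], info = col)
  }
  for (cat in cats) {
    u <- paste0("unique_views_", cat)
    expect_true(all(ov[[u]] <= ov[[paste0("total_views_", cat)]]))
    # a component seen in two months is unique once overall
    monthly_u <- tapply(s$monthly[[u]], s$monthly$user_id, sum)
    expect_true(all(ov[[u]] <= monthly_u[ov$user_id]))
  }
  expect_true(all(
    s$monthly$unique_views_exercise <= s$monthly$total_views_exercise
  ))
})

test_that("adding a visit never decreases totals and adds at most one session", {
  set.seed(13)
  for (rep in 1:20) {
    v <- random_user_log(12)
    extra_time <- max(v$timestamp) + sample(c(60, 5000), 1)
    v2 <- dplyr::bind_rows(v, tibble::tibble(
      user_id = "u1", timestamp = extra_time,
      is_login = sample(c(TRUE, FALSE), 1), component_id = "ex_001"
    ))
    acc <- access_windows("u1", min(v$timestamp))
    s1 <- summarize_usage(v, access = acc)
    s2 <- summarize_usage(v2, access = acc)
    expect_true(s2$overall$total_views_exercise >=
      s1$overall$total_views_exercise)
    expect_true((s2$overall$sessions - s1$overall$sessions) %in% 0:1)
  }
})

test_that("cohort table reports sample SD with n-1 denominator", {
  one <- summarize_usage(fig1_visits(), access = access_windows("u1", T0))
  ct1 <- cohort_table(one)
  expect_true(all(is.na(ct1$sd)))

  two <- dplyr::bind_rows(fig1_visits("u1"), fig1_visits("u2"))
  s2 <- summarize_usage(two, access = access_windows(c("u1", "u2"), T0))
  ct2 <- cohort_table(s2)
  expect_true(all(ct2$sd == 0))

  m <- usage_matrix(s2, "logins")
  expect_equal(dim(m), c(2, 3))
  expect_equal(unname(m[, 1]), c(1, 1))
})

test_that("suggested dose arithmetic matches the enrollment instructions", {
  dose <- suggested_dose()
  expect_equal(dose$logins_min, 24)
  expect_equal(dose$minutes_min, 480)
  expect_equal(dose$minutes_max, 1080)
})
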