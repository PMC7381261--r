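test_that("a login followed by gaps of 5, 5 and 10 minutes is one 20-minute session", {
  sv <- sessionize(fig1_visits())
  st <- session_table(sv)
  expect_equal(nrow(st), 1)
  expect_equal(st$duration_seconds, 20 * 60)
  expect_true(st$started_by_login)
  expect_equal(sv$dwell_seconds, c(300, 300, 600, 0))
})

test_that("a 31-minute gap splits one login into two sessions", {
  sv <- sessionize(fig2_visits())
  st <- session_table(sv)
  expect_equal(nrow(st), 2)
  expect_equal(count_logins(sv), 1)
  expect_equal(count_sessions(sv), 2)
  expect_equal(st$started_by_login, c(TRUE, FALSE))
})

test_that("a single login visit is one session of duration zero", {
  st <- session_table(sessionize(mk_visits(0)))
  expect_equal(nrow(st), 1)
  expect_equal(st$duration_seconds, 0)
})

test_that("a gap exactly at the timeout expires the session; just under does not", {
  at_timeout <- mk_visits(c(0, 30), logins = c(TRUE, FALSE))
  expect_equal(count_sessions(sessionize(at_timeout)), 2)
  under <- mk_visits(c(0, 29.9), logins = c(TRUE, FALSE))
  expect_equal(count_sessions(sessionize(under)), 1)
  # and the timeout is configurable
  expect_equal(count_sessions(sessionize(at_timeout, timeout_minutes = 31)), 1)
})

test_that("count_logins and count_sessions on simple logs", {
  expect_equal(count_logins(mk_visits(numeric(0))), 0)
  three <- dplyr::bind_rows(lapply(1:3, function(i) {
    mk_visits(c(0, 2) + 100 * i, user = "u1", logins = c(TRUE, FALSE))
  }))
  sv <- sessionize(three)
  expect_equal(count_logins(sv), 3)
  expect_equal(count_sessions(sv), 3)
})

test_that("unsorted input is rejected", {
  v <- mk_visits(c(10, 0), logins = c(TRUE, TRUE))
  expect_error(sessionize(v), "sorted")
})

test_that("session boundaries match the brute-force splitter on random logs", {
  set.seed(42)
  for (rep in 1:200) {
    v <- random_user_log(sample(2:25, 1))
    sv <- sessionize(v)
    expect_equal(
      sv$session_index,
      oracle_session_index(v$timestamp, v$is_login),
      info = paste("rep", rep)
    )
    expect_equal(
      sv$dwell_seconds,
      oracle_dwell(v$timestamp, sv$session_index),
      info = paste("rep", rep)
    )
  }
})

test_that("sessionization partitions the input and is timeout-monotone", {
  set.seed(7)
  for (rep in 1:30) {
    v <- random_log(n_users = 3, n_visits = 15)
    sv <- sessionize(v)
    # partition: visits reproduced exactly, each in exactly one session
    expect_equal(
      as.data.frame(sv[, names(v)]), as.data.frame(v)
    )
    expect_false(anyNA(sv$session_id))
    # duration identity within each session
    st <- session_table(sv)
    dwell_sums <- tapply(sv$dwell_seconds, sv$session_id, sum)
    expect_equal(
      as.numeric(dwell_sums[st$session_id]), st$duration_seconds
    )
    # shrinking the timeout never merges sessions
    n_by_timeout <- vapply(
      c(60, 30, 10, 5),
      function(tm) count_sessions(sessionize(v, timeout_minutes = tm)),
      numeric(1)
    )
    expect_true(all(diff(n_by_timeout) >= 0))
  }
})

test_that("dwell accumulates per component and matches the pairwise oracle", {
  v <- mk_visits(c(0, 2, 4),
    logins = c(TRUE, FALSE, FALSE),
    comps = c("ex_001", "sec_001", "ex_001")
  )
  d <- dwell_by_component(sessionize(v))
  expect_equal(d$dwell_seconds[d$component_id == "ex_001"], 120)
  expect_equal(d$dwell_seconds[d$component_id == "sec_001"], 120)

  # the same component in two sessions: dwell is additive
  v2 <- dplyr::bind_rows(
    mk_visits(c(0, 1, 2), logins = c(TRUE, FALSE, FALSE),
      comps = c("ex_001", NA, NA)
    ),
    mk_visits(c(100, 101, 102), logins = c(TRUE, FALSE, FALSE),
      comps = c("ex_001", NA, NA)
    )
  )
  d2 <- dwell_by_component(sessionize(v2))
  expect_equal(d2$dwell_seconds[d2$component_id == "ex_001"], 120)

  set.seed(11)
  for (rep in 1:25) {
    v <- random_user_log(sample(3:20, 1))
    sv <- sessionize(v)
    got <- dwell_by_component(sv)
    od <- oracle_dwell(v$timestamp, sv$session_index)
    for (i in seq_len(nrow(got))) {
      keep <- !is.na(v$component_id) & v$component_id == got$component_id[i]
      expect_equal(got$dwell_seconds[i], sum(od[keep]))
    }
  }
})

test_that("observed durations are lower bounds for true session durations", {
  co <- generate_cohort(cohort_config(n_users = 12), seed = 5)
  sv <- sessionize(co$visits,
    timeout_minutes = co$config$inactivity_timeout_minutes
  )
  st <- session_table(sv)
  truth <- co$truth$sessions
  joined <- dplyr::inner_join(
    st, truth,
    by = c("user_id", "start")
  )
  # every reconstructed session matches a generated one, and vice versa
  expect_equal(nrow(joined), nrow(st))
  expect_equal(nrow(st), nrow(truth))
  true_dur <- as.numeric(difftime(joined$true_end, joined$start,
    units = "secs"
  ))
  expect_true(all(joined$duration_seconds <= true_dur))
  # equality exactly when the last page's unobserved dwell is zero
  expect_equal(
    joined$duration_seconds == true_dur,
    as.numeric(difftime(joined$true_end, joined$observed_end,
      units = "secs"
    )) == 0
  )
})
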