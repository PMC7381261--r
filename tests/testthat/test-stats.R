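test_that("within-subject ANOVA df pattern is (k-1, (k-1)(n-1))", {
  set.seed(1)
  m <- matrix(rnorm(53 * 3), 53, 3)
  res <- rm_anova(m)
  expect_equal(res$df1, 2L)
  expect_equal(res$df2, 104L)
  res2 <- rm_anova(matrix(rnorm(10 * 4), 10, 4))
  expect_equal(res2$df1, 3L)
  expect_equal(res2$df2, 27L)
})

test_that("identical conditions give F = 0, p = 1; missing cells error", {
  m <- cbind(1:10, 1:10, 1:10)
  res <- rm_anova(m)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  m2 <- matrix(rnorm(12), 4, 3)
  m2[2, 3] <- NA
  expect_error(rm_anova(m2), "complete")
  expect_error(rm_anova(matrix(1:3, 1, 3)), "at least 2")
})

test_that("rm_anova agrees with the aov() oracle to 1e-10", {
  set.seed(22)
  for (rep in 1:25) {
    n <- sample(4:40, 1)
    k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, sd = sample(1:5, 1)), n, k) +
      rnorm(n) # subject effects
    got <- rm_anova(m)
    want <- oracle_rm_anova(m)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$df1, want$df1)
    expect_equal(got$df2, want$df2)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-10)
  }
})

test_that("rm_anova is invariant to adding per-subject constants", {
  set.seed(3)
  m <- matrix(rnorm(30), 10, 3)
  shifted <- m + rnorm(10, sd = 100)
  expect_equal(rm_anova(m)$statistic, rm_anova(shifted)$statistic,
    tolerance = 1e-8
  )
})

test_that("under the null the within-subject F rejects at the nominal rate", {
  set.seed(101)
  rejections <- vapply(seq_len(2000), function(i) {
    rm_anova(matrix(rnorm(53 * 3), 53, 3))$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.03)
  expect_lt(mean(rejections), 0.07)
})

test_that("paired contrast is the squared paired t-test", {
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    x <- rnorm(n)
    y <- x + rnorm(n, mean = 0.3)
    got <- paired_contrast(x, y)
    tt <- stats::t.test(y, x, paired = TRUE)
    expect_equal(got$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(got$p.value, tt$p.value, tolerance = 1e-10)
    expect_equal(got$df1, 1L)
    expect_equal(got$df2, n - 1L)
  }
  x <- rnorm(53)
  expect_equal(paired_contrast(x, x + rnorm(53))$df2, 52L)
})

test_that("degenerate paired contrasts are handled explicitly", {
  x <- rnorm(10)
  same <- paired_contrast(x, x)
  expect_equal(same$statistic, 0)
  expect_true(is.na(same$p.value))
  # a constant (exactly representable) shift: zero variance, nonzero mean
  counts <- as.numeric(rpois(10, 5))
  shifted <- paired_contrast(counts, counts + 2)
  expect_equal(shifted$statistic, Inf)
  expect_true(is.na(shifted$p.value))
  expect_error(paired_contrast(1:3, 1:4), "equal length")
})

test_that("pearson_cor matches cor.test and handles perfect correlation", {
  expect_equal(pearson_cor(1:10, 1:10)$estimate, 1)
  expect_equal(pearson_cor(1:10, -(1:10))$estimate, -1)
  set.seed(6)
  for (rep in 1:20) {
    n <- sample(5:80, 1)
    x <- rnorm(n)
    y <- 0.4 * x + rnorm(n)
    got <- pearson_cor(x, y)
    want <- stats::cor.test(x, y)
    expect_equal(got$estimate, unname(want$estimate), tolerance = 1e-12)
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-10)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-12)
  }
  expect_error(pearson_cor(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_cor(1:2, 2:1), "at least 3")
  # pairs with missing values are dropped
  res <- pearson_cor(c(1, 2, 3, 4, NA), c(2, 4, 5, 9, 1))
  expect_equal(res$n, 4L)
})

test_that("change scores are later minus earlier, with exclusions logged", {
  psych <- mk_psych(c("u1", "u2"))
  cs <- change_scores(psych, "intrusive_avoidant")
  expect_equal(cs$delta, c(-10, -10))
  # a decline in symptoms is a negative delta
  expect_true(all(cs$delta < 0))
  # drop u2's month 3: u2 is excluded and counted
  psych_miss <- psych[!(psych$user_id == "u2" & psych$timepoint == "m3"), ]
  expect_message(
    cs2 <- change_scores(psych_miss, "intrusive_avoidant"),
    "1 user"
  )
  expect_equal(cs2$user_id, "u1")
  expect_equal(attr(cs2, "excluded"), "u2")
  cs3 <- change_scores(psych, "distress", from = "m1", to = "m2")
  expect_equal(cs3$delta, c(-1, -1))
})

test_that("attrition tests and correlations run end to end on a cohort", {
  co <- generate_cohort(cohort_config(n_users = 24), seed = 12)
  s <- summarize_usage(co$visits, access = co$access)
  att <- attrition_tests(s)
  expect_setequal(unique(att$metric), c("logins", "sessions", "minutes"))
  expect_equal(
    att$df1[att$test == "months_1_to_3"], rep(2L, 3)
  )
  expect_equal(
    att$df2[att$test == "months_1_to_3"], rep(23L * 2L, 3)
  )
  expect_true(all(att$df1[att$test != "months_1_to_3"] == 1L))
  corr <- usage_outcome_correlations(s, co$psychosocial)
  expect_true(all(c("usage_metric", "outcome", "estimate") %in% names(corr)))
  expect_true(attr(corr, "n_tests") > 0)
  expect_true(all(abs(corr$estimate) <= 1, na.rm = TRUE))
})
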