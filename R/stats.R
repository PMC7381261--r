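# Inferential layer: one-way within-subject (repeated-measures) ANOVA
# across study months, paired contrasts, Pearson correlations and
# psychosocial change scores. Tests are sphericity-naive and unadjusted
# for multiplicity, matching how attrition analyses of this kind are
# conventionally reported; two-sided p-values throughout.

#' One-way within-subject ANOVA
#'
#' For an n-subjects by k-conditions complete matrix, removes the subject
#' means and tests the condition effect:
#' `F = MS_condition / MS_error` with `df1 = k - 1` and
#' `df2 = (k - 1)(n - 1)`. With n = 53 users and k = 3 study months this
#' yields the familiar (2, 104) degrees of freedom. When the
#' between-condition sum of squares is exactly zero (all columns
#' identical), F = 0 and p = 1 are reported.
#'
#' @param x Numeric matrix or data frame, rows = subjects, columns =
#'   conditions; missing cells are an error.
#' @return One-row tibble: `statistic`, `df1`, `df2`, `p.value`.
#' @export
rm_anova <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric", call. = FALSE)
  if (anyNA(x)) stop("missing cells: rm_anova requires a complete matrix",
    call. = FALSE
  )
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 conditions",
    call. = FALSE
  )
  grand <- mean(x)
  ss_cond <- n * sum((colMeans(x) - grand)^2)
  ss_subj <- k * sum((rowMeans(x) - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- max(ss_tot - ss_cond - ss_subj, 0)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  if (ss_cond == 0) {
    f <- 0
    p <- 1
  } else if (ss_err == 0) {
    f <- Inf
    p <- 0
  } else {
    f <- (ss_cond / df1) / (ss_err / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  tibble(
    statistic = f, df1 = as.integer(df1), df2 = as.integer(df2), p.value = p
  )
}

#' Paired contrast between two conditions
#'
#' The F form of the paired t-test: `F = t^2` with `df1 = 1` and
#' `df2 = n - 1`. With zero variance of the differences the p-value is
#' undefined and reported as missing (F is 0 when the vectors are
#' identical).
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2).
#' @return One-row tibble: `statistic`, `df1`, `df2`, `p.value`.
#' @export
paired_contrast <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
    call. = FALSE
  )
  if (anyNA(x) || anyNA(y)) stop("missing values in paired vectors",
    call. = FALSE
  )
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- y - x
  if (sd(d) == 0) {
    f <- if (mean(d) == 0) 0 else Inf
    p <- NA_real_
  } else {
    t_stat <- mean(d) / (sd(d) / sqrt(n))
    f <- t_stat^2
    p <- pf(f, 1, n - 1, lower.tail = FALSE)
  }
  tibble(
    statistic = f, df1 = 1L, df2 = as.integer(n - 1), p.value = p
  )
}

#' Pearson product-moment correlation
#'
#' Standard r with a two-sided t-based p-value:
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#' Pairs with a missing value in either vector are dropped; at least three
#' complete pairs and nonzero variance in both vectors are required.
#'
#' @param x,y Numeric vectors of equal length.
#' @return One-row tibble: `estimate` (r), `n`, `statistic` (t),
#'   `p.value`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
    call. = FALSE
  )
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  dx <- x - mean(x)
  dy <- y - mean(y)
  r <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) {
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t_stat), n - 2)
  }
  tibble(estimate = r, n = as.integer(n), statistic = t_stat, p.value = p)
}

#' Psychosocial change scores
#'
#' Per-user change `score(to) - score(from)` for one measure; negative
#' deltas mean decline. Users missing either timepoint are excluded; their
#' ids are recorded in the `"excluded"` attribute and counted in a message.
#'
#' @param records Psychosocial tibble (see [read_psychosocial()]).
#' @param measure One of `"distress"`, `"depressive"`,
#'   `"intrusive_avoidant"`, `"sc_partner"`, `"sc_family"`.
#' @param from,to Timepoints (`"baseline"`, `"m1"`, `"m2"`, `"m3"`).
#' @return Tibble `user_id`, `measure`, `from`, `to`, `delta`, with
#'   attribute `excluded`.
#' @export
change_scores <- function(records, measure, from = "baseline", to = "m3") {
  validate_psychosocial(records)
  stopifnot(
    measure %in% setdiff(PSYCH_COLUMNS, c("user_id", "timepoint")),
    from %in% TIMEPOINTS, to %in% TIMEPOINTS
  )
  wide <- records |>
    filter(.data$timepoint %in% c(from, to)) |>
    select("user_id", "timepoint", dplyr::all_of(measure)) |>
    pivot_wider(names_from = "timepoint", values_from = dplyr::all_of(measure))
  for (tp in c(from, to)) {
    if (!tp %in% names(wide)) wide[[tp]] <- NA_real_
  }
  ok <- !is.na(wide[[from]]) & !is.na(wide[[to]])
  excluded <- wide$user_id[!ok]
  if (length(excluded) > 0) {
    message(
      length(excluded), " user(s) excluded from ", measure, " change ",
      from, "->", to, " (missing a timepoint)"
    )
  }
  delta <- wide[[to]][ok] - wide[[from]][ok]
  out <- tibble(
    user_id = wide$user_id[ok],
    measure = measure,
    from = from,
    to = to,
    delta = delta
  )
  attr(out, "excluded") <- excluded
  out
}

#' Monthly attrition tests for a cohort
#'
#' For logins, sessions and minutes: the within-subject ANOVA across the
#' three study months plus the month 1 vs 2 and month 2 vs 3 paired
#' contrasts, alongside monthly means and SDs.
#'
#' @param summary A `usage_summary` object.
#' @return Tibble with one row per metric and test.
#' @export
attrition_tests <- function(summary) {
  stopifnot(inherits(summary, "usage_summary"))
  rows <- lapply(c("logins", "sessions", "minutes"), function(metric) {
    m <- usage_matrix(summary, metric)
    if (nrow(m) < 2) {
      return(NULL)
    }
    omnibus <- rm_anova(m)
    c12 <- paired_contrast(m[, 1], m[, 2])
    c23 <- paired_contrast(m[, 2], m[, 3])
    bind_rows(
      mutate(omnibus, metric = metric, test = "months_1_to_3"),
      mutate(c12, metric = metric, test = "month_1_vs_2"),
      mutate(c23, metric = metric, test = "month_2_vs_3")
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) > 0) {
    out <- out[, c("metric", "test", "statistic", "df1", "df2", "p.value")]
  }
  out
}

#' Extract an n-users by k-months metric matrix
#'
#' @param summary A `usage_summary` object.
#' @param metric A column of `summary$monthly` (e.g. `"logins"`).
#' @return Numeric matrix with one row per user, one column per month.
#' @export
usage_matrix <- function(summary, metric = "logins") {
  stopifnot(inherits(summary, "usage_summary"))
  if (!metric %in% names(summary$monthly)) {
    stop("unknown metric: ", metric, call. = FALSE)
  }
  wide <- summary$monthly |>
    select("user_id", "month", dplyr::all_of(metric)) |>
    pivot_wider(names_from = "month", values_from = dplyr::all_of(metric))
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$user_id
  colnames(m) <- paste0("m", colnames(m))
  m
}

#' Correlations between usage metrics and psychosocial outcomes
#'
#' Pearson correlations of per-user usage metrics (total logins, sessions,
#' minutes, unique views by category, distinct components opened) against
#' baseline psychosocial scores and baseline-to-month-3 change scores.
#' Pairs with fewer than three complete observations or a constant vector
#' are reported with missing estimates. The number of tests run is included
#' as an attribute; no multiplicity adjustment is applied.
#'
#' @param summary A `usage_summary` object.
#' @param records Psychosocial tibble.
#' @return Tibble `usage_metric`, `outcome`, `estimate`, `n`, `p.value`
#'   with attribute `n_tests`.
#' @export
usage_outcome_correlations <- function(summary, records) {
  stopifnot(inherits(summary, "usage_summary"))
  validate_psychosocial(records)
  ov <- summary$overall
  usage_cols <- c(
    "logins", "sessions", "minutes",
    paste0("unique_views_", countable_categories()),
    "overall_unique_components"
  )
  measures <- c("distress", "depressive", "intrusive_avoidant",
    "sc_partner", "sc_family"
  )
  base <- records |>
    filter(.data$timepoint == "baseline") |>
    select("user_id", dplyr::all_of(measures))
  names(base)[-1] <- paste0("baseline_", measures)
  deltas <- lapply(measures, function(ms) {
    cs <- suppressMessages(change_scores(records, ms))
    out <- cs[, c("user_id", "delta")]
    names(out)[2] <- paste0("change_", ms)
    out
  })
  outcomes <- Reduce(
    function(a, b) full_join(a, b, by = "user_id"),
    c(list(base), deltas)
  )
  d <- left_join(ov, outcomes, by = "user_id")
  outcome_cols <- setdiff(names(outcomes), "user_id")
  grid <- expand.grid(
    usage_metric = usage_cols, outcome = outcome_cols,
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- d[[grid$usage_metric[i]]]
    y <- d[[grid$outcome[i]]]
    res <- tryCatch(pearson_cor(x, y), error = function(e) NULL)
    if (is.null(res)) {
      tibble(
        usage_metric = grid$usage_metric[i], outcome = grid$outcome[i],
        estimate = NA_real_, n = sum(!is.na(x) & !is.na(y)),
        p.value = NA_real_
      )
    } else {
      tibble(
        usage_metric = grid$usage_metric[i], outcome = grid$outcome[i],
        estimate = res$estimate, n = res$n, p.value = res$p.value
      )
    }
  })
  out <- bind_rows(rows)
  attr(out, "n_tests") <- sum(!is.na(out$estimate))
  out
}
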