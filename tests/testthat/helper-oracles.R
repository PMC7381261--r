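# Independent oracles: deliberately naive re-implementations (explicit
# loops, or base-R model fits) used only to cross-check the package's
# vectorized implementations.

# Brute-force session splitter: scan the gaps, cut at logins and at gaps
# reaching the timeout.
oracle_session_index <- function(timestamps, is_login, timeout_minutes = 30) {
  n <- length(timestamps)
  idx <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    gap <- if (i == 1) {
      Inf
    } else {
      as.numeric(difftime(timestamps[i], timestamps[i - 1], units = "secs"))
    }
    if (i == 1 || is_login[i] || gap >= timeout_minutes * 60) cur <- cur + 1L
    idx[i] <- cur
  }
  idx
}

# Pairwise-difference dwell: time to the next visit in the same session,
# zero for a session's last visit.
oracle_dwell <- function(timestamps, session_index) {
  n <- length(timestamps)
  d <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- if (i < n && session_index[i + 1] == session_index[i]) {
      as.numeric(difftime(timestamps[i + 1], timestamps[i], units = "secs"))
    } else {
      0
    }
  }
  d
}

# Within-subject ANOVA via base aov() with an Error() stratum.
oracle_rm_anova <- function(m) {
  d <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), ncol(m))),
    cond = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  fit <- summary(stats::aov(y ~ cond + Error(subject), data = d))
  tab <- fit[["Error: Within"]][[1]]
  list(
    statistic = tab["cond", "F value"],
    df1 = tab["cond", "Df"],
    df2 = tab["Residuals", "Df"],
    p.value = tab["cond", "Pr(>F)"]
  )
}

# Naive per-window recount of one user's monthly metrics, built on the
# brute-force splitter above and explicit loops.
oracle_user_monthly <- function(visits_u, access_start, catalog,
                                timeout_minutes = 30, access_days = 84) {
  day <- floor(as.numeric(
    difftime(visits_u$timestamp, access_start, units = "secs")
  ) / 86400)
  v <- visits_u[day < access_days, , drop = FALSE]
  day <- day[day < access_days]
  month <- day %/% 28 + 1
  sess <- oracle_session_index(v$timestamp, v$is_login, timeout_minutes)
  cats <- catalog$category[match(v$component_id, catalog$component_id)]
  countable <- microengage::countable_categories()
  out <- list()
  for (m in 1:3) {
    row <- list(month = m)
    row$logins <- sum(v$is_login & month == m)
    sess_ids <- unique(sess)
    first_month <- vapply(
      sess_ids, function(s) month[which(sess == s)[1]], numeric(1)
    )
    row$sessions <- sum(first_month == m)
    mins <- 0
    for (s in sess_ids[first_month == m]) {
      tt <- v$timestamp[sess == s]
      mins <- mins + as.numeric(difftime(max(tt), min(tt), units = "secs")) / 60
    }
    row$minutes <- mins
    for (cat in countable) {
      in_cat <- !is.na(cats) & cats == cat & month == m
      row[[paste0("total_views_", cat)]] <- sum(in_cat)
      row[[paste0("unique_views_", cat)]] <-
        length(unique(v$component_id[in_cat]))
    }
    out[[m]] <- as.data.frame(row)
  }
  do.call(rbind, out)
}

# Overall distinct countable components opened by one user.
oracle_overall_unique <- function(visits_u, access_start, catalog,
                                  access_days = 84) {
  day <- floor(as.numeric(
    difftime(visits_u$timestamp, access_start, units = "secs")
  ) / 86400)
  v <- visits_u[day < access_days, , drop = FALSE]
  cats <- catalog$category[match(v$component_id, catalog$component_id)]
  keep <- !is.na(cats) & cats %in% microengage::countable_categories()
  length(unique(v$component_id[keep]))
}
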