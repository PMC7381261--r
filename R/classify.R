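# Rule-based user classification: adherence status, login-frequency tier,
# activity tier, and the cross-tabulated use group.

STATUS_LEVELS <- c("non_user", "intermittent", "continuous")
TIER_LEVELS <- c("low", "moderate", "high")
CROSS_LEVELS <- c("low_low", "mod_mod", "high_high", "mixed")

#' Classify adherence status
#'
#' A non-user registered at most one login and zero recorded minutes (both
#' conditions must hold: several zero-duration single-page sessions do not
#' make a non-user). A continuous user registered at least one session in
#' every study month. Everyone else is intermittent.
#'
#' @param total_logins,total_minutes Per-user totals over the access
#'   window.
#' @param sessions_m1,sessions_m2,sessions_m3 Per-user session counts in
#'   study months 1-3.
#' @return Character vector over `c("non_user", "intermittent",
#'   "continuous")`.
#' @export
classify_status <- function(total_logins, total_minutes,
                            sessions_m1, sessions_m2, sessions_m3) {
  dplyr::case_when(
    total_logins <= 1 & total_minutes == 0 ~ "non_user",
    sessions_m1 >= 1 & sessions_m2 >= 1 & sessions_m3 >= 1 ~ "continuous",
    TRUE ~ "intermittent"
  )
}

#' Login-frequency tier
#'
#' Low is 1-12 total logins (half or less of the suggested minimum of 24),
#' moderate is 13-24, high is 25 or more. Zero logins is not classifiable
#' (the non-user path) and returns `NA`.
#'
#' @param total_logins Integer vector of total logins over the study.
#' @return Character vector over `c("low", "moderate", "high")`.
#' @export
freq_tier <- function(total_logins) {
  dplyr::case_when(
    is.na(total_logins) | total_logins < 1 ~ NA_character_,
    total_logins <= 12 ~ "low",
    total_logins <= 24 ~ "moderate",
    TRUE ~ "high"
  )
}

#' Activity tier
#'
#' Based on the proportion of the program's countable components ever
#' opened (unique views): low is 0-25%, moderate is more than 25% up to
#' 50%, high is above 50%. Proportions rather than pre-rounded integer
#' cutoffs are used, so the rule generalizes to catalogs of any size.
#'
#' @param unique_components Count of distinct countable components opened.
#' @param catalog A catalog tibble, or a single number giving the activity
#'   denominator directly.
#' @return Character vector over `c("low", "moderate", "high")`.
#' @export
activity_tier <- function(unique_components, catalog = default_catalog()) {
  denom <- if (is.numeric(catalog)) catalog else catalog_denominator(catalog)
  if (denom <= 0) stop("activity denominator must be positive", call. = FALSE)
  if (any(unique_components > denom, na.rm = TRUE)) {
    stop("unique component count exceeds the catalog denominator",
      call. = FALSE
    )
  }
  p <- unique_components / denom
  eps <- sqrt(.Machine$double.eps)
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 0.25 + eps ~ "low",
    p <= 0.50 + eps ~ "moderate",
    TRUE ~ "high"
  )
}

#' Cross-tabulated use group
#'
#' Matching frequency and activity tiers map to `low_low`, `mod_mod` or
#' `high_high`; any disagreement is `mixed`.
#'
#' @param freq,activity Tier vectors from [freq_tier()] and
#'   [activity_tier()].
#' @return Character vector over `c("low_low", "mod_mod", "high_high",
#'   "mixed")`.
#' @export
cross_group <- function(freq, activity) {
  matched <- c(low = "low_low", moderate = "mod_mod", high = "high_high")
  freq <- as.character(freq)
  activity <- as.character(activity)
  dplyr::case_when(
    is.na(freq) | is.na(activity) ~ NA_character_,
    freq == activity ~ unname(matched[freq]),
    TRUE ~ "mixed"
  )
}

#' Classify every user in a usage summary
#'
#' Applies the status, tier and cross-group rules to each user. Non-users
#' carry `NA` tiers. Users active in months 2-3 but not month 1 fall outside
#' the usual intermittent pattern (which presumes month-1 activity); they
#' are still classified intermittent and flagged via `unusual_pattern`.
#'
#' @param summary A `usage_summary` object from [summarize_usage()].
#' @return Tibble with one row per user: `user_id`, `status`, `freq_tier`,
#'   `activity_tier`, `cross_group`, `unusual_pattern`.
#' @export
classify_users <- function(summary) {
  stopifnot(inherits(summary, "usage_summary"))
  sess <- summary$monthly |>
    select("user_id", "month", "sessions") |>
    pivot_wider(
      names_from = "month", values_from = "sessions", names_prefix = "m"
    )
  d <- left_join(summary$overall, sess, by = "user_id")
  status <- classify_status(
    d$logins, d$minutes, d$m1, d$m2, d$m3
  )
  ft <- ifelse(status == "non_user", NA_character_, freq_tier(d$logins))
  at <- ifelse(
    status == "non_user", NA_character_,
    activity_tier(d$overall_unique_components, summary$denominator)
  )
  tibble(
    user_id = d$user_id,
    status = status,
    freq_tier = ft,
    activity_tier = at,
    cross_group = cross_group(ft, at),
    unusual_pattern = status != "non_user" & d$m1 == 0 & (d$m2 > 0 | d$m3 > 0)
  )
}

#' Cross-tabulation of use groups
#'
#' Counts users by status and cross group, the table used to report how
#' many users matched, exceeded or fell below the intended usage on both
#' frequency and activity.
#'
#' @param classification Output of [classify_users()].
#' @return Tibble of counts by `status` and `cross_group`.
#' @export
crosstab_groups <- function(classification) {
  classification |>
    count(.data$status, .data$cross_group, name = "n_users") |>
    arrange(
      match(.data$status, STATUS_LEVELS),
      match(.data$cross_group, CROSS_LEVELS)
    )
}
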