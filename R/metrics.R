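# Per-user, per-study-month micro-level engagement metrics. Study months
# are 28-day blocks from each user's access_start (12 weeks = 3 x 28 days),
# so windows are disjoint and aligned per user. Sessions, logins and
# minutes are credited to the month of the session's first visit; views are
# credited to the month of the visit itself.

#' Assign a visit to a study month
#'
#' Day offset is `floor((timestamp - access_start) / 86400)`; month is
#' `offset %/% 28 + 1` for offsets inside the access window, `NA`
#' (out-of-window) at or beyond `access_days`. A visit before
#' `access_start` is an error: the log would precede the credentials.
#'
#' @param timestamp POSIXct vector of visit instants.
#' @param access_start POSIXct access start (recycled).
#' @param access_days Length of the access window in days (default 84).
#' @param month_length_days Days per study month (default 28).
#' @return Integer vector of study months (1-based), `NA` when
#'   out-of-window.
#' @export
assign_study_month <- function(timestamp, access_start, access_days = 84,
                               month_length_days = 28) {
  offset <- floor(
    as.numeric(difftime(timestamp, access_start, units = "secs")) / 86400
  )
  if (any(offset < 0)) {
    stop("page visit precedes access_start (row(s) ",
      paste(head(which(offset < 0), 10), collapse = ", "), ")",
      call. = FALSE
    )
  }
  month <- offset %/% month_length_days + 1
  month[offset >= access_days] <- NA_integer_
  as.integer(month)
}

derive_access <- function(visits, access_days = 84L) {
  visits |>
    group_by(.data$user_id) |>
    summarise(access_start = min(.data$timestamp), .groups = "drop") |>
    mutate(access_days = as.integer(access_days))
}

#' Summarize per-user engagement by study month
#'
#' The full micro-level metric set: per user and study month (and overall),
#' the number of logins, sessions, lower-bound minutes, and total/unique
#' component views split by countable category, plus overall repeat views
#' (total minus unique) and the count of distinct countable components ever
#' opened (the numerator of the activity percentage).
#'
#' @param visits Visit tibble (sorted; see [read_visits()]).
#' @param catalog Catalog tibble; defaults to the built-in program catalog.
#' @param access Optional access-window tibble ([access_windows()]). When
#'   `NULL`, each user's window starts at their first recorded visit.
#' @param timeout_minutes Inactivity timeout passed to [sessionize()].
#' @param n_months Number of study months reported (default 3).
#' @return An object of class `usage_summary`: a list with tibbles
#'   `monthly` (user x month grid) and `overall` (one row per user), plus
#'   the activity `denominator` and the settings used.
#' @export
summarize_usage <- function(visits, catalog = default_catalog(),
                            access = NULL, timeout_minutes = 30,
                            n_months = 3L) {
  validate_visits(visits)
  validate_catalog(catalog)
  denom <- catalog_denominator(catalog)
  access <- access %||% derive_access(visits)
  users <- sort(unique(c(visits$user_id, access$user_id)))
  no_window <- setdiff(visits$user_id, access$user_id)
  if (length(no_window) > 0) {
    stop("no access window for user(s): ",
      paste(unique(no_window), collapse = ", "),
      call. = FALSE
    )
  }

  empty_grid <- tidyr::expand_grid(
    user_id = users, month = seq_len(n_months)
  )

  if (nrow(visits) == 0) {
    monthly <- fill_monthly(empty_grid, NULL, NULL, NULL)
    return(new_usage_summary(monthly, overall_from_monthly(monthly, NULL,
      denom = denom
    ), denom, timeout_minutes, access))
  }

  v <- left_join(visits, access, by = "user_id")
  v$month <- assign_study_month(
    v$timestamp, v$access_start, v$access_days
  )
  late <- is.na(v$month)
  if (any(late)) {
    warning("dropping ", sum(late),
      " visit(s) after the access window ended",
      call. = FALSE
    )
    v <- v[!late, , drop = FALSE]
  }
  v <- v[, c(VISIT_COLUMNS, "month")]
  sv <- attach_categories(
    sessionize(v, timeout_minutes = timeout_minutes), catalog
  )

  sess <- sv |>
    group_by(.data$user_id, .data$session_id) |>
    summarise(
      month = first(.data$month),
      duration_seconds = as.numeric(difftime(max(.data$timestamp),
        min(.data$timestamp),
        units = "secs"
      )),
      .groups = "drop"
    )

  logins <- sv |>
    filter(.data$is_login) |>
    count(.data$user_id, .data$month, name = "logins")
  sessions <- sess |>
    count(.data$user_id, .data$month, name = "sessions")
  minutes <- sess |>
    group_by(.data$user_id, .data$month) |>
    summarise(minutes = sum(.data$duration_seconds) / 60, .groups = "drop")

  countable <- sv |>
    filter(.data$category %in% countable_categories())
  views_month <- countable |>
    group_by(.data$user_id, .data$month, .data$category) |>
    summarise(
      total_views = n(),
      unique_views = n_distinct(.data$component_id),
      .groups = "drop"
    )

  monthly <- fill_monthly(empty_grid, logins, sessions, minutes, views_month)

  views_overall <- countable |>
    group_by(.data$user_id, .data$category) |>
    summarise(
      total_views = n(),
      unique_views = n_distinct(.data$component_id),
      .groups = "drop"
    )
  unique_overall <- countable |>
    group_by(.data$user_id) |>
    summarise(
      overall_unique_components = n_distinct(.data$component_id),
      .groups = "drop"
    )
  overall <- overall_from_monthly(monthly, views_overall,
    unique_overall = unique_overall, denom = denom
  )
  new_usage_summary(monthly, overall, denom, timeout_minutes, access)
}

fill_monthly <- function(grid, logins, sessions, minutes, views = NULL) {
  out <- grid
  for (tb in list(logins, sessions, minutes)) {
    if (!is.null(tb)) out <- left_join(out, tb, by = c("user_id", "month"))
  }
  for (col in c("logins", "sessions", "minutes")) {
    if (!col %in% names(out)) out[[col]] <- 0
    out[[col]][is.na(out[[col]])] <- 0
  }
  cats <- countable_categories()
  if (!is.null(views) && nrow(views) > 0) {
    wide <- views |>
      pivot_wider(
        names_from = "category",
        values_from = c("total_views", "unique_views"),
        values_fill = 0
      )
    out <- left_join(out, wide, by = c("user_id", "month"))
  }
  for (col in c(
    paste0("total_views_", cats), paste0("unique_views_", cats)
  )) {
    if (!col %in% names(out)) out[[col]] <- 0L
    out[[col]][is.na(out[[col]])] <- 0L
  }
  out$logins <- as.integer(out$logins)
  out$sessions <- as.integer(out$sessions)
  out |> arrange(.data$user_id, .data$month)
}

overall_from_monthly <- function(monthly, views_overall,
                                 unique_overall = NULL, denom) {
  cats <- countable_categories()
  sum_cols <- c(
    "logins", "sessions", "minutes", paste0("total_views_", cats)
  )
  overall <- monthly |>
    group_by(.data$user_id) |>
    summarise(
      dplyr::across(dplyr::all_of(sum_cols), sum),
      .groups = "drop"
    )
  for (cat in cats) {
    ucol <- paste0("unique_views_", cat)
    if (!is.null(views_overall) && nrow(views_overall) > 0) {
      u <- views_overall |>
        filter(.data$category == cat) |>
        select("user_id", "unique_views")
      overall <- left_join(overall, u, by = "user_id")
      overall[[ucol]] <- as.integer(replace_na(overall$unique_views, 0L))
      overall$unique_views <- NULL
    } else {
      overall[[ucol]] <- 0L
    }
    overall[[paste0("repeat_views_", cat)]] <-
      overall[[paste0("total_views_", cat)]] - overall[[ucol]]
  }
  if (!is.null(unique_overall)) {
    overall <- left_join(overall, unique_overall, by = "user_id")
    overall$overall_unique_components <-
      as.integer(replace_na(overall$overall_unique_components, 0L))
  } else {
    overall$overall_unique_components <- 0L
  }
  overall$activity_proportion <- if (denom > 0) {
    overall$overall_unique_components / denom
  } else {
    NA_real_
  }
  overall
}

new_usage_summary <- function(monthly, overall, denominator,
                              timeout_minutes, access) {
  structure(
    list(
      monthly = monthly, overall = overall, denominator = denominator,
      timeout_minutes = timeout_minutes, access = access
    ),
    class = "usage_summary"
  )
}

#' @export
print.usage_summary <- function(x, ...) {
  cat(
    "<usage_summary> ", nrow(x$overall), " user(s), ",
    "denominator ", x$denominator, " components, timeout ",
    x$timeout_minutes, " min\n",
    sep = ""
  )
  invisible(x)
}

#' Cohort-level monthly table
#'
#' Mean and sample standard deviation (n-1 denominator) of each monthly
#' metric across users. With a single user the SD is reported as missing.
#'
#' @param summary A `usage_summary` object.
#' @return Long tibble with columns `month`, `metric`, `mean`, `sd`, `n`.
#' @export
cohort_table <- function(summary) {
  stopifnot(inherits(summary, "usage_summary"))
  if (nrow(summary$overall) < 1) {
    stop("cohort_table needs at least one user", call. = FALSE)
  }
  summary$monthly |>
    pivot_longer(-c("user_id", "month"),
      names_to = "metric", values_to = "value"
    ) |>
    group_by(.data$month, .data$metric) |>
    summarise(
      mean = mean(.data$value),
      sd = sd(.data$value),
      n = n(),
      .groups = "drop"
    )
}

#' Suggested program dose
#'
#' The usage suggestion given to participants at enrollment: 20-30 minutes,
#' 2-3 times per week, for 12 weeks. The minimum adds up to 24 logins and
#' 480 total minutes; the maximum to 36 logins and 1080 minutes. The
#' low-frequency tier boundary (12 logins) is half the suggested minimum.
#'
#' @return Named list with `logins_min`, `logins_max`, `minutes_min`,
#'   `minutes_max`.
#' @export
suggested_dose <- function() {
  weeks <- 12
  list(
    logins_min = 2 * weeks,
    logins_max = 3 * weeks,
    minutes_min = 20 * 2 * weeks,
    minutes_max = 30 * 3 * weeks
  )
}
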