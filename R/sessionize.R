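# Session reconstruction. A session is a maximal run of one user's
# consecutive page visits: it begins at a login event and ends at the next
# login or when the gap to the next visit reaches the inactivity timeout.
# Activity resuming after a timeout opens a new session that is *not*
# counted as a login (the printed cohort means distinguish logins from
# sessions, which requires exactly this convention). Dwell on a visit is the
# time to the next visit within the session; the last visit's dwell is
# unknowable from the log and contributes 0, so durations are lower bounds.

#' Reconstruct sessions from page visits
#'
#' Annotates a sorted visit table with session membership and per-visit
#' dwell. A new session starts at every login event and at every visit whose
#' gap from the previous visit is at least `timeout_minutes` (a gap exactly
#' equal to the timeout expires the session). Sessions opened by a timeout
#' split carry `started_by_login = FALSE`.
#'
#' @param visits Visit tibble sorted by user and timestamp (as returned by
#'   [read_visits()] or [generate_cohort()]); unsorted input is an error.
#' @param timeout_minutes Positive inactivity timeout; default 30 minutes.
#' @return `visits` with added columns `session_id`, `session_index`
#'   (per-user ordinal), `started_by_login` and `dwell_seconds`.
#' @examples
#' v <- tibble::tibble(
#'   user_id = "u1",
#'   timestamp = as.POSIXct("2024-01-01 09:00:00", tz = "UTC") +
#'     c(0, 300, 600, 1200),
#'   is_login = c(TRUE, FALSE, FALSE, FALSE),
#'   component_id = c(NA, "sec_001", "sec_002", "ex_001")
#' )
#' sessionize(v)
#' @export
sessionize <- function(visits, timeout_minutes = 30) {
  validate_visits(visits)
  if (!is.numeric(timeout_minutes) || length(timeout_minutes) != 1 ||
    is.na(timeout_minutes) || timeout_minutes <= 0) {
    stop("timeout_minutes must be a single positive number", call. = FALSE)
  }
  timeout_sec <- timeout_minutes * 60
  out <- visits |>
    group_by(.data$user_id) |>
    mutate(
      .gap = as.numeric(difftime(.data$timestamp, lag(.data$timestamp),
        units = "secs"
      ))
    ) |>
    ungroup()
  if (any(!is.na(out$.gap) & out$.gap < 0)) {
    stop("visits must be sorted by timestamp within each user", call. = FALSE)
  }
  out <- out |>
    group_by(.data$user_id) |>
    mutate(
      .new = .data$is_login | is.na(.data$.gap) | .data$.gap >= timeout_sec,
      session_index = cumsum(.data$.new)
    ) |>
    group_by(.data$user_id, .data$session_index) |>
    mutate(
      started_by_login = first(.data$is_login),
      dwell_seconds = {
        d <- as.numeric(difftime(lead(.data$timestamp), .data$timestamp,
          units = "secs"
        ))
        d[is.na(d)] <- 0
        d
      }
    ) |>
    ungroup() |>
    mutate(
      session_id = sprintf("%s_s%04d", .data$user_id, .data$session_index)
    ) |>
    select(-".gap", -".new")
  out
}

#' Per-session summary table
#'
#' @param visits A sessionized visit tibble (see [sessionize()]).
#' @return One row per session: `user_id`, `session_id`, `session_index`,
#'   `start`, `end`, `n_visits`, `started_by_login`, `duration_seconds`
#'   (lower bound: last timestamp minus first).
#' @export
session_table <- function(visits) {
  require_sessionized(visits)
  visits |>
    group_by(.data$user_id, .data$session_id, .data$session_index) |>
    summarise(
      start = min(.data$timestamp),
      end = max(.data$timestamp),
      n_visits = n(),
      started_by_login = first(.data$started_by_login),
      duration_seconds = as.numeric(difftime(max(.data$timestamp),
        min(.data$timestamp),
        units = "secs"
      )),
      .groups = "drop"
    ) |>
    arrange(.data$user_id, .data$start)
}

require_sessionized <- function(visits) {
  needed <- c("session_id", "session_index", "started_by_login", "dwell_seconds")
  if (!all(needed %in% names(visits))) {
    stop("expected a sessionized visit table; run sessionize() first",
      call. = FALSE
    )
  }
  invisible(visits)
}

#' Count login events and sessions
#'
#' Logins are login events in the log; sessions are reconstructed usage
#' episodes. More than one session can occur within a single login when an
#' inactivity timeout splits it, so session counts are at least login
#' counts on logs whose every session chain begins with a login.
#'
#' @param x A visit tibble (for `count_logins()`) or a sessionized visit
#'   tibble / session table (for `count_sessions()`).
#' @return Integer count.
#' @export
count_logins <- function(x) {
  if (!"is_login" %in% names(x)) {
    stop("expected a visit table with an is_login column", call. = FALSE)
  }
  sum(x$is_login)
}

#' @rdname count_logins
#' @export
count_sessions <- function(x) {
  if ("session_id" %in% names(x) && "timestamp" %in% names(x)) {
    return(n_distinct(x$session_id))
  }
  if (all(c("session_id", "duration_seconds") %in% names(x))) {
    return(nrow(x))
  }
  stop("expected a sessionized visit table or a session table", call. = FALSE)
}

#' Cumulative dwell per user and component
#'
#' Sums within-session dwell over all visits to each component. The last
#' visit of a session contributes 0, so totals are lower bounds for true
#' viewing time.
#'
#' @param visits A sessionized visit tibble.
#' @return Tibble with `user_id`, `component_id`, `dwell_seconds`.
#' @export
dwell_by_component <- function(visits) {
  require_sessionized(visits)
  visits |>
    filter(!is.na(.data$component_id)) |>
    group_by(.data$user_id, .data$component_id) |>
    summarise(dwell_seconds = sum(.data$dwell_seconds), .groups = "drop")
}
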