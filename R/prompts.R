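# Automated usage-prompt trigger detection. The intervention sent
# congratulatory emails after every two hours of accumulated program use
# and a pre-written informative email for each cognitive-behavioral
# exercise once a user spent two or more minutes on it. This module detects
# the trigger instants from the log; it does not send mail.

#' Congratulatory-prompt triggers
#'
#' One trigger per user at the first instant cumulative lower-bound use
#' reaches `k * every_minutes` for k = 1, 2, .... Cumulative use is the sum
#' of within-session dwell; the trigger instant is interpolated inside the
#' visit whose dwell interval crosses the threshold. The trigger count per
#' user equals `floor(total_minutes / every_minutes)`.
#'
#' @param visits A sessionized visit tibble (see [sessionize()]).
#' @param every_minutes Accumulated-use step between prompts; default 120
#'   (two hours).
#' @return Tibble with `user_id`, `k` (trigger index), `time`.
#' @export
congrats_triggers <- function(visits, every_minutes = 120) {
  require_sessionized(visits)
  thr <- every_minutes * 60
  per_user <- split(visits, visits$user_id)
  rows <- lapply(per_user, function(v) {
    v <- v[order(v$timestamp), , drop = FALSE]
    d <- v$dwell_seconds
    after <- cumsum(d)
    before <- c(0, head(after, -1))
    klo <- floor(before / thr) + 1
    khi <- floor(after / thr)
    hit <- which(khi >= klo)
    if (length(hit) == 0) {
      return(NULL)
    }
    ks <- unlist(lapply(hit, function(i) seq(klo[i], khi[i])))
    idx <- rep(hit, khi[hit] - klo[hit] + 1)
    tibble(
      user_id = v$user_id[1],
      k = as.integer(ks),
      time = v$timestamp[idx] + (ks * thr - before[idx])
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(
      user_id = character(), k = integer(),
      time = as.POSIXct(character(), tz = "UTC")
    ))
  }
  out |> arrange(.data$user_id, .data$k)
}

#' Exercise-email triggers
#'
#' Fires at most once per user and exercise, at the first page visit whose
#' within-session dwell on that exercise reaches `min_seconds` (a single
#' continuous viewing episode, not dwell accumulated across visits). The
#' trigger instant is the visit start plus `min_seconds`.
#'
#' @param visits A sessionized visit tibble; a `category` column is
#'   attached from `catalog` when absent.
#' @param catalog Catalog tibble used to identify exercise components.
#' @param min_seconds Dwell threshold; default 120 (two minutes).
#' @return Tibble with `user_id`, `component_id`, `time`.
#' @export
exercise_triggers <- function(visits, catalog = default_catalog(),
                              min_seconds = 120) {
  require_sessionized(visits)
  if (!"category" %in% names(visits)) {
    visits <- attach_categories(visits, catalog)
  }
  hits <- visits |>
    filter(.data$category == "exercise", .data$dwell_seconds >= min_seconds) |>
    arrange(.data$user_id, .data$timestamp) |>
    group_by(.data$user_id, .data$component_id) |>
    slice_head(n = 1) |>
    ungroup()
  tibble(
    user_id = hits$user_id,
    component_id = hits$component_id,
    time = hits$timestamp + min_seconds
  )
}
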