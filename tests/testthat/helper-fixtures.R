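# Shared fixtures: small hand-built visit logs and random-log generators.

T0 <- as.POSIXct("2024-01-01 09:00:00", tz = "UTC")

# One user's visits at the given minute offsets from `start`.
mk_visits <- function(mins, user = "u1", logins = NULL, comps = NULL,
                      start = T0) {
  n <- length(mins)
  if (is.null(logins)) {
    logins <- if (n == 0) logical(0) else c(TRUE, rep(FALSE, n - 1))
  }
  if (is.null(comps)) comps <- rep(NA_character_, n)
  tibble::tibble(
    user_id = user,
    timestamp = start + round(mins * 60),
    is_login = logins,
    component_id = comps
  )
}

# Four visits at gaps 5, 5 and 10 minutes after a login: one session that
# lasted at least 20 minutes.
fig1_visits <- function(user = "u1") {
  mk_visits(c(0, 5, 10, 20),
    user = user,
    comps = c(NA, "sec_001", "sec_002", "ex_001")
  )
}

# A login, one more visit, then activity resuming after a 31-minute gap:
# one login but two sessions.
fig2_visits <- function(user = "u1") {
  mk_visits(c(0, 4, 35, 40),
    user = user,
    logins = c(TRUE, FALSE, FALSE, FALSE),
    comps = c(NA, "sec_001", "sec_002", "vid_001")
  )
}

# Random single-user log: mixed short/long gaps (some beyond the timeout),
# random login flags, occasional zero gaps (timestamp ties).
random_user_log <- function(n, user = "u1", timeout_minutes = 30,
                            p_login = 0.25, start = T0) {
  gaps <- sample(
    c(0, 30, 120, 600, 1500, 1799, 1800, 1801, 3600, 7200),
    n,
    replace = TRUE,
    prob = c(.05, .2, .2, .2, .1, .05, .05, .05, .05, .05)
  )
  comp_pool <- c(NA, sprintf("sec_%03d", 1:5), sprintf("ex_%03d", 1:5))
  tibble::tibble(
    user_id = user,
    timestamp = start + cumsum(gaps),
    is_login = c(TRUE, stats::runif(n - 1) < p_login),
    component_id = sample(comp_pool, n, replace = TRUE)
  )
}

# Random multi-user log, sorted the way read_visits() returns it.
random_log <- function(n_users = 3, n_visits = 20, ...) {
  out <- dplyr::bind_rows(lapply(seq_len(n_users), function(i) {
    random_user_log(n_visits, user = sprintf("u%02d", i), ...)
  }))
  out[order(out$user_id, out$timestamp), ]
}

# Small psychosocial table for I/O and change-score tests.
mk_psych <- function(users = c("u1", "u2")) {
  grid <- expand.grid(
    user_id = users, timepoint = c("baseline", "m1", "m2", "m3"),
    stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$user_id), ]
  tibble::tibble(
    user_id = grid$user_id,
    timepoint = grid$timepoint,
    distress = rep(c(6, 4, 3, 3), length(users)),
    depressive = rep(c(20, 17, 15, 12), length(users)),
    intrusive_avoidant = rep(c(30, 26, 24, 20), length(users)),
    sc_partner = rep(c(22, 21, 20, 20), length(users)),
    sc_family = rep(c(18, 18, 17, 16), length(users))
  )
}
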