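# Seeded synthetic-cohort generator. Produces clickstreams plus
# psychosocial trajectories with the statistical structure the analysis
# pipeline assumes, and records ground truth (archetype labels, tier
# targets, latent parameters, true session exit times) so that recovery can
# be tested exactly. Generation is archetype-conditional: labels are drawn
# first and logs are generated to match them, which gives exact ground
# truth for classifier-recovery experiments.

#' Cohort generator configuration
#'
#' Defaults emulate the study conditions of a 53-user pilot with a 12-week
#' (84-day) access window: a 70/28/2 continuous/intermittent/non-user mix,
#' month-over-month attrition in session rate and duration (sharpest
#' decline between months 1 and 2), geometric visits-per-session around 6,
#' log-normal per-visit dwell with a 90-second median, category preferences
#' with revisit affinity concentrated on exercises and module pages, and a
#' shared latent-distress variable that couples usage to the psychosocial
#' scores: it raises total duration for users with high baseline
#' intrusive/avoidant scores, raises login frequency for users with high
#' baseline depressive scores, and makes the intrusive/avoidant decline
#' steeper with more unique exercise views.
#'
#' @param n_users Cohort size (default 53).
#' @param seed Default RNG seed used by [generate_cohort()].
#' @param archetype_mix Proportions of continuous/intermittent/non-user
#'   archetypes; must sum to 1.
#' @param freq_tier_mix Proportions of low/moderate/high login-frequency
#'   tiers among continuous users.
#' @param tier_match_prob Probability that a continuous user's activity
#'   tier matches their frequency tier (the matched cross groups).
#' @param freq_bands Per-tier target bands for total logins, kept strictly
#'   inside the classification boundaries (1-12 / 13-24 / >=25) so that
#'   tier recovery is exact.
#' @param intermittent_logins Range of total logins for intermittent users.
#' @param activity_bands Per-tier target bands for the unique-component
#'   proportion, strictly inside 0-25% / 26-50% / 51-100%.
#' @param month_multipliers Relative expected login/session rate by study
#'   month.
#' @param duration_multipliers Relative per-visit dwell scale by study
#'   month.
#' @param visits_per_session_mean Mean page visits per session.
#' @param dwell_median_seconds,dwell_sdlog Log-normal dwell parameters.
#' @param timeout_split_prob Probability that a session contains an
#'   inactivity gap and is split in two by the sessionizer.
#' @param inactivity_timeout_minutes Timeout assumed when generating (and
#'   later reconstructing) sessions.
#' @param category_weights Expected share of views per countable category.
#' @param revisit_affinity Relative repeat-view propensity per category.
#' @param coupling Latent-distress coupling strengths: `duration_ies`
#'   (log-scale dwell increase per latent unit), `freq_cesd` (weight of the
#'   latent variable in frequency-tier placement), `ies_exercise`
#'   (additional intrusive/avoidant decline per unique exercise view).
#' @param psychosocial Baseline means, latent loadings, noise SDs, monthly
#'   decline trends and follow-up noise for the instrument totals.
#' @param access_days,access_start The shared access window.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_users = 53,
                          seed = 1L,
                          archetype_mix = c(
                            continuous = 0.70, intermittent = 0.28,
                            non_user = 0.02
                          ),
                          freq_tier_mix = c(
                            low = 0.32, moderate = 0.40, high = 0.28
                          ),
                          tier_match_prob = 0.65,
                          freq_bands = list(
                            low = c(4, 10), moderate = c(15, 22),
                            high = c(26, 34)
                          ),
                          intermittent_logins = c(2, 9),
                          activity_bands = list(
                            low = c(0.08, 0.20), moderate = c(0.30, 0.45),
                            high = c(0.55, 0.75)
                          ),
                          month_multipliers = c(1, 0.60, 0.55),
                          duration_multipliers = c(1, 0.75, 0.60),
                          visits_per_session_mean = 6,
                          dwell_median_seconds = 90,
                          dwell_sdlog = 0.9,
                          timeout_split_prob = 0.08,
                          inactivity_timeout_minutes = 30,
                          category_weights = c(
                            module_section = 0.30, exercise = 0.25,
                            video = 0.30, resource = 0.15
                          ),
                          revisit_affinity = c(
                            module_section = 3.0, exercise = 3.5,
                            video = 1.0, resource = 1.8
                          ),
                          coupling = list(
                            duration_ies = 0.35, freq_cesd = 1.0,
                            ies_exercise = 0.6
                          ),
                          psychosocial = list(
                            dt_mean = 4.5, dt_load = 1.8, dt_sd = 0.9,
                            cesd_mean = 14, cesd_load = 6, cesd_sd = 7,
                            ies_mean = 24, ies_load = 10, ies_sd = 8,
                            scp_mean = 22, scp_load = 4, scp_sd = 4,
                            scp_missing = 0.35,
                            scf_mean = 20, scf_load = 3, scf_sd = 4,
                            monthly_decline = c(dt = 0.35, cesd = 1.0, ies = 1.5),
                            follow_noise = c(dt = 1.0, cesd = 3.0, ies = 4.0, sc = 2.0)
                          ),
                          access_days = 84L,
                          access_start = as.POSIXct("2024-01-01 00:00:00",
                            tz = "UTC"
                          )) {
  cfg <- list(
    n_users = as.integer(n_users), seed = seed,
    archetype_mix = archetype_mix, freq_tier_mix = freq_tier_mix,
    tier_match_prob = tier_match_prob, freq_bands = freq_bands,
    intermittent_logins = intermittent_logins,
    activity_bands = activity_bands,
    month_multipliers = month_multipliers,
    duration_multipliers = duration_multipliers,
    visits_per_session_mean = visits_per_session_mean,
    dwell_median_seconds = dwell_median_seconds,
    dwell_sdlog = dwell_sdlog,
    timeout_split_prob = timeout_split_prob,
    inactivity_timeout_minutes = inactivity_timeout_minutes,
    category_weights = category_weights,
    revisit_affinity = revisit_affinity,
    coupling = coupling, psychosocial = psychosocial,
    access_days = as.integer(access_days), access_start = access_start
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_users < 1) stop("n_users must be positive", call. = FALSE)
  if (abs(sum(cfg$archetype_mix) - 1) > 1e-8) {
    stop("archetype_mix proportions must sum to 1", call. = FALSE)
  }
  if (any(cfg$archetype_mix < 0)) {
    stop("archetype_mix proportions must be nonnegative", call. = FALSE)
  }
  if (!setequal(
    names(cfg$archetype_mix), c("continuous", "intermittent", "non_user")
  )) {
    stop("archetype_mix must name continuous, intermittent, non_user",
      call. = FALSE
    )
  }
  if (abs(sum(cfg$freq_tier_mix) - 1) > 1e-8 || any(cfg$freq_tier_mix < 0)) {
    stop("freq_tier_mix must be nonnegative proportions summing to 1",
      call. = FALSE
    )
  }
  for (b in cfg$freq_bands) {
    if (length(b) != 2 || b[1] > b[2] || b[1] < 1) {
      stop("freq_bands must be increasing pairs of positive logins",
        call. = FALSE
      )
    }
  }
  ab <- unlist(cfg$activity_bands)
  if (any(ab < 0) || any(ab > 1)) {
    stop("activity bands must be proportions in [0, 1] of the catalog size",
      call. = FALSE
    )
  }
  if (any(cfg$month_multipliers <= 0) || any(cfg$duration_multipliers <= 0)) {
    stop("monthly multipliers must be positive", call. = FALSE)
  }
  if (cfg$visits_per_session_mean < 1 || cfg$dwell_median_seconds <= 0 ||
    cfg$inactivity_timeout_minutes <= 0) {
    stop("session-shape parameters must be positive", call. = FALSE)
  }
  if (cfg$timeout_split_prob < 0 || cfg$timeout_split_prob > 1 ||
    cfg$tier_match_prob < 0 || cfg$tier_match_prob > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

# Integer allocation of `total` across `weights` (largest-remainder rule;
# deterministic, ties broken by position).
largest_remainder <- function(total, weights) {
  w <- weights / sum(weights)
  raw <- total * w
  base <- floor(raw)
  need <- total - sum(base)
  if (need > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(need)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

resample <- function(x, ...) x[sample.int(length(x), ...)]

# Multinomial split of `total` logins over months, honoring active months
# and a minimum of one login in each required month. The min-one fix-up
# draws the donor month at random among the maxima, so under equal
# multipliers the months stay exchangeable (the null harness depends on
# this).
distribute_logins <- function(total, mult, active = rep(TRUE, 3),
                              required = active) {
  p <- ifelse(active, mult, 0)
  p <- p / sum(p)
  m <- as.vector(rmultinom(1, total, p))
  for (j in which(required & m == 0)) {
    donors <- which(m > 1)
    if (length(donors) == 0) donors <- setdiff(which(m >= 1), j)
    mx <- donors[m[donors] == max(m[donors])]
    i <- mx[sample.int(length(mx), 1)]
    m[i] <- m[i] - 1
    m[j] <- m[j] + 1
  }
  as.integer(m)
}

# One user's clickstream. Returns numeric second offsets from access start;
# every planned login is emitted as a login event, every component of
# `unique_ids` appears at least once, and all dwell draws stay strictly
# below the timeout so sessions split only where the generator plants a
# gap. The dwell of each session's true last page is drawn but invisible in
# the observable log, giving known true exit times.
gen_user_log <- function(uid, logins_by_month, unique_ids, comp_cat,
                         dwell_scale, config, intro_ids) {
  total_logins <- sum(logins_by_month)
  if (total_logins == 0) {
    return(NULL)
  }
  timeout_sec <- config$inactivity_timeout_minutes * 60
  dwell_cap <- max(min(1500, timeout_sec - 300), 10)
  month_len <- 28 * 86400
  u <- length(unique_ids)
  if (u > 0) {
    mean_content <- max(config$visits_per_session_mean - 1, 1)
    # per-session content cap keeps sessions short enough to stay inside
    # their time slot; raised when few sessions must cover many components
    cap <- max(20L, as.integer(ceiling(u / total_logins)))
    k <- pmin(1 + rgeom(total_logins, 1 / mean_content), cap)
    i <- 1
    while (sum(k) < u) {
      if (k[i] < cap) k[i] <- k[i] + 1
      i <- i %% total_logins + 1
    }
    n_repeat <- sum(k) - u
    repeats <- if (n_repeat > 0) {
      resample(
        unique_ids, n_repeat,
        replace = TRUE,
        prob = config$revisit_affinity[comp_cat[unique_ids]]
      )
    } else {
      character(0)
    }
    content <- resample(c(unique_ids, repeats), sum(k))
    content_by_session <- split(
      content, factor(rep(seq_len(total_logins), k),
        levels = seq_len(total_logins)
      )
    )
  } else {
    content_by_session <- rep(list(character(0)), total_logins)
  }

  v_off <- vector("list", total_logins)
  v_login <- vector("list", total_logins)
  v_comp <- vector("list", total_logins)
  t_start <- vector("list", total_logins)
  t_oend <- vector("list", total_logins)
  t_tend <- vector("list", total_logins)
  t_nv <- vector("list", total_logins)
  sidx <- 0
  for (m in 1:3) {
    km <- logins_by_month[m]
    if (km == 0) next
    w <- month_len / km
    base <- (m - 1) * month_len + (seq_len(km) - 1) * w
    st <- floor(base + runif(km, 0, 0.4 * w))
    for (j in seq_len(km)) {
      sidx <- sidx + 1
      comps <- content_by_session[[sidx]]
      comps <- c(
        NA_character_,
        if (sidx == 1 && length(comps) > 0) intro_ids,
        comps
      )
      nv <- length(comps)
      dw <- pmax(5, pmin(dwell_cap, round(
        rlnorm(nv, log(config$dwell_median_seconds), config$dwell_sdlog) *
          config$duration_multipliers[m] * dwell_scale
      )))
      true_dwell <- dw
      if (nv >= 3 && runif(1) < config$timeout_split_prob) {
        cut <- if (nv == 3) 2L else resample(2:(nv - 1), 1)
        dw[cut] <- timeout_sec + floor(runif(1, 60, 900))
      }
      times <- st[j] + cumsum(c(0, dw[-nv]))
      piece <- cumsum(c(TRUE, dw[-nv] >= timeout_sec))
      v_off[[sidx]] <- times
      v_login[[sidx]] <- c(TRUE, rep(FALSE, nv - 1))
      v_comp[[sidx]] <- comps
      changes <- which(c(TRUE, diff(piece) == 1))
      firsts <- changes
      lasts <- c(changes[-1] - 1L, nv)
      t_start[[sidx]] <- times[firsts]
      t_oend[[sidx]] <- times[lasts]
      t_tend[[sidx]] <- times[lasts] + true_dwell[lasts]
      t_nv[[sidx]] <- lasts - firsts + 1L
    }
  }
  nvis <- length(unlist(v_off))
  list(
    user_id = rep(uid, nvis),
    offset = unlist(v_off),
    is_login = unlist(v_login),
    component_id = unlist(v_comp),
    truth_user = rep(uid, length(unlist(t_start))),
    truth_start = unlist(t_start),
    truth_oend = unlist(t_oend),
    truth_tend = unlist(t_tend),
    truth_nv = unlist(t_nv)
  )
}

#' Generate a synthetic cohort
#'
#' Draws archetype labels, tier targets and a latent-distress variable,
#' then generates a clickstream that matches the targets exactly (every
#' planned login is a login event; the set of distinct components opened
#' equals the target) together with four-timepoint psychosocial records.
#' Reproducible: a fixed seed yields identical output.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An object of class `synthetic_cohort`: a list with `visits`,
#'   `psychosocial`, `truth` (`$users` with archetype/tier targets and
#'   latent parameters, `$sessions` with true exit times), `access`,
#'   `config` and `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  set.seed(as.integer(seed))

  catalog <- default_catalog()
  countable <- catalog[catalog$category %in% countable_categories(), ]
  denom <- nrow(countable)
  comp_ids <- countable$component_id
  comp_cat <- setNames(countable$category, comp_ids)
  n_by_cat <- table(countable$category)
  comp_w <- as.numeric(
    config$category_weights[countable$category] /
      n_by_cat[countable$category]
  )
  intro_ids <- catalog$component_id[catalog$category == "intro"]

  n <- config$n_users
  counts <- largest_remainder(
    n, config$archetype_mix[c("continuous", "intermittent", "non_user")]
  )
  status <- sample(rep(c("continuous", "intermittent", "non_user"), counts))
  z <- rnorm(n)
  uid <- sprintf("u%03d", seq_len(n))

  target_logins <- integer(n)
  target_p <- numeric(n)
  ft <- rep(NA_character_, n)
  at <- rep(NA_character_, n)

  ic <- which(status == "continuous")
  if (length(ic) > 0) {
    nc <- length(ic)
    rank_var <- config$coupling$freq_cesd * z[ic] + rnorm(nc, 0, 0.5)
    ord <- order(rank_var, decreasing = TRUE)
    tier_counts <- largest_remainder(
      nc, config$freq_tier_mix[c("high", "moderate", "low")]
    )
    ftc <- character(nc)
    ftc[ord] <- rep(c("high", "moderate", "low"), tier_counts)
    atc <- ftc
    jit <- runif(nc) > config$tier_match_prob
    atc[jit & ftc == "low"] <- "moderate"
    atc[jit & ftc == "high"] <- "moderate"
    mid <- which(jit & ftc == "moderate")
    if (length(mid) > 0) {
      atc[mid] <- resample(c("low", "high"), length(mid), replace = TRUE)
    }
    # keep the top-ranked user of each frequency tier matched so all three
    # matched cross groups are populated under the default mix
    for (tier in c("high", "moderate", "low")) {
      top <- ord[ftc[ord] == tier][1]
      if (!is.na(top)) atc[top] <- tier
    }
    sd_rank <- sqrt(config$coupling$freq_cesd^2 + 0.25)
    u01 <- stats::pnorm(rank_var / sd_rank)
    lo <- vapply(config$freq_bands, `[`, numeric(1), 1)[ftc]
    hi <- vapply(config$freq_bands, `[`, numeric(1), 2)[ftc]
    target_logins[ic] <- as.integer(round(lo + u01 * (hi - lo)))
    act_var <- z[ic] + rnorm(nc, 0, 0.7)
    a01 <- stats::pnorm(act_var / sqrt(1.49))
    alo <- vapply(config$activity_bands, `[`, numeric(1), 1)[atc]
    ahi <- vapply(config$activity_bands, `[`, numeric(1), 2)[atc]
    target_p[ic] <- alo + a01 * (ahi - alo)
    ft[ic] <- ftc
    at[ic] <- atc
  }

  ii <- which(status == "intermittent")
  if (length(ii) > 0) {
    ni <- length(ii)
    rng <- config$intermittent_logins
    target_logins[ii] <- resample(
      rep(seq(rng[1], rng[2]), 2), ni,
      replace = TRUE
    )
    in_moderate <- runif(ni) < 0.25
    blo <- ifelse(in_moderate, config$activity_bands$moderate[1],
      config$activity_bands$low[1]
    )
    bhi <- ifelse(in_moderate, config$activity_bands$moderate[2],
      config$activity_bands$low[2]
    )
    target_p[ii] <- blo + runif(ni) * (bhi - blo)
  }

  inu <- which(status == "non_user")
  target_logins[inu] <- 1L
  target_p[inu] <- 0

  target_unique <- as.integer(round(target_p * denom))
  target_unique[status != "non_user"] <- pmax(
    target_unique[status != "non_user"], 1L
  )
  if (any(target_unique > denom)) {
    stop("activity band implies more unique components than the catalog holds",
      call. = FALSE
    )
  }
  ft[ii] <- freq_tier(target_logins[ii])
  at[ii] <- activity_tier(target_unique[ii], denom)

  lbm <- matrix(0L, n, 3)
  for (i in seq_len(n)) {
    lbm[i, ] <- switch(status[i],
      non_user = c(1L, 0L, 0L),
      continuous = distribute_logins(
        target_logins[i], config$month_multipliers
      ),
      intermittent = {
        pattern <- resample(c("m1", "m12", "m13"), 1)
        active <- switch(pattern,
          m1 = c(TRUE, FALSE, FALSE),
          m12 = c(TRUE, TRUE, FALSE),
          m13 = c(TRUE, FALSE, TRUE)
        )
        distribute_logins(target_logins[i], config$month_multipliers,
          active = active, required = c(TRUE, FALSE, FALSE)
        )
      }
    )
  }

  dwell_scale <- exp(config$coupling$duration_ies * z)
  parts <- vector("list", n)
  unique_sets <- vector("list", n)
  for (i in seq_len(n)) {
    unique_sets[[i]] <- if (target_unique[i] > 0) {
      resample(comp_ids, target_unique[i], prob = comp_w)
    } else {
      character(0)
    }
    parts[[i]] <- gen_user_log(
      uid[i], lbm[i, ], unique_sets[[i]], comp_cat, dwell_scale[i],
      config, intro_ids
    )
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  pull_part <- function(field) unlist(lapply(parts, `[[`, field))
  visits <- tibble(
    user_id = pull_part("user_id"),
    timestamp = config$access_start + pull_part("offset"),
    is_login = pull_part("is_login"),
    component_id = pull_part("component_id")
  )
  visits <- visits[order(visits$user_id, visits$timestamp), , drop = FALSE]
  truth_sessions <- tibble(
    user_id = pull_part("truth_user"),
    start = config$access_start + pull_part("truth_start"),
    observed_end = config$access_start + pull_part("truth_oend"),
    true_end = config$access_start + pull_part("truth_tend"),
    n_visits = pull_part("truth_nv")
  )
  truth_sessions <- truth_sessions[
    order(truth_sessions$user_id, truth_sessions$start), ,
    drop = FALSE
  ]

  uex <- vapply(unique_sets, function(s) {
    sum(comp_cat[s] == "exercise")
  }, numeric(1))
  psychosocial <- gen_psychosocial(uid, z, uex, config)

  truth_users <- tibble(
    user_id = uid,
    archetype = status,
    freq_tier_target = ft,
    activity_tier_target = at,
    logins_target = target_logins,
    unique_target = target_unique,
    unique_exercises = as.integer(uex),
    latent_distress = z,
    dwell_scale = dwell_scale
  )

  structure(
    list(
      visits = visits,
      psychosocial = psychosocial,
      truth = list(users = truth_users, sessions = truth_sessions),
      access = access_windows(uid, config$access_start, config$access_days),
      config = config,
      seed = seed
    ),
    class = "synthetic_cohort"
  )
}

gen_psychosocial <- function(uid, z, uex, config) {
  p <- config$psychosocial
  n <- length(uid)
  clamp01_10 <- function(x) pmin(10, pmax(0, round(x)))
  nonneg <- function(x) pmax(0, round(x))
  dt0 <- clamp01_10(p$dt_mean + p$dt_load * z + rnorm(n, 0, p$dt_sd))
  cesd0 <- nonneg(p$cesd_mean + p$cesd_load * z + rnorm(n, 0, p$cesd_sd))
  ies0 <- nonneg(p$ies_mean + p$ies_load * z + rnorm(n, 0, p$ies_sd))
  partnered <- runif(n) >= p$scp_missing
  scp0 <- ifelse(
    partnered, nonneg(p$scp_mean + p$scp_load * z + rnorm(n, 0, p$scp_sd)),
    NA_real_
  )
  scf0 <- nonneg(p$scf_mean + p$scf_load * z + rnorm(n, 0, p$scf_sd))
  ies_slope <- p$monthly_decline[["ies"]] +
    config$coupling$ies_exercise * uex / 3
  rows <- vector("list", 4)
  rows[[1]] <- tibble(
    user_id = uid, timepoint = "baseline", distress = dt0,
    depressive = cesd0, intrusive_avoidant = ies0,
    sc_partner = scp0, sc_family = scf0
  )
  for (t in 1:3) {
    rows[[t + 1]] <- tibble(
      user_id = uid,
      timepoint = paste0("m", t),
      distress = clamp01_10(
        dt0 - t * p$monthly_decline[["dt"]] +
          rnorm(n, 0, p$follow_noise[["dt"]])
      ),
      depressive = nonneg(
        cesd0 - t * p$monthly_decline[["cesd"]] +
          rnorm(n, 0, p$follow_noise[["cesd"]])
      ),
      intrusive_avoidant = nonneg(
        ies0 - t * ies_slope + rnorm(n, 0, p$follow_noise[["ies"]])
      ),
      sc_partner = ifelse(
        partnered,
        nonneg(scp0 - 0.3 * t + rnorm(n, 0, p$follow_noise[["sc"]])),
        NA_real_
      ),
      sc_family = nonneg(scf0 - 0.3 * t + rnorm(n, 0, p$follow_noise[["sc"]]))
    )
  }
  out <- bind_rows(rows)
  out <- out[order(out$user_id, match(out$timepoint, TIMEPOINTS)), ,
    drop = FALSE
  ]
  validate_psychosocial(out)
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(
    "<synthetic_cohort> ", nrow(x$truth$users), " users, ",
    nrow(x$visits), " page visits, seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

#' Null configuration and null cohort
#'
#' `null_config()` strips the structure the inferential layer is meant to
#' detect: monthly attrition multipliers are set equal and all
#' latent-distress couplings to zero. The archetype mix is also set to
#' all-continuous: intermittent and non-user archetypes are month-1-heavy
#' by definition and would re-introduce a real month effect into a harness
#' meant to have none. `null_cohort()` generates a cohort under that
#' configuration; the within-subject ANOVA on its monthly login counts
#' should then reject at close to the nominal rate.
#'
#' @param config A [cohort_config()] to neutralize.
#' @param seed Integer seed.
#' @return `null_config()` a `cohort_config`; `null_cohort()` a
#'   `synthetic_cohort`.
#' @export
null_config <- function(config = cohort_config()) {
  config$archetype_mix <- c(continuous = 1, intermittent = 0, non_user = 0)
  config$month_multipliers <- c(1, 1, 1)
  config$duration_multipliers <- c(1, 1, 1)
  config$coupling <- list(
    duration_ies = 0, freq_cesd = 0, ies_exercise = 0
  )
  validate_cohort_config(config)
  config
}

#' @rdname null_config
#' @export
null_cohort <- function(config = cohort_config(), seed = config$seed) {
  generate_cohort(null_config(config), seed = seed)
}

#' Monthly login-count matrix of a cohort
#'
#' Fast path for simulation harnesses: counts login events per user and
#' study month directly from the visit log (no session reconstruction
#' needed, since logins are raw events).
#'
#' @param cohort A `synthetic_cohort`.
#' @return Integer matrix, users by months 1-3.
#' @export
monthly_login_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  v <- cohort$visits[cohort$visits$is_login, , drop = FALSE]
  acc <- cohort$access
  idx <- match(v$user_id, acc$user_id)
  m <- assign_study_month(
    v$timestamp, acc$access_start[idx], acc$access_days[idx]
  )
  tab <- table(
    factor(v$user_id, levels = acc$user_id),
    factor(m, levels = 1:3)
  )
  matrix(as.integer(tab),
    nrow = nrow(acc),
    dimnames = list(acc$user_id, paste0("m", 1:3))
  )
}

#' Usage-psychosocial association estimates for a synthetic cohort
#'
#' Runs the full pipeline (sessionization, metrics, correlations) on a
#' generated cohort and returns the three associations the generator
#' imposes, with their configured signs: baseline intrusive/avoidant score
#' vs total minutes (+), baseline depressive score vs total logins (+),
#' and intrusive/avoidant change from baseline to month 3 vs unique
#' exercise views (-). Used by sign-recovery experiments.
#'
#' @param cohort A `synthetic_cohort`.
#' @return Tibble `association`, `estimate`, `expected_sign`.
#' @export
association_estimates <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  summary <- summarize_usage(
    cohort$visits,
    access = cohort$access,
    timeout_minutes = cohort$config$inactivity_timeout_minutes
  )
  ov <- summary$overall
  base <- cohort$psychosocial |>
    filter(.data$timepoint == "baseline")
  d <- left_join(ov, base, by = "user_id")
  r_minutes <- pearson_cor(d$intrusive_avoidant, d$minutes)$estimate
  r_logins <- pearson_cor(d$depressive, d$logins)$estimate
  cs <- suppressMessages(
    change_scores(cohort$psychosocial, "intrusive_avoidant", "baseline", "m3")
  )
  d2 <- left_join(cs, ov, by = "user_id")
  r_ex <- pearson_cor(d2$unique_views_exercise, d2$delta)$estimate
  tibble(
    association = c(
      "ies_baseline_vs_minutes", "cesd_baseline_vs_logins",
      "ies_change_vs_unique_exercise"
    ),
    estimate = c(r_minutes, r_logins, r_ex),
    expected_sign = c(1, 1, -1)
  )
}
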