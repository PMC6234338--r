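#' Simulation configuration for a synthetic cohort
#'
#' Returns the default configuration for the synthetic-cohort generator,
#' with any element overridable by name. Defaults emulate the study
#' conditions of a self-selected mobile cohort: an age distribution
#' skewed young with a floor spike at 18 (the lowest selectable age),
#' ~60% female among those reporting gender, small missingness rates for
#' age/gender/questionnaire, an age-morningness correlation of about 0.3,
#' male advantages in the rotation / tracking / vigilance / action games
#' (none in the 2-back), age-related decline strongest in the vigilance
#' game, heavy-tailed session counts positively correlated with age, and
#' rising-then-stable practice curves in every game except the vigilance
#' game.
#'
#' @param n_participants cohort size.
#' @param seed master seed used by [simulate_dataset()]; mandatory there.
#' @param ... named overrides of any top-level element.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 1000L, seed = NULL, ...) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    seed = seed,
    games = GAMES,
    # age in years: floor spike at 18, else 18 + gamma
    age = list(floor = 18L, spike_prob = 0.07, shape = 1.8, scale = 9),
    missing = list(age = 0.074, gender = 0.0165, meq = 0.016),
    p_female = 0.60,
    # chronotype total: mean/sd on the 4-25 scale, coupled to age
    meq = list(mean = 13.2, sd = 4.0, age_coupling = 0.298),
    # session counts: 1 + negative binomial, log-linear in age
    engagement = list(mu = 7, size = 1.4, age_coupling = 0.18,
                      noise_sd = 0.35),
    # gender effect sizes (male - female), latent sd units, per game
    gender_d = c(hotspot = 0.31, react = 0.13, spin = 0.39,
                 supersnap = 0, track = 0.10),
    # latent shift per decade of age beyond 35, per game
    age_beta = c(hotspot = -0.03, react = -0.25, spin = -0.22,
                 supersnap = -0.20, track = -0.07),
    # practice: deficit * exp(-rate * (play_index - 1)) below asymptote
    practice = list(
      rate = c(hotspot = 0.4, react = 0, spin = 0.4,
               supersnap = 0.4, track = 0.4),
      deficit = c(hotspot = 0.8, react = 0, spin = 0.8,
                  supersnap = 0.8, track = 0.8)),
    mood = list(baseline_mean = 7, baseline_sd = 1.2, ar = 0.5,
                noise_sd = 1.0, performance_coupling = 0,
                skip_prob = 0.05),
    skip_prob = 0.08,               # per game per session
    sleep_question_skip_prob = 0.10,
    day_gap_mean = 2.5,             # days between sessions
    start_date = "2026-01-01",
    # hour-of-day preference shifts earlier with morningness
    time_of_day = list(mean_hour = 14, meq_shift = -0.35, sd = 3)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown sim_config element(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$n_participants >= 1L,
            cfg$p_female >= 0, cfg$p_female <= 1,
            all(unlist(cfg$missing) >= 0), all(unlist(cfg$missing) <= 1),
            cfg$skip_prob >= 0, cfg$skip_prob < 1)
  structure(cfg, class = "sim_config")
}

#' Sample a cohort of participant profiles
#'
#' Draws demographics (with the configured floor spike at age 18 and
#' independent missingness for reported age/gender), a chronotype total
#' coupled to age at the configured correlation, per-game latent
#' abilities, an engagement propensity coupled to age, and a mood
#' baseline.
#'
#' @param cfg a [sim_config()].
#' @return a tibble with one row per participant. True demographics are
#'   kept alongside the (possibly missing) reported values; columns
#'   `ability_<game>` hold standardized latent abilities.
#' @export
sample_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_participants
  id <- sprintf("p%06d", seq_len(n))

  spike <- stats::runif(n) < cfg$age$spike_prob
  age_true <- ifelse(spike, cfg$age$floor,
                     cfg$age$floor +
                       round(stats::rgamma(n, shape = cfg$age$shape,
                                           scale = cfg$age$scale)))
  gender_true <- ifelse(stats::runif(n) < cfg$p_female, "female", "male")

  z_age <- as.numeric(scale(age_true))
  r <- cfg$meq$age_coupling
  latent <- r * z_age + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
  meq_total <- pmin(25L, pmax(4L, as.integer(round(
    cfg$meq$mean + cfg$meq$sd * latent))))
  meq_total[stats::runif(n) < cfg$missing$meq] <- NA_integer_

  eng <- cfg$engagement
  engagement <- exp(eng$age_coupling * z_age +
                      stats::rnorm(n, sd = eng$noise_sd))

  abilities <- matrix(stats::rnorm(n * length(cfg$games)), nrow = n,
                      dimnames = list(NULL, paste0("ability_", cfg$games)))

  out <- tibble::tibble(
    participant_id = id,
    age_true = as.integer(age_true),
    gender_true = gender_true,
    age = ifelse(stats::runif(n) < cfg$missing$age, NA_integer_,
                 as.integer(age_true)),
    gender = ifelse(stats::runif(n) < cfg$missing$gender, NA_character_,
                    gender_true),
    meq_total = meq_total,
    engagement = engagement,
    mood_baseline = pmin(10, pmax(1, stats::rnorm(
      n, cfg$mood$baseline_mean, cfg$mood$baseline_sd)))
  )
  out[colnames(abilities)] <- as.data.frame(abilities)
  out
}

#' Sample per-participant session counts
#'
#' Heavy-tailed: `1 + NegBin(size, mu)` with the mean proportional to
#' the participant's engagement propensity, which is itself coupled to
#' age, reproducing the positive age-plays correlation of self-selected
#' cohorts. The count is always at least 1 and the implied survival
#' curve over session index is non-increasing.
#'
#' @param cohort tibble from [sample_cohort()].
#' @param cfg a [sim_config()].
#' @return integer vector of session counts, one per participant.
#' @export
sample_session_count <- function(cohort, cfg) {
  eng <- cfg$engagement
  norm <- exp((eng$age_coupling^2 + eng$noise_sd^2) / 2)
  1L + stats::rnbinom(nrow(cohort), size = eng$size,
                      mu = eng$mu * cohort$engagement / norm)
}

latent_skill <- function(profile, game, play_index, cfg, mood = NULL) {
  theta <- profile[[paste0("ability_", game)]]
  d <- cfg$gender_d[[game]]
  theta <- theta + ifelse(profile$gender_true == "male", d / 2, -d / 2)
  theta <- theta + cfg$age_beta[[game]] * (profile$age_true - 35) / 10
  theta <- theta - cfg$practice$deficit[[game]] *
    exp(-cfg$practice$rate[[game]] * (play_index - 1))
  if (!is.null(mood) && cfg$mood$performance_coupling != 0)
    theta <- theta + cfg$mood$performance_coupling * (mood - 5.5) / 2.7
  theta
}

#' Build a simulated responder for one participant, game and play
#'
#' The responder's expected performance follows the learning curve
#' `asymptote - deficit * exp(-rate * (play_index - 1))` on the latent
#' skill scale, with gender and age shifts applied per the configured
#' effect sizes. Response models are simple parametric forms: shifted
#' lognormal latencies with logistic accuracy for the vigilance and
#' rotation games, logistic hit/false-alarm probabilities for the
#' 2-back, a binomial per-target tracking capacity with uniform guessing
#' for object tracking, and a lognormal search time for the action task.
#'
#' @param profile one-row slice of a [sample_cohort()] tibble.
#' @param game one of [GAMES].
#' @param play_index 1-based count of this participant's plays of this
#'   game, including the current one.
#' @param cfg a [sim_config()].
#' @param mood this session's mood rating, for the (default off)
#'   mood-performance coupling.
#' @return a responder function for the matching engine, carrying the
#'   `itemwise`/`needs_state` fast-path attributes.
#' @export
make_responder <- function(profile, game, play_index, cfg = sim_config(),
                           mood = NULL) {
  stopifnot(play_index >= 1L)
  game <- match.arg(game, GAMES)
  theta <- latent_skill(profile, game, play_index, cfg, mood)

  if (game == "react") {
    f <- function(n, trials) {
      lat <- 100 + stats::rlnorm(n, log(80) - 0.25 * theta, 0.35)
      premature <- stats::runif(n) < 0.02
      wrong <- stats::runif(n) < 0.02
      lapply(seq_len(n), function(i) {
        btn <- trials[[i]]$correct_button
        if (wrong[i]) btn <- (btn %% 4L) + 1L
        list(latency_ms = lat[i], button = btn, premature = premature[i])
      })
    }
    attr(f, "itemwise") <- TRUE
    return(f)
  }

  if (game == "spin") {
    f <- function(n) {
      list(correct = stats::runif(n) < stats::plogis(0.85 + 0.7 * theta),
           latency_ms = 1000 * stats::rlnorm(n, log(3.1) - 0.08 * theta, 0.3))
    }
    attr(f, "itemwise") <- TRUE
    return(f)
  }

  if (game == "supersnap") {
    p_hit <- stats::plogis(1.6 + 0.7 * theta)
    p_fa <- stats::plogis(-2.8 - 0.5 * theta)
    f <- function(shapes, match_flags) {
      u <- stats::runif(length(shapes))
      ifelse(match_flags, u < p_hit, u < p_fa)
    }
    attr(f, "itemwise") <- TRUE
    return(f)
  }

  if (game == "track") {
    f <- function(state, trial) {
      n_balls <- trial$set_size
      p <- stats::plogis(1.7 + 0.8 * theta - 0.15 * (n_balls - 8))
      tracked <- trial$target_ids[stats::runif(3) < p]
      pool <- setdiff(seq_len(n_balls), tracked)
      guesses <- sample(pool, 3L - length(tracked))
      c(tracked, guesses)
    }
    attr(f, "needs_state") <- FALSE
    return(f)
  }

  # hotspot: lognormal search time, then settle in the target; the
  # trajectory is truncated once the outcome is decided
  function(target, cfg_engine) {
    find_s <- stats::rlnorm(1, log(7) - 0.3 * theta, 0.7)
    hz <- cfg_engine$hz
    if (find_s > cfg_engine$t_limit_s - cfg_engine$dwell_s) {
      away <- if (target$center[1L] > 0.5) c(0.01, 0.01) else c(0.99, 0.99)
      return(matrix(away, ncol = 2L))
    }
    k <- round(find_s * hz)
    dwell_ticks <- round((cfg_engine$dwell_s + cfg_engine$window_s) * hz)
    away <- if (target$center[1L] > 0.5) c(0, 0) else c(1, 1)
    rbind(matrix(rep(away, each = k), ncol = 2L),
          matrix(rep(target$center, each = dwell_ticks), ncol = 2L))
  }
}

#' Simulate a full longitudinal dataset
#'
#' Samples a cohort, a session count per participant, and then executes
#' every session through the game engines with simulated responders:
#' randomized game order, per-game skipping, mood drawn AR(1) around the
#' participant's baseline, chronotype-dependent time of day, wake-time
#' and sleep-hours fields on each first-session-of-day, demographics and
#' questionnaire total echoed on session 1, and practice curves driven
#' by each participant's per-game play count.
#'
#' @param cfg a [sim_config()]; `cfg$seed` is mandatory.
#' @return a list of [session_record()]s (class `cog_records`), with the
#'   ground-truth cohort tibble attached as attribute `"cohort"`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  if (is.null(cfg$seed)) stop("cfg$seed is mandatory for simulate_dataset()")
  set.seed(cfg$seed)
  cohort <- sample_cohort(cfg)
  counts <- sample_session_count(cohort, cfg)
  start <- as.Date(cfg$start_date)
  tod <- cfg$time_of_day

  records <- vector("list", sum(counts))
  k <- 0L
  for (i in seq_len(nrow(cohort))) {
    prof <- cohort[i, ]
    n_sess <- counts[i]
    gaps <- 1L + stats::rgeom(n_sess, 1 / cfg$day_gap_mean)
    days <- cumsum(c(0L, gaps[-1L]))
    meq_c <- if (is.na(prof$meq_total)) 0 else prof$meq_total - 13
    mood_prev <- prof$mood_baseline
    play_idx <- stats::setNames(integer(length(cfg$games)), cfg$games)
    for (s in seq_len(n_sess)) {
      hour <- round(stats::rnorm(1, tod$mean_hour + tod$meq_shift * meq_c,
                                 tod$sd))
      hour <- min(23, max(7, hour))
      minute <- sample.int(60L, 1L) - 1L
      timestamp <- sprintf("%sT%02d:%02d:00Z",
                           format(start + days[s], "%Y-%m-%d"), hour, minute)

      mood_lat <- prof$mood_baseline +
        cfg$mood$ar * (mood_prev - prof$mood_baseline) +
        stats::rnorm(1, sd = cfg$mood$noise_sd)
      mood_lat <- min(10, max(1, mood_lat))
      mood_prev <- mood_lat
      mood <- if (stats::runif(1) < cfg$mood$skip_prob) NULL else
        round(mood_lat, 1)

      if (stats::runif(1) < cfg$sleep_question_skip_prob) {
        wake_time <- NULL
        sleep_hours <- NULL
      } else {
        wh <- stats::rnorm(1, 7.5 - 0.12 * meq_c, 0.8)
        wh <- min(12, max(4, wh))
        wake_time <- sprintf("%02d:%02d", floor(wh),
                             round(60 * (wh - floor(wh))) %% 60)
        sleep_hours <- round(min(12, max(3, stats::rnorm(1, 7.4, 1.1))), 1)
      }

      played <- cfg$games[stats::runif(length(cfg$games)) >= cfg$skip_prob]
      responders <- list()
      for (g in played) {
        play_idx[[g]] <- play_idx[[g]] + 1L
        responders[[g]] <- make_responder(prof, g, play_idx[[g]], cfg,
                                          mood = mood)
      }

      demographics <- if (s == 1L)
        list(age = prof$age, gender = prof$gender,
             meq_total = prof$meq_total)

      k <- k + 1L
      records[[k]] <- run_session(
        responders, games_to_play = played,
        participant_id = prof$participant_id, session_index = s,
        timestamp = timestamp, utc_offset_min = 0L, mood = mood,
        wake_time = wake_time, sleep_hours = sleep_hours,
        demographics = demographics)
    }
  }
  structure(records, class = "cog_records", cohort = cohort)
}
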