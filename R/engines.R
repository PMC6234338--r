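#' Per-game score container
#'
#' @param game one of `"hotspot"`, `"react"`, `"spin"`, `"supersnap"`,
#'   `"track"`.
#' @param score numeric session score.
#' @param n_correct integer count of correct responses.
#' @param trial_detail list of per-trial outcome lists.
#' @return a list of class `game_score`.
#' @export
game_score <- function(game, score, n_correct, trial_detail = list()) {
  game <- match.arg(game, GAMES)
  structure(list(game = game, score = score, n_correct = as.integer(n_correct),
                 trial_detail = trial_detail),
            class = "game_score")
}

#' The five battery games
#' @export
GAMES <- c("hotspot", "react", "spin", "supersnap", "track")

#' @export
print.game_score <- function(x, ...) {
  cat(sprintf("<%s> score %.1f (%d correct, %d trials)\n",
              x$game, x$score, x$n_correct, length(x$trial_detail)))
  invisible(x)
}

# ---------------------------------------------------------------- react ----

#' Score one vigilance-task trial
#'
#' A correct response within the 100 ms grace period earns the full
#' per-trial maximum `s_trial`; thereafter points decay linearly to zero
#' at the 600 ms response deadline. Premature responses (before the go
#' signal), wrong-button presses and responses after 600 ms score zero.
#'
#' @param latency_ms response latency in ms (`NA` for no response).
#' @param chosen_button,correct_button button indices 1--4.
#' @param premature was the response made before the go signal?
#' @param s_trial per-trial maximum score.
#' @return points in `[0, s_trial]`.
#' @export
score_react_trial <- function(latency_ms, chosen_button, correct_button,
                              premature = FALSE, s_trial = 62.5) {
  if (isTRUE(premature)) return(0)
  if (is.na(latency_ms) || is.na(chosen_button)) return(0)
  stopifnot(latency_ms >= 0)
  if (chosen_button != correct_button) return(0)
  if (latency_ms > 600) return(0)
  if (latency_ms <= 100) return(s_trial)
  s_trial * (1 - (latency_ms - 100) / 500)
}

#' Run one vigilance-task session
#'
#' Eight trials. On each, one of four buttons (uniformly chosen) turns
#' "go" after a uniform 2--7 s foreperiod, and the responder has a 600 ms
#' window to press it; scoring per [score_react_trial()]. The session
#' score is the sum over trials (maximum `8 * s_trial`).
#'
#' The responder is called as `responder(trial)` with
#' `trial = list(index, interval_s, correct_button)` and must return a
#' list with `latency_ms` (`NA` for no response), `button` and
#' `premature`. A responder carrying `attr(x, "itemwise") = TRUE` is
#' instead called once as `responder(n, trials)` and must return a list
#' of such per-trial lists.
#'
#' @param responder responder function (see Details).
#' @param n_trials number of trials.
#' @param s_trial per-trial maximum score.
#' @return a [game_score()].
#' @export
run_react_session <- function(responder, n_trials = 8L, s_trial = 62.5) {
  intervals <- sample_react_interval(n_trials)
  buttons <- sample.int(4L, n_trials, replace = TRUE)
  trials <- lapply(seq_len(n_trials), function(i)
    list(index = i, interval_s = intervals[i], correct_button = buttons[i]))
  events <- if (isTRUE(attr(responder, "itemwise"))) {
    responder(n_trials, trials)
  } else {
    lapply(trials, responder)
  }
  detail <- vector("list", n_trials)
  total <- 0
  n_correct <- 0L
  for (i in seq_len(n_trials)) {
    ev <- events[[i]]
    pts <- score_react_trial(ev$latency_ms, ev$button, buttons[i],
                             premature = isTRUE(ev$premature),
                             s_trial = s_trial)
    total <- total + pts
    if (pts > 0) n_correct <- n_correct + 1L
    detail[[i]] <- list(interval_s = intervals[i],
                        correct_button = buttons[i],
                        latency_ms = ev$latency_ms,
                        button = ev$button,
                        premature = isTRUE(ev$premature),
                        points = pts)
  }
  game_score("react", score = total, n_correct = n_correct,
             trial_detail = detail)
}

# ------------------------------------------------------------ supersnap ----

#' Run one 2-back session
#'
#' Shapes are presented one at a time (1.5 s exposure, 1.5 s blank
#' inter-item delay; the timeline is carried in trial detail). The
#' responder taps when the current shape matches the one shown two
#' positions earlier. The session starts at `start_score` (default 60)
#' and loses `penalty` (default 6) points for every false alarm or miss,
#' floored at 0; it ends once `max_matches` matches have been presented
#' or `max_responses` taps (including false alarms) have been made,
#' whichever comes first.
#'
#' The responder is called as `responder(item)` with
#' `item = list(index, shape, is_match, onset_s)` (`is_match` is provided
#' for simulated responders; a memory-based responder should ignore it)
#' and must return `TRUE` to tap. A responder with
#' `attr(x, "itemwise") = TRUE` is called once as
#' `responder(shapes, match_flags)` on a pre-generated stream and must
#' return a logical vector of taps; termination is then applied to the
#' precomputed decisions, which is equivalent for responders that decide
#' each item independently.
#'
#' @param responder responder function (see Details).
#' @param max_matches matches presented before the session ends.
#' @param max_responses taps made before the session ends.
#' @param start_score,penalty scoring constants.
#' @param exposure_s,isi_s presentation timeline, seconds.
#' @return a [game_score()]; `score` is in `{0, 6, ..., 60}` under the
#'   defaults and `n_correct` counts hits.
#' @export
run_supersnap_session <- function(responder, max_matches = 10L,
                                  max_responses = 10L, start_score = 60,
                                  penalty = 6, exposure_s = 1.5, isi_s = 1.5) {
  item_period <- exposure_s + isi_s
  if (isTRUE(attr(responder, "itemwise"))) {
    stream <- generate_shape_stream(max_matches = max_matches)
    taps <- as.logical(responder(stream$shapes, stream$match_flags))
    stopifnot(length(taps) == length(stream$shapes))
    cum_resp <- cumsum(taps)
    cum_match <- cumsum(stream$match_flags)
    stop_at <- length(taps)
    hit_resp <- match(max_responses, cum_resp)
    if (!is.na(hit_resp)) stop_at <- min(stop_at, hit_resp)
    hit_match <- match(max_matches, cum_match)
    if (!is.na(hit_match)) stop_at <- min(stop_at, hit_match)
    keep <- seq_len(stop_at)
    shapes <- stream$shapes[keep]
    flags <- stream$match_flags[keep]
    taps <- taps[keep]
  } else {
    stream <- generate_shape_stream(max_matches = max_matches)
    shapes <- character(0)
    flags <- logical(0)
    taps <- logical(0)
    matches_presented <- 0L
    responses <- 0L
    for (i in seq_along(stream$shapes)) {
      shape <- stream$shapes[i]
      is_match <- stream$match_flags[i]
      shapes[i] <- shape
      flags[i] <- is_match
      tap <- isTRUE(responder(list(index = i, shape = shape,
                                   is_match = is_match,
                                   onset_s = (i - 1L) * item_period)))
      taps[i] <- tap
      if (is_match) matches_presented <- matches_presented + 1L
      if (tap) responses <- responses + 1L
      if (matches_presented >= max_matches || responses >= max_responses) break
    }
  }
  hits <- sum(taps & flags)
  false_alarms <- sum(taps & !flags)
  misses <- sum(!taps & flags)
  score <- max(0, start_score - penalty * (false_alarms + misses))
  detail <- list(shapes = shapes, match_flags = flags, taps = taps,
                 hits = hits, false_alarms = false_alarms, misses = misses,
                 exposure_s = exposure_s, isi_s = isi_s)
  game_score("supersnap", score = score, n_correct = hits,
             trial_detail = list(detail))
}

# ----------------------------------------------------------------- spin ----

#' Run one mental-rotation session
#'
#' All 18 patterns are shuffled and presented without replacement. The
#' responder has 45 s of task time: a trial is presented while elapsed
#' time is below the limit, and its response counts only if it completes
#' within the limit. `n_correct` is capped at 18 by construction; the
#' session score is `points_per_correct * n_correct`.
#'
#' The responder is called as `responder(trial)` with a
#' [make_spin_trial()] object plus `$index`, and must return
#' `list(choice, latency_ms)`. A responder with
#' `attr(x, "itemwise") = TRUE` is called once as `responder(n)` and
#' must return `list(correct = logical(n), latency_ms = numeric(n))`;
#' stimulus construction is skipped, which is distribution-identical for
#' stimulus-blind responders.
#'
#' @param responder responder function (see Details).
#' @param time_limit_s session time budget, seconds.
#' @param points_per_correct in-app points per correct judgment.
#' @param pattern_set list of patterns (defaults to the packaged 18).
#' @return a [game_score()].
#' @export
run_spin_session <- function(responder, time_limit_s = 45,
                             points_per_correct = 2.5,
                             pattern_set = NULL) {
  itemwise <- isTRUE(attr(responder, "itemwise"))
  if (is.null(pattern_set)) {
    n_pat <- 18L
    if (!itemwise) pattern_set <- load_pattern_set()
  } else n_pat <- length(pattern_set)
  ord <- sample.int(n_pat)
  if (itemwise) {
    resp <- responder(n_pat)
    lat_s <- resp$latency_ms / 1000
    ends <- cumsum(lat_s)
    starts <- ends - lat_s
    presented <- starts < time_limit_s
    counted <- presented & ends <= time_limit_s
    n_correct <- sum(resp$correct & counted)
    detail <- lapply(which(presented), function(i)
      list(pattern_index = ord[i], latency_ms = resp$latency_ms[i],
           correct = resp$correct[i] && counted[i], counted = counted[i]))
  } else {
    t <- 0
    detail <- list()
    n_correct <- 0L
    for (i in seq_len(n_pat)) {
      if (t >= time_limit_s) break
      trial <- make_spin_trial(pattern_set[[ord[i]]])
      trial$index <- i
      resp <- responder(trial)
      lat_s <- resp$latency_ms / 1000
      counted <- (t + lat_s) <= time_limit_s
      correct <- counted && !is.na(resp$choice) &&
        resp$choice == trial$correct_index
      if (correct) n_correct <- n_correct + 1L
      detail[[length(detail) + 1L]] <-
        list(pattern_index = ord[i], rotation_deg = trial$rotation_deg,
             choice = resp$choice, latency_ms = resp$latency_ms,
             correct = correct, counted = counted)
      t <- t + lat_s
    }
  }
  game_score("spin", score = points_per_correct * n_correct,
             n_correct = n_correct, trial_detail = detail)
}

# -------------------------------------------------------------- hotspot ----

#' Evaluate one action-task attempt
#'
#' The responder supplies a ball-center trajectory sampled at the tick
#' rate. The engine computes the in-target indicator (ball center inside
#' the target circle), a feedback trace lagging it by the 100 ms feedback
#' delay, and success as the first tick at which any sliding 1 s window
#' contains at least 500 ms of cumulative in-target time. Half the
#' attempt maximum is awarded for discovery (ever entering the target);
#' the other half is a time bonus decaying linearly from attempt onset to
#' zero at the attempt time limit. A trajectory that never enters the
#' target scores 0.
#'
#' The responder is called as `responder(target, cfg)` where `cfg` holds
#' the timing constants, and must return an n x 2 matrix of positions
#' (one row per tick, at most `t_limit_s * hz` rows). Simulated
#' responders may use `target` directly; a faithful replay responder
#' would use only the feedback trace of a previous run.
#'
#' @param responder responder function (see Details).
#' @param target a [place_hotspot_target()].
#' @param a_max per-attempt maximum score.
#' @param t_limit_s attempt time limit, seconds.
#' @param dwell_s required cumulative in-target time.
#' @param window_s width of the sliding window.
#' @param feedback_delay_s lag between in-target state and feedback.
#' @param hz tick rate.
#' @return list with `found` (dwell criterion met), `points`,
#'   `t_success_s` (`NA` if not found), `entered`, and the `in_target`
#'   and `feedback` tick traces.
#' @export
run_hotspot_attempt <- function(responder, target, a_max = 10,
                                t_limit_s = 15, dwell_s = 0.5, window_s = 1,
                                feedback_delay_s = 0.1, hz = 60) {
  cfg <- list(a_max = a_max, t_limit_s = t_limit_s, dwell_s = dwell_s,
              window_s = window_s, feedback_delay_s = feedback_delay_s,
              hz = hz)
  traj <- responder(target, cfg)
  stopifnot(is.matrix(traj), ncol(traj) == 2L)
  max_ticks <- round(t_limit_s * hz)
  if (nrow(traj) > max_ticks) traj <- traj[seq_len(max_ticks), , drop = FALSE]
  d2 <- (traj[, 1L] - target$center[1L])^2 + (traj[, 2L] - target$center[2L])^2
  in_target <- d2 <= target$radius^2
  lag_ticks <- round(feedback_delay_s * hz)
  feedback <- c(rep(FALSE, lag_ticks),
                in_target)[seq_along(in_target)]
  entered <- any(in_target)
  w <- round(window_s * hz)
  need <- round(dwell_s * hz)
  cum <- cumsum(in_target)
  n <- length(in_target)
  found <- FALSE
  t_success <- NA_real_
  if (n >= need) {
    in_window <- cum - c(rep(0L, min(w, n)), cum[seq_len(max(0L, n - w))])
    idx <- which(in_window >= need)
    if (length(idx)) {
      found <- TRUE
      t_success <- idx[1L] / hz
    }
  }
  points <- 0
  if (entered) points <- points + 0.5 * a_max
  if (found) points <- points + 0.5 * a_max * max(0, 1 - t_success / t_limit_s)
  list(found = found, points = points, t_success_s = t_success,
       entered = entered, in_target = in_target, feedback = feedback)
}

#' Run one action-task session
#'
#' Five attempts, each with a fresh uniformly placed target covering 5%
#' of the arena; the session score is the sum of attempt points
#' (maximum `5 * a_max`).
#'
#' @inheritParams run_hotspot_attempt
#' @param n_attempts number of attempts.
#' @param area_fraction target area as a fraction of the arena.
#' @return a [game_score()]; `n_correct` counts successful attempts.
#' @export
run_hotspot_session <- function(responder, n_attempts = 5L, a_max = 10,
                                t_limit_s = 15, area_fraction = 0.05,
                                hz = 60) {
  detail <- vector("list", n_attempts)
  total <- 0
  n_found <- 0L
  for (i in seq_len(n_attempts)) {
    target <- place_hotspot_target(area_fraction = area_fraction)
    res <- run_hotspot_attempt(responder, target, a_max = a_max,
                               t_limit_s = t_limit_s, hz = hz)
    total <- total + res$points
    if (res$found) n_found <- n_found + 1L
    detail[[i]] <- list(center = target$center, found = res$found,
                        t_success_s = res$t_success_s, points = res$points)
  }
  game_score("hotspot", score = total, n_correct = n_found,
             trial_detail = detail)
}
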