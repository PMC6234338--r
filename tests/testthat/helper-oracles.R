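# Independent brute-force oracles used across tests.

# Rotate a 3x3 grid clockwise via the hand-derived index map
# (row r, col c) -> (c, 4 - r), 1-based.
oracle_rotate_cw <- function(m) {
  out <- matrix(FALSE, 3, 3)
  for (r in 1:3) for (c in 1:3) out[c, 4 - r] <- m[r, c]
  out
}

# Least-squares via explicit normal equations (no lm machinery).
oracle_rss <- function(y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  sum((y - X %*% beta)^2)
}

# Pooled two-sample t statistic, closed form.
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# First tick at which a sliding window of `w` ticks holds >= `need`
# in-target ticks; NA if never.
oracle_dwell_success <- function(in_target, w, need) {
  n <- length(in_target)
  for (i in seq_len(n)) {
    lo <- max(1L, i - w + 1L)
    if (sum(in_target[lo:i]) >= need) return(i)
  }
  NA_integer_
}

# Replay a 2-back session from a fixed stream and itemwise tap
# decisions, applying the termination rules independently of the engine.
oracle_snap_score <- function(shapes, flags, taps, max_matches = 10L,
                              max_responses = 10L) {
  matches <- 0L; responses <- 0L
  fa <- 0L; miss <- 0L; hits <- 0L
  for (i in seq_along(shapes)) {
    if (taps[i] && flags[i]) hits <- hits + 1L
    if (taps[i] && !flags[i]) fa <- fa + 1L
    if (!taps[i] && flags[i]) miss <- miss + 1L
    if (flags[i]) matches <- matches + 1L
    if (taps[i]) responses <- responses + 1L
    if (matches >= max_matches || responses >= max_responses) break
  }
  list(score = max(0, 60 - 6 * (fa + miss)), hits = hits, fa = fa,
       miss = miss)
}

# Minimal fast responders for session-level tests.
fast_responders <- function() {
  hotspot <- function(target, cfg) matrix(c(0.5, 0.5), ncol = 2)
  list(hotspot = hotspot,
       react = responder_react_perfect(200),
       spin = responder_spin_perfect(2000),
       supersnap = responder_snap_perfect(),
       track = responder_track_oracle())
}

# Build a tiny flat records table directly (bypassing the engines).
flat_fixture <- function(participant_id, scores, game = "spin",
                         age = NA_integer_, gender = NA_character_,
                         meq_total = NA_integer_, mood = NA_real_) {
  n <- length(scores)
  tibble::tibble(
    participant_id = participant_id, session_index = seq_len(n),
    timestamp = sprintf("2026-01-%02dT12:00:00Z", seq_len(n)),
    mood = rep_len(mood, n), wake_time = NA_character_,
    sleep_hours = NA_real_, age = age, gender = gender,
    meq_total = meq_total, game = game, play_order = 1L,
    play_index = seq_len(n), score = as.numeric(scores),
    n_correct = 0L)
}
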