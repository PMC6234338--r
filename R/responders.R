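#' @title Built-in deterministic responders
#' @description Simple forced responders used for engine verification and
#'   the deterministic self-check: oracles that always succeed, responders
#'   that never respond, and fixed-latency responders. They exercise the
#'   documented responder contracts of the five engines.
#' @name responders
NULL

#' @describeIn responders taps all three true targets on every
#'   object-tracking trial (uses the trial's `target_ids`).
#' @export
responder_track_oracle <- function() {
  f <- function(state, trial) trial$target_ids
  attr(f, "needs_state") <- FALSE
  f
}

#' @describeIn responders taps nothing on every object-tracking trial.
#' @export
responder_track_none <- function() {
  f <- function(state, trial) integer(0)
  attr(f, "needs_state") <- FALSE
  f
}

#' @describeIn responders taps on all and only the 2-back matches.
#' @export
responder_snap_perfect <- function() {
  f <- function(item) isTRUE(item$is_match)
  f
}

#' @describeIn responders never taps in the 2-back task.
#' @export
responder_snap_silent <- function() {
  function(item) FALSE
}

#' @describeIn responders presses the correct vigilance button at a fixed
#'   latency (default instantaneous).
#' @param latency_ms fixed response latency in milliseconds.
#' @export
responder_react_perfect <- function(latency_ms = 0) {
  force(latency_ms)
  function(trial) list(latency_ms = latency_ms,
                       button = trial$correct_button, premature = FALSE)
}

#' @describeIn responders always responds before the go signal.
#' @export
responder_react_premature <- function() {
  function(trial) list(latency_ms = 0, button = 1L, premature = TRUE)
}

#' @describeIn responders picks the correct rotation option at a fixed
#'   latency.
#' @export
responder_spin_perfect <- function(latency_ms = 0) {
  force(latency_ms)
  function(trial) list(choice = trial$correct_index, latency_ms = latency_ms)
}

#' @describeIn responders always picks a wrong rotation option.
#' @export
responder_spin_wrong <- function(latency_ms = 1000) {
  force(latency_ms)
  function(trial) {
    wrong <- setdiff(1:3, trial$correct_index)[1L]
    list(choice = wrong, latency_ms = latency_ms)
  }
}

#' @describeIn responders moves the ball straight into the target center
#'   after `find_after_s` seconds and keeps it there (uses the target
#'   location directly; a simulation oracle, not a faithful player).
#' @param find_after_s seconds spent outside the target before entry.
#' @export
responder_hotspot_direct <- function(find_after_s = 0) {
  force(find_after_s)
  function(target, cfg) {
    n <- round(cfg$t_limit_s * cfg$hz)
    k <- min(n, round(find_after_s * cfg$hz))
    # park outside the target, then jump to its center and dwell
    away <- if (target$center[1L] > 0.5) c(0, 0) else c(1, 1)
    rbind(matrix(rep(away, each = k), ncol = 2L),
          matrix(rep(target$center, each = n - k), ncol = 2L))
  }
}

#' @describeIn responders never enters the target.
#' @export
responder_hotspot_never <- function() {
  function(target, cfg) {
    n <- round(cfg$t_limit_s * cfg$hz)
    away <- if (target$center[1L] > 0.5) c(0.01, 0.01) else c(0.99, 0.99)
    matrix(rep(away, each = n), ncol = 2L)
  }
}
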