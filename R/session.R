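#' Construct a session record
#'
#' One record per participant-session: identification, timing, the
#' optional start-of-session questions (mood always asked; wake time and
#' sleep hours only on the first session of a day), demographics echoed
#' on the first session, and the per-game results in play order.
#'
#' @param participant_id opaque participant token.
#' @param session_index 1-based session counter for this participant.
#' @param timestamp ISO-8601 UTC timestamp string.
#' @param utc_offset_min local-time offset from UTC, minutes.
#' @param mood mood rating 1--10, or `NULL` if skipped.
#' @param wake_time wake time as `"HH:MM"`, or `NULL`.
#' @param sleep_hours hours slept the previous night, or `NULL`.
#' @param demographics list with `age`, `gender`, `meq_total` (each
#'   possibly `NA`), or `NULL` after the first session.
#' @param games list of [game_score()] objects, in play order.
#' @return a list of class `session_record`.
#' @export
session_record <- function(participant_id, session_index, timestamp,
                           utc_offset_min = 0, mood = NULL,
                           wake_time = NULL, sleep_hours = NULL,
                           demographics = NULL, games = list()) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L,
            session_index >= 1L)
  if (!is.null(mood) && !is.na(mood) && (mood < 1 || mood > 10))
    stop("mood must be in [1, 10]")
  structure(list(participant_id = participant_id,
                 session_index = as.integer(session_index),
                 timestamp = timestamp,
                 utc_offset_min = as.integer(utc_offset_min),
                 mood = mood, wake_time = wake_time,
                 sleep_hours = sleep_hours,
                 demographics = demographics, games = games),
            class = "session_record")
}

#' Run one full battery session
#'
#' Executes the requested games in a freshly randomized order, recording
#' skipped games as absent. Session-level questions (mood, wake time,
#' sleep hours) and demographics are attached as supplied; any of them
#' may be skipped.
#'
#' @param responders named list mapping game names to responder
#'   functions (see the per-game engines for responder contracts).
#' @param games_to_play subset of [GAMES] actually played this session.
#' @param engine_opts named list of per-game argument lists passed on to
#'   the engines (e.g. `list(spin = list(time_limit_s = 45))`).
#' @inheritParams session_record
#' @return a [session_record()] whose `games` hold one [game_score()]
#'   per played game, in play order.
#' @export
run_session <- function(responders, games_to_play = names(responders),
                        participant_id = "anon", session_index = 1L,
                        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                           tz = "UTC"),
                        utc_offset_min = 0, mood = NULL, wake_time = NULL,
                        sleep_hours = NULL, demographics = NULL,
                        engine_opts = list()) {
  if (!all(games_to_play %in% GAMES))
    stop("unknown game in `games_to_play`")
  order <- sample(games_to_play)
  scores <- vector("list", length(order))
  for (i in seq_along(order)) {
    g <- order[i]
    responder <- responders[[g]]
    if (is.null(responder)) stop("no responder supplied for game '", g, "'")
    runner <- switch(g,
                     hotspot = run_hotspot_session,
                     react = run_react_session,
                     spin = run_spin_session,
                     supersnap = run_supersnap_session,
                     track = run_track_session)
    args <- c(list(responder), engine_opts[[g]])
    scores[[i]] <- do.call(runner, args)
  }
  session_record(participant_id = participant_id,
                 session_index = session_index, timestamp = timestamp,
                 utc_offset_min = utc_offset_min, mood = mood,
                 wake_time = wake_time, sleep_hours = sleep_hours,
                 demographics = demographics, games = scores)
}
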