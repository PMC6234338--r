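#' Flatten session records to a tidy table
#'
#' One row per participant-session-game. Demographics and questionnaire
#' total (echoed on session 1) are filled onto every row for that
#' participant; `play_index` counts that participant's plays of that game
#' in session order, starting at 1.
#'
#' @param records a `cog_records` list of [session_record()]s, or an
#'   already-flat tibble (returned unchanged).
#' @return a tibble with columns `participant_id`, `session_index`,
#'   `timestamp`, `mood`, `wake_time`, `sleep_hours`, `age`, `gender`,
#'   `meq_total`, `game`, `play_order`, `play_index`, `score`,
#'   `n_correct`.
#' @export
records_table <- function(records) {
  if (is.data.frame(records)) return(records)
  stopifnot(is.list(records))
  if (!length(records)) {
    return(tibble::tibble(
      participant_id = character(), session_index = integer(),
      timestamp = character(), mood = numeric(), wake_time = character(),
      sleep_hours = numeric(), age = integer(), gender = character(),
      meq_total = integer(), game = character(), play_order = integer(),
      play_index = integer(), score = numeric(), n_correct = integer()))
  }

  scalar_or <- function(x, default) if (is.null(x) || !length(x)) default else x

  # session-level fields, one pass each, replicated per game row
  n_games <- vapply(records, function(r) length(r$games), 0L)
  pid_all <- vapply(records, `[[`, "", "participant_id")

  # demographics echoed on (normally) session 1, filled onto all rows
  demo_of <- list()
  for (rec in records) {
    if (!is.null(rec$demographics))
      demo_of[[rec$participant_id]] <- rec$demographics
  }
  demo_field <- function(field, default, cast) {
    vapply(pid_all, function(p)
      cast(scalar_or(demo_of[[p]][[field]], default)), default,
      USE.NAMES = FALSE)
  }
  age_all <- demo_field("age", NA_integer_, as.integer)
  gender_all <- demo_field("gender", NA_character_, as.character)
  meq_all <- demo_field("meq_total", NA_integer_, as.integer)

  keep <- n_games > 0L
  recs <- records[keep]
  ng <- n_games[keep]
  rep_field <- function(x) rep(x, ng)

  out <- tibble::tibble(
    participant_id = rep_field(pid_all[keep]),
    session_index = rep_field(vapply(recs, `[[`, 0L, "session_index")),
    timestamp = rep_field(vapply(recs, `[[`, "", "timestamp")),
    mood = rep_field(vapply(recs, function(r)
      as.numeric(scalar_or(r$mood, NA_real_)), 0)),
    wake_time = rep_field(vapply(recs, function(r)
      as.character(scalar_or(r$wake_time, NA_character_)), "")),
    sleep_hours = rep_field(vapply(recs, function(r)
      as.numeric(scalar_or(r$sleep_hours, NA_real_)), 0)),
    age = rep_field(age_all[keep]),
    gender = rep_field(gender_all[keep]),
    meq_total = rep_field(meq_all[keep]),
    game = unlist(lapply(recs, function(r)
      vapply(r$games, `[[`, "", "game"))),
    play_order = unlist(lapply(ng, seq_len)),
    score = unlist(lapply(recs, function(r)
      vapply(r$games, function(g) as.numeric(g$score), 0))),
    n_correct = unlist(lapply(recs, function(r)
      vapply(r$games, function(g) as.integer(g$n_correct), 0L))))

  out <- out[order(out$participant_id, out$session_index, out$play_order), ]
  # per participant-game play counter in session order
  key <- paste(out$participant_id, out$game, sep = "\r")
  out$play_index <- stats::ave(seq_along(key), key, FUN = seq_along)
  out
}
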