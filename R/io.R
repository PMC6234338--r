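#' Write session records to disk
#'
#' Two plain-text formats are supported. `"jsonl"` (canonical) writes a
#' schema/version header line followed by one JSON object per record;
#' optional run metadata (e.g. seed and configuration) is embedded in
#' the header. `"csv"` writes the flattened tidy table (one row per
#' participant-session-game), suitable for statistics tooling. Per-trial
#' detail is summary-stripped by default so that a write/read round trip
#' reproduces the records exactly; pass `include_detail = TRUE` to embed
#' the nested trial detail in JSONL (it is then read back as plain
#' lists).
#'
#' @param records a `cog_records` list of [session_record()]s.
#' @param path output file path.
#' @param format `"jsonl"` or `"csv"`; default inferred from the file
#'   extension (`.csv` means CSV, anything else JSONL).
#' @param metadata optional named list stored in the JSONL header.
#' @param include_detail embed nested per-game trial detail (JSONL only).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = NULL, metadata = NULL,
                          include_detail = FALSE) {
  if (is.null(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  format <- match.arg(format, c("jsonl", "csv"))
  if (format == "csv") {
    flat <- records_table(records)
    flat$play_index <- NULL
    utils::write.csv(flat, path, row.names = FALSE, na = "")
    return(invisible(path))
  }
  header <- list(schema = "cogbattery-session-records", version = 1L)
  if (!is.null(metadata)) header$metadata <- metadata
  lines <- character(length(records) + 1L)
  lines[1L] <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = I(17),
                                null = "null", na = "null")
  for (i in seq_along(records)) {
    rec <- unclass(records[[i]])
    rec$games <- lapply(rec$games, function(g) {
      g <- unclass(g)
      if (!include_detail) g$trial_detail <- NULL
      g
    })
    lines[i + 1L] <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17),
                                      null = "null", na = "null")
  }
  writeLines(lines, path)
  invisible(path)
}

null_if_na <- function(x) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) NULL else x
}

rebuild_record <- function(x, line) {
  need <- c("participant_id", "session_index", "timestamp")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("line ", line, ": record missing field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  games <- lapply(x$games, function(g) {
    if (is.null(g$game) || is.null(g$score))
      stop("line ", line, ": malformed game entry", call. = FALSE)
    game_score(g$game, score = as.numeric(g$score),
               n_correct = as.integer(g$n_correct %||% 0L),
               trial_detail = g$trial_detail %||% list())
  })
  demo <- x$demographics
  if (!is.null(demo))
    demo <- list(age = if (is.null(demo$age)) NA_integer_ else as.integer(demo$age),
                 gender = if (is.null(demo$gender)) NA_character_ else demo$gender,
                 meq_total = if (is.null(demo$meq_total)) NA_integer_
                             else as.integer(demo$meq_total))
  session_record(
    participant_id = x$participant_id,
    session_index = as.integer(x$session_index),
    timestamp = x$timestamp,
    utc_offset_min = as.integer(x$utc_offset_min %||% 0L),
    mood = if (is.null(x$mood)) NULL else as.numeric(x$mood),
    wake_time = null_if_na(x$wake_time),
    sleep_hours = if (is.null(x$sleep_hours)) NULL else as.numeric(x$sleep_hours),
    demographics = demo,
    games = games)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read session records from disk
#'
#' Reads either format written by [write_records()], validating as it
#' goes: an unknown schema or version is rejected, and a malformed line
#' is reported with its line number. CSV input is reconstructed into
#' session records (demographics are recovered from each participant's
#' first session).
#'
#' @param path input file path.
#' @param format `"jsonl"` or `"csv"`; default inferred from extension.
#' @return a `cog_records` list of [session_record()]s. For JSONL input
#'   the header metadata, if any, is attached as attribute `"metadata"`.
#' @export
read_records <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  format <- match.arg(format, c("jsonl", "csv"))

  if (format == "csv") {
    flat <- utils::read.csv(path, stringsAsFactors = FALSE,
                            na.strings = "", colClasses = c(
                              participant_id = "character",
                              timestamp = "character",
                              wake_time = "character",
                              gender = "character",
                              game = "character"))
    return(records_from_flat(flat))
  }

  lines <- readLines(path)
  if (!length(lines)) stop("empty file, missing schema header: ", path)
  header <- tryCatch(jsonlite::fromJSON(lines[1L], simplifyVector = FALSE),
                     error = function(e) stop("line 1: invalid header JSON",
                                              call. = FALSE))
  if (!identical(header$schema, "cogbattery-session-records"))
    stop("unknown schema: ", header$schema %||% "<missing>")
  if (!identical(as.integer(header$version), 1L))
    stop("unsupported schema version: ", header$version %||% "<missing>")
  records <- vector("list", length(lines) - 1L)
  for (i in seq_along(records)) {
    line_no <- i + 1L
    x <- tryCatch(jsonlite::fromJSON(lines[line_no], simplifyVector = FALSE),
                  error = function(e)
                    stop("line ", line_no, ": invalid JSON", call. = FALSE))
    records[[i]] <- rebuild_record(x, line_no)
  }
  structure(records, class = "cog_records",
            metadata = header$metadata)
}

records_from_flat <- function(flat) {
  need <- c("participant_id", "session_index", "timestamp", "game", "score")
  miss <- setdiff(need, names(flat))
  if (length(miss))
    stop("CSV missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(flat$participant_id, flat$session_index, sep = "\r")
  chunks <- split(flat, factor(key, levels = unique(key)))
  records <- lapply(chunks, function(df) {
    df <- df[order(df$play_order), ]
    games <- lapply(seq_len(nrow(df)), function(j)
      game_score(df$game[j], score = df$score[j],
                 n_correct = df$n_correct[j]))
    demo <- if (df$session_index[1L] == 1L)
      list(age = as.integer(df$age[1L]), gender = df$gender[1L],
           meq_total = as.integer(df$meq_total[1L]))
    session_record(
      participant_id = df$participant_id[1L],
      session_index = df$session_index[1L],
      timestamp = df$timestamp[1L],
      utc_offset_min = as.integer(df$utc_offset_min[1L] %||% 0L),
      mood = null_if_na(df$mood[1L]),
      wake_time = null_if_na(df$wake_time[1L]),
      sleep_hours = null_if_na(df$sleep_hours[1L]),
      demographics = demo, games = games)
  })
  names(records) <- NULL
  ord <- order(vapply(records, `[[`, "", "participant_id"),
               vapply(records, `[[`, 0L, "session_index"))
  structure(records[ord], class = "cog_records")
}
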