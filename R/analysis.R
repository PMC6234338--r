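#' @title Cohort analysis pipeline
#' @description The analysis protocol for battery datasets: per-participant
#'   game summaries, an adherence filter (minimum 4 plays), trimming of the
#'   most extreme 1% of average scores, gender ANCOVA with a plays
#'   covariate, plays t-tests, decade-binned age ANOVA on early-session
#'   means, correlations, mood-performance protocol, practice curves and
#'   chronotype class summaries.
#' @name analysis
NULL

result_row <- function(statistic, value, df1, df2, p_value,
                       effect = NA_character_, effect_value = NA_real_,
                       n = NA_integer_, term = NA_character_) {
  tibble::tibble(term = term, statistic = statistic, value = value,
                 df1 = df1, df2 = df2, p_value = p_value, effect = effect,
                 effect_value = effect_value, n = as.integer(n))
}

#' Summarize one game per participant
#'
#' One row per participant who played the game at least once: play count,
#' mean score over all plays, and the mean over plays 4--6 only (the
#' "early snapshot", present only for participants with at least 6
#' plays), with demographics and questionnaire total carried along.
#'
#' @param records a `cog_records` list or flat [records_table()] tibble.
#' @param game one of [GAMES].
#' @return a tibble with columns `participant_id`, `game`, `n_plays`,
#'   `mean_score`, `early_mean_score`, `age`, `gender`, `meq_total`.
#' @export
summarize_by_participant <- function(records, game) {
  game <- match.arg(game, GAMES)
  flat <- records_table(records)
  need <- c("participant_id", "game", "play_index", "score")
  miss <- setdiff(need, names(flat))
  if (length(miss))
    stop("malformed records: missing column(s) ", paste(miss, collapse = ", "))
  flat <- flat[flat$game == game, ]
  if (!nrow(flat)) {
    return(tibble::tibble(participant_id = character(), game = character(),
                          n_plays = integer(), mean_score = numeric(),
                          early_mean_score = numeric(), age = integer(),
                          gender = character(), meq_total = integer()))
  }
  idx <- split(seq_len(nrow(flat)), flat$participant_id)
  n_plays <- lengths(idx)
  first <- vapply(idx, `[`, 0L, 1L)
  score <- flat$score
  early_ok <- flat$play_index %in% 4:6
  out <- tibble::tibble(
    participant_id = names(idx),
    game = game,
    n_plays = as.integer(n_plays),
    mean_score = unname(vapply(idx, function(i) mean(score[i]), 0)),
    early_mean_score = unname(vapply(idx, function(i) {
      if (length(i) < 6L) NA_real_ else mean(score[i][early_ok[i]])
    }, 0)),
    age = flat$age[first],
    gender = flat$gender[first],
    meq_total = flat$meq_total[first])
  out[order(out$participant_id), ]
}

#' Keep participants meeting the adherence cutoff
#'
#' Participants who played a game fewer than `min_plays` times (default
#' 4) are excluded from that game's analysis, removing those who played
#' no more than a practice-trial set.
#'
#' @param summaries tibble from [summarize_by_participant()].
#' @param min_plays inclusion cutoff.
#' @return the retained rows.
#' @export
adherence_filter <- function(summaries, min_plays = 4L) {
  stopifnot(min_plays >= 1L)
  summaries[summaries$n_plays >= min_plays, ]
}

#' Exclude the most extreme average scores
#'
#' Removes the most extreme `fraction` (default 1%) of participants by
#' mean score before analysis. `"tails"` removes `floor(n * fraction / 2)`
#' participants from each tail; `"mad"` removes the `2 * floor(n *
#' fraction / 2)` largest absolute deviations from the median. Ties are
#' broken by participant id, so the selection is deterministic. The
#' result is marked trimmed and a second application returns it
#' unchanged (the exclusion is defined on the original set).
#'
#' @param summaries tibble from [summarize_by_participant()].
#' @param fraction total fraction to remove, in `[0, 0.5)`.
#' @param method ranking rule; see Details.
#' @return the retained rows, with attribute `trimmed = TRUE`.
#' @export
trim_outliers <- function(summaries, fraction = 0.01,
                          method = c("tails", "mad")) {
  method <- match.arg(method)
  stopifnot(fraction >= 0, fraction < 0.5)
  if (isTRUE(attr(summaries, "trimmed"))) return(summaries)
  n <- nrow(summaries)
  k <- floor(n * fraction / 2)
  if (k > 0L && n > 0L) {
    ord <- order(summaries$mean_score, summaries$participant_id)
    drop <- if (method == "tails") {
      c(ord[seq_len(k)], ord[n - seq_len(k) + 1L])
    } else {
      dev <- abs(summaries$mean_score - stats::median(summaries$mean_score))
      order(-dev, summaries$participant_id)[seq_len(2L * k)]
    }
    summaries <- summaries[-drop, ]
  }
  attr(summaries, "trimmed") <- TRUE
  summaries
}

rss <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Gender ANCOVA with a plays covariate
#'
#' Linear model `mean_score ~ gender + plays`, where the covariate is by
#' default the number of plays beyond the adherence minimum
#' (`n_plays - min_plays`). Type-II sums of squares (each term adjusted
#' for the other; no interaction fitted). Effect sizes are partial
#' eta-squared, `SS_term / (SS_term + SS_residual)`. Rows with missing
#' gender or score are excluded first.
#'
#' @param summaries tibble from [summarize_by_participant()], normally
#'   after [adherence_filter()] and [trim_outliers()].
#' @param covariate `"beyond_min"` (default) or `"raw"` plays coding.
#' @param min_plays the adherence minimum subtracted under
#'   `"beyond_min"`.
#' @return a two-row tibble (terms `gender` and `plays`) with F
#'   statistics, degrees of freedom `(1, n - 3)`, p-values and partial
#'   eta-squared.
#' @export
gender_ancova <- function(summaries, covariate = c("beyond_min", "raw"),
                          min_plays = 4L) {
  covariate <- match.arg(covariate)
  d <- summaries[!is.na(summaries$gender) & !is.na(summaries$mean_score), ]
  if (length(unique(d$gender)) < 2L)
    stop("gender ANCOVA requires both genders present")
  if (any(table(d$gender) < 2L))
    stop("gender ANCOVA requires at least 2 participants per gender")
  n <- nrow(d)
  y <- d$mean_score
  male <- as.numeric(d$gender == "male")
  plays <- d$n_plays - if (covariate == "beyond_min") min_plays else 0L

  rss_full <- rss(y, cbind(1, male, plays))
  ss_gender <- rss(y, cbind(1, plays)) - rss_full
  ss_plays <- rss(y, cbind(1, male)) - rss_full
  df2 <- n - 3L
  ms_res <- rss_full / df2
  f_g <- ss_gender / ms_res
  f_p <- ss_plays / ms_res
  rbind(
    result_row(term = "gender", statistic = "F", value = f_g, df1 = 1,
               df2 = df2, p_value = stats::pf(f_g, 1, df2, lower.tail = FALSE),
               effect = "partial_eta2",
               effect_value = ss_gender / (ss_gender + rss_full), n = n),
    result_row(term = "plays", statistic = "F", value = f_p, df1 = 1,
               df2 = df2, p_value = stats::pf(f_p, 1, df2, lower.tail = FALSE),
               effect = "partial_eta2",
               effect_value = ss_plays / (ss_plays + rss_full), n = n))
}

#' Two-sample t-test on the number of plays by gender
#'
#' Pooled-variance two-sided t-test confirming that play counts do not
#' differ by gender (so the ANCOVA covariate is not confounded with the
#' factor). Degrees of freedom are `n1 + n2 - 2`.
#'
#' @param summaries tibble from [summarize_by_participant()] (normally
#'   after [adherence_filter()]).
#' @return a one-row tibble with `t`, df, p-value, group sizes and
#'   means.
#' @export
plays_t_test <- function(summaries) {
  d <- summaries[!is.na(summaries$gender), ]
  x <- d$n_plays[d$gender == "male"]
  y <- d$n_plays[d$gender == "female"]
  if (!length(x) || !length(y)) stop("both genders must be present")
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- if (se == 0) {
    if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
  } else (mean(x) - mean(y)) / se
  p <- if (is.infinite(tval)) 0 else 2 * stats::pt(-abs(tval), df)
  out <- result_row(term = "gender", statistic = "t", value = tval,
                    df1 = df, df2 = NA_real_, p_value = p, n = n1 + n2)
  out$n_male <- n1
  out$n_female <- n2
  out$mean_male <- mean(x)
  out$mean_female <- mean(y)
  out
}

#' Decade bins used by the age-stratified analysis
#'
#' `<20`, `20-29`, ..., `60-69`, `>70` (the top bin holds ages 70 and
#' above, following the printed labels).
#'
#' @param age integer ages.
#' @return factor of bin labels.
#' @export
age_decade_bin <- function(age) {
  cut(age, breaks = c(-Inf, 20, 30, 40, 50, 60, 70, Inf), right = FALSE,
      labels = c("<20", "20-29", "30-39", "40-49", "50-59", "60-69", ">70"))
}

#' Age-stratified ANOVA on early-session means
#'
#' One-way ANOVA of the early snapshot (mean of plays 4--6) across the
#' seven decade bins, controlling for the number of plays by design
#' rather than covariance. Empty bins are dropped with a warning and the
#' degrees of freedom adjusted. Effect size is
#' `eta2 = SS_between / SS_total`. Standard denominator degrees of
#' freedom `n - k` are computed; `df2_reported` additionally echoes the
#' `n - 1` print convention of some reports.
#'
#' @param summaries tibble from [summarize_by_participant()], normally
#'   after [adherence_filter()] and [trim_outliers()].
#' @return a one-row tibble with F, dfs, p-value and eta-squared.
#' @export
age_stratified_anova <- function(summaries) {
  d <- summaries[!is.na(summaries$age) & !is.na(summaries$early_mean_score), ]
  if (nrow(d) < 3L) stop("too few participants with early snapshot and age")
  bin <- age_decade_bin(d$age)
  present <- levels(bin)[table(bin) > 0L]
  if (length(present) < nlevels(bin))
    warning("empty age bin(s) dropped: ",
            paste(setdiff(levels(bin), present), collapse = ", "))
  bin <- factor(as.character(bin), levels = present)
  if (nlevels(bin) < 2L) stop("need at least 2 non-empty age bins")
  y <- d$early_mean_score
  n <- length(y)
  k <- nlevels(bin)
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  means <- tapply(y, bin, mean)
  counts <- tapply(y, bin, length)
  ss_between <- sum(counts * (means - grand)^2)
  ss_within <- ss_total - ss_between
  df1 <- k - 1L
  df2 <- n - k
  fval <- (ss_between / df1) / (ss_within / df2)
  out <- result_row(term = "age_bin", statistic = "F", value = fval,
                    df1 = df1, df2 = df2,
                    p_value = stats::pf(fval, df1, df2, lower.tail = FALSE),
                    effect = "eta2", effect_value = ss_between / ss_total,
                    n = n)
  out$df2_reported <- n - 1L
  out
}

#' Pearson correlation with a t-based test
#'
#' @param x,y paired numeric vectors; pairs with missing values are
#'   dropped; at least 3 complete pairs and nonzero variance required.
#' @return a one-row tibble with `r`, df `n - 2`, two-sided p-value and
#'   `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y)
  result_row(term = "r", statistic = "r", value = unname(ct$estimate),
             df1 = unname(ct$parameter), df2 = NA_real_,
             p_value = ct$p.value, effect = "r",
             effect_value = unname(ct$estimate), n = n)
}

#' Mood-performance protocol for one game
#'
#' Includes participants with at least `min_plays` plays of the game.
#' Reports (a) the group-level Pearson correlation between each
#' participant's average mood and average score, and (b) the mean of
#' per-participant Spearman correlations between mood and score across
#' sessions; participants with fewer than 3 mood-score pairs or zero
#' variance in either variable are skipped and counted.
#'
#' @param records a `cog_records` list or flat table.
#' @param game one of [GAMES].
#' @param min_plays inclusion cutoff.
#' @return list with `group_r` (tibble from [pearson_r()] or `NULL` if
#'   infeasible), `mean_individual_rho`, `n_individual`, `n_skipped`.
#' @export
mood_performance_analysis <- function(records, game, min_plays = 4L) {
  game <- match.arg(game, GAMES)
  flat <- records_table(records)
  flat <- flat[flat$game == game, ]
  counts <- table(flat$participant_id)
  keep <- names(counts)[counts >= min_plays]
  flat <- flat[flat$participant_id %in% keep, ]
  sp <- split(flat, flat$participant_id)

  avg_mood <- vapply(sp, function(df) mean(df$mood, na.rm = TRUE), 0)
  avg_score <- vapply(sp, function(df) mean(df$score), 0)
  group_r <- tryCatch(pearson_r(avg_mood, avg_score), error = function(e) NULL)

  rhos <- numeric(0)
  n_skipped <- 0L
  for (df in sp) {
    ok <- !is.na(df$mood)
    m <- df$mood[ok]; s <- df$score[ok]
    if (length(m) < 3L || stats::sd(m) == 0 || stats::sd(s) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    rhos <- c(rhos, stats::cor(m, s, method = "spearman"))
  }
  list(group_r = group_r,
       mean_individual_rho = if (length(rhos)) mean(rhos) else NA_real_,
       n_individual = length(rhos), n_skipped = n_skipped)
}

#' Group practice curve for one game
#'
#' Mean score over all participants contributing at each play index,
#' with the number still playing at that index (non-increasing).
#'
#' @param records a `cog_records` list or flat table.
#' @param game one of [GAMES].
#' @return tibble with `play_index`, `mean_score`, `n_remaining`.
#' @export
practice_curve <- function(records, game) {
  game <- match.arg(game, GAMES)
  flat <- records_table(records)
  flat <- flat[flat$game == game, ]
  if (!nrow(flat))
    return(tibble::tibble(play_index = integer(), mean_score = numeric(),
                          n_remaining = integer()))
  idx <- sort(unique(flat$play_index))
  tibble::tibble(
    play_index = as.integer(idx),
    mean_score = as.numeric(tapply(flat$score, flat$play_index, mean)[as.character(idx)]),
    n_remaining = as.integer(table(flat$play_index)[as.character(idx)]))
}

#' Chronotype class counts and proportions
#'
#' @param x a tibble with a `meq_total` column (one row per participant)
#'   or an integer vector of totals; missing totals are dropped.
#' @return tibble with `class`, `n`, `proportion` (proportions sum to 1).
#' @export
meq_summary <- function(x) {
  totals <- if (is.data.frame(x)) x$meq_total else x
  totals <- totals[!is.na(totals)]
  cls <- classify_meq(totals)
  tab <- table(cls)
  tibble::tibble(class = names(tab), n = as.integer(tab),
                 proportion = as.numeric(tab) / length(totals))
}
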