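test_that("per-participant summaries match hand computation", {
  flat <- rbind(flat_fixture("a", c(10, 20, 30), age = 25L, gender = "male",
                             meq_total = 10L),
                flat_fixture("b", c(5, 5, 5, 5, 5), age = 40L,
                             gender = "female", meq_total = 18L),
                flat_fixture("c", c(0, 10, 20, 30, 40, 50, 60), age = 60L,
                             gender = "female", meq_total = 22L))
  s <- summarize_by_participant(flat, "spin")
  expect_equal(s$n_plays, c(3L, 5L, 7L))
  expect_equal(s$mean_score, c(20, 5, 30))
  # early snapshot requires >= 6 plays and averages plays 4-6 only
  expect_true(is.na(s$early_mean_score[1]))
  expect_true(is.na(s$early_mean_score[2]))
  expect_equal(s$early_mean_score[3], mean(c(30, 40, 50)))
  expect_equal(s$age, c(25L, 40L, 60L))
  expect_error(summarize_by_participant(flat[, 1:3], "spin"), "missing column")
})

test_that("the adherence filter keeps exactly those with enough plays", {
  flat <- do.call(rbind, lapply(1:10, function(i)
    flat_fixture(sprintf("p%02d", i), rep(10, i))))
  s <- summarize_by_participant(flat, "spin")
  kept <- adherence_filter(s, 4)
  expect_equal(nrow(kept), 7)           # counting oracle: plays 4..10
  expect_true(all(kept$n_plays >= 4))
  expect_equal(nrow(adherence_filter(s[0, ], 4)), 0)
  expect_equal(nrow(adherence_filter(s, 1)), 10)
  # boundary: 4 retained, 3 dropped
  expect_true("p04" %in% kept$participant_id)
  expect_false("p03" %in% kept$participant_id)
})

test_that("outlier trimming removes the extreme tails deterministically", {
  set.seed(1)
  scores <- rnorm(1000)
  flat <- do.call(rbind, lapply(seq_along(scores), function(i)
    flat_fixture(sprintf("p%04d", i), scores[i])))
  s <- summarize_by_participant(flat, "spin")
  trimmed <- trim_outliers(s, 0.01)
  expect_equal(nrow(trimmed), 990)      # order-statistics count: 5 per tail
  expect_equal(sort(trimmed$mean_score)[1], sort(scores)[6])
  expect_equal(max(trimmed$mean_score), sort(scores)[995])

  # ties broken by stable participant id
  flat2 <- do.call(rbind, lapply(1:200, function(i)
    flat_fixture(sprintf("q%03d", i), 7)))
  s2 <- summarize_by_participant(flat2, "spin")
  t2 <- trim_outliers(s2, 0.01)
  expect_equal(nrow(t2), 198)
  expect_false("q001" %in% t2$participant_id)
  expect_false("q200" %in% t2$participant_id)

  # fraction 0 leaves the input unchanged; trimming is idempotent
  expect_equal(nrow(trim_outliers(s, 0)), 1000)
  expect_identical(trim_outliers(trimmed, 0.01), trimmed)

  # median-deviation ranking removes the same count
  expect_equal(nrow(trim_outliers(s, 0.01, method = "mad")), 990)
})

test_that("gender ANCOVA equals the normal-equations brute force on a small fixture", {
  set.seed(2)
  n <- 12
  gender <- rep(c("male", "female"), each = 6)
  plays <- c(4, 5, 6, 7, 8, 9, 4, 5, 6, 8, 9, 12)
  score <- c(10, 12, 11, 14, 13, 15, 9, 10, 8, 12, 11, 13)
  s <- tibble::tibble(participant_id = sprintf("p%02d", 1:n), game = "spin",
                      n_plays = plays, mean_score = score,
                      early_mean_score = NA_real_, age = NA_integer_,
                      gender = gender, meq_total = NA_integer_)
  res <- gender_ancova(s)

  male <- as.numeric(gender == "male")
  cov <- plays - 4
  rss_full <- oracle_rss(score, cbind(1, male, cov))
  ss_g <- oracle_rss(score, cbind(1, cov)) - rss_full
  ss_p <- oracle_rss(score, cbind(1, male)) - rss_full
  f_g <- ss_g / (rss_full / (n - 3))
  f_p <- ss_p / (rss_full / (n - 3))

  expect_equal(res$value[res$term == "gender"], f_g, tolerance = 1e-10)
  expect_equal(res$value[res$term == "plays"], f_p, tolerance = 1e-10)
  expect_equal(res$effect_value[res$term == "gender"],
               ss_g / (ss_g + rss_full), tolerance = 1e-10)
  expect_equal(res$df2[1], n - 3)
  expect_equal(res$p_value[res$term == "gender"],
               pf(f_g, 1, n - 3, lower.tail = FALSE), tolerance = 1e-10)

  # identical score vectors in both groups, same covariate: no gender SS
  s0 <- s
  s0$mean_score <- rep(c(1, 3, 2, 6, 4, 5), 2)
  s0$n_plays <- rep(c(4, 5, 6, 7, 8, 9), 2)
  res0 <- gender_ancova(s0)
  expect_equal(res0$value[res0$term == "gender"], 0, tolerance = 1e-10)

  expect_error(gender_ancova(s[s$gender == "male", ]), "both genders")
})

test_that("with an orthogonalized null covariate the ANCOVA reduces to one-way ANOVA", {
  # construct plays orthogonal to gender and score orthogonal to plays,
  # so the covariate carries exactly zero sum of squares
  set.seed(3)
  n <- 20
  male <- rep(c(1, 0), each = n / 2)
  plays0 <- rnorm(n)
  X1 <- cbind(1, male)
  plays <- plays0 - X1 %*% solve(crossprod(X1), crossprod(X1, plays0))
  score0 <- rnorm(n) + 2 * male
  score <- score0 - plays %*% crossprod(plays, score0) / sum(plays^2)
  s <- tibble::tibble(participant_id = sprintf("p%02d", 1:n), game = "spin",
                      n_plays = as.numeric(plays) + 4, mean_score = as.numeric(score),
                      early_mean_score = NA_real_, age = NA_integer_,
                      gender = ifelse(male == 1, "male", "female"),
                      meq_total = NA_integer_)
  res <- gender_ancova(s)
  # nested-model algebra: same SS decomposition as one-way ANOVA, error
  # df differ by the covariate's single degree of freedom
  a <- anova(lm(as.numeric(score) ~ factor(male)))
  f_oneway <- a$`F value`[1]
  expect_equal(res$value[res$term == "plays"], 0, tolerance = 1e-8)
  expect_equal(res$value[res$term == "gender"],
               f_oneway * (n - 3) / (n - 2), tolerance = 1e-8)
})

test_that("plays t-test matches the pooled closed form with df n1+n2-2", {
  s <- tibble::tibble(participant_id = sprintf("p%d", 1:6), game = "spin",
                      n_plays = c(3, 4, 5, 4, 5, 6),
                      mean_score = 0, early_mean_score = NA_real_,
                      age = NA_integer_,
                      gender = rep(c("male", "female"), each = 3),
                      meq_total = NA_integer_)
  res <- plays_t_test(s)
  expect_equal(res$value, oracle_pooled_t(c(3, 4, 5), c(4, 5, 6)),
               tolerance = 1e-12)
  expect_equal(res$df1, 4)

  # identical groups: t = 0, p = 1
  s2 <- s; s2$n_plays <- rep(c(3, 4, 5), 2)
  res2 <- plays_t_test(s2)
  expect_equal(res2$value, 0)
  expect_equal(res2$p_value, 1)

  # degenerate variance with unequal means: infinite t, p ~ 0
  s3 <- s; s3$n_plays <- rep(c(4, 7), each = 3)
  res3 <- plays_t_test(s3)
  expect_true(is.infinite(res3$value))
  expect_equal(res3$p_value, 0)
})

test_that("age-stratified ANOVA bins by decade and matches F = t^2 on two bins", {
  mk <- function(ages, scores) {
    tibble::tibble(participant_id = sprintf("p%03d", seq_along(ages)),
                   game = "spin", n_plays = 6L, mean_score = scores,
                   early_mean_score = scores, age = ages,
                   gender = NA_character_, meq_total = NA_integer_)
  }
  # bin edges follow the printed labels
  expect_equal(as.character(age_decade_bin(c(19, 20, 29, 30, 69, 70, 85))),
               c("<20", "20-29", "20-29", "30-39", "60-69", ">70", ">70"))

  set.seed(4)
  ages <- rep(c(25, 45), each = 10)
  scores <- rnorm(20) + 0.5 * (ages == 45)
  res <- suppressWarnings(age_stratified_anova(mk(ages, scores)))
  tt <- oracle_pooled_t(scores[ages == 25], scores[ages == 45])
  expect_equal(res$value, tt^2, tolerance = 1e-10)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 18)
  expect_equal(res$df2_reported, 19)

  # identical bin means: F ~ 0, eta2 ~ 0
  res0 <- suppressWarnings(age_stratified_anova(
    mk(rep(c(25, 45), each = 5), rep(c(1, 2, 3, 4, 5), 2))))
  expect_equal(res0$value, 0, tolerance = 1e-12)
  expect_equal(res0$effect_value, 0, tolerance = 1e-12)

  # eta2 equals SS_between / SS_total and the decomposition is exact
  ages7 <- c(19, 19, 25, 25, 35, 35, 45, 45, 55, 55, 65, 65, 75, 75)
  sc7 <- c(5, 6, 7, 8, 4, 5, 6, 7, 8, 9, 3, 4, 5, 6)
  res7 <- age_stratified_anova(mk(ages7, sc7))
  grand <- mean(sc7)
  ss_tot <- sum((sc7 - grand)^2)
  bin <- age_decade_bin(ages7)
  ss_b <- sum(tapply(sc7, bin, length) * (tapply(sc7, bin, mean) - grand)^2)
  expect_equal(res7$effect_value, ss_b / ss_tot, tolerance = 1e-12)
  expect_equal(res7$df1, 6)
  expect_equal(res7$df2, 7)
  # empty bins are dropped with a warning
  expect_warning(age_stratified_anova(mk(ages, scores)), "dropped")
})

test_that("pearson_r matches the covariance formula and rejects degenerate input", {
  expect_equal(pearson_r(1:10, 1:10)$value, 1)
  expect_equal(pearson_r(1:10, -(1:10))$value, -1)
  x <- c(2.1, 3.4, 1.2, 5.6, 4.4, 3.3, 2.8, 4.9, 5.1, 1.9)
  y <- c(1.0, 2.2, 0.8, 4.9, 3.6, 2.4, 2.2, 4.4, 4.0, 1.5)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_r(x, y)
  expect_equal(res$value, r_hand, tolerance = 1e-12)
  expect_equal(res$n, 10L)
  expect_equal(res$df1, 8)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("practice curves average per play index with non-increasing n", {
  flat <- flat_fixture("solo", c(1, 2, 3))
  pc <- practice_curve(flat, "spin")
  expect_equal(pc$mean_score, c(1, 2, 3))
  expect_equal(pc$n_remaining, c(1L, 1L, 1L))

  flat2 <- rbind(flat_fixture("a", c(10, 20)), flat_fixture("b", 30))
  pc2 <- practice_curve(flat2, "spin")
  expect_equal(pc2$mean_score, c(20, 20))
  expect_equal(pc2$n_remaining, c(2L, 1L))
  expect_true(all(diff(pc2$n_remaining) <= 0))
  expect_equal(nrow(practice_curve(flat2, "react")), 0)
})

test_that("mood protocol skips degenerate participants and recovers the null", {
  # constant mood: every participant is skipped
  flat <- do.call(rbind, lapply(1:5, function(i)
    flat_fixture(sprintf("p%d", i), rnorm(6), mood = 5)))
  res <- mood_performance_analysis(flat, "spin")
  expect_equal(res$n_skipped, 5)
  expect_equal(res$n_individual, 0)
  expect_true(is.na(res$mean_individual_rho))

  # independent mood and score: mean rho near zero
  set.seed(5)
  flat2 <- do.call(rbind, lapply(1:80, function(i) {
    f <- flat_fixture(sprintf("q%02d", i), rnorm(8, 20, 5))
    f$mood <- runif(8, 1, 10)
    f
  }))
  res2 <- mood_performance_analysis(flat2, "spin")
  expect_equal(res2$n_individual, 80)
  expect_lt(abs(res2$mean_individual_rho), 0.08)
  expect_gt(res2$group_r$p_value, 0.001)

  # participants below the adherence cutoff are excluded
  flat3 <- rbind(flat2, flat_fixture("short", c(1, 2), mood = c(3, 4)))
  res3 <- mood_performance_analysis(flat3, "spin")
  expect_equal(res3$n_individual + res3$n_skipped, 80)
})

test_that("filters are idempotent in sequence", {
  set.seed(6)
  flat <- do.call(rbind, lapply(1:50, function(i)
    flat_fixture(sprintf("p%02d", i), rnorm(sample(2:8, 1), 20, 5))))
  s <- summarize_by_participant(flat, "spin")
  once <- trim_outliers(adherence_filter(s, 4), 0.02)
  twice <- trim_outliers(adherence_filter(once, 4), 0.02)
  expect_identical(once, twice)
})
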