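test_that("cohort ages respect the 18-year floor and the configured spike", {
  set.seed(1)
  co <- sample_cohort(sim_config(n_participants = 5000))
  expect_true(all(co$age_true >= 18))
  expect_gt(mean(co$age_true == 18), 0.05)
  expect_true(all(co$meq_total >= 4 & co$meq_total <= 25, na.rm = TRUE))
  expect_true(anyNA(co$age))      # reported age has missingness
  expect_true(anyNA(co$gender))
  expect_equal(anyDuplicated(co$participant_id), 0)
})

test_that("the age-chronotype coupling is recovered at its configured value", {
  set.seed(2)
  cfg <- sim_config(n_participants = 10000,
                    meq = list(mean = 13.2, sd = 4, age_coupling = 0.3))
  co <- sample_cohort(cfg)
  r <- cor(co$age_true, co$meq_total, use = "complete.obs")
  expect_lt(abs(r - 0.3), 0.03)

  cfg0 <- sim_config(n_participants = 5000,
                     meq = list(mean = 13.2, sd = 4, age_coupling = 0))
  set.seed(3)
  co0 <- sample_cohort(cfg0)
  expect_lt(abs(cor(co0$age_true, co0$meq_total, use = "complete.obs")), 0.05)
})

test_that("session counts are heavy-tailed, positive and age-coupled", {
  set.seed(4)
  cfg <- sim_config(n_participants = 10000)
  co <- sample_cohort(cfg)
  cnt <- sample_session_count(co, cfg)
  expect_true(all(cnt >= 1))
  expect_gt(sd(cnt), mean(cnt) - 1)          # overdispersed
  expect_lt(abs(cor(co$age_true, cnt) - 0.2), 0.05)
  # the survival curve over session index is non-increasing
  surv <- vapply(1:30, function(k) sum(cnt >= k), 0L)
  expect_true(all(diff(surv) <= 0))

  cfg0 <- sim_config(n_participants = 5000,
                     engagement = list(mu = 7, size = 1.4, age_coupling = 0,
                                       noise_sd = 0.35))
  set.seed(5)
  co0 <- sample_cohort(cfg0)
  cnt0 <- sample_session_count(co0, cfg0)
  expect_lt(abs(cor(co0$age_true, cnt0)), 0.05)
})

test_that("responder skill is flat over plays when the practice rate is zero", {
  cfg <- sim_config()
  prof <- {
    set.seed(6)
    sample_cohort(sim_config(n_participants = 1))[1, ]
  }
  th <- vapply(1:12, function(k)
    cogbattery:::latent_skill(prof, "react", k, cfg), 0)
  expect_equal(diff(th), rep(0, 11))
  # nonzero rate: increasing, and play 10 within 2% of the asymptote gap
  th_spin <- vapply(1:30, function(k)
    cogbattery:::latent_skill(prof, "spin", k, cfg), 0)
  expect_true(all(diff(th_spin) > 0))
  # residual deficit at play 10 is a negligible fraction of a latent sd
  asym <- th_spin[30]
  expect_lt(asym - th_spin[10], 0.05)
})

test_that("a zero gender effect leaves no group difference in simulated scores", {
  set.seed(7)
  cfg <- sim_config(n_participants = 400, seed = 7, games = "spin",
                    gender_d = c(hotspot = 0, react = 0, spin = 0,
                                 supersnap = 0, track = 0))
  recs <- simulate_dataset(cfg)
  s <- summarize_by_participant(recs, "spin")
  d <- s[!is.na(s$gender), ]
  diff_means <- mean(d$mean_score[d$gender == "male"]) -
    mean(d$mean_score[d$gender == "female"])
  expect_lt(abs(diff_means) / sd(d$mean_score), 0.25)
})

test_that("simulated datasets are byte-identical under the master seed", {
  cfg <- sim_config(n_participants = 25, seed = 123, games = c("react", "spin"))
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  attr(a, "cohort") <- NULL; attr(b, "cohort") <- NULL
  expect_identical(a, b)
  expect_error(simulate_dataset(sim_config(n_participants = 5)), "seed")
})

test_that("a small full-battery run yields complete, well-formed records", {
  cfg <- sim_config(n_participants = 60, seed = 8)
  recs <- simulate_dataset(cfg)
  expect_gte(length(recs), 60)
  flat <- records_table(recs)
  expect_setequal(unique(flat$game), GAMES)
  # questionnaire totals present for nearly all participants
  first <- flat[!duplicated(flat$participant_id), ]
  expect_gte(mean(!is.na(first$meq_total)), 0.9)
  # per-game score ranges
  expect_true(all(flat$score[flat$game == "track"] <= 45))
  expect_true(all(flat$score[flat$game == "supersnap"] %in% seq(0, 60, 6)))
  expect_true(all(flat$score[flat$game == "react"] <= 500 + 1e-9))
  expect_true(all(flat$score[flat$game == "spin"] <= 45))
  expect_true(all(flat$score[flat$game == "hotspot"] <= 50 + 1e-9))
  expect_true(all(flat$score >= 0))
  # timestamps parse and are non-decreasing within participant
  ts <- as.POSIXct(flat$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  expect_false(anyNA(ts))
  # mood ratings live on the 1-10 scale when present
  expect_true(all(flat$mood >= 1 & flat$mood <= 10, na.rm = TRUE))
})

test_that("unknown config overrides are rejected and bounds enforced", {
  expect_error(sim_config(bogus_option = 1), "unknown")
  expect_error(sim_config(n_participants = 0))
  expect_error(sim_config(skip_prob = 1.5))
})
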