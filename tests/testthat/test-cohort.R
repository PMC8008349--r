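test_that("schedule A yields twice-weekly and schedule B weekly short surveys", {
  co_a <- generate_cohort(cohort_config(n_participants = 5, weeks = 12,
                                        short_schedule = "A"), seed = 67)
  per <- table(co_a$events$kind) / 5
  expect_equal(unname(per["short"]), 24)
  expect_equal(unname(per["topic"]), 12)
  expect_equal(unname(per["interest"]), 12)
  co_b <- generate_cohort(cohort_config(n_participants = 5, weeks = 12,
                                        short_schedule = "B"), seed = 67)
  expect_equal(sum(co_b$events$kind == "short"), 5 * 12)
  expect_true(all(co_b$events$day[co_b$events$kind == "short"] == 7))
  expect_true(all(co_a$events$day %in% c(3, 7)))
})

test_that("topic surveys cycle through the catalogue in week order", {
  co <- generate_cohort(cohort_config(n_participants = 2, weeks = 12,
                                      topic_catalogue_size = 13), seed = 71)
  tp <- co$events[co$events$kind == "topic" & co$events$participant == 1, ]
  expect_equal(tp$topic, ((seq_len(12) - 1) %% 13) + 1)
  expect_true(all(is.na(co$events$topic[co$events$kind != "topic"])))
})

test_that("degenerate completion probabilities behave deterministically", {
  co0 <- generate_cohort(cohort_config(n_participants = 4, weeks = 3,
                                       baseline = 0), seed = 73)
  expect_false(any(co0$events$completed))
  co1 <- generate_cohort(cohort_config(n_participants = 4, weeks = 3,
                                       baseline = 1), seed = 73)
  expect_true(all(co1$events$completed))
})

test_that("empirical completion converges to the configured baseline", {
  cfg <- cohort_config(n_participants = 275, weeks = 12, baseline = 0.20)
  co <- generate_cohort(cfg, seed = 79)
  n <- nrow(co$events)
  expect_equal(n, 275 * 48)
  expect_lt(abs(mean(co$events$completed) - 0.20),
            3 * sqrt(0.2 * 0.8 / n))
})

test_that("arm effects shift completion additively per arm", {
  eff <- lapply(default_aspects(), function(sp)
    stats::setNames(c(0, 0), c(sp$option_a, sp$option_b)))
  eff$schedule <- c(twice_weekly = 0.2, weekly = -0.05)
  cfg <- cohort_config(n_participants = 400, weeks = 4, baseline = 0.2,
                       arm_effects = eff)
  co <- generate_cohort(cfg, seed = 83)
  ev <- co$events
  for (arm in c("twice_weekly", "weekly")) {
    sub <- ev[ev$schedule == arm, ]
    target <- 0.2 + eff$schedule[[arm]]
    expect_lt(abs(mean(sub$completed) - target),
              3 * sqrt(target * (1 - target) / nrow(sub)))
  }
  expect_error(
    cohort_config(baseline = 0.2, arm_effects = local({
      e <- eff; e$schedule <- c(twice_weekly = 0.9, weekly = 0); e
    })), "outside")
})

test_that("the event calendar is fixed while completions are stochastic", {
  cfg <- cohort_config(n_participants = 10, weeks = 6)
  c1 <- generate_cohort(cfg, seed = 89)
  c2 <- generate_cohort(cfg, seed = 97)
  cal_cols <- c("participant", "enrol_week", "study_week", "week", "day",
                "kind", "topic")
  expect_identical(c1$events[cal_cols], c2$events[cal_cols])
  expect_false(identical(c1$events$completed, c2$events$completed))
  c3 <- generate_cohort(cfg, seed = 89)
  expect_identical(c1, c3)
})

test_that("enrolment spread staggers calendar weeks without shortening follow-up", {
  cfg <- cohort_config(n_participants = 9, weeks = 4, enrolment_spread = 3)
  co <- generate_cohort(cfg, seed = 101)
  expect_setequal(unique(co$events$enrol_week), 1:3)
  per <- table(co$events$participant)
  expect_true(all(per == per[1]))
  expect_true(all(co$events$week ==
                    co$events$enrol_week + co$events$study_week - 1))
})

test_that("cohort CSV round-trips losslessly", {
  co <- generate_cohort(cohort_config(n_participants = 6, weeks = 3),
                        seed = 103)
  f <- withr::local_tempfile(fileext = ".csv")
  written <- write_cohort(co, f)
  expect_equal(nrow(written), nrow(co$events))
  back <- read_cohort(f)
  expect_equal(back$events, co$events)
  expect_equal(nrow(back$participants), 6)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(n_participants = 0), "positive")
  expect_error(cohort_config(weeks = 0.5), "positive")
  expect_error(cohort_config(baseline = 1.2), "probability")
  expect_error(cohort_config(participant_sd = -1), "non-negative")
})
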