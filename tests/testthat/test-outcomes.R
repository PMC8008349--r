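test_that("completion rate is the exact completed/available ratio", {
  ev <- events_with_rates(c(6), available = 24)
  cr <- completion_rate(ev)
  expect_equal(cr$completion_rate, 0.25)
  expect_equal(cr$n_completed, 6)
  expect_equal(cr$n_available, 24)
  ev_all <- events_with_rates(c(10, 10), available = 10)
  expect_equal(completion_rate(ev_all)$completion_rate, 1.0)
  expect_error(completion_rate(ev[0, ]), "undefined")
})

test_that("completion rate from a generated cohort recovers the true rate", {
  co <- generate_cohort(cohort_config(n_participants = 275, weeks = 12,
                                      baseline = 0.2), seed = 107)
  cr <- completion_rate(co)
  expect_lt(abs(cr$completion_rate - 0.2),
            3 * sqrt(0.2 * 0.8 / cr$n_available))
  # partition conservation: per-kind and per-arm counts sum to the total
  expect_equal(sum(cr$by_kind$n_completed), cr$n_completed)
  expect_equal(sum(cr$by_kind$n_available), cr$n_available)
  for (asp in unique(cr$by_arm$aspect)) {
    sub <- cr$by_arm[cr$by_arm$aspect == asp, ]
    expect_equal(sum(sub$n_completed), cr$n_completed)
    expect_equal(sum(sub$n_available), cr$n_available)
  }
})

test_that("high-completer proportion uses a strict 80% cutoff", {
  # 39/48 = 81.25% counts; 24/30 = 80% exactly does not
  ev <- rbind(events_with_rates(39, 48),
              transform(events_with_rates(24, 30), participant = 2L))
  expect_equal(proportion_high_completers(ev), 0.5)
  expect_equal(proportion_high_completers(events_with_rates(c(0, 0), 10)), 0)
})

test_that("high-completer proportion is non-increasing in the cutoff", {
  set.seed(109)
  ev <- events_with_rates(rbinom(40, 20, 0.5), available = 20)
  cuts <- seq(0.1, 0.9, by = 0.1)
  props <- vapply(cuts, function(ct) proportion_high_completers(ev, ct), 0)
  expect_true(all(diff(props) <= 0))
})

test_that("low completers are flagged with a strict 20% cutoff", {
  # 19/100 flagged, 20/100 exactly not
  ev <- rbind(events_with_rates(19, 100),
              transform(events_with_rates(20, 100), participant = 2L),
              transform(events_with_rates(90, 100), participant = 3L))
  expect_equal(low_completer_flags(ev), 1L)
  expect_equal(low_completer_flags(ev[0, ]), integer(0))
})

test_that("compute_outcomes assembles primary and secondary outcomes", {
  co <- generate_cohort(cohort_config(n_participants = 50, weeks = 12,
                                      baseline = 0.2), seed = 113)
  out <- compute_outcomes(co)
  expect_s3_class(out, "outcome_summary")
  expect_equal(out$completion_rate, out$n_completed / out$n_available)
  expect_equal(out$n_participants, 50)
  expect_true(out$retention_rate >= 0 && out$retention_rate <= 1)
  expect_true(all(out$low_completer_ids == sort(out$low_completer_ids)))
  # short-only denominator restricts availability accordingly
  short <- compute_outcomes(co, denominator = "short")
  expect_equal(short$n_available, sum(co$events$kind == "short"))
  f <- withr::local_tempfile(fileext = ".json")
  compute_outcomes(co, path = f)
  j <- jsonlite::read_json(f)
  expect_equal(j$n_available, out$n_available)
})
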