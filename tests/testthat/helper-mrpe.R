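# Monte-Carlo oracles for the Beta-Bernoulli quantities, independent of
# the package's closed-form/quadrature implementation. Variance estimates
# carry a 1/draws floor so the SE stays meaningful when the empirical
# proportion is degenerate (0 or 1 observed exceedances).
mc_prob_superior <- function(a, b, draws = 1e5) {
  pa <- rbeta(draws, a$alpha, a$beta)
  pb <- rbeta(draws, b$alpha, b$beta)
  est <- mean(pb > pa)
  list(est = est, se = sqrt((est * (1 - est) + 1 / draws) / draws))
}

mc_expected_loss <- function(choose, other, draws = 1e5) {
  pc <- rbeta(draws, choose$alpha, choose$beta)
  po <- rbeta(draws, other$alpha, other$beta)
  loss <- pmax(po - pc, 0)
  list(est = mean(loss), se = sqrt((stats::var(loss) + 1 / draws) / draws))
}

# Random belief pair with integer or fractional shapes.
random_belief_pair <- function(integer_shapes = TRUE) {
  draw <- function() {
    if (integer_shapes) beta_belief(sample(1:40, 1), sample(1:40, 1))
    else beta_belief(runif(1, 0.5, 40), runif(1, 0.5, 40))
  }
  list(a = draw(), b = draw())
}

# Compact aspect spec for trial tests.
test_spec <- function(...) aspect_spec("test", "A", "B", ...)

# Hand-built events table with exact per-participant completion counts.
events_with_rates <- function(completed_counts, available) {
  do.call(rbind, lapply(seq_along(completed_counts), function(i) {
    data.frame(participant = i, enrol_week = 1L,
               study_week = rep(seq_len(available), length.out = available),
               week = 1L, day = 7L, kind = "short", topic = NA_integer_,
               completed = seq_len(available) <= completed_counts[i])
  }))
}
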