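test_that("posterior_update performs conjugate counting", {
  expect_equal(posterior_update(beta_belief(1, 1), 2, 3),
               beta_belief(3, 4))
  b <- beta_belief(3, 4)
  expect_equal(posterior_update(b, 0, 0), b)
  expect_error(posterior_update(b, -1, 0), "non-negative")
  expect_error(beta_belief(0, 1), "positive")
  expect_error(beta_belief(1, -2), "positive")
})

test_that("posterior mean converges to the true completion rate", {
  set.seed(101)
  p <- 0.2
  n <- 50
  y <- rbinom(1, n, p)
  post <- posterior_update(beta_belief(1, 1), y, n - y)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(post) - p), 3 * se + 2 / n)  # prior pulls by <= 2/n
})

test_that("prob_superior matches symmetry and the analytic value", {
  expect_equal(prob_superior(beta_belief(1, 1), beta_belief(1, 1)), 0.5,
               tolerance = 1e-9)
  expect_equal(prob_superior(beta_belief(7, 3), beta_belief(7, 3)), 0.5,
               tolerance = 1e-9)
  # closed-form double integral of 2x(1-x)^2 over the unit square
  expect_equal(prob_superior(beta_belief(2, 1), beta_belief(1, 2)), 1 / 6,
               tolerance = 1e-6)
})

test_that("prob_superior complements sum to one across shape regimes", {
  set.seed(11)
  for (i in 1:10) {
    pr <- random_belief_pair(integer_shapes = i <= 5)
    expect_equal(prob_superior(pr$a, pr$b) + prob_superior(pr$b, pr$a), 1,
                 tolerance = 1e-9)
  }
  # mixed integer/fractional pair exercises the swapped closed form
  a <- beta_belief(2.5, 1.5); b <- beta_belief(2, 3)
  expect_equal(prob_superior(a, b) + prob_superior(b, a), 1,
               tolerance = 1e-9)
})

test_that("an extra completion never lowers the probability of superiority", {
  grid <- expand.grid(a1 = 1:6, b1 = 1:6, a2 = 1:6, b2 = 1:6)
  grid <- grid[sample.int(nrow(grid), 60), ]
  for (i in seq_len(nrow(grid))) {
    a <- beta_belief(grid$a1[i], grid$b1[i])
    b <- beta_belief(grid$a2[i], grid$b2[i])
    b2 <- posterior_update(b, 1, 0)
    expect_gte(prob_superior(a, b2), prob_superior(a, b) - 1e-12)
  }
})

test_that("expected_loss obeys the mean-difference identity", {
  # E[(x)+] - E[(-x)+] = E[x], so the loss gap equals the gap in means
  a <- beta_belief(2, 1); b <- beta_belief(1, 2)
  expect_equal(expected_loss(a, b) - expected_loss(b, a), 1 / 3 - 2 / 3,
               tolerance = 1e-9)
  set.seed(21)
  for (i in 1:15) {
    pr <- random_belief_pair(integer_shapes = i <= 8)
    gap <- expected_loss(pr$a, pr$b) - expected_loss(pr$b, pr$a)
    expect_equal(gap, mean(pr$b) - mean(pr$a), tolerance = 1e-9)
  }
})

test_that("expected_loss is symmetric for exchangeable beliefs and non-negative", {
  a <- beta_belief(1, 1); b <- beta_belief(1, 1)
  expect_equal(expected_loss(a, b), expected_loss(b, a), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:10) {
    pr <- random_belief_pair(integer_shapes = i %% 2 == 0)
    expect_gte(expected_loss(pr$a, pr$b), 0)
  }
})

test_that("closed form and quadrature agree with a Monte-Carlo oracle", {
  set.seed(41)
  for (i in 1:6) {
    pr <- random_belief_pair(integer_shapes = i <= 3)
    ps <- mc_prob_superior(pr$a, pr$b)
    expect_lt(abs(prob_superior(pr$a, pr$b) - ps$est), 3 * ps$se + 1e-6)
    el <- mc_expected_loss(pr$a, pr$b)
    expect_lt(abs(expected_loss(pr$a, pr$b) - el$est), 3 * el$se + 1e-6)
  }
})
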