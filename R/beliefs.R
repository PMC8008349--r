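#' Beta belief over a completion probability
#'
#' A Beta distribution used as the conjugate posterior for one arm's
#' survey-completion probability. `alpha` counts completions (plus prior
#' pseudo-count), `beta` counts non-completions.
#'
#' @param alpha Positive shape parameter (pseudo-count of completions).
#' @param beta Positive shape parameter (pseudo-count of non-completions).
#' @return An object of class `beta_belief`.
#' @examples
#' b <- beta_belief(1, 1)          # uniform prior
#' posterior_update(b, 2, 3)       # Beta(3, 4)
#' @export
beta_belief <- function(alpha = 1, beta = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single positive number", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("`beta` must be a single positive number", call. = FALSE)
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "beta_belief")
}

#' @export
print.beta_belief <- function(x, ...) {
  cat(sprintf("<beta_belief> Beta(%g, %g), mean %.4f\n",
              x$alpha, x$beta, mean(x)))
  invisible(x)
}

#' @export
mean.beta_belief <- function(x, ...) x$alpha / (x$alpha + x$beta)

#' @export
format.beta_belief <- function(x, ...) sprintf("Beta(%g, %g)", x$alpha, x$beta)

#' @export
as.list.beta_belief <- function(x, ...) list(alpha = x$alpha, beta = x$beta)

is_beta_belief <- function(x) inherits(x, "beta_belief")

assert_belief <- function(x, arg = deparse(substitute(x))) {
  if (!is_beta_belief(x))
    stop(sprintf("`%s` must be a beta_belief object", arg), call. = FALSE)
  invisible(x)
}

#' Conjugate posterior update from binomial counts
#'
#' @param belief A [beta_belief()].
#' @param completions Number of completed surveys observed (non-negative).
#' @param non_completions Number of non-completed surveys observed.
#' @return The updated `beta_belief`.
#' @export
posterior_update <- function(belief, completions, non_completions) {
  assert_belief(belief)
  for (v in list(completions, non_completions)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 ||
        abs(v - round(v)) > 1e-8)
      stop("counts must be single non-negative integers", call. = FALSE)
  }
  beta_belief(belief$alpha + completions, belief$beta + non_completions)
}

is_whole <- function(x) abs(x - round(x)) < 1e-9

## P(X2 > X1) for X1 ~ Beta(a1, b1), X2 ~ Beta(a2, b2), a2 a positive
## integer: sum over the integer shape (standard Beta-Bernoulli identity).
psup_int <- function(a1, b1, a2, b2) {
  i <- seq.int(0L, round(a2) - 1L)
  s <- sum(exp(lbeta(a1 + i, b1 + b2) - log(b2 + i) - lbeta(1 + i, b2) -
                 lbeta(a1, b1)))
  min(max(s, 0), 1)
}

## General case by quadrature: P(X2 > X1) = E[ F1(X2) ].
psup_quad <- function(a1, b1, a2, b2) {
  f <- function(x) stats::pbeta(x, a1, b1) * stats::dbeta(x, a2, b2)
  stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 1e-10,
                   subdivisions = 500L)$value
}

psup_num <- function(a1, b1, a2, b2) {
  if (is_whole(a2)) psup_int(a1, b1, a2, b2)
  else if (is_whole(a1)) 1 - psup_int(a2, b2, a1, b1)
  else psup_quad(a1, b1, a2, b2)
}

#' Probability that one arm's completion rate exceeds another's
#'
#' Computes `P(p_b > p_a)` for independent Beta beliefs, by closed-form
#' summation when a shape parameter is a whole number and by adaptive
#' quadrature otherwise. Absolute error below 1e-6.
#'
#' @param a,b [beta_belief()] objects for the two arms.
#' @return A probability in (0, 1).
#' @examples
#' prob_superior(beta_belief(2, 1), beta_belief(1, 2))  # 1/6
#' @export
prob_superior <- function(a, b) {
  assert_belief(a); assert_belief(b)
  psup_num(a$alpha, a$beta, b$alpha, b$beta)
}

## E[(p_other - p_choose)^+] via the shifted-shape identity:
## E[p_b 1{p_b > p_a}] = mean(b) P(p_b' > p_a) with p_b' ~ Beta(a2+1, b2).
eloss_num <- function(ca, cb, oa, ob) {
  v <- (oa / (oa + ob)) * psup_num(ca, cb, oa + 1, ob) -
       (ca / (ca + cb)) * psup_num(ca + 1, cb, oa, ob)
  max(v, 0)
}

#' Expected loss of committing to one arm
#'
#' The posterior-expected shortfall in completion probability incurred by
#' choosing `choose` when `other` may in truth be better:
#' `E[max(p_other - p_choose, 0)]` under independent beliefs, in
#' completion-rate units. This is the quantity compared against the
#' acceptable-loss threshold by [decide()].
#'
#' @param choose Belief for the arm being committed to.
#' @param other Belief for the arm being given up.
#' @return A non-negative expected loss.
#' @export
expected_loss <- function(choose, other) {
  assert_belief(choose); assert_belief(other)
  eloss_num(choose$alpha, choose$beta, other$alpha, other$beta)
}
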