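#' Expected-loss stopping decision for a two-arm evaluation
#'
#' Applies the sequential decision rule: before `n_initial` outcomes the
#' trial always continues; from then on the arm whose expected loss (see
#' [expected_loss()]) is smallest is chosen as soon as that loss falls below
#' the acceptable threshold `epsilon`, and at `n_max` participants the
#' lowest-loss arm is chosen whether or not its loss is under the threshold.
#' An exact tie in losses retains `option_a`, the app's default.
#'
#' @param a,b Current [beta_belief()] for option A and option B.
#' @param n_so_far Number of outcomes observed so far (total across arms).
#' @param spec The [aspect_spec()] supplying `n_initial`, `n_max`,
#'   `epsilon` and the option labels.
#' @return An object of class `mrpe_decision` with fields `action`
#'   ("continue" or "stop"), `chosen` (option label, `NA` while
#'   continuing), `reason` ("below_threshold", "cap_reached" or "none")
#'   and `losses` (named pair: expected loss of committing to each option).
#' @export
decide <- function(a, b, n_so_far, spec) {
  assert_belief(a); assert_belief(b)
  if (!inherits(spec, "aspect_spec"))
    stop("`spec` must be an aspect_spec", call. = FALSE)
  if (!is.numeric(n_so_far) || n_so_far < 0 || !is_whole(n_so_far))
    stop("`n_so_far` must be a non-negative integer", call. = FALSE)
  if (n_so_far > spec$n_max)
    stop(sprintf("n_so_far (%d) exceeds n_max (%d)", n_so_far, spec$n_max),
         call. = FALSE)
  loss_a <- eloss_num(a$alpha, a$beta, b$alpha, b$beta)
  loss_b <- eloss_num(b$alpha, b$beta, a$alpha, a$beta)
  losses <- c(loss_a, loss_b)
  names(losses) <- c(spec$option_a, spec$option_b)

  new_decision <- function(action, chosen, reason)
    structure(list(action = action, chosen = chosen, reason = reason,
                   losses = losses),
              class = "mrpe_decision")

  if (n_so_far < spec$n_initial)
    return(new_decision("continue", NA_character_, "none"))
  best <- if (loss_a <= loss_b) spec$option_a else spec$option_b
  if (min(losses) < spec$epsilon)
    return(new_decision("stop", best, "below_threshold"))
  if (n_so_far >= spec$n_max)
    return(new_decision("stop", best, "cap_reached"))
  new_decision("continue", NA_character_, "none")
}

#' @export
print.mrpe_decision <- function(x, ...) {
  cat(sprintf("<mrpe_decision> %s", x$action))
  if (x$action == "stop")
    cat(sprintf(": choose '%s' (%s)", x$chosen, x$reason))
  cat(sprintf("\n  expected losses: %s = %.5f, %s = %.5f\n",
              names(x$losses)[1], x$losses[1],
              names(x$losses)[2], x$losses[2]))
  invisible(x)
}
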