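#' Specification of one micro-randomised process evaluation (MRPE)
#'
#' One MRPE compares two design options of the app (e.g. twice-weekly vs
#' weekly short surveys) on a binary survey-completion outcome. The design
#' allocates participants 1:1 (by default), waits for an initial group of
#' `n_initial` outcomes, then after every further outcome stops as soon as
#' the expected loss of committing to the better-looking option falls below
#' `epsilon`, with a forced decision at `n_max` participants.
#'
#' @param name Label for the aspect under evaluation.
#' @param option_a,option_b Labels of the two options. `option_a` is the
#'   baseline/default option, retained on an exact tie in expected loss.
#' @param alloc_prob Probability of allocating a participant to `option_a`
#'   (strictly between 0 and 1; default 0.5).
#' @param n_initial Number of outcomes (total across both arms) observed
#'   before the stopping rule is first evaluated. Default 10.
#' @param n_max Maximum number of participants for the aspect; a decision is
#'   forced when reached. Default 50.
#' @param epsilon Acceptable expected loss in completion-rate units
#'   (default 0.01, i.e. one percentage point of completion probability).
#' @param prior_a,prior_b Prior [beta_belief()] for each arm; default the
#'   uniform Beta(1, 1).
#' @return An object of class `aspect_spec`.
#' @export
aspect_spec <- function(name, option_a = "A", option_b = "B",
                        alloc_prob = 0.5, n_initial = 10L, n_max = 50L,
                        epsilon = 0.01,
                        prior_a = beta_belief(1, 1),
                        prior_b = beta_belief(1, 1)) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string", call. = FALSE)
  if (!is.numeric(alloc_prob) || length(alloc_prob) != 1L ||
      alloc_prob <= 0 || alloc_prob >= 1)
    stop("`alloc_prob` must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(n_initial) || n_initial < 1 || !is_whole(n_initial))
    stop("`n_initial` must be a positive integer", call. = FALSE)
  if (!is.numeric(n_max) || !is_whole(n_max) || n_max < n_initial)
    stop("`n_max` must be an integer >= n_initial", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0 ||
      epsilon >= 1)
    stop("`epsilon` must lie in [0, 1)", call. = FALSE)
  assert_belief(prior_a); assert_belief(prior_b)
  structure(list(name = name,
                 option_a = as.character(option_a),
                 option_b = as.character(option_b),
                 alloc_prob = alloc_prob,
                 n_initial = as.integer(n_initial),
                 n_max = as.integer(n_max),
                 epsilon = epsilon,
                 prior_a = prior_a, prior_b = prior_b),
            class = "aspect_spec")
}

#' @export
print.aspect_spec <- function(x, ...) {
  cat(sprintf("<aspect_spec> %s: '%s' vs '%s'\n", x$name, x$option_a,
              x$option_b))
  cat(sprintf("  alloc %.2f | n_initial %d | n_max %d | epsilon %g\n",
              x$alloc_prob, x$n_initial, x$n_max, x$epsilon))
  invisible(x)
}

#' The five app-design aspects evaluated sequentially
#'
#' Returns the five MRPEs in their planned order: short-survey schedule,
#' time of the initial notification, lag of the reminder notification, text
#' content of the initial notification, and text content of the reminder.
#' Option A of each aspect is the app's current default; the winner of each
#' evaluation is carried forward as the default for the next.
#'
#' @param n_initial,n_max,epsilon Design parameters shared by all five
#'   aspects (defaults 10, 50 and 0.01).
#' @return A named list of five [aspect_spec()] objects.
#' @export
default_aspects <- function(n_initial = 10L, n_max = 50L, epsilon = 0.01) {
  mk <- function(name, a, b)
    aspect_spec(name, a, b, n_initial = n_initial, n_max = n_max,
                epsilon = epsilon)
  list(
    schedule      = mk("schedule", "twice_weekly", "weekly"),
    notify_time   = mk("notify_time", "16:00", "21:00"),
    reminder_lag  = mk("reminder_lag", "1_day", "3_days"),
    notify_text   = mk("notify_text", "conventional", "behavioural"),
    reminder_text = mk("reminder_text", "conventional", "behavioural")
  )
}
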