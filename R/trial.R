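#' Randomise one participant between the two options of an aspect
#'
#' Emulates the app's A/B allocation with computer-generated random numbers:
#' returns `option_a` with probability `alloc_prob`, else `option_b`. Uses
#' R's global random stream, so sequences are reproducible under
#' [set.seed()].
#'
#' @param spec An [aspect_spec()].
#' @return One of the two option labels.
#' @export
allocate <- function(spec) {
  if (!inherits(spec, "aspect_spec"))
    stop("`spec` must be an aspect_spec", call. = FALSE)
  if (stats::runif(1) < spec$alloc_prob) spec$option_a else spec$option_b
}

#' Run one micro-randomised evaluation participant by participant
#'
#' Simulates the full sequential loop for a single aspect: allocate each
#' participant, draw a Bernoulli completion outcome at that arm's true
#' rate, update the arm's Beta posterior, and apply [decide()] after every
#' outcome once `n_initial` outcomes have accrued. Stops at the first stop
#' decision (threshold met or `n_max` reached).
#'
#' @param spec An [aspect_spec()].
#' @param true_rates Numeric pair: the true completion probabilities of
#'   option A and option B, each strictly inside (0, 1) — or exactly 0/1
#'   for degenerate stress tests.
#' @return An object of class `mrpe_trajectory`: a list with `spec`, a
#'   `steps` data frame (one row per participant: `participant`, `option`,
#'   `outcome`, `loss_a`, `loss_b`, `action`), the final `decision`,
#'   `n_used`, and the closing beliefs `belief_a`, `belief_b`.
#' @export
run_aspect <- function(spec, true_rates) {
  if (!inherits(spec, "aspect_spec"))
    stop("`spec` must be an aspect_spec", call. = FALSE)
  if (!is.numeric(true_rates) || length(true_rates) != 2L ||
      any(true_rates < 0 | true_rates > 1))
    stop("`true_rates` must be two probabilities in [0, 1]", call. = FALSE)

  n_max <- spec$n_max
  opt    <- character(n_max)
  out    <- logical(n_max)
  loss_a <- numeric(n_max)
  loss_b <- numeric(n_max)
  act    <- character(n_max)
  bel_a <- spec$prior_a
  bel_b <- spec$prior_b
  decision <- NULL

  for (n in seq_len(n_max)) {
    arm_a <- stats::runif(1) < spec$alloc_prob
    p <- if (arm_a) true_rates[1] else true_rates[2]
    y <- stats::runif(1) < p
    if (arm_a) bel_a <- beta_belief(bel_a$alpha + y, bel_a$beta + !y)
    else       bel_b <- beta_belief(bel_b$alpha + y, bel_b$beta + !y)
    d <- decide(bel_a, bel_b, n, spec)
    opt[n] <- if (arm_a) spec$option_a else spec$option_b
    out[n] <- y
    loss_a[n] <- d$losses[1]
    loss_b[n] <- d$losses[2]
    act[n] <- d$action
    if (d$action == "stop") { decision <- d; break }
  }
  used <- n
  structure(list(
    spec = spec,
    steps = data.frame(participant = seq_len(used), option = opt[1:used],
                       outcome = out[1:used], loss_a = loss_a[1:used],
                       loss_b = loss_b[1:used], action = act[1:used],
                       stringsAsFactors = FALSE),
    decision = decision, n_used = used,
    belief_a = bel_a, belief_b = bel_b),
    class = "mrpe_trajectory")
}

#' @export
print.mrpe_trajectory <- function(x, ...) {
  cat(sprintf("<mrpe_trajectory> %s: %d participants, chose '%s' (%s)\n",
              x$spec$name, x$n_used, x$decision$chosen, x$decision$reason))
  invisible(x)
}

#' Run the five evaluations sequentially, carrying winners forward
#'
#' Aspects run strictly one after another: the next evaluation starts only
#' after the previous one has reached its stop decision, and each winner is
#' recorded as the carried-forward default configuration of the app for
#' subsequent evaluations.
#'
#' @param aspects Non-empty list of [aspect_spec()] objects, in evaluation
#'   order (see [default_aspects()]).
#' @param true_rate_map Named list mapping each aspect name to its pair of
#'   true completion rates `(option A, option B)`.
#' @param seed Optional integer seed applied before the first aspect.
#' @return An object of class `mrpe_study`: list with `trajectories`,
#'   `winners` (named character vector), `participant_ranges` (start/end
#'   participant index of each aspect in the combined sequence) and
#'   `total_n`.
#' @export
run_study <- function(aspects, true_rate_map, seed = NULL) {
  if (!is.list(aspects) || length(aspects) == 0L)
    stop("`aspects` must be a non-empty list of aspect_spec objects",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  trajectories <- vector("list", length(aspects))
  winners <- character(length(aspects))
  ranges <- data.frame(aspect = character(length(aspects)),
                       start = integer(length(aspects)),
                       end = integer(length(aspects)),
                       stringsAsFactors = FALSE)
  offset <- 0L
  for (k in seq_along(aspects)) {
    spec <- aspects[[k]]
    if (!inherits(spec, "aspect_spec"))
      stop("every element of `aspects` must be an aspect_spec",
           call. = FALSE)
    rates <- true_rate_map[[spec$name]]
    if (is.null(rates))
      stop(sprintf("true_rate_map has no entry for aspect '%s'", spec$name),
           call. = FALSE)
    tr <- run_aspect(spec, rates)
    trajectories[[k]] <- tr
    winners[k] <- tr$decision$chosen
    ranges$aspect[k] <- spec$name
    ranges$start[k] <- offset + 1L
    ranges$end[k] <- offset + tr$n_used
    offset <- offset + tr$n_used
  }
  names(trajectories) <- vapply(aspects, `[[`, "", "name")
  names(winners) <- names(trajectories)
  structure(list(trajectories = trajectories, winners = winners,
                 participant_ranges = ranges, total_n = offset),
            class = "mrpe_study")
}

#' @export
print.mrpe_study <- function(x, ...) {
  cat(sprintf("<mrpe_study> %d aspects, %d participants total\n",
              length(x$trajectories), x$total_n))
  for (nm in names(x$winners))
    cat(sprintf("  %-14s -> %s\n", nm, x$winners[[nm]]))
  invisible(x)
}

#' Write study trajectories as tidy CSV
#'
#' One row per participant: aspect, within-aspect index, allocated arm,
#' binary outcome, the two expected losses at that point, and the action
#' taken.
#'
#' @param study An [run_study()] result (or a single trajectory).
#' @param path Output CSV path.
#' @return The combined data frame, invisibly.
#' @export
write_trajectories <- function(study, path) {
  trajs <- if (inherits(study, "mrpe_trajectory")) list(study)
           else study$trajectories
  rows <- lapply(trajs, function(tr) {
    cbind(aspect = tr$spec$name, tr$steps, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Per-aspect JSON summary of a study
#'
#' @param study An [run_study()] result.
#' @param path Optional path; when given the summary is written as JSON.
#' @return A list (one element per aspect) with chosen option, reason,
#'   sample size used and closing posterior beliefs.
#' @export
study_summary <- function(study, path = NULL) {
  if (!inherits(study, "mrpe_study"))
    stop("`study` must be an mrpe_study", call. = FALSE)
  out <- lapply(study$trajectories, function(tr) {
    list(aspect = tr$spec$name,
         chosen = tr$decision$chosen,
         reason = tr$decision$reason,
         n_used = tr$n_used,
         losses = as.list(tr$decision$losses),
         belief_a = as.list(tr$belief_a),
         belief_b = as.list(tr$belief_b))
  })
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(out)
}
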