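#' A true-rate scenario for operating-characteristic simulation
#'
#' @param name Scenario label.
#' @param p_option1,p_option2 True completion probabilities of the two
#'   options, strictly inside (0, 1).
#' @return An object of class `oc_scenario`.
#' @export
oc_scenario <- function(name, p_option1, p_option2) {
  for (p in c(p_option1, p_option2))
    if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
      stop("scenario probabilities must lie strictly in (0, 1)",
           call. = FALSE)
  structure(list(name = as.character(name), p_option1 = p_option1,
                 p_option2 = p_option2),
            class = "oc_scenario")
}

#' Monte-Carlo operating characteristics of the sequential design
#'
#' Runs [run_aspect()] repeatedly under a fixed pair of true completion
#' rates and summarises how often the design picks the truly better option
#' and how many participants it uses. There is no closed-form power
#' calculation for the expected-loss rule, so these frequencies play the
#' role of power in the design calibration.
#'
#' @param scenario An [oc_scenario()] (or numeric pair of rates).
#' @param spec An [aspect_spec()]; defaults to the study design
#'   (1:1 allocation, n_initial 10, n_max 50, epsilon 0.01, uniform priors).
#' @param replicates Number of replicate trials (default 10000, giving a
#'   Monte-Carlo standard error of at most half a percentage point).
#' @param seed Optional integer seed.
#' @return An object of class `oc_result` with `p_correct` (for equal true
#'   rates, the fraction choosing option 1, flagged by `tie = TRUE`),
#'   its Monte-Carlo standard error `mc_se`, `mean_n`, the sample-size
#'   distribution `n_table`, `replicates` and `seed`.
#' @export
simulate_oc <- function(scenario, spec = aspect_spec("aspect"),
                        replicates = 10000L, seed = NULL) {
  if (is.numeric(scenario) && length(scenario) == 2L)
    scenario <- oc_scenario("scenario", scenario[1], scenario[2])
  if (!inherits(scenario, "oc_scenario"))
    stop("`scenario` must be an oc_scenario or a numeric pair",
         call. = FALSE)
  if (!is.numeric(replicates) || replicates < 1)
    stop("`replicates` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  replicates <- as.integer(replicates)
  rates <- c(scenario$p_option1, scenario$p_option2)
  tie <- rates[1] == rates[2]
  target <- if (tie || rates[1] > rates[2]) spec$option_a else spec$option_b

  chose_target <- logical(replicates)
  n_used <- integer(replicates)
  for (r in seq_len(replicates)) {
    tr <- run_aspect(spec, rates)
    chose_target[r] <- tr$decision$chosen == target
    n_used[r] <- tr$n_used
  }
  p <- mean(chose_target)
  structure(list(scenario = scenario, spec = spec,
                 p_correct = p,
                 mc_se = sqrt(p * (1 - p) / replicates),
                 mean_n = mean(n_used),
                 n_table = table(n_used),
                 tie = tie,
                 replicates = replicates, seed = seed),
            class = "oc_result")
}

#' @export
print.oc_result <- function(x, ...) {
  lbl <- if (x$tie) "P(choose option 1) [tie scenario]"
         else "P(choose better option)"
  cat(sprintf("<oc_result> %s (%.2f vs %.2f), %d replicates\n",
              x$scenario$name, x$scenario$p_option1, x$scenario$p_option2,
              x$replicates))
  cat(sprintf("  %s = %.3f (MC SE %.4f), mean n = %.1f\n",
              lbl, x$p_correct, x$mc_se, x$mean_n))
  invisible(x)
}

#' The design-calibration scenario grid for the five app aspects
#'
#' For each of the five evaluations the baseline completion rate is assumed
#' to be 20%. The optimistic scenario hopes the new option raises
#' completion by 20 percentage points (survey schedule and the two
#' notification-timing tests) or 10 points (the two text-content tests);
#' the pessimistic scenario fears a 5-point drop in all five.
#'
#' @return A data frame with one row per test x scenario (10 rows):
#'   `test`, `scenario` ("optimistic"/"pessimistic"), `p_option1`,
#'   `p_option2`, and the published approximate probability of choosing
#'   the better option (`published_p_correct`, as a percentage).
#' @export
table1_grid <- function() {
  tests <- c("Survey schedule", "Time of initial notification",
             "Time of reminder notification",
             "Text content of initial notification",
             "Text content of reminder notification")
  optimistic_p2 <- c(0.40, 0.40, 0.40, 0.30, 0.30)
  published_opt <- c(90, 90, 90, 75, 75)
  grid <- rbind(
    data.frame(test = tests, scenario = "optimistic", p_option1 = 0.20,
               p_option2 = optimistic_p2,
               published_p_correct = published_opt,
               stringsAsFactors = FALSE),
    data.frame(test = tests, scenario = "pessimistic", p_option1 = 0.20,
               p_option2 = 0.15, published_p_correct = 65,
               stringsAsFactors = FALSE))
  grid[order(match(grid$test, tests), grid$scenario), , drop = FALSE]
}

#' Recompute the design-calibration table by simulation
#'
#' Runs [simulate_oc()] on every row of [table1_grid()] and reports the
#' simulated probability of choosing the better option side by side with
#' the published approximate values. Identical scenarios (the same pair of
#' true rates under the shared design) are simulated once and reused.
#'
#' @param replicates Replicates per scenario (default 10000).
#' @param seed Integer master seed; each distinct scenario derives its own
#'   substream via [derive_seed()].
#' @param spec Design parameters shared by all tests.
#' @param path Optional CSV output path.
#' @return Data frame: test, scenario, p1, p2, p_correct (%), mc_se (%),
#'   mean_n, reps, seed, published_p_correct (%).
#' @export
reproduce_table1 <- function(replicates = 10000L, seed = 1L,
                             spec = aspect_spec("aspect"), path = NULL) {
  grid <- table1_grid()
  key <- sprintf("%.3f_%.3f", grid$p_option1, grid$p_option2)
  cache <- new.env(parent = emptyenv())
  res <- lapply(seq_len(nrow(grid)), function(i) {
    k <- key[i]
    if (is.null(cache[[k]])) {
      cache[[k]] <- simulate_oc(
        oc_scenario(k, grid$p_option1[i], grid$p_option2[i]), spec,
        replicates = replicates, seed = derive_seed(seed, k))
    }
    cache[[k]]
  })
  out <- data.frame(
    test = grid$test, scenario = grid$scenario,
    p1 = grid$p_option1, p2 = grid$p_option2,
    p_correct = 100 * vapply(res, `[[`, 0, "p_correct"),
    mc_se = 100 * vapply(res, `[[`, 0, "mc_se"),
    mean_n = vapply(res, `[[`, 0, "mean_n"),
    reps = as.integer(replicates), seed = as.integer(seed),
    published_p_correct = grid$published_p_correct,
    stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
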