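## Accept either an mrpe_cohort or a bare events data frame.
as_events <- function(x) {
  if (inherits(x, "mrpe_cohort")) return(x$events)
  if (is.data.frame(x)) {
    if (!all(c("participant", "kind", "completed") %in% names(x)))
      stop("events must have participant, kind and completed columns",
           call. = FALSE)
    return(x)
  }
  stop("expected an mrpe_cohort or an events data frame", call. = FALSE)
}

filter_denominator <- function(events, denominator) {
  denominator <- match.arg(denominator, c("all", "short"))
  if (denominator == "short") events[events$kind == "short", , drop = FALSE]
  else events
}

#' Overall survey completion rate
#'
#' The study's primary outcome: surveys completed divided by surveys made
#' available, overall and broken down by survey kind and (when arm columns
#' are present) by each aspect's arm.
#'
#' @param cohort An `mrpe_cohort` or events data frame.
#' @param denominator `"all"` (short + topic + interest surveys, the
#'   default) or `"short"`.
#' @return A list with `completion_rate`, `n_completed`, `n_available`,
#'   `by_kind` and `by_arm` data frames.
#' @export
completion_rate <- function(cohort, denominator = "all") {
  events <- filter_denominator(as_events(cohort), denominator)
  if (nrow(events) == 0L)
    stop("completion rate is undefined: no available surveys", call. = FALSE)
  by_kind <- stats::aggregate(completed ~ kind, events,
                              function(z) c(sum(z), length(z)))
  by_kind <- data.frame(kind = by_kind$kind,
                        n_completed = by_kind$completed[, 1],
                        n_available = by_kind$completed[, 2])
  by_kind$rate <- by_kind$n_completed / by_kind$n_available
  arm_cols <- intersect(c("schedule", "notify_time", "reminder_lag",
                          "notify_text", "reminder_text"), names(events))
  by_arm <- do.call(rbind, lapply(arm_cols, function(col) {
    agg <- stats::aggregate(events$completed, list(arm = events[[col]]),
                            function(z) c(sum(z), length(z)))
    data.frame(aspect = col, arm = agg$arm, n_completed = agg$x[, 1],
               n_available = agg$x[, 2], rate = agg$x[, 1] / agg$x[, 2],
               stringsAsFactors = FALSE)
  }))
  list(completion_rate = sum(events$completed) / nrow(events),
       n_completed = sum(events$completed),
       n_available = nrow(events),
       by_kind = by_kind, by_arm = by_arm)
}

per_participant_rates <- function(events) {
  agg <- stats::aggregate(events$completed, list(id = events$participant),
                          function(z) c(sum(z), length(z)))
  data.frame(id = agg$id, n_completed = agg$x[, 1], n_available = agg$x[, 2],
             rate = agg$x[, 1] / agg$x[, 2])
}

#' Proportion of participants completing more than a cutoff fraction
#'
#' Secondary outcome: the fraction of participants completing strictly
#' greater than `cutoff` (default 80%) of the surveys made available to
#' them; each participant's denominator is their own available surveys.
#'
#' @inheritParams completion_rate
#' @param cutoff Completion fraction that must be strictly exceeded
#'   (default 0.8).
#' @return A fraction in [0, 1].
#' @export
proportion_high_completers <- function(cohort, cutoff = 0.8,
                                       denominator = "all") {
  events <- filter_denominator(as_events(cohort), denominator)
  if (nrow(events) == 0L) return(0)
  rates <- per_participant_rates(events)
  mean(rates$rate > cutoff)
}

#' Identify low-completing participants for follow-up
#'
#' Participants completing strictly less than `cutoff` (default 20%) of
#' their available surveys over the study are flagged for an email
#' follow-up about reasons for disengagement.
#'
#' @inheritParams proportion_high_completers
#' @param cutoff Completion fraction below which a participant is flagged
#'   (default 0.2, strict inequality).
#' @return Sorted integer vector of flagged participant ids.
#' @export
low_completer_flags <- function(cohort, cutoff = 0.2, denominator = "all") {
  events <- filter_denominator(as_events(cohort), denominator)
  if (nrow(events) == 0L) return(integer(0))
  rates <- per_participant_rates(events)
  sort(rates$id[rates$rate < cutoff])
}

#' Full outcome summary of a cohort
#'
#' Computes the primary outcome (overall completion rate with per-kind and
#' per-arm breakdowns) and the secondary outcomes: proportion of
#' participants completing more than 80% of surveys, the list of
#' participants below 20% flagged for follow-up, and the retention rate.
#' Retention has no single agreed numeric definition in app cohorts; it is
#' operationalised here, explicitly as an interpretation, as the fraction
#' of participants completing at least one survey in their final study
#' week.
#'
#' @inheritParams completion_rate
#' @param path Optional path; when given the summary is written as JSON.
#' @return An object of class `outcome_summary`.
#' @export
compute_outcomes <- function(cohort, denominator = "all", path = NULL) {
  events <- filter_denominator(as_events(cohort), denominator)
  cr <- completion_rate(events)
  rates <- per_participant_rates(events)
  final_week <- stats::aggregate(
    events$study_week, list(id = events$participant), max)
  last <- merge(events, stats::setNames(final_week, c("participant", "fw")))
  retained <- stats::aggregate(
    last$completed & last$study_week == last$fw,
    list(id = last$participant), any)
  out <- structure(list(
    completion_rate = cr$completion_rate,
    n_completed = cr$n_completed,
    n_available = cr$n_available,
    by_kind = cr$by_kind,
    by_arm = cr$by_arm,
    prop_over_80 = proportion_high_completers(events),
    low_completer_ids = low_completer_flags(events),
    retention_rate = mean(retained$x),
    n_participants = nrow(rates),
    denominator = denominator), class = "outcome_summary")
  if (!is.null(path)) {
    json <- out
    class(json) <- NULL
    jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  out
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat("<outcome_summary>\n")
  cat(sprintf("  completion rate: %d/%d = %.3f\n", x$n_completed,
              x$n_available, x$completion_rate))
  cat(sprintf("  completing >80%% of surveys: %.3f of %d participants\n",
              x$prop_over_80, x$n_participants))
  cat(sprintf("  flagged <20%% completers: %d\n",
              length(x$low_completer_ids)))
  cat(sprintf("  retention (>=1 completion in final week): %.3f\n",
              x$retention_rate))
  invisible(x)
}
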