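#' Configuration of a synthetic app cohort
#'
#' Describes a cohort of app participants followed for `weeks` weeks, each
#' receiving short health-status surveys (twice weekly on days 3 and 7
#' under schedule A, weekly on day 7 under schedule B), one weekly
#' five-minute topic survey cycling through a catalogue of
#' `topic_catalogue_size` validated surveys, and one weekly interest
#' survey. Every scheduled survey is completed independently with a
#' probability equal to the baseline completion rate plus the additive
#' effects of the participant's arm in each design aspect.
#'
#' @param n_participants Cohort size (default 275).
#' @param weeks Follow-up length in weeks per participant (default 12).
#' @param short_schedule `"A"` (days 3 and 7), `"B"` (day 7 only) or
#'   `"randomised"` (each participant follows their schedule-aspect arm).
#' @param topic_catalogue_size Number of topic surveys cycled through
#'   (default 13).
#' @param baseline Baseline per-survey completion probability
#'   (default 0.20).
#' @param arm_effects Named list, one element per aspect, each a named
#'   numeric vector of additive percentage-point effects (on the
#'   probability scale) for that aspect's two options. Default: zero for
#'   every arm, so all surveys complete at `baseline`.
#' @param enrolment_spread Number of weeks over which enrolment is spread;
#'   participants are assigned evenly (round-robin) to enrolment weeks
#'   `1..enrolment_spread`. Default 1 (everyone starts in week 1).
#' @param participant_sd Standard deviation of an optional logit-normal
#'   per-participant random effect on completion (default 0: independent
#'   Bernoulli completions, the study's working assumption).
#' @param aspects List of [aspect_spec()]s whose arms participants are
#'   randomised between (default [default_aspects()]).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 275L, weeks = 12L,
                          short_schedule = c("A", "B", "randomised"),
                          topic_catalogue_size = 13L, baseline = 0.20,
                          arm_effects = NULL, enrolment_spread = 1L,
                          participant_sd = 0,
                          aspects = default_aspects()) {
  short_schedule <- match.arg(short_schedule)
  if (!is.numeric(n_participants) || n_participants < 1 ||
      !is_whole(n_participants))
    stop("`n_participants` must be a positive integer", call. = FALSE)
  if (!is.numeric(weeks) || weeks < 1 || !is_whole(weeks))
    stop("`weeks` must be a positive integer", call. = FALSE)
  if (!is.numeric(topic_catalogue_size) || topic_catalogue_size < 1)
    stop("`topic_catalogue_size` must be a positive integer", call. = FALSE)
  if (!is.numeric(baseline) || baseline < 0 || baseline > 1)
    stop("`baseline` must be a probability in [0, 1]", call. = FALSE)
  if (!is.numeric(enrolment_spread) || enrolment_spread < 1)
    stop("`enrolment_spread` must be a positive integer", call. = FALSE)
  if (!is.numeric(participant_sd) || participant_sd < 0)
    stop("`participant_sd` must be non-negative", call. = FALSE)
  if (is.null(arm_effects)) {
    arm_effects <- lapply(aspects, function(sp) {
      stats::setNames(c(0, 0), c(sp$option_a, sp$option_b))
    })
  }
  for (nm in names(aspects)) {
    sp <- aspects[[nm]]
    eff <- arm_effects[[nm]]
    if (is.null(eff) || !all(c(sp$option_a, sp$option_b) %in% names(eff)))
      stop(sprintf("arm_effects for aspect '%s' must name both options", nm),
           call. = FALSE)
    if (any(baseline + eff < -1e-12 | baseline + eff > 1 + 1e-12))
      stop(sprintf(
        "arm_effects for aspect '%s' push completion probability outside [0, 1]",
        nm), call. = FALSE)
  }
  structure(list(n_participants = as.integer(n_participants),
                 weeks = as.integer(weeks),
                 short_schedule = short_schedule,
                 topic_catalogue_size = as.integer(topic_catalogue_size),
                 baseline = baseline, arm_effects = arm_effects,
                 enrolment_spread = as.integer(enrolment_spread),
                 participant_sd = participant_sd, aspects = aspects),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d participants, %d weeks, schedule %s, baseline %.2f\n",
    x$n_participants, x$weeks, x$short_schedule, x$baseline))
  invisible(x)
}

## Per-participant deterministic survey calendar: study weeks 1..weeks,
## short surveys on days 3+7 (A) or 7 (B), topic + interest on day 7.
participant_calendar <- function(weeks, schedule, catalogue) {
  wk <- seq_len(weeks)
  short_days <- if (schedule == "A") c(3L, 7L) else 7L
  short <- expand.grid(study_week = wk, day = short_days,
                       KEEP.OUT.ATTRS = FALSE)
  short$kind <- "short"; short$topic <- NA_integer_
  topic <- data.frame(study_week = wk, day = 7L, kind = "topic",
                      topic = ((wk - 1L) %% catalogue) + 1L)
  interest <- data.frame(study_week = wk, day = 7L, kind = "interest",
                         topic = NA_integer_)
  cal <- rbind(short, topic, interest)
  cal[order(cal$study_week, cal$day, match(cal$kind,
                                           c("short", "topic", "interest"))),
      , drop = FALSE]
}

#' Generate a synthetic app cohort
#'
#' Randomises each participant between the two options of every design
#' aspect, lays out the deterministic survey calendar implied by their
#' schedule, and draws per-survey Bernoulli completions. Given a config,
#' only arm assignments, random effects and completion flags are
#' stochastic; the calendar itself is fixed.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed.
#' @return An object of class `mrpe_cohort`: list with `config`,
#'   `participants` (id, enrol_week, one arm column per aspect) and
#'   `events` (one row per scheduled survey: participant, enrol_week,
#'   study_week, week (calendar), day, kind, topic, the five arm labels,
#'   completion probability and `completed` flag).
#' @export
generate_cohort <- function(config, seed = NULL) {
  if (!inherits(config, "cohort_config"))
    stop("`config` must be a cohort_config", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_participants
  aspects <- config$aspects

  participants <- data.frame(
    id = seq_len(n),
    enrol_week = ((seq_len(n) - 1L) %% config$enrolment_spread) + 1L)
  for (nm in names(aspects)) {
    sp <- aspects[[nm]]
    participants[[nm]] <- ifelse(stats::runif(n) < sp$alloc_prob,
                                 sp$option_a, sp$option_b)
  }
  u <- if (config$participant_sd > 0)
    stats::rnorm(n, 0, config$participant_sd) else numeric(n)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sched <- if (config$short_schedule == "randomised")
      if (participants$schedule[i] == aspects$schedule$option_a) "A" else "B"
    else config$short_schedule
    cal <- participant_calendar(config$weeks, sched,
                                config$topic_catalogue_size)
    p <- config$baseline
    for (nm in names(aspects))
      p <- p + config$arm_effects[[nm]][[participants[[nm]][i]]]
    p <- min(max(p, 0), 1)
    if (config$participant_sd > 0 && p > 0 && p < 1)
      p <- stats::plogis(stats::qlogis(p) + u[i])
    m <- nrow(cal)
    rows[[i]] <- data.frame(
      participant = participants$id[i],
      enrol_week = participants$enrol_week[i],
      study_week = cal$study_week,
      week = participants$enrol_week[i] + cal$study_week - 1L,
      day = cal$day, kind = cal$kind, topic = cal$topic,
      schedule = participants$schedule[i],
      notify_time = participants$notify_time[i],
      reminder_lag = participants$reminder_lag[i],
      notify_text = participants$notify_text[i],
      reminder_text = participants$reminder_text[i],
      p_complete = p,
      completed = stats::runif(m) < p,
      stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(config = config, participants = participants,
                 events = events),
            class = "mrpe_cohort")
}

#' @export
print.mrpe_cohort <- function(x, ...) {
  cat(sprintf(
    "<mrpe_cohort> %d participants, %d survey events (%.1f%% completed)\n",
    nrow(x$participants), nrow(x$events),
    100 * mean(x$events$completed)))
  invisible(x)
}

#' Write a cohort's survey events as tidy CSV
#'
#' One row per scheduled survey event with all event and arm fields; the
#' file round-trips losslessly through [read_cohort()].
#'
#' @param cohort An [generate_cohort()] result.
#' @param path Output CSV path.
#' @return The events data frame, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (!inherits(cohort, "mrpe_cohort"))
    stop("`cohort` must be an mrpe_cohort", call. = FALSE)
  if (nrow(cohort$events) == 0L)
    stop("cohort has no events to write", call. = FALSE)
  utils::write.csv(cohort$events, path, row.names = FALSE)
  invisible(cohort$events)
}

#' Read a cohort events CSV back into an `mrpe_cohort`
#'
#' Participants and their arm assignments are reconstructed from the event
#' rows; the original generating configuration is not stored in the file.
#'
#' @param path CSV path written by [write_cohort()].
#' @return An `mrpe_cohort` with `config = NULL`.
#' @export
read_cohort <- function(path) {
  events <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant", "enrol_week", "study_week", "week", "day",
              "kind", "topic", "completed")
  missing <- setdiff(needed, names(events))
  if (length(missing))
    stop("cohort file is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  events$completed <- as.logical(events$completed)
  arm_cols <- intersect(c("schedule", "notify_time", "reminder_lag",
                          "notify_text", "reminder_text"), names(events))
  participants <- unique(events[, c("participant", "enrol_week", arm_cols)])
  names(participants)[1] <- "id"
  participants <- participants[order(participants$id), , drop = FALSE]
  rownames(participants) <- NULL
  structure(list(config = NULL, participants = participants,
                 events = events),
            class = "mrpe_cohort")
}
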