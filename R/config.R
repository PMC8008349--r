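#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Every stage of the pipeline draws its randomness from its own substream
#' so that, e.g., the cohort stays fixed while decision-rule knobs vary.
#' The substream seed is a deterministic polynomial hash of the stage
#' label combined with the master seed, reduced modulo 2^31 - 1 so it is
#' always a valid R integer seed.
#'
#' @param master Integer master seed.
#' @param label Stage label (non-empty string).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  if (!is.numeric(master) || length(master) != 1L || !is.finite(master))
    stop("`master` must be a single integer", call. = FALSE)
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("`label` must be a non-empty string", call. = FALSE)
  m <- 2147483647
  h <- abs(as.numeric(master)) %% m
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% m
  as.integer(h)
}

default_true_rates <- function(baseline = 0.20) {
  lapply(default_aspects(), function(sp) c(baseline, baseline))
}

## The full default configuration: the study's stated design values.
#' Default pipeline configuration
#'
#' The defaults are the study's design values: 275 participants followed
#' for 12 weeks at a 20% baseline completion rate; five sequential
#' evaluations each with n_initial 10, n_max 50 and an acceptable expected
#' loss of 0.01; 10000 operating-characteristic replicates.
#'
#' @return A named list (class `mrpe_config`).
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    design = list(n_initial = 10L, n_max = 50L, epsilon = 0.01,
                  alloc_prob = 0.5),
    cohort = list(n_participants = 275L, weeks = 12L, short_schedule = "A",
                  topic_catalogue_size = 13L, baseline = 0.20,
                  enrolment_spread = 1L, participant_sd = 0),
    true_rates = default_true_rates(0.20),
    oc = list(replicates = 10000L)
  ), class = "mrpe_config")
}

check_scalar <- function(value, key, lo = -Inf, hi = Inf, whole = FALSE) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value < lo || value > hi || (whole && !is_whole(value)))
    stop(sprintf("config key '%s' is invalid (value: %s)", key,
                 paste(value, collapse = ",")), call. = FALSE)
  value
}

validate_config <- function(cfg) {
  d <- cfg$design
  check_scalar(d$n_initial, "design.n_initial", 1, Inf, whole = TRUE)
  check_scalar(d$n_max, "design.n_max", d$n_initial, Inf, whole = TRUE)
  check_scalar(d$epsilon, "design.epsilon", 0, 1 - 1e-12)
  check_scalar(d$alloc_prob, "design.alloc_prob", 1e-12, 1 - 1e-12)
  co <- cfg$cohort
  check_scalar(co$n_participants, "cohort.n_participants", 1, Inf,
               whole = TRUE)
  check_scalar(co$weeks, "cohort.weeks", 1, Inf, whole = TRUE)
  if (!co$short_schedule %in% c("A", "B", "randomised"))
    stop("config key 'cohort.short_schedule' must be A, B or randomised",
         call. = FALSE)
  check_scalar(co$topic_catalogue_size, "cohort.topic_catalogue_size", 1,
               Inf, whole = TRUE)
  check_scalar(co$baseline, "cohort.baseline", 0, 1)
  check_scalar(co$enrolment_spread, "cohort.enrolment_spread", 1, Inf,
               whole = TRUE)
  check_scalar(co$participant_sd, "cohort.participant_sd", 0, Inf)
  check_scalar(cfg$oc$replicates, "oc.replicates", 1, Inf, whole = TRUE)
  check_scalar(cfg$seed, "seed", whole = TRUE)
  known <- names(default_true_rates())
  for (nm in names(cfg$true_rates)) {
    if (!nm %in% known)
      stop(sprintf("config key 'true_rates.%s' is not a known aspect", nm),
           call. = FALSE)
    r <- unlist(cfg$true_rates[[nm]])
    if (length(r) != 2L || any(r <= 0 | r >= 1))
      stop(sprintf(
        "config key 'true_rates.%s' must be two probabilities in (0, 1)",
        nm), call. = FALSE)
    cfg$true_rates[[nm]] <- as.numeric(r)
  }
  cfg
}

merge_strict <- function(defaults, user, prefix = "") {
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(defaults))
      stop(sprintf("unknown config key '%s'", full), call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        key != "true_rates") {
      if (!is.list(user[[key]]))
        stop(sprintf("config key '%s' must be a mapping", full),
             call. = FALSE)
      defaults[[key]] <- merge_strict(defaults[[key]], user[[key]],
                                      paste0(full, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML or JSON configuration file, fills every omitted key with
#' the study defaults from [default_config()], rejects unknown keys, and
#' validates all values. An empty file yields the full default
#' configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for the
#'   defaults.
#' @return A validated `mrpe_config` list.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(validate_config(default_config()))
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user))
    stop("config file must contain a mapping", call. = FALSE)
  cfg <- merge_strict(unclass(default_config()), user)
  class(cfg) <- "mrpe_config"
  validate_config(cfg)
}

config_aspects <- function(cfg) {
  default_aspects(n_initial = cfg$design$n_initial,
                  n_max = cfg$design$n_max,
                  epsilon = cfg$design$epsilon)
}

## Order-independent content hash of a config (hex string), for manifests.
config_hash <- function(cfg) {
  flat <- function(x, prefix = "") {
    if (is.list(x)) {
      nms <- names(x)
      unlist(lapply(seq_along(x),
                    function(i) flat(x[[i]], paste0(prefix, nms[i], "="))))
    } else paste0(prefix, paste(format(x, digits = 15), collapse = ","))
  }
  parts <- sort(flat(unclass(cfg)))
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(paste(parts, collapse = ";")))
    h <- (h * 31 + b) %% m
  sprintf("%08x", as.integer(h))
}
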