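# Service configuration: every numerical parameter of the cataract service
# model lives in one flat validated list (the `service_config`), read from and
# written to a plain YAML file.

EXAM_OUTCOMES <- c("not_suitable", "listed_direct", "preop_clinic", "preop_phone")

DURATION_NAMES <- c(
  "eye_exam", "preop_clinic", "preop_phone", "presurgery_tests",
  "anaesthesia_local", "anaesthesia_general", "surgery",
  "recovery_chair", "recovery_bed"
)

# scalar fields with documented defaults; everything else is required
CONFIG_OPTIONAL <- list(
  session_minutes = 240,
  working_days_per_week = 5L,
  weeks_per_year = 52L,
  warmup_weeks = 4L,
  unfit_reschedule_delay_weeks = 2,
  p_noshow_rebooked = 0.75,
  booking_lead_days = 7,
  tariff_preop_clinic = 0,
  overhead_per_surgery = 0
)

CONFIG_REQUIRED <- c(
  "referral_rate_optometrist", "referral_rate_internal",
  "exam_outcome_probs",
  "p_unfit_on_day", "p_noshow_elderly", "p_noshow_other", "p_elderly",
  "p_general_anaesthesia", "p_bed_local_elderly", "p_overnight",
  "durations",
  "theatres", "lists_per_theatre_per_week", "patients_per_list",
  "consult_rooms", "presurgery_rooms", "recovery_chairs", "recovery_beds",
  "doctors", "nurses",
  "tariff_surgery", "tariff_first_appointment", "tariff_followup",
  "hourly_cost_doctor", "hourly_cost_nurse"
)

#' Construct a service configuration
#'
#' Builds a validated `service_config` from named parameters. Fields not
#' supplied among the optional ones take their documented defaults
#' (`session_minutes = 240`, `working_days_per_week = 5`,
#' `weeks_per_year = 52`, `warmup_weeks = 4`,
#' `unfit_reschedule_delay_weeks = 2`, `p_noshow_rebooked = 0.75`,
#' `booking_lead_days = 7`, `tariff_preop_clinic = 0`,
#' `overhead_per_surgery = 0`).
#'
#' @param ... Named configuration fields; see [default_parameters()] for the
#'   full schema and a complete worked set of values.
#' @return A validated `service_config` object.
#' @seealso [load_config()], [validate_config()], [default_parameters()]
#' @export
service_config <- function(...) {
  fields <- list(...)
  if (length(fields) == 1L && is.null(names(fields)) && is.list(fields[[1L]])) {
    fields <- fields[[1L]]
  }
  missing <- setdiff(CONFIG_REQUIRED, names(fields))
  if (length(missing) > 0L) {
    stop("configuration is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (key in names(CONFIG_OPTIONAL)) {
    if (is.null(fields[[key]])) fields[[key]] <- CONFIG_OPTIONAL[[key]]
  }
  unknown <- setdiff(names(fields), c(CONFIG_REQUIRED, names(CONFIG_OPTIONAL)))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  validate_config(structure(fields[c(CONFIG_REQUIRED, names(CONFIG_OPTIONAL))],
                            class = "service_config"))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("field '", name, "' must be a probability in [0, 1]", call. = FALSE)
  }
  as.numeric(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop("field '", name, "' must be an integer count >= ", min, call. = FALSE)
  }
  as.integer(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop("field '", name, "' must be a non-negative number", call. = FALSE)
  }
  as.numeric(x)
}

#' Validate a service configuration
#'
#' Checks every schema invariant: probabilities in \[0, 1\], the four
#' examination-outcome probabilities summing to one, non-negative counts and
#' rates, positive duration means, and a session timetable that fits the
#' working week. Errors name the offending field and bound.
#'
#' @param config A `service_config` (or a bare list with the same fields).
#' @return The validated config, invisibly classed as `service_config`.
#' @export
validate_config <- function(config) {
  cf <- unclass(config)

  for (f in c("referral_rate_optometrist", "referral_rate_internal",
              "tariff_surgery", "tariff_first_appointment", "tariff_followup",
              "tariff_preop_clinic", "hourly_cost_doctor", "hourly_cost_nurse",
              "overhead_per_surgery", "unfit_reschedule_delay_weeks",
              "booking_lead_days")) {
    cf[[f]] <- check_nonneg(cf[[f]], f)
  }
  for (f in c("p_unfit_on_day", "p_noshow_elderly", "p_noshow_other", "p_elderly",
              "p_general_anaesthesia", "p_bed_local_elderly", "p_overnight",
              "p_noshow_rebooked")) {
    cf[[f]] <- check_prob(cf[[f]], f)
  }
  for (f in c("theatres", "lists_per_theatre_per_week", "patients_per_list",
              "consult_rooms", "presurgery_rooms", "recovery_chairs",
              "recovery_beds", "doctors", "nurses", "warmup_weeks")) {
    cf[[f]] <- check_count(cf[[f]], f)
  }
  cf$working_days_per_week <- check_count(cf$working_days_per_week, "working_days_per_week", min = 1L)
  cf$weeks_per_year <- check_count(cf$weeks_per_year, "weeks_per_year", min = 1L)
  if (!is.numeric(cf$session_minutes) || length(cf$session_minutes) != 1L ||
      is.na(cf$session_minutes) || cf$session_minutes <= 0) {
    stop("field 'session_minutes' must be > 0", call. = FALSE)
  }
  if (cf$working_days_per_week > 7L) {
    stop("field 'working_days_per_week' must be <= 7", call. = FALSE)
  }

  probs <- cf$exam_outcome_probs
  if (is.list(probs)) probs <- unlist(probs)
  if (!is.numeric(probs) || length(probs) != 4L || anyNA(probs)) {
    stop("field 'exam_outcome_probs' must be 4 numbers (",
         paste(EXAM_OUTCOMES, collapse = ", "), ")", call. = FALSE)
  }
  if (is.null(names(probs)) || !all(nzchar(names(probs)))) {
    names(probs) <- EXAM_OUTCOMES
  } else if (!setequal(names(probs), EXAM_OUTCOMES)) {
    stop("field 'exam_outcome_probs' must be named ",
         paste(EXAM_OUTCOMES, collapse = ", "), call. = FALSE)
  }
  probs <- probs[EXAM_OUTCOMES]
  if (any(probs < 0) || any(probs > 1)) {
    stop("field 'exam_outcome_probs' entries must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("field 'exam_outcome_probs' must sum to 1 (got ", sum(probs), ")",
         call. = FALSE)
  }
  cf$exam_outcome_probs <- probs

  if (!is.list(cf$durations)) {
    stop("field 'durations' must be a named list of duration specs", call. = FALSE)
  }
  missing_d <- setdiff(DURATION_NAMES, names(cf$durations))
  if (length(missing_d) > 0L) {
    stop("field 'durations' is missing: ", paste(missing_d, collapse = ", "),
         call. = FALSE)
  }
  cf$durations <- lapply(
    stats::setNames(DURATION_NAMES, DURATION_NAMES),
    function(nm) validate_duration_spec(cf$durations[[nm]], nm)
  )

  max_lists <- cf$working_days_per_week * 2L
  if (cf$lists_per_theatre_per_week > max_lists) {
    stop("field 'lists_per_theatre_per_week' (", cf$lists_per_theatre_per_week,
         ") exceeds the available half-day slots per week (",
         max_lists, ")", call. = FALSE)
  }

  invisible(structure(cf, class = "service_config"))
}

#' Read a service configuration from a YAML file
#'
#' The file holds the flat key/value schema documented in
#' [default_parameters()]; a complete annotated example ships at
#' `system.file("extdata", "default_config.yaml", package = "cataractsim")`.
#' Optional keys absent from the file take their documented defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `service_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$exam_outcome_probs)) {
    raw$exam_outcome_probs <- unlist(raw$exam_outcome_probs)
  }
  service_config(raw)
}

#' Write a service configuration to a YAML file
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces `cfg` exactly.
#'
#' @param config A validated `service_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  out <- unclass(config)
  out$exam_outcome_probs <- as.list(out$exam_outcome_probs)
  out$durations <- lapply(out$durations, unclass)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Planned weekly surgical capacity
#'
#' The number of cataract surgeries planned per week:
#' theatres x lists per theatre per week x patients per list. For the worked
#' service arrangement of one theatre with three half-day lists of six
#' patients this is 18.
#'
#' @param config A validated `service_config`.
#' @return An integer count of planned surgeries per week.
#' @examples
#' cfg <- default_parameters()
#' planned_weekly_capacity(cfg)
#' @export
planned_weekly_capacity <- function(config) {
  config$theatres * config$lists_per_theatre_per_week * config$patients_per_list
}

#' @export
print.service_config <- function(x, ...) {
  cat("<service_config>\n")
  cat("  demand: ", x$referral_rate_optometrist, " optometrist + ",
      x$referral_rate_internal, " internal referrals/week\n", sep = "")
  cat("  capacity: ", x$theatres, " theatre(s) x ", x$lists_per_theatre_per_week,
      " lists/week x ", x$patients_per_list, " patients/list = ",
      planned_weekly_capacity(x), " surgeries/week\n", sep = "")
  cat("  staff: ", x$doctors, " doctors, ", x$nurses, " nurses; rooms: ",
      x$consult_rooms, " consult, ", x$presurgery_rooms, " pre-surgery; recovery: ",
      x$recovery_chairs, " chairs, ", x$recovery_beds, " beds\n", sep = "")
  cat("  horizon: ", x$weeks_per_year, " reporting weeks (+", x$warmup_weeks,
      " warm-up)\n", sep = "")
  invisible(x)
}
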