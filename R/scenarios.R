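# What-if scenarios: each scenario raises the number of surgeries per
# half-day theatre list and, because the process changes that make this
# feasible (earlier admission for pre-surgery tests, rapid 3D biometry,
# earlier lens preparation) shorten some activities, rescales the named
# activity-duration distributions.

#' Define a what-if scenario
#'
#' A scenario is a named delta on a service configuration: a new number of
#' patients per theatre list plus multiplicative rescalings of named activity
#' durations.
#'
#' @param name Scenario name (free text; the shipped set uses `"baseline"`,
#'   `"scenario1"`, `"scenario2"`, `"scenario3"`).
#' @param patients_per_list Number of surgeries booked per half-day list.
#' @param duration_multipliers Named list mapping duration names (see
#'   `cataractsim:::DURATION_NAMES`) to positive factors.
#' @return A `scenario_spec` object.
#' @examples
#' scenario_spec("scenario1", 7, list(presurgery_tests = 0.85))
#' @export
scenario_spec <- function(name, patients_per_list, duration_multipliers = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  patients_per_list <- check_count(patients_per_list, "patients_per_list", min = 1L)
  if (length(duration_multipliers) > 0L) {
    if (is.null(names(duration_multipliers)) || !all(nzchar(names(duration_multipliers)))) {
      stop("duration_multipliers must be a named list", call. = FALSE)
    }
    bad <- setdiff(names(duration_multipliers), DURATION_NAMES)
    if (length(bad) > 0L) {
      stop("unknown duration name(s) in multipliers: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (nm in names(duration_multipliers)) {
      m <- duration_multipliers[[nm]]
      if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= 0) {
        stop("multiplier for '", nm, "' must be a positive number", call. = FALSE)
      }
    }
  }
  structure(
    list(name = name, patients_per_list = patients_per_list,
         duration_multipliers = duration_multipliers),
    class = "scenario_spec"
  )
}

#' The shipped four-scenario sweep
#'
#' Baseline books 6 surgeries per half-day list. The alternatives raise this
#' to 7, 8 and 9 by shortening parts of the day-of-surgery process:
#' scenario 1 admits patients earlier for the pre-surgery tests
#' (pre-surgery tests x 0.85); scenario 2 additionally uses a 3D imaging
#' machine for rapid lens measurement (pre-surgery tests x 0.6); scenario 3
#' additionally prepares the lens earlier during surgery
#' (pre-surgery tests x 0.6, surgery x 0.9). The multiplier values are
#' modelling assumptions: the process changes are qualitative service
#' redesigns and the shipped factors are chosen so each list's expected
#' workload still fits one session.
#'
#' @return A named list of four [scenario_spec()] objects.
#' @export
default_scenarios <- function() {
  list(
    baseline  = scenario_spec("baseline", 6L),
    scenario1 = scenario_spec("scenario1", 7L, list(presurgery_tests = 0.85)),
    scenario2 = scenario_spec("scenario2", 8L, list(presurgery_tests = 0.6)),
    scenario3 = scenario_spec("scenario3", 9L, list(presurgery_tests = 0.6, surgery = 0.9))
  )
}

#' Apply a scenario to a configuration
#'
#' Returns a new configuration with `patients_per_list` replaced and each
#' named duration rescaled by its multiplier; every other field is unchanged
#' and the input config is not modified.
#'
#' @param config A validated `service_config`.
#' @param scenario A [scenario_spec()].
#' @return A new validated `service_config`.
#' @examples
#' cfg <- default_parameters()
#' s3 <- apply_scenario(cfg, default_scenarios()$scenario3)
#' s3$patients_per_list
#' @export
apply_scenario <- function(config, scenario) {
  config <- validate_config(config)
  if (!inherits(scenario, "scenario_spec")) {
    stop("'scenario' must be a scenario_spec", call. = FALSE)
  }
  out <- unclass(config)
  out$patients_per_list <- scenario$patients_per_list
  for (nm in names(scenario$duration_multipliers)) {
    if (!nm %in% names(out$durations)) {
      stop("unknown duration name in multipliers: ", nm, call. = FALSE)
    }
    out$durations[[nm]] <- scale_duration(out$durations[[nm]],
                                          scenario$duration_multipliers[[nm]])
  }
  validate_config(structure(out, class = "service_config"))
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario '", x$name, "': ", x$patients_per_list, " patients/list", sep = "")
  if (length(x$duration_multipliers) > 0L) {
    cat("; ", paste(sprintf("%s x%g", names(x$duration_multipliers),
                            unlist(x$duration_multipliers)), collapse = ", "))
  }
  cat(">\n")
  invisible(x)
}
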