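# Replication machinery: independent replications of the one-year run,
# t-based confidence intervals, and the four-scenario sweep with common
# random numbers.

#' Replicate a run and summarise the annual indicators
#'
#' Runs `n_reps` independent one-year replications (seeds derived from the
#' master seed) and returns, per indicator, the replication mean, standard
#' deviation and a t-based confidence interval.
#'
#' @param config A validated `service_config`.
#' @param scenario Optional [scenario_spec()].
#' @param n_reps Number of replications (>= 2).
#' @param master_seed Master seed from which replication seeds are derived.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with columns `indicator`, `mean`, `sd`, `conf_low`,
#'   `conf_high`, `n_reps`.
#' @export
replicate_and_summarise <- function(config, scenario = NULL, n_reps = 10L,
                                    master_seed = 1L, conf_level = 0.95) {
  if (!is.numeric(n_reps) || n_reps < 2L) {
    stop("n_reps must be >= 2 to form a confidence interval", call. = FALSE)
  }
  n_reps <- as.integer(n_reps)
  seeds <- derive_seeds(master_seed, n_reps)
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    g <- glance(simulate_service(config, scenario = scenario, seed = seeds[r]))
    dplyr::mutate(g, rep = r, .before = 1L)
  })
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n_reps - 1L)
  reps |>
    tidyr::pivot_longer(-"rep", names_to = "indicator", values_to = "value") |>
    dplyr::group_by(.data$indicator) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      conf_low = .data$mean - tcrit * .data$sd / sqrt(n_reps),
      conf_high = .data$mean + tcrit * .data$sd / sqrt(n_reps),
      n_reps = n_reps
    )
}

#' Run the what-if scenario sweep
#'
#' Simulates each scenario for the same set of replication seeds (common
#' random numbers: the same referral pattern, outcome draws and attendance
#' behaviour hit every scenario, so the contrasts between scenarios are not
#' blurred by sampling noise).
#'
#' @param config A validated `service_config`.
#' @param scenarios A named list of [scenario_spec()]s, by default the
#'   shipped four-scenario sweep ([default_scenarios()]).
#' @param replications Replications per scenario.
#' @param master_seed Master seed from which the shared replication seeds
#'   are derived.
#' @param verbose If `TRUE`, log progress to standard error.
#' @return A `scenario_sweep` tibble: one row per scenario x replication
#'   with the annual indicators. Summarise with [scenario_summary()] /
#'   [tidy()], plot with [autoplot()].
#' @examples
#' \donttest{
#' sweep <- run_scenarios(default_parameters(), replications = 3, master_seed = 1)
#' scenario_summary(sweep)
#' }
#' @export
run_scenarios <- function(config, scenarios = default_scenarios(),
                          replications = 5L, master_seed = 1L, verbose = FALSE) {
  stopifnot(length(scenarios) >= 1L)
  replications <- as.integer(replications)
  seeds <- derive_seeds(master_seed, replications)
  scen_names <- vapply(scenarios, function(s) s$name, character(1))
  out <- purrr::map_dfr(scenarios, function(sc) {
    if (verbose) message("[cataractsim] scenario '", sc$name, "': ",
                         replications, " replications")
    purrr::map_dfr(seq_len(replications), function(r) {
      g <- glance(simulate_service(config, scenario = sc, seed = seeds[r]))
      dplyr::mutate(g,
                    scenario = factor(sc$name, levels = scen_names),
                    rep = r, seed = seeds[r], .before = 1L)
    })
  })
  class(out) <- c("scenario_sweep", class(out))
  out
}
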