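# broom-style accessors and print methods for simulation results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

GLANCE_COLS <- c(
  "surgeries", "doctor_hours", "nurse_hours",
  "util_presurgery_room", "util_recovery_chair", "util_recovery_bed",
  "revenue", "cost", "surplus",
  "cancellations", "no_shows", "mean_referral_to_discharge_weeks"
)

#' @export
print.cataract_sim <- function(x, ...) {
  a <- x$annual
  cat("<cataract_sim: scenario '", x$scenario, "', seed ", x$seed, ">\n", sep = "")
  cat("  reporting year: ", a$surgeries, " surgeries, ",
      a$cancellations, " cancellations, ", a$no_shows, " no-shows\n", sep = "")
  cat(sprintf("  staff: %.0f doctor h, %.0f nurse h\n", a$doctor_hours, a$nurse_hours))
  cat(sprintf("  utilisation: pre-surgery room %.0f%%, chair %.0f%%, bed %.0f%%\n",
              a$util_presurgery_room, a$util_recovery_chair, a$util_recovery_bed))
  cat(sprintf("  finance: revenue GBP %s, cost GBP %s, surplus GBP %s\n",
              format(a$revenue, big.mark = ","), format(a$cost, big.mark = ","),
              format(a$surplus, big.mark = ",")))
  invisible(x)
}

#' Monthly indicators of a run in long form
#'
#' @param x A `cataract_sim`.
#' @param ... Unused.
#' @return A tibble with columns `month`, `indicator`, `value`.
#' @method tidy cataract_sim
#' @export
tidy.cataract_sim <- function(x, ...) {
  x$monthly |>
    dplyr::select(dplyr::all_of(c("month", GLANCE_COLS))) |>
    tidyr::pivot_longer(-"month", names_to = "indicator", values_to = "value")
}

#' Annual KPI row of a run
#'
#' @param x A `cataract_sim`.
#' @param ... Unused.
#' @return A one-row tibble of the annual indicators.
#' @method glance cataract_sim
#' @export
glance.cataract_sim <- function(x, ...) {
  dplyr::select(x$annual, dplyr::all_of(GLANCE_COLS))
}

#' Plot monthly surgeries and finance of a run
#'
#' @param object A `cataract_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cataract_sim
#' @export
autoplot.cataract_sim <- function(object, ...) {
  df <- object$monthly |>
    dplyr::select(dplyr::all_of(c("month", "surgeries", "revenue", "cost", "surplus"))) |>
    tidyr::pivot_longer(-"month", names_to = "indicator", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$month, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~indicator, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = 1:12) +
    ggplot2::labs(
      x = "calendar month", y = NULL,
      title = paste0("Cataract service, scenario '", object$scenario, "'"),
      subtitle = "monthly surgeries and finance (GBP)"
    ) +
    ggplot2::theme_minimal()
}

#' @export
print.scenario_sweep <- function(x, ...) {
  cat("<scenario_sweep: ", dplyr::n_distinct(x$scenario), " scenarios x ",
      dplyr::n_distinct(x$rep), " replications>\n", sep = "")
  print(scenario_summary(x))
  invisible(x)
}

#' Per-scenario means of a sweep, with throughput increments
#'
#' @param x A `scenario_sweep` from [run_scenarios()].
#' @param ... Unused.
#' @return A tibble with one row per scenario: replication means of every
#'   indicator plus `surgeries_increase_pct`, the percentage increase in
#'   annual surgeries over the previous scenario in the sweep.
#' @export
tidy.scenario_sweep <- function(x, ...) {
  scenario_summary(x)
}

#' @rdname tidy.scenario_sweep
#' @export
scenario_summary <- function(x, ...) {
  x |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(GLANCE_COLS), mean), .groups = "drop") |>
    dplyr::mutate(
      surgeries_increase_pct =
        100 * (.data$surgeries / dplyr::lag(.data$surgeries) - 1)
    )
}

#' Plot annual surgeries across a scenario sweep
#'
#' @param object A `scenario_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scenario_sweep
#' @export
autoplot.scenario_sweep <- function(object, ...) {
  summ <- object |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(
      mean = mean(.data$surgeries),
      lo = min(.data$surgeries), hi = max(.data$surgeries),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$scenario, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi), width = 0.15) +
    ggplot2::labs(
      x = NULL, y = "annual surgeries",
      title = "Annual cataract surgeries by patients-per-list scenario",
      subtitle = "bars: replication means; whiskers: replication range"
    ) +
    ggplot2::theme_minimal()
}
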