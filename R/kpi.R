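# The nine performance indicators, monthly and annually: surgeries
# performed, doctor and nurse hours, utilisation of pre-surgery rooms and
# recovery chairs/beds, revenue, cost and surplus — plus diagnostics
# (cancellations, no-shows, mean referral-to-discharge time).
#
# Utilisation denominators use scheduled operating time (08:00-18:00 on
# working days), never the wall-clock year; theatres are excluded from the
# utilisation report because the timetable keeps them fully used during
# their sessions by construction.

# total busy minutes of an interval log within [from, to)
clip_busy <- function(iv, from, to) {
  if (is.null(iv) || nrow(iv) == 0L) return(0)
  sum(pmax(pmin(iv[, 2], to) - pmax(iv[, 1], from), 0))
}

monthly_busy <- function(iv, mw) {
  vapply(seq_len(nrow(mw)), function(m) clip_busy(iv, mw$from[m], mw$to[m]), numeric(1))
}

count_by_month <- function(times, config) {
  times <- times[!is.na(times)]
  m <- month_of(times, config)
  tabulate(m[!is.na(m)], 12L)
}

build_kpi_report <- function(patients, sessions, intervals, config) {
  if (config$weeks_per_year < 52L) {
    stop("the KPI report needs a full 52-week reporting year ",
         "(weeks_per_year = ", config$weeks_per_year, ")", call. = FALSE)
  }
  mw <- month_windows(config)
  mw$op_window <- vapply(seq_len(12L), function(m) {
    weekday_window_minutes(mw$from[m], mw$to[m], config$working_days_per_week)
  }, numeric(1))

  ses <- sessions[!is.na(sessions$month), , drop = FALSE]
  agg <- ses |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(
      surgeries = sum(.data$completed),
      cancellations = sum(.data$cancelled_unfit),
      no_shows = sum(.data$no_show),
      .groups = "drop"
    )
  base <- tibble::tibble(month = 1:12) |>
    dplyr::left_join(agg, by = "month") |>
    dplyr::mutate(dplyr::across(dplyr::everything(), ~ tidyr::replace_na(.x, 0L)))

  doc_min <- monthly_busy(intervals$doctor, mw)
  nur_min <- monthly_busy(intervals$nurse, mw)

  util_of <- function(pool_name, capacity) {
    if (capacity == 0L) return(rep(0, 12L))
    busy <- monthly_busy(intervals[[pool_name]], mw)
    pmin(100, pmax(0, 100 * busy / (capacity * mw$op_window)))
  }

  # activity counts for tariff revenue, by month of the activity
  completed <- patients$status %in% c("completed", "overnight_then_discharged")
  n_first <- count_by_month(patients$t_exam, config)
  n_preop <- count_by_month(patients$t_preop[!is.na(patients$preop_mode) &
                                             patients$preop_mode == "clinic"], config)
  n_fup <- count_by_month(patients$t_discharge[completed], config)

  pence <- function(gbp) round(gbp * 100)
  rev_pence <- base$surgeries * pence(config$tariff_surgery) +
    n_first * pence(config$tariff_first_appointment) +
    n_fup * pence(config$tariff_followup) +
    n_preop * pence(config$tariff_preop_clinic)
  cost_pence <- round(doc_min / 60 * pence(config$hourly_cost_doctor)) +
    round(nur_min / 60 * pence(config$hourly_cost_nurse)) +
    base$surgeries * pence(config$overhead_per_surgery)

  # referral-to-discharge, excluding the synthetic primed backlog
  rtd_pool <- patients[completed & patients$source != "primed" &
                         !is.na(patients$t_discharge), , drop = FALSE]
  rtd_month <- month_of(rtd_pool$t_discharge, config)
  rtd_weeks <- (rtd_pool$t_discharge - rtd_pool$t_referral) / MIN_PER_WEEK
  mean_rtd_m <- vapply(1:12, function(m) {
    v <- rtd_weeks[!is.na(rtd_month) & rtd_month == m]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))

  monthly <- tibble::tibble(
    month = 1:12,
    surgeries = as.integer(base$surgeries),
    doctor_hours = doc_min / 60,
    nurse_hours = nur_min / 60,
    util_presurgery_room = util_of("presurgery_room", config$presurgery_rooms),
    util_recovery_chair = util_of("recovery_chair", config$recovery_chairs),
    util_recovery_bed = util_of("recovery_bed", config$recovery_beds),
    revenue_pence = rev_pence,
    cost_pence = cost_pence,
    surplus_pence = rev_pence - cost_pence,
    revenue = rev_pence / 100,
    cost = cost_pence / 100,
    surplus = (rev_pence - cost_pence) / 100,
    cancellations = as.integer(base$cancellations),
    no_shows = as.integer(base$no_shows),
    mean_referral_to_discharge_weeks = mean_rtd_m
  )

  tot_window <- sum(mw$op_window)
  ann_rev <- sum(rev_pence); ann_cost <- sum(cost_pence)
  util_ann <- function(pool_name, capacity) {
    if (capacity == 0L) return(0)
    busy <- clip_busy(intervals[[pool_name]], mw$from[1], mw$to[12])
    min(100, max(0, 100 * busy / (capacity * tot_window)))
  }
  annual <- tibble::tibble(
    surgeries = sum(monthly$surgeries),
    doctor_hours = sum(doc_min) / 60,
    nurse_hours = sum(nur_min) / 60,
    util_presurgery_room = util_ann("presurgery_room", config$presurgery_rooms),
    util_recovery_chair = util_ann("recovery_chair", config$recovery_chairs),
    util_recovery_bed = util_ann("recovery_bed", config$recovery_beds),
    revenue_pence = ann_rev,
    cost_pence = ann_cost,
    surplus_pence = ann_rev - ann_cost,
    revenue = ann_rev / 100,
    cost = ann_cost / 100,
    surplus = (ann_rev - ann_cost) / 100,
    cancellations = sum(monthly$cancellations),
    no_shows = sum(monthly$no_shows),
    mean_referral_to_discharge_weeks =
      if (length(rtd_weeks) == 0L) NA_real_ else mean(rtd_weeks)
  )

  list(monthly = monthly, annual = annual)
}

#' Monthly KPI report of a simulation run
#'
#' Twelve monthly rows of the performance indicators (surgeries, doctor and
#' nurse hours, resource utilisations in percent, revenue, cost and surplus
#' in GBP, cancellations, no-shows, mean referral-to-discharge time in
#' weeks). The annual row is available via [glance()].
#'
#' @param sim A `cataract_sim` from [simulate_service()].
#' @return A tibble with 12 rows.
#' @export
monthly_report <- function(sim) {
  stopifnot(inherits(sim, "cataract_sim"))
  sim$monthly
}

#' Staff hours spent on simulated activities
#'
#' Total hours a staff role was held by pathway activities (doctors:
#' examinations and surgeries; nurses: pre-operative assessments and
#' day-of-surgery tests) within a time window, by default the reporting
#' year.
#'
#' @param sim A `cataract_sim`.
#' @param role `"doctor"` or `"nurse"`.
#' @param from,to Window bounds in minutes; default the reporting window.
#' @return Hours (numeric scalar).
#' @export
staff_hours <- function(sim, role = c("doctor", "nurse"), from = NULL, to = NULL) {
  stopifnot(inherits(sim, "cataract_sim"))
  role <- match.arg(role)
  if (is.null(from)) from <- sim$window[["from"]]
  if (is.null(to)) to <- sim$window[["to"]]
  clip_busy(sim$intervals[[role]], from, to) / 60
}

#' Mean referral-to-discharge time
#'
#' Arithmetic mean of (discharge time - referral time) over completed
#' patients, in weeks. This is the validation metric used to compare the
#' model with observed service data. Synthetic primed waiting-list patients
#' (whose referral predates the run) are excluded.
#'
#' @param patients A patients tibble from a `cataract_sim`, or the
#'   `cataract_sim` itself.
#' @return Mean weeks from referral to discharge.
#' @export
mean_referral_to_discharge <- function(patients) {
  if (inherits(patients, "cataract_sim")) patients <- patients$patients
  done <- patients[patients$status %in% c("completed", "overnight_then_discharged") &
                     !is.na(patients$t_discharge), , drop = FALSE]
  if ("source" %in% names(done)) {
    done <- done[done$source != "primed", , drop = FALSE]
  }
  if (nrow(done) == 0L) {
    stop("no completed patients to average over", call. = FALSE)
  }
  mean((done$t_discharge - done$t_referral) / MIN_PER_WEEK)
}
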