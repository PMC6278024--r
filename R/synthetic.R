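# Synthetic stand-in parameter set and calibration utilities.
#
# The real service's parameter values are confidential hospital data; this
# module ships a complete, internally consistent stand-in with the
# statistical structure the analysis assumes — a capacity-saturated
# service, four-way examination outcomes, ~20-minute surgeries,
# age-dependent attendance, national-tariff-style prices — so that every
# other module is fully exercisable. Every value here is an ASSUMED
# placeholder, documented in the shipped config file and the vignette.

#' The shipped synthetic parameter set
#'
#' A complete validated configuration of the modelled service. Headline
#' structure:
#' * demand slightly above the largest scenario's effective capacity
#'   (about 9,150 referrals/year, of whom ~85% prove suitable — roughly
#'   7,800 listable patients against 6,240-9,360 planned slots), so the
#'   service is saturated at baseline and demand-limited only in the most
#'   aggressive scenario;
#' * surgery duration centred on 20 minutes;
#' * elderly patients (65% of the population) miss surgery more often than
#'   others (12% vs 5%) and sometimes recover on a bed even after local
#'   anaesthesia;
#' * general anaesthesia is rare (5%) and overnight stays very rare (1% of
#'   bed recoveries);
#' * tariffs and hourly staff costs on the scale of published NHS tariffs
#'   and PSSRU unit costs.
#'
#' @return A validated `service_config`.
#' @examples
#' cfg <- default_parameters()
#' planned_weekly_capacity(cfg)
#' @export
default_parameters <- function() {
  service_config(
    # demand (expected referrals per week)
    referral_rate_optometrist = 150,
    referral_rate_internal = 26,
    # four-way examination outcome
    exam_outcome_probs = c(not_suitable = 0.15, listed_direct = 0.35,
                           preop_clinic = 0.30, preop_phone = 0.20),
    # day-of-surgery behaviour
    p_unfit_on_day = 0.02,
    p_noshow_elderly = 0.12,
    p_noshow_other = 0.05,
    p_elderly = 0.65,
    p_general_anaesthesia = 0.05,
    p_bed_local_elderly = 0.35,
    p_overnight = 0.01,
    p_noshow_rebooked = 0.75,
    unfit_reschedule_delay_weeks = 2,
    # activity durations (minutes)
    durations = list(
      eye_exam = duration_spec("lognormal", mean = 20, sd = 6),
      preop_clinic = duration_spec("lognormal", mean = 30, sd = 8),
      preop_phone = duration_spec("lognormal", mean = 12, sd = 4),
      presurgery_tests = duration_spec("lognormal", mean = 18, sd = 5),
      anaesthesia_local = duration_spec("triangular", min = 4, mode = 8, max = 15),
      anaesthesia_general = duration_spec("lognormal", mean = 25, sd = 6),
      surgery = duration_spec("lognormal", mean = 20, sd = 5),
      recovery_chair = duration_spec("lognormal", mean = 40, sd = 10),
      recovery_bed = duration_spec("lognormal", mean = 90, sd = 20)
    ),
    # capacity: 4 theatres x 5 half-day lists/week x 6 patients/list
    theatres = 4,
    lists_per_theatre_per_week = 5,
    patients_per_list = 6,
    session_minutes = 240,
    working_days_per_week = 5,
    weeks_per_year = 52,
    warmup_weeks = 4,
    booking_lead_days = 7,
    # other resources
    consult_rooms = 3,
    presurgery_rooms = 3,
    recovery_chairs = 3,
    recovery_beds = 2,
    doctors = 3,
    nurses = 3,
    # finance: national-tariff-style prices (GBP per activity) and hourly
    # staff costs (GBP per hour)
    tariff_surgery = 650,
    tariff_first_appointment = 70,
    tariff_followup = 50,
    tariff_preop_clinic = 0,
    hourly_cost_doctor = 140,
    hourly_cost_nurse = 44,
    overhead_per_surgery = 0
  )
}

# expected probability that a booked slot is lost to a no-show or a same-day
# unfit cancellation
expected_slot_loss <- function(config) {
  p_ns <- config$p_elderly * config$p_noshow_elderly +
    (1 - config$p_elderly) * config$p_noshow_other
  p_ns + (1 - p_ns) * config$p_unfit_on_day
}

#' Calibrate the referral rate to a target annual throughput
#'
#' Monotone bisection on a common multiplier of both referral rates until
#' the mean simulated annual number of surgeries is within `tol` of the
#' target. Targets above the service's effective capacity — planned annual
#' slots times the expected fraction of slots not lost to no-shows and
#' same-day cancellations — are reported as capacity-limited rather than
#' chased.
#'
#' @param target_annual_surgeries Target annual completed surgeries.
#' @param config A validated `service_config` (its referral rates are the
#'   starting point that the multiplier scales).
#' @param n_reps Replications per evaluation of the simulator.
#' @param seed Master seed.
#' @param tol Absolute tolerance on the achieved annual surgeries.
#' @param max_iter Maximum bisection iterations.
#' @return A `calibration_result`: a list with the fitted rates, the
#'   achieved value, the target, tolerance, replications used, iterations,
#'   and a `feasible` flag (with `capacity_limit` when infeasible).
#' @export
calibrate_arrival_rate <- function(target_annual_surgeries, config,
                                   n_reps = 2L, seed = 1L, tol = 50,
                                   max_iter = 12L) {
  config <- validate_config(config)
  if (target_annual_surgeries < 0) {
    stop("target must be >= 0", call. = FALSE)
  }
  result <- function(mult, achieved, iters, feasible, capacity_limit = NA_real_) {
    structure(list(
      parameter = "referral rate multiplier",
      multiplier = mult,
      referral_rate_optometrist = config$referral_rate_optometrist * mult,
      referral_rate_internal = config$referral_rate_internal * mult,
      achieved = achieved,
      target = target_annual_surgeries,
      tolerance = tol,
      replications = n_reps,
      iterations = iters,
      feasible = feasible,
      capacity_limit = capacity_limit
    ), class = "calibration_result")
  }
  if (target_annual_surgeries == 0) {
    return(result(0, 0, 0L, TRUE))
  }
  capacity_limit <- planned_weekly_capacity(config) * config$weeks_per_year *
    (1 - expected_slot_loss(config))
  if (target_annual_surgeries > capacity_limit) {
    return(result(NA_real_, NA_real_, 0L, FALSE, capacity_limit = capacity_limit))
  }
  base_rate <- config$referral_rate_optometrist + config$referral_rate_internal
  if (base_rate <= 0) {
    stop("config referral rates are zero; nothing to scale", call. = FALSE)
  }
  seeds <- derive_seeds(seed, n_reps)
  evaluate <- function(mult) {
    cf <- unclass(config)
    cf$referral_rate_optometrist <- cf$referral_rate_optometrist * mult
    cf$referral_rate_internal <- cf$referral_rate_internal * mult
    cf <- validate_config(structure(cf, class = "service_config"))
    mean(vapply(seeds, function(s) {
      simulate_service(cf, seed = s)$annual$surgeries
    }, numeric(1)))
  }
  # initial bracket: listed demand at multiplier m is roughly proportional
  # to m, so scale so the bracket top comfortably exceeds the target
  p_listed <- 1 - config$exam_outcome_probs[["not_suitable"]]
  annual_completable <- base_rate * config$weeks_per_year * p_listed *
    (1 - expected_slot_loss(config))
  hi <- max(1, 2 * target_annual_surgeries / annual_completable)
  lo <- 0; f_lo <- 0
  f_hi <- evaluate(hi)
  tries <- 0L
  while (f_hi < target_annual_surgeries && tries < 4L) {
    lo <- hi; f_lo <- f_hi
    hi <- hi * 2
    f_hi <- evaluate(hi)
    tries <- tries + 1L
  }
  if (f_hi < target_annual_surgeries - tol) {
    stop("calibration bracket [", lo, ", ", hi, "] cannot reach target ",
         target_annual_surgeries, " (achieved ", round(f_hi, 1),
         "); the service appears capacity-limited", call. = FALSE)
  }
  iters <- 0L
  mid <- hi; f_mid <- f_hi
  while (iters < max_iter && abs(f_mid - target_annual_surgeries) > tol) {
    mid <- (lo + hi) / 2
    f_mid <- evaluate(mid)
    if (f_mid < target_annual_surgeries) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid; f_hi <- f_mid
    }
    iters <- iters + 1L
  }
  if (abs(f_mid - target_annual_surgeries) > tol) {
    stop("calibration did not converge after ", max_iter,
         " iterations; bracket [", lo, ", ", hi, "], achieved ",
         round(f_mid, 1), " vs target ", target_annual_surgeries, call. = FALSE)
  }
  result(mid, f_mid, iters, TRUE)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  if (!x$feasible) {
    cat("  INFEASIBLE: target ", x$target, " exceeds effective capacity ",
        round(x$capacity_limit, 1), " surgeries/year\n", sep = "")
  } else {
    cat("  multiplier ", signif(x$multiplier, 4), " -> rates ",
        signif(x$referral_rate_optometrist, 4), " + ",
        signif(x$referral_rate_internal, 4), " per week\n", sep = "")
    cat("  achieved ", round(x$achieved, 1), " vs target ", x$target,
        " (tol ", x$tolerance, ", ", x$iterations, " iterations, ",
        x$replications, " reps)\n", sep = "")
  }
  invisible(x)
}

#' Split an annual referral total into monthly counts
#'
#' Multinomial split of an annual total across 12 months with mild
#' seasonality weights (a +/-6% sinusoid peaking in early summer by
#' default); the counts always sum exactly to the annual total. This is a
#' stand-in demand series generator — it emulates the shape of a forecast
#' demand profile, not a fit to any real activity data.
#'
#' @param annual_total Annual number of referrals (>= 0).
#' @param months Number of periods (default 12).
#' @param seed Seed for the multinomial draw.
#' @param weights Optional positive weights, length `months`; default mild
#'   seasonality.
#' @return An integer vector of length `months` summing to `annual_total`.
#' @export
generate_demand_series <- function(annual_total, months = 12L, seed = 1L,
                                   weights = NULL) {
  if (!is.numeric(annual_total) || annual_total < 0 ||
      annual_total != round(annual_total)) {
    stop("annual_total must be a non-negative integer", call. = FALSE)
  }
  months <- as.integer(months)
  if (is.null(weights)) {
    weights <- 1 + 0.06 * sin(2 * pi * (seq_len(months) - 2) / months)
  }
  if (length(weights) != months || any(weights <= 0)) {
    stop("weights must be ", months, " positive numbers", call. = FALSE)
  }
  if (annual_total == 0) return(integer(months))
  stream <- rng_stream(derive_seeds(seed, 1L))
  # sequential binomial decomposition of the multinomial via inverse CDF,
  # so the split is reproducible from a uniform stream
  remaining <- as.integer(annual_total)
  wleft <- sum(weights)
  out <- integer(months)
  for (m in seq_len(months - 1L)) {
    p <- weights[m] / wleft
    out[m] <- as.integer(stats::qbinom(stream$draw(1L), remaining, p))
    remaining <- remaining - out[m]
    wleft <- wleft - weights[m]
  }
  out[months] <- remaining
  out
}
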