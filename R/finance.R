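# Tariff-based finance. Revenue follows the national-tariff model: a fixed
# reimbursement per activity (surgery, first outpatient appointment,
# follow-up, pre-operative clinic assessment). Cost is staff-hours times
# hourly rates plus an optional per-surgery overhead. All arithmetic is
# integer pence internally so that monthly surpluses sum to the annual
# surplus with zero rounding drift.

REVENUE_ACTIVITIES <- c("surgery", "first_appointment", "followup", "preop_clinic")

tariff_pence <- function(config) {
  c(surgery = round(config$tariff_surgery * 100),
    first_appointment = round(config$tariff_first_appointment * 100),
    followup = round(config$tariff_followup * 100),
    preop_clinic = round(config$tariff_preop_clinic * 100))
}

#' Tariff revenue for a basket of activities
#'
#' Sum over activity types of count x national tariff. Activities are
#' `"surgery"`, `"first_appointment"`, `"followup"` and `"preop_clinic"`.
#'
#' @param counts A tibble/data frame with columns `activity` and `n`, or a
#'   named numeric vector of counts.
#' @param config A validated `service_config` holding the tariffs.
#' @return Revenue in GBP.
#' @examples
#' cfg <- default_parameters()
#' revenue(c(surgery = 10), cfg)
#' @export
revenue <- function(counts, config) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("activity", "n") %in% names(counts)))
    counts <- stats::setNames(counts$n, counts$activity)
  }
  if (is.null(names(counts)) || !all(nzchar(names(counts)))) {
    stop("activity counts must be named", call. = FALSE)
  }
  bad <- setdiff(names(counts), REVENUE_ACTIVITIES)
  if (length(bad) > 0L) {
    stop("no configured tariff for activity: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0)) stop("activity counts must be >= 0", call. = FALSE)
  tp <- tariff_pence(config)
  sum(counts * tp[names(counts)]) / 100
}

#' Staff cost of simulated activity
#'
#' `doctor_hours x hourly doctor cost + nurse_hours x hourly nurse cost`,
#' in GBP.
#'
#' @param doctor_hours,nurse_hours Hours worked (>= 0).
#' @param config A validated `service_config` holding the hourly rates.
#' @return Cost in GBP.
#' @export
cost <- function(doctor_hours, nurse_hours, config) {
  if (doctor_hours < 0 || nurse_hours < 0) {
    stop("staff hours must be >= 0", call. = FALSE)
  }
  (round(doctor_hours * config$hourly_cost_doctor * 100) +
     round(nurse_hours * config$hourly_cost_nurse * 100)) / 100
}

#' Financial surplus
#'
#' Revenue minus cost; may be negative.
#'
#' @param revenue,cost Amounts in GBP.
#' @return Surplus in GBP.
#' @export
surplus <- function(revenue, cost) {
  (round(revenue * 100) - round(cost * 100)) / 100
}
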