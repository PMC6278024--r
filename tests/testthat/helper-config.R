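# Small configurations used across the tests.
#
# `tiny_config()` is a deliberately small deterministic service — one
# theatre, constant activity durations, every behavioural probability zero
# unless overridden — so that queueing arithmetic can be checked by hand.
# Tests override single fields through `...`.

constant_durations <- function() {
  list(
    eye_exam = duration_spec("constant", value = 30),
    preop_clinic = duration_spec("constant", value = 30),
    preop_phone = duration_spec("constant", value = 10),
    presurgery_tests = duration_spec("constant", value = 15),
    anaesthesia_local = duration_spec("constant", value = 5),
    anaesthesia_general = duration_spec("constant", value = 20),
    surgery = duration_spec("constant", value = 20),
    recovery_chair = duration_spec("constant", value = 30),
    recovery_bed = duration_spec("constant", value = 60)
  )
}

tiny_config <- function(...) {
  overrides <- list(...)
  base <- list(
    referral_rate_optometrist = 25,
    referral_rate_internal = 0,
    exam_outcome_probs = c(not_suitable = 0, listed_direct = 1,
                           preop_clinic = 0, preop_phone = 0),
    p_unfit_on_day = 0,
    p_noshow_elderly = 0,
    p_noshow_other = 0,
    p_elderly = 0,
    p_general_anaesthesia = 0,
    p_bed_local_elderly = 0,
    p_overnight = 0,
    p_noshow_rebooked = 0,
    unfit_reschedule_delay_weeks = 2,
    durations = constant_durations(),
    theatres = 1,
    lists_per_theatre_per_week = 3,
    patients_per_list = 6,
    session_minutes = 240,
    working_days_per_week = 5,
    weeks_per_year = 52,
    warmup_weeks = 2,
    booking_lead_days = 7,
    consult_rooms = 2,
    presurgery_rooms = 2,
    recovery_chairs = 2,
    recovery_beds = 1,
    doctors = 2,
    nurses = 2,
    tariff_surgery = 650,
    tariff_first_appointment = 70,
    tariff_followup = 50,
    tariff_preop_clinic = 0,
    hourly_cost_doctor = 140,
    hourly_cost_nurse = 44,
    overhead_per_surgery = 0
  )
  base[names(overrides)] <- overrides
  do.call(service_config, base)
}

# final-status bookkeeping used by flow-conservation checks
status_groups <- function(patients) {
  referred <- patients[patients$source != "primed", , drop = FALSE]
  list(
    referred = nrow(referred),
    not_suitable = sum(referred$status == "not_suitable"),
    completed = sum(referred$status %in% c("completed", "overnight_then_discharged")),
    lost = sum(referred$status == "no_show"),
    in_system = sum(referred$status %in%
                      c("in_pathway", "cancelled_unfit", "no_show_rebooking"))
  )
}
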