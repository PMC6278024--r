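# Synthetic stand-in parameter set for the cataract service simulation.
#
# The real service's parameter list is confidential hospital data, so every
# value below is ASSUMED: chosen to give a plausible mid-sized NHS hospital
# service that is saturated at baseline (demand slightly above what the
# theatre timetable can deliver) and demand-limited only under the most
# aggressive patients-per-list scenario. Values identical to
# cataractsim::default_parameters().

# --- demand (expected referrals per week; ASSUMED, Poisson arrivals) ---
referral_rate_optometrist: 150.0
referral_rate_internal: 26.0        # e.g. referrals from Diabetes services

# --- four-way examination outcome (ASSUMED; must sum to 1) ---
exam_outcome_probs:
  not_suitable: 0.15
  listed_direct: 0.35
  preop_clinic: 0.30
  preop_phone: 0.20

# --- day-of-surgery behaviour (ASSUMED) ---
p_unfit_on_day: 0.02        # same-day cancellation at the pre-surgery check
p_noshow_elderly: 0.12      # elderly patients miss surgery more often
p_noshow_other: 0.05
p_elderly: 0.65             # fraction of patients in the elderly age band
p_general_anaesthesia: 0.05
p_bed_local_elderly: 0.35   # elderly local-anaesthesia patients on a bed
p_overnight: 0.01           # overnight observation after bed recovery
p_noshow_rebooked: 0.75     # no-shows that rejoin the waiting list
unfit_reschedule_delay_weeks: 2.0

# --- activity durations, minutes (families ASSUMED; surgery ~20 min) ---
durations:
  eye_exam: {family: lognormal, mean: 20.0, sd: 6.0}
  preop_clinic: {family: lognormal, mean: 30.0, sd: 8.0}
  preop_phone: {family: lognormal, mean: 12.0, sd: 4.0}
  presurgery_tests: {family: lognormal, mean: 18.0, sd: 5.0}
  anaesthesia_local: {family: triangular, min: 4.0, mode: 8.0, max: 15.0}
  anaesthesia_general: {family: lognormal, mean: 25.0, sd: 6.0}
  surgery: {family: lognormal, mean: 20.0, sd: 5.0}
  recovery_chair: {family: lognormal, mean: 40.0, sd: 10.0}
  recovery_bed: {family: lognormal, mean: 90.0, sd: 20.0}

# --- theatre capacity (ASSUMED arrangement: 20 half-day lists/week) ---
theatres: 4
lists_per_theatre_per_week: 5
patients_per_list: 6        # the baseline scenario value
session_minutes: 240.0      # a list is half a day
working_days_per_week: 5
weeks_per_year: 52
warmup_weeks: 4             # excluded from all statistics
booking_lead_days: 7.0      # elective surgeries are planned in advance

# --- other resources (ASSUMED counts) ---
consult_rooms: 3
presurgery_rooms: 3
recovery_chairs: 3
recovery_beds: 2
doctors: 3
nurses: 3

# --- finance: tariff-style prices, GBP per activity (ASSUMED) ---
tariff_surgery: 650.0
tariff_first_appointment: 70.0
tariff_followup: 50.0
tariff_preop_clinic: 0.0
hourly_cost_doctor: 140.0   # GBP per hour, including overheads
hourly_cost_nurse: 44.0
overhead_per_surgery: 0.0   # optional non-staff cost per surgery
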