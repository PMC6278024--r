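---
title: "Modelling a hospital cataract service as a discrete event simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a hospital cataract service as a discrete event simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cataractsim)
```

## The service being modelled

Cataract surgery is the highest-volume elective procedure in the NHS, and
many hospital ophthalmology units run at full theatre capacity with long
waiting lists. `cataractsim` models one such unit as a process-oriented
discrete event simulation (DES): patients are individual entities with
attributes (age band, referral source, anaesthesia type), and everything
that happens to them — examination, listing, booking, surgery, recovery —
is an event competing for finite resources.

The pathway is:

1. **Referral**, from community optometrists or from other hospital
   services (e.g. Diabetes clinics). Both streams are Poisson over working
   days; internal referrals are handled identically downstream.
2. **Eye examination** by a doctor in a consultation room, with four
   possible outcomes: not suitable for surgery; listed directly; listed
   after a pre-operative clinic assessment (nurse + pre-surgery room); or
   listed after a pre-operative phone assessment (nurse only).
3. **Waiting list**, first-come-first-served by listing time. Theatre
   sessions are half-day lists with a fixed number of booked patients
   (`patients_per_list`); each session is filled FIFO from patients listed
   at least `booking_lead_days` before it starts.
4. **Day of surgery.** A booked patient may fail to attend (no-show, with
   an age-dependent probability) or be found unfit during the nurse-led
   pre-surgery tests (same-day cancellation). Because these are elective
   slots planned in advance, **a vacated slot is lost** — it cannot be
   refilled on the day. This lost-slot rule is the central mechanism of
   the model. Attending, fit patients receive local (usual) or general
   (rare) anaesthesia and a ~20-minute surgery by a doctor in the theatre.
5. **Recovery and discharge.** Local-anaesthesia patients recover on a
   chair; general-anaesthesia patients on a bed; elderly local-anaesthesia
   patients sometimes on a bed too. Almost everyone is discharged the same
   day; a small fraction of bed patients stay overnight, keeping the bed
   until 08:00. A community follow-up appointment is counted for revenue
   but consumes no modelled hospital resource.

Cancelled-unfit patients rejoin the list after a configurable delay;
no-shows rejoin with probability `p_noshow_rebooked`, otherwise they leave
the service.

## The what-if question

The service cannot obtain more theatre sessions, but process changes
(earlier admission for pre-surgery tests, rapid 3D biometry, earlier lens
preparation) allow more surgeries per half-day list. The shipped sweep
compares four configurations: the baseline with 6 patients per list and
three alternatives with 7, 8 and 9, each paired with duration multipliers
on the activities those process changes shorten (`default_scenarios()`).
The multiplier values (pre-surgery tests ×0.85 and ×0.6, surgery ×0.9) are
modelling assumptions — the redesigns are qualitative, and the factors are
chosen so a list's expected workload still fits a session.

Because every booked patient no-shows or is cancelled with positive
probability and each such slot is lost, raising `patients_per_list` buys
less than proportional throughput; once effective demand is exhausted, the
marginal scenario adds almost nothing. The sweep therefore shows annual
surgeries rising from baseline to scenario 3 with strictly shrinking
percentage increments — the saturation signature that the test suite and
the acceptance script verify.

## Parameters

All parameters live in a flat `service_config` (YAML on disk; an annotated
example ships in `inst/extdata/default_config.yaml`). The important ones:

| parameter | unit | default | why |
|---|---|---|---|
| `referral_rate_optometrist` / `_internal` | patients/week | 150 / 26 | listable demand (~7,800/yr) sits between baseline effective capacity and scenario-3 planned capacity, so the service is saturated at baseline and demand-limited only in the most aggressive scenario |
| `exam_outcome_probs` | probabilities | .15/.35/.30/.20 | four-way examination outcome; must sum to 1 |
| `p_noshow_elderly` / `p_noshow_other` | probability | 0.12 / 0.05 | elderly patients, the dominant cataract population (`p_elderly` = 0.65), miss surgery more often |
| `p_unfit_on_day` | probability | 0.02 | same-day cancellation at the pre-surgery check |
| `durations$surgery` | minutes | lognormal(20, 5) | cataract surgery takes about 20 minutes |
| `theatres` × `lists_per_theatre_per_week` × `patients_per_list` | counts | 4 × 5 × 6 | 120 planned surgeries/week (~6,240/yr) at baseline |
| `session_minutes` | minutes | 240 | a list is half a day |
| `tariff_*`, `hourly_cost_*` | GBP | 650/70/50; 140/44 | national-tariff-style reimbursements per activity and PSSRU-style hourly staff costs |
| `warmup_weeks` | weeks | 4 | excluded from all statistics |

Every default is an assumption standing in for confidential hospital data,
and is flagged `ASSUMED` in the shipped file. The theatre arrangement in
particular (4 theatres × 5 half-day lists) is not published anywhere; only
its product matters to weekly capacity.

## Engine and numerical choices

* **Time** is minutes from midnight on the Monday of week 1. The run is
  `warmup_weeks` plus a 52-week reporting year; reporting maps onto the
  calendar months of a non-leap year starting 1 January, with December
  truncated at day 364. A session belongs to the month of its start.
* **Events** sit in a binary min-heap keyed by time with a stable
  insertion counter, so simultaneous events fire in the order they were
  scheduled — this makes runs bit-reproducible. Scheduling into the past
  is an error.
* **Resources** are FIFO pools; a unit freed by one patient is handed to
  the queue head at the same instant. Paired acquisitions (room + staff)
  acquire the room first and hold it while waiting for staff. Every busy
  interval is logged, which is what utilisation and staff-hours
  accounting integrate over.
* **Randomness** comes from four independent uniform streams (arrivals,
  outcomes, durations, attendance), each seeded from the master seed, with
  all distributions sampled by inverse CDF. Changing a duration parameter
  therefore never perturbs the arrival pattern, and the scenario sweep
  reuses the same replication seeds across scenarios (common random
  numbers), sharpening the contrasts.
* **Durations** support constant, lognormal (parameterised by
  natural-scale mean and sd), triangular and exponential families; no
  distribution family for any activity is published, so the choices are
  configuration, not code. Draws below 0.1 minutes are floored there.
* **Sessions** are spread Monday-Friday, alternating 08:00 and 13:00
  starts; booked patients get appointment times staggered by
  `session_minutes / patients_per_list`. A session never cuts a patient
  off: overruns finish their work, so in a degenerate lossless
  configuration annual completed surgeries equal planned capacity exactly.
* **Money** is integer pence internally; monthly surpluses sum to the
  annual surplus with zero rounding drift.
* **Warm-up**: the waiting list is primed at t = 0 with
  `warmup_weeks × planned weekly capacity` synthetic patients so the
  service starts saturated rather than empty. Primed patients are excluded
  from the referral-to-discharge metric (their referral predates the run)
  and warm-up activity is excluded from every KPI.
* **Utilisation denominators** are scheduled operating time — 08:00-18:00
  on working days — not the wall-clock year; theatres are excluded from
  the utilisation report because the timetable occupies them fully during
  sessions by construction.

Degenerate inputs are handled explicitly: zero referral rates give an
empty, all-zero report; zero-capacity pools report 0% utilisation; a
probability of 0 or 1 routes every patient one way (the tests exercise
each such corner).

## Open design choices

Where the service description is silent, the package fixes a choice and
documents it here:

* **Booking lead time** defaults to 7 days ("planned in advance" without a
  number). Sessions whose cutoff predates the run start book from the
  primed list at t = 0.
* **No-show rebooking timing** reuses `unfit_reschedule_delay_weeks`
  (default 2 weeks); nothing is published about what happens to these
  patients afterwards, so the probability and delay are both
  configuration.
* **Overnight stays** are drawn only for patients already recovering on a
  bed, since the stay consists of holding that bed until morning.
* **Anaesthesia** occupies the patient but no modelled staff resource
  (anaesthetists are not one of the costed roles); general anaesthesia
  additionally forces bed recovery.
* **Follow-up appointments** are revenue-bearing but zero-resource
  (community/outpatient), so they add no doctor hours. Doctor hours
  therefore cover examinations and surgeries; nurse hours cover
  pre-operative assessments and day-of-surgery tests.

## What the synthetic generator does and does not emulate

`default_parameters()` reproduces the *structure* the analysis needs:
capacity-saturated Poisson demand, the four-way examination split,
age-dependent attendance, ~20-minute surgeries, tariff-style finance. It
does **not** reproduce any real hospital's numbers: no fit to Hospital
Episodes Statistics, no seasonality in referrals (a separate
`generate_demand_series()` utility exists for shaping monthly totals), no
gender effects, no surgical complications (about 1% in practice, not a
modelled branch), no patient-satisfaction measures. Passing tests
demonstrate the mechanics and their consequences — capacity identities,
binomial loss rates, the saturation signature — not agreement with any
particular hospital's operational data, which would require that
hospital's parameter values.

`calibrate_arrival_rate()` closes part of that gap: given a target annual
throughput it bisects on a common referral-rate multiplier (the simulated
throughput is monotone in demand) until the replication mean lands within
an absolute tolerance, and reports targets above the effective capacity
bound — planned slots × (1 − expected slot loss) — as capacity-limited
rather than chasing them.

## Problem sizes

The shipped configuration simulates roughly 9,900 referrals and 1,120
half-day sessions per run (4 warm-up + 52 reporting weeks), about 60,000
events, in a few seconds. The scenario sweep used by the acceptance
script and the test suite runs 4 scenarios × 30 replications; unit tests
use much smaller one-theatre services with constant durations so that
queueing arithmetic can be checked by hand.

## Limitations

* The replication interval in `replicate_and_summarise()` is a plain
  t-interval over independent replications; no variance-reduction beyond
  common random numbers across scenarios.
* Slot losses depend only on patient attributes, not on list position or
  calendar effects, so the diminishing-returns curve is driven by the
  per-slot loss probability and demand saturation alone. Mechanisms that
  would make the marginal slot *itself* likelier to fail (session-end
  pressure, staff fatigue) are not modelled, and the shipped sweep's
  increments shrink more gently than a service with such effects would
  show.
* Intervals still open at the horizon (e.g. an overnight bed on the final
  night) are not counted in busy time; the effect is negligible at a
  52-week horizon.
* One surgeon pool serves examinations and surgeries; there is no rota or
  individual-clinician modelling.
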