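# One full simulation run: referral -> examination -> (four outcomes) ->
# listing -> theatre session booking -> day of surgery (no-show / unfit /
# surgery) -> recovery -> discharge, with the lost-slot rule for same-day
# cancellations and no-shows of elective lists.
#
# All mutable run state (patient attribute vectors, waiting list, session
# tallies) lives as locals of `simulate_service`, and every event closure
# mutates it with `<<-`; this keeps updates in place and the run fast.

PATIENT_STATUS <- c(
  "in_pathway",                  # 0 waiting somewhere in the pathway
  "not_suitable",                # 1 examined, not suitable for surgery
  "completed",                   # 2 operated and discharged same day
  "cancelled_unfit",             # 3 same-day cancellation, awaiting relisting
  "no_show",                     # 4 missed surgery, left the service
  "overnight_then_discharged",   # 5 operated, kept overnight
  "no_show_rebooking"            # 6 missed surgery, awaiting relisting
)

#' Simulate the cataract service for one year
#'
#' Runs the full discrete event simulation: warm-up weeks plus a 52-week
#' reporting year. The waiting list is primed at the start with
#' `warmup_weeks` x planned weekly capacity patients so the service starts
#' saturated (the shipped parameters describe a service running at full
#' capacity), and everything that happens during warm-up is excluded from
#' the KPI report.
#'
#' @param config A validated `service_config` (see [default_parameters()]).
#' @param scenario Optional [scenario_spec()] applied to `config` first.
#' @param seed Master seed; the same config and seed give a bit-identical
#'   run.
#' @param trace If `TRUE`, keep a per-event log (time, patient, event,
#'   resource) in the result — slower and memory-hungry, intended for
#'   debugging and verification on small configurations.
#' @param arrivals Optional tibble of referrals (`time`, `source`,
#'   `elderly`) to use instead of sampling them; used for hand-traceable
#'   verification runs.
#' @param verbose If `TRUE`, log one line per phase to standard error.
#' @return A `cataract_sim` object: a list with tibbles `patients`,
#'   `sessions`, `monthly`, `annual`, `resources`, the `config`, and the
#'   event `trace` (or `NULL`). Use [glance()] for the annual KPI row,
#'   [tidy()] for monthly indicators in long form, and [autoplot()] to
#'   plot.
#' @examples
#' \donttest{
#' cfg <- default_parameters()
#' run <- simulate_service(cfg, scenario = default_scenarios()$baseline, seed = 1)
#' glance(run)
#' }
#' @export
simulate_service <- function(config, scenario = NULL, seed = 1L, trace = FALSE,
                             arrivals = NULL, verbose = FALSE) {
  config <- validate_config(config)
  scen_name <- "as-configured"
  if (!is.null(scenario)) {
    config <- apply_scenario(config, scenario)
    scen_name <- scenario$name
  }
  log_phase <- function(...) if (verbose) message("[cataractsim] ", ...)

  horizon <- run_horizon(config)
  st <- rng_streams(seed)
  cal <- event_calendar()
  sched <- cal$schedule
  clock_now <- cal$now
  log_phase("configured scenario '", scen_name, "', horizon ", horizon, " min")

  # --- resources ----------------------------------------------------------
  p_consult <- resource_pool("consult_room", config$consult_rooms)
  p_room    <- resource_pool("presurgery_room", config$presurgery_rooms)
  p_chair   <- resource_pool("recovery_chair", config$recovery_chairs)
  p_bed     <- resource_pool("recovery_bed", config$recovery_beds)
  p_doctor  <- resource_pool("doctor", config$doctors)
  p_nurse   <- resource_pool("nurse", config$nurses)
  theatre_pools <- lapply(seq_len(config$theatres),
                          function(i) resource_pool(paste0("theatre_", i), 1L))
  room_req <- p_room$request; room_rel <- p_room$release
  nurse_req <- p_nurse$request; nurse_rel <- p_nurse$release
  doctor_req <- p_doctor$request; doctor_rel <- p_doctor$release

  # --- timetable and arrivals --------------------------------------------
  tt <- build_timetable(config)
  n_ses <- nrow(tt)
  tt_theatre <- tt$theatre
  tt_start <- tt$start
  tt_cap <- tt$capacity
  log_phase("timetable built: ", n_ses, " sessions")

  n_prime <- config$warmup_weeks * planned_weekly_capacity(config)
  prime_elderly <- if (n_prime > 0L) st$arrivals$draw(n_prime) < config$p_elderly else logical(0)
  if (is.null(arrivals)) {
    arrivals <- generate_referrals(config, horizon, st$arrivals)
  } else {
    stopifnot(all(c("time", "source", "elderly") %in% names(arrivals)))
    arrivals <- dplyr::arrange(tibble::as_tibble(arrivals), .data$time)
  }
  n_arr <- nrow(arrivals)
  n_pat <- n_prime + n_arr
  log_phase("arrivals: ", n_arr, " referrals + ", n_prime, " primed waiting-list patients")

  # --- patient state (columnar, mutated in place via <<-) -----------------
  elderly  <- c(prime_elderly, arrivals$elderly)
  source_i <- c(rep(3L, n_prime), ifelse(arrivals$source == "internal", 2L, 1L))
  status   <- integer(n_pat)          # codes of PATIENT_STATUS (0-based)
  outcome  <- integer(n_pat)          # 0 unset, 1..4 = EXAM_OUTCOMES
  preop    <- integer(n_pat)          # 0 none, 1 clinic, 2 phone
  anaes    <- integer(n_pat)          # 0 unset, 1 local, 2 general
  recov    <- integer(n_pat)          # 0 unset, 1 chair, 2 bed
  p_session <- rep(NA_integer_, n_pat)
  t_ref    <- c(rep(0, n_prime), arrivals$time)
  t_exam   <- rep(NA_real_, n_pat)
  t_preop  <- rep(NA_real_, n_pat)
  t_listed <- rep(NA_real_, n_pat)
  t_booked <- rep(NA_real_, n_pat)
  t_surg   <- rep(NA_real_, n_pat)
  t_disch  <- rep(NA_real_, n_pat)

  # per-session slot tallies
  s_booked <- integer(n_ses); s_comp <- integer(n_ses)
  s_ns <- integer(n_ses); s_unfit <- integer(n_ses)

  # --- waiting list (FIFO by listing time) --------------------------------
  wl_cap <- n_pat + n_ses * config$patients_per_list + 16L
  wl_ids <- integer(wl_cap); wl_t <- numeric(wl_cap)
  wl_head <- 0L; wl_tail <- 0L
  wl_push <- function(id, t) {
    wl_tail <<- wl_tail + 1L
    wl_ids[wl_tail] <<- id; wl_t[wl_tail] <<- t
  }
  wl_pop <- function(cutoff) {
    if (wl_head >= wl_tail) return(NA_integer_)
    if (wl_t[wl_head + 1L] > cutoff) return(NA_integer_)
    wl_head <<- wl_head + 1L
    wl_ids[wl_head]
  }

  # --- trace --------------------------------------------------------------
  tr_on <- isTRUE(trace)
  tr_n <- 0L
  tr_t <- numeric(1024L); tr_p <- integer(1024L)
  tr_e <- character(1024L); tr_r <- character(1024L)
  rec <- function(t, id, ev, res) {
    tr_n <<- tr_n + 1L
    if (tr_n > length(tr_t)) {
      tr_t <<- c(tr_t, numeric(length(tr_t))); tr_p <<- c(tr_p, integer(length(tr_p)))
      tr_e <<- c(tr_e, character(length(tr_e))); tr_r <<- c(tr_r, character(length(tr_r)))
    }
    tr_t[tr_n] <<- t; tr_p[tr_n] <<- id; tr_e[tr_n] <<- ev; tr_r[tr_n] <<- res
  }

  # --- hoisted parameters -------------------------------------------------
  D <- config$durations
  cum_outcome <- cumsum(config$exam_outcome_probs)[1:3]
  p_ns_e <- config$p_noshow_elderly; p_ns_o <- config$p_noshow_other
  p_unfit <- config$p_unfit_on_day; p_rebook <- config$p_noshow_rebooked
  p_ga <- config$p_general_anaesthesia; p_bed_le <- config$p_bed_local_elderly
  p_over <- config$p_overnight
  relist_delay <- config$unfit_reschedule_delay_weeks * MIN_PER_WEEK
  lead_min <- config$booking_lead_days * MIN_PER_DAY
  spacing <- config$session_minutes / config$patients_per_list
  du <- st$durations$draw; ou <- st$outcomes$draw; au <- st$attendance$draw
  sdur <- function(spec) sample_duration_u(spec, du(1L))
  next_morning <- function(t) (floor(t / MIN_PER_DAY) + 1) * MIN_PER_DAY + DAY_OPEN

  # --- pathway processes --------------------------------------------------
  list_patient <- function(id, t) {
    t_listed[id] <<- t
    status[id] <<- 0L
    wl_push(id, t)
    if (tr_on) rec(t, id, "listed", NA_character_)
  }

  relist <- function(id) {
    tnow <- clock_now()
    t_listed[id] <<- tnow
    status[id] <<- 0L
    wl_push(id, tnow)
    if (tr_on) rec(tnow, id, "relisted", NA_character_)
  }

  preop_clinic_step <- function(id, t) {
    preop[id] <<- 1L
    room_req(t, function(t_r) {
      nurse_req(t_r, function(t_n) {
        if (tr_on) rec(t_n, id, "preop_clinic_start", "presurgery_room+nurse")
        te <- t_n + sdur(D$preop_clinic)
        sched(te, function() {
          nurse_rel(te, t_n)
          room_rel(te, t_r)
          t_preop[id] <<- te
          if (tr_on) rec(te, id, "preop_clinic_end", NA_character_)
          list_patient(id, te)
        })
      })
    })
  }

  preop_phone_step <- function(id, t) {
    preop[id] <<- 2L
    nurse_req(t, function(t_n) {
      if (tr_on) rec(t_n, id, "preop_phone_start", "nurse")
      te <- t_n + sdur(D$preop_phone)
      sched(te, function() {
        nurse_rel(te, t_n)
        t_preop[id] <<- te
        if (tr_on) rec(te, id, "preop_phone_end", NA_character_)
        list_patient(id, te)
      })
    })
  }

  refer <- function(id, t) {
    if (tr_on) rec(t, id, "referral", NA_character_)
    p_consult$request(t, function(t_room) {
      doctor_req(t_room, function(t_doc) {
        if (tr_on) rec(t_doc, id, "exam_start", "consult_room+doctor")
        te <- t_doc + sdur(D$eye_exam)
        sched(te, function() {
          doctor_rel(te, t_doc)
          p_consult$release(te, t_room)
          t_exam[id] <<- te
          k <- findInterval(ou(1L), cum_outcome) + 1L
          outcome[id] <<- k
          if (tr_on) rec(te, id, paste0("outcome_", EXAM_OUTCOMES[k]), NA_character_)
          if (k == 1L) {
            status[id] <<- 1L
          } else if (k == 2L) {
            list_patient(id, te)
          } else if (k == 3L) {
            preop_clinic_step(id, te)
          } else {
            preop_phone_step(id, te)
          }
        })
      })
    })
  }

  recover_step <- function(id, t) {
    use_bed <- if (anaes[id] == 2L) TRUE
               else if (elderly[id]) ou(1L) < p_bed_le
               else FALSE
    recov[id] <<- if (use_bed) 2L else 1L
    pool <- if (use_bed) p_bed else p_chair
    pool$request(t, function(t_g) {
      if (tr_on) rec(t_g, id, "recovery_start", if (use_bed) "recovery_bed" else "recovery_chair")
      te <- t_g + sdur(if (use_bed) D$recovery_bed else D$recovery_chair)
      sched(te, function() {
        if (use_bed && ou(1L) < p_over) {
          status[id] <<- 5L
          tm <- next_morning(te)
          sched(tm, function() {
            pool$release(tm, t_g)
            t_disch[id] <<- tm
            if (tr_on) rec(tm, id, "discharge_overnight", NA_character_)
          })
        } else {
          pool$release(te, t_g)
          t_disch[id] <<- te
          if (tr_on) rec(te, id, "discharge", NA_character_)
        }
      })
    })
  }

  enter_theatre <- function(id, s, t) {
    thp <- theatre_pools[[tt_theatre[s]]]
    thp$request(t, function(t_th) {
      doctor_req(t_th, function(t_d) {
        if (tr_on) rec(t_d, id, "surgery_start", "theatre+doctor")
        te <- t_d + sdur(D$surgery)
        sched(te, function() {
          doctor_rel(te, t_d)
          thp$release(te, t_th)
          t_surg[id] <<- te
          s_comp[s] <<- s_comp[s] + 1L
          status[id] <<- 2L
          if (tr_on) rec(te, id, "surgery_end", NA_character_)
          recover_step(id, te)
        })
      })
    })
  }

  attend <- function(id, s, t) {
    if (tr_on) rec(t, id, "arrive_session", NA_character_)
    if (au(1L) < (if (elderly[id]) p_ns_e else p_ns_o)) {
      s_ns[s] <<- s_ns[s] + 1L
      if (tr_on) rec(t, id, "no_show", NA_character_)
      if (au(1L) < p_rebook) {
        status[id] <<- 6L
        sched(t + relist_delay, function() relist(id))
      } else {
        status[id] <<- 4L
      }
      return(invisible(NULL))
    }
    room_req(t, function(t_r) {
      nurse_req(t_r, function(t_n) {
        if (tr_on) rec(t_n, id, "presurgery_tests_start", "presurgery_room+nurse")
        te <- t_n + sdur(D$presurgery_tests)
        sched(te, function() {
          nurse_rel(te, t_n)
          room_rel(te, t_r)
          if (au(1L) < p_unfit) {
            s_unfit[s] <<- s_unfit[s] + 1L
            status[id] <<- 3L
            if (tr_on) rec(te, id, "cancelled_unfit", NA_character_)
            sched(te + relist_delay, function() relist(id))
          } else {
            ga <- ou(1L) < p_ga
            anaes[id] <<- if (ga) 2L else 1L
            if (tr_on) rec(te, id, if (ga) "anaesthesia_general" else "anaesthesia_local", NA_character_)
            ta <- te + sdur(if (ga) D$anaesthesia_general else D$anaesthesia_local)
            sched(ta, function() enter_theatre(id, s, ta))
          }
        })
      })
    })
  }

  book_session <- function(s, tb, t_start) {
    k <- 0L
    repeat {
      if (k >= tt_cap[s]) break
      id <- wl_pop(tb)
      if (is.na(id)) break
      k <- k + 1L
      t_booked[id] <<- tb
      p_session[id] <<- s
      if (tr_on) rec(tb, id, "booked", NA_character_)
      local({
        idl <- id
        tal <- t_start + (k - 1L) * spacing
        sched(tal, function() attend(idl, s, tal))
      })
    }
    s_booked[s] <<- k
  }

  # --- schedule everything ------------------------------------------------
  # bookings and referrals are self-chaining event streams (each event
  # schedules its successor), keeping the pending-event heap small
  if (n_prime > 0L) {
    for (id in seq_len(n_prime)) {
      t_listed[id] <- 0
      wl_push(id, 0)
    }
    outcome[seq_len(n_prime)] <- 2L
  }
  tb_all <- pmax(0, tt_start - lead_min)  # non-decreasing with session order
  next_ses <- 1L
  booking_event <- function() {
    sl <- next_ses
    book_session(sl, tb_all[sl], tt_start[sl])
    next_ses <<- next_ses + 1L
    if (next_ses <= n_ses) sched(tb_all[next_ses], booking_event)
  }
  if (n_ses > 0L) sched(tb_all[1L], booking_event)
  next_arr <- 1L
  arrival_event <- function() {
    id <- n_prime + next_arr
    refer(id, t_ref[id])
    next_arr <<- next_arr + 1L
    if (next_arr <= n_arr) sched(t_ref[n_prime + next_arr], arrival_event)
  }
  if (n_arr > 0L) sched(t_ref[n_prime + 1L], arrival_event)

  log_phase("running events to horizon")
  cal$run_until(horizon)
  log_phase("run complete: clock ", round(clock_now()), " min")

  # --- assemble outputs ---------------------------------------------------
  patients <- tibble::tibble(
    id = seq_len(n_pat),
    source = c("optometrist", "internal", "primed")[source_i],
    elderly = elderly,
    status = PATIENT_STATUS[status + 1L],
    exam_outcome = ifelse(outcome == 0L, NA_character_, EXAM_OUTCOMES[pmax(outcome, 1L)]),
    preop_mode = c(NA_character_, "clinic", "phone")[preop + 1L],
    anaesthesia = c(NA_character_, "local", "general")[anaes + 1L],
    recovery = c(NA_character_, "chair", "bed")[recov + 1L],
    session = p_session,
    t_referral = t_ref, t_exam = t_exam, t_preop = t_preop,
    t_listed = t_listed, t_booked = t_booked,
    t_surgery = t_surg, t_discharge = t_disch
  )

  sessions <- tt
  sessions$booked <- s_booked
  sessions$completed <- s_comp
  sessions$no_show <- s_ns
  sessions$cancelled_unfit <- s_unfit
  sessions$unused <- sessions$capacity - s_booked
  sessions$lost <- s_ns + s_unfit

  theatre_iv <- do.call(rbind, lapply(theatre_pools, function(p) p$intervals()))
  intervals <- list(
    consult_room = p_consult$intervals(),
    presurgery_room = p_room$intervals(),
    recovery_chair = p_chair$intervals(),
    recovery_bed = p_bed$intervals(),
    doctor = p_doctor$intervals(),
    nurse = p_nurse$intervals(),
    theatre = theatre_iv
  )
  capacities <- c(
    consult_room = config$consult_rooms, presurgery_room = config$presurgery_rooms,
    recovery_chair = config$recovery_chairs, recovery_bed = config$recovery_beds,
    doctor = config$doctors, nurse = config$nurses, theatre = config$theatres
  )

  log_phase("building KPI report")
  report <- build_kpi_report(patients, sessions, intervals, config)

  w0 <- warmup_end(config)
  win <- weekday_window_minutes(w0, horizon, config$working_days_per_week)
  resources <- tibble::tibble(
    pool = names(intervals),
    capacity = as.integer(capacities[names(intervals)]),
    busy_minutes = unname(vapply(intervals, function(iv) {
      if (is.null(iv) || nrow(iv) == 0L) return(0)
      sum(pmax(pmin(iv[, 2], horizon) - pmax(iv[, 1], w0), 0))
    }, numeric(1))),
    utilisation = NA_real_
  )
  resources$utilisation <- ifelse(
    resources$capacity > 0L,
    pmin(100, 100 * resources$busy_minutes / (resources$capacity * win)),
    0
  )

  trace_tbl <- NULL
  if (tr_on) {
    idx <- seq_len(tr_n)
    trace_tbl <- tibble::tibble(
      time = tr_t[idx], patient = tr_p[idx], event = tr_e[idx], resource = tr_r[idx]
    )
  }

  structure(
    list(
      scenario = scen_name, seed = seed, config = config,
      patients = patients, sessions = sessions,
      monthly = report$monthly, annual = report$annual,
      resources = resources, intervals = intervals,
      horizon = horizon, window = c(from = w0, to = horizon),
      trace = trace_tbl
    ),
    class = "cataract_sim"
  )
}
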