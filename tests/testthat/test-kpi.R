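stochastic_run <- local({
  run <- NULL
  function() {
    if (is.null(run)) {
      cfg <- tiny_config(referral_rate_optometrist = 25, referral_rate_internal = 5,
                         p_elderly = 0.5, exam_outcome_probs = c(0.1, 0.4, 0.3, 0.2),
                         p_noshow_elderly = 0.12, p_noshow_other = 0.05,
                         p_unfit_on_day = 0.03, p_noshow_rebooked = 0.6,
                         p_general_anaesthesia = 0.08, p_bed_local_elderly = 0.3,
                         p_overnight = 0.02, tariff_preop_clinic = 35,
                         overhead_per_surgery = 120)
      run <<- simulate_service(cfg, seed = 101)
    }
    run
  }
})

test_that("monthly indicators aggregate exactly to the annual row", {
  run <- stochastic_run()
  m <- run$monthly; a <- run$annual
  expect_equal(sum(m$surgeries), a$surgeries)
  expect_equal(sum(m$cancellations), a$cancellations)
  expect_equal(sum(m$no_shows), a$no_shows)
  expect_equal(sum(m$doctor_hours), a$doctor_hours)
  expect_equal(sum(m$nurse_hours), a$nurse_hours)
  expect_identical(sum(m$revenue_pence), a$revenue_pence)
  expect_identical(sum(m$cost_pence), a$cost_pence)
  expect_identical(sum(m$surplus_pence), a$surplus_pence)
})

test_that("surplus equals revenue minus cost to the penny on every row", {
  run <- stochastic_run()
  rows <- dplyr::bind_rows(run$monthly[names(run$annual)], run$annual)
  expect_identical(rows$surplus_pence, rows$revenue_pence - rows$cost_pence)
  expect_equal(rows$revenue_pence %% 1, rep(0, nrow(rows)))
  expect_equal(rows$cost_pence %% 1, rep(0, nrow(rows)))
})

test_that("utilisations lie in [0, 100] everywhere", {
  run <- stochastic_run()
  for (col in c("util_presurgery_room", "util_recovery_chair", "util_recovery_bed")) {
    v <- c(run$monthly[[col]], run$annual[[col]])
    expect_true(all(v >= 0 & v <= 100))
  }
  expect_true(all(run$resources$utilisation >= 0 & run$resources$utilisation <= 100))
})

test_that("annual surgeries equal session slot outcomes and patient statuses", {
  run <- stochastic_run()
  s <- run$sessions[!is.na(run$sessions$month), ]
  expect_equal(run$annual$surgeries, sum(s$completed))
  w0 <- run$window[["from"]]
  p <- run$patients
  ops_in_year <- sum(!is.na(p$t_surgery) & p$t_surgery >= w0 & p$t_surgery < run$horizon)
  expect_equal(run$annual$surgeries, ops_in_year)
})

test_that("flow is conserved: every referral ends in exactly one state", {
  run <- stochastic_run()
  g <- status_groups(run$patients)
  expect_equal(g$referred, g$not_suitable + g$completed + g$lost + g$in_system)
})

test_that("a zero-demand service reports zeros across the board", {
  cfg <- tiny_config(referral_rate_optometrist = 0, warmup_weeks = 0)
  run <- simulate_service(cfg, seed = 1)
  expect_equal(run$annual$surgeries, 0L)
  expect_equal(run$annual$revenue, 0)
  expect_equal(run$annual$cost, 0)
  expect_equal(run$annual$util_presurgery_room, 0)
  expect_true(all(run$monthly$surgeries == 0))
})

test_that("a saturated deterministic service fills every session every month", {
  cfg <- tiny_config(referral_rate_optometrist = 25)
  run <- simulate_service(cfg, seed = 7)
  ses_per_month <- run$sessions |>
    dplyr::filter(!is.na(month)) |>
    dplyr::count(month)
  expect_equal(run$monthly$surgeries, 6L * ses_per_month$n)
})

test_that("staff hours equal the hand-computed activity minutes", {
  # one patient: a 30-minute examination and a 20-minute surgery for the
  # doctor; 15 minutes of day-of-surgery tests for the nurse
  cfg <- tiny_config(referral_rate_optometrist = 0, warmup_weeks = 0,
                     patients_per_list = 2, lists_per_theatre_per_week = 1,
                     booking_lead_days = 0)
  arr <- tibble::tibble(time = 100, source = "optometrist", elderly = FALSE)
  run <- simulate_service(cfg, seed = 1, arrivals = arr)
  expect_equal(staff_hours(run, "doctor"), (30 + 20) / 60)
  expect_equal(staff_hours(run, "nurse"), 15 / 60)
  expect_equal(run$annual$doctor_hours, 50 / 60)
  # monthly staff hours sum to the annual value exactly
  expect_equal(sum(run$monthly$doctor_hours), run$annual$doctor_hours)
})

test_that("mean referral-to-discharge averages completed journeys in weeks", {
  p1 <- tibble::tibble(status = "completed", t_referral = 0,
                       t_discharge = 21 * 1440)
  expect_equal(mean_referral_to_discharge(p1), 3)
  p2 <- tibble::tibble(status = c("completed", "completed"), t_referral = c(0, 0),
                       t_discharge = c(2 * 10080, 4 * 10080))
  expect_equal(mean_referral_to_discharge(p2), 3)
  expect_error(mean_referral_to_discharge(
    tibble::tibble(status = "in_pathway", t_referral = 0, t_discharge = NA_real_)),
    "no completed")

  run <- stochastic_run()
  done <- run$patients[run$patients$status %in%
                         c("completed", "overnight_then_discharged") &
                         run$patients$source != "primed" &
                         !is.na(run$patients$t_discharge), ]
  brute <- mean((done$t_discharge - done$t_referral) / 10080)
  expect_equal(mean_referral_to_discharge(run), brute)
})

test_that("replication summaries behave like t-intervals", {
  expect_error(replicate_and_summarise(tiny_config(), n_reps = 1), "n_reps")

  # a deterministic (zero-demand) service replicates identically:
  # zero-width intervals centred on the mean
  cfg0 <- tiny_config(referral_rate_optometrist = 0, warmup_weeks = 0)
  s0 <- replicate_and_summarise(cfg0, n_reps = 3, master_seed = 5)
  expect_true(all(s0$sd == 0, na.rm = TRUE))
  expect_equal(s0$conf_low[!is.na(s0$sd)], s0$mean[!is.na(s0$sd)])

  cfg <- tiny_config(referral_rate_optometrist = 20, p_elderly = 0.5,
                     p_noshow_elderly = 0.1, p_noshow_other = 0.05)
  s5 <- replicate_and_summarise(cfg, n_reps = 5, master_seed = 11)
  expect_true(all(s5$conf_low <= s5$mean & s5$mean <= s5$conf_high, na.rm = TRUE))
  # interval width shrinks roughly like 1/sqrt(n) with more replications
  s20 <- replicate_and_summarise(cfg, n_reps = 20, master_seed = 11)
  w5 <- with(s5[s5$indicator == "surgeries", ], conf_high - conf_low)
  w20 <- with(s20[s20$indicator == "surgeries", ], conf_high - conf_low)
  expect_lt(w20, w5)
})
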