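test_that("the timetable lays out theatres x lists x weeks half-day sessions", {
  cfg <- tiny_config(warmup_weeks = 0)
  tt <- build_timetable(cfg)
  expect_equal(nrow(tt), 3 * 52)
  expect_true(all(tt$capacity == 6L))
  # half-day starts at 08:00 or 13:00, Mon-Fri only
  tod <- tt$start %% 1440
  expect_true(all(tod %in% c(480, 780)))
  expect_true(all(((tt$start %/% 1440) %% 7) < 5))
  expect_equal(as.integer(table(tt$week)), rep(3L, 52))

  expect_equal(nrow(build_timetable(tiny_config(lists_per_theatre_per_week = 0))), 0L)
  tt2 <- build_timetable(tiny_config(theatres = 2, patients_per_list = 9,
                                     warmup_weeks = 1))
  expect_equal(nrow(tt2), 2 * 3 * 53)
  expect_true(all(tt2$capacity == 9L))
  expect_true(all(is.na(tt2$month[tt2$week == 1])))
})

test_that("sessions fill FIFO from the waiting list, spilling to later sessions", {
  arr <- tibble::tibble(time = 600 + 0:9, source = "optometrist", elderly = FALSE)
  cfg <- tiny_config(referral_rate_optometrist = 0, warmup_weeks = 0)
  run <- simulate_service(cfg, seed = 1, arrivals = arr)
  used <- run$sessions[run$sessions$booked > 0, ]
  expect_equal(used$booked, c(6L, 4L))
  expect_equal(used$unused, c(0L, 2L))
  # the six earliest-listed patients take the earlier session
  p <- run$patients
  first_ses <- used$session_id[1]
  expect_setequal(p$id[!is.na(p$session) & p$session == first_ses], 1:6)
  # every booked patient appears in exactly one session and completes
  expect_equal(sum(used$completed), 10L)
})

test_that("patients listed inside the booking lead time wait for a later session", {
  cfg <- tiny_config(referral_rate_optometrist = 0, warmup_weeks = 0)
  arr <- tibble::tibble(time = 600, source = "optometrist", elderly = FALSE)
  run <- simulate_service(cfg, seed = 1, arrivals = arr)
  p <- run$patients[1, ]
  ses <- run$sessions[run$sessions$session_id == p$session, ]
  # listed at 630 (600 + 30 min exam); only sessions whose booking cutoff
  # (start - 7 days) is at or after listing are eligible
  expect_equal(p$t_listed, 630)
  expect_gte(ses$start - 7 * 1440, p$t_listed)
  earlier <- run$sessions[run$sessions$start < ses$start, ]
  expect_true(all(earlier$start - 7 * 1440 < p$t_listed))
})

test_that("lost slots are never backfilled and session arithmetic balances", {
  cfg <- tiny_config(referral_rate_optometrist = 25, p_elderly = 0.5,
                     p_noshow_elderly = 0.15, p_noshow_other = 0.05,
                     p_unfit_on_day = 0.05)
  run <- simulate_service(cfg, seed = 19)
  s <- run$sessions
  expect_true(all(s$completed + s$no_show + s$cancelled_unfit == s$booked))
  expect_true(all(s$completed <= s$capacity - s$lost))
  expect_true(all(s$booked <= s$capacity))
  # hard annual capacity bound
  expect_lte(run$annual$surgeries,
             planned_weekly_capacity(cfg) * cfg$weeks_per_year)
})

test_that("mean lost slots per session match the binomial loss rate", {
  p_loss <- 0.1  # single age band, no unfit cancellations
  cfg <- tiny_config(referral_rate_optometrist = 25, p_elderly = 0,
                     p_noshow_other = p_loss)
  run <- simulate_service(cfg, seed = 23)
  s <- run$sessions[!is.na(run$sessions$month), ]
  n_booked <- sum(s$booked)
  expect_equal(n_booked, 936L)  # saturated list books every slot
  phat <- sum(s$lost) / n_booked
  expect_lt(abs(phat - p_loss), 3 * sqrt(p_loss * (1 - p_loss) / n_booked))
})

test_that("unfit patients rejoin the list after exactly the configured delay", {
  cfg <- tiny_config(referral_rate_optometrist = 20, p_unfit_on_day = 0.3,
                     unfit_reschedule_delay_weeks = 2)
  run <- simulate_service(cfg, seed = 29, trace = TRUE)
  tr <- run$trace
  cancels <- tr[tr$event == "cancelled_unfit", ]
  relists <- tr[tr$event == "relisted", ]
  expect_gt(nrow(cancels), 100)
  horizon <- run$horizon
  for (i in seq_len(nrow(cancels))) {
    tc <- cancels$time[i]
    if (tc + 2 * 10080 <= horizon) {
      expect_true(any(relists$patient == cancels$patient[i] &
                        abs(relists$time - (tc + 2 * 10080)) < 1e-9))
    }
  }
})

test_that("no-show rebooking honours the rebooking probability", {
  base <- list(referral_rate_optometrist = 20, p_noshow_elderly = 1,
               p_noshow_other = 1, p_elderly = 0.5)
  never <- simulate_service(do.call(tiny_config, c(base, p_noshow_rebooked = 0)),
                            seed = 37, trace = TRUE)
  expect_equal(sum(never$trace$event == "relisted"), 0L)
  booked <- never$patients[!is.na(never$patients$t_booked), ]
  expect_true(all(booked$status == "no_show"))
  expect_equal(never$annual$surgeries, 0L)

  always <- simulate_service(do.call(tiny_config, c(base, p_noshow_rebooked = 1)),
                             seed = 37, trace = TRUE)
  tr <- always$trace
  ns <- tr[tr$event == "no_show" & tr$time + 2 * 10080 <= always$horizon, ]
  rl <- tr[tr$event == "relisted", ]
  for (i in seq_len(nrow(ns))) {
    expect_true(any(rl$patient == ns$patient[i] &
                      abs(rl$time - (ns$time[i] + 2 * 10080)) < 1e-9))
  }
})
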