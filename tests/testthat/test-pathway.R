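test_that("referral generation matches its Poisson superposition", {
  cfg <- tiny_config(referral_rate_optometrist = 0, referral_rate_internal = 0)
  empty <- generate_referrals(cfg, 52 * 10080, rng_stream(1))
  expect_equal(nrow(empty), 0L)

  cfg <- tiny_config(referral_rate_optometrist = 60, referral_rate_internal = 40,
                     p_elderly = 1)
  refs <- generate_referrals(cfg, 52 * 10080, rng_stream(2))
  # total ~ Poisson(5200): within 3 standard deviations
  expect_lt(abs(nrow(refs) - 5200), 3 * sqrt(5200))
  expect_true(all(refs$elderly))
  expect_true(all(refs$source %in% c("optometrist", "internal")))
  expect_true(all(diff(refs$time) >= 0))
  # referrals only on working days, inside the daytime window
  mins <- refs$time %% 10080
  expect_true(all((mins %/% 1440) < 5))
  tod <- refs$time %% 1440
  expect_true(all(tod >= 480 & tod <= 1080))
})

test_that("examination outcomes follow the configured four-way split", {
  probs <- c(not_suitable = 0.2, listed_direct = 0.3,
             preop_clinic = 0.3, preop_phone = 0.2)
  # no theatre lists: the run only examines and lists patients
  cfg <- tiny_config(referral_rate_optometrist = 200, exam_outcome_probs = probs,
                     lists_per_theatre_per_week = 0, warmup_weeks = 0,
                     consult_rooms = 4, doctors = 4, nurses = 4)
  run <- simulate_service(cfg, seed = 31)
  seen <- run$patients$exam_outcome[!is.na(run$patients$exam_outcome)]
  n <- length(seen)
  expect_gt(n, 9000)
  for (k in names(probs)) {
    phat <- mean(seen == k)
    expect_lt(abs(phat - probs[[k]]),
              2.58 * sqrt(probs[[k]] * (1 - probs[[k]]) / n) + 1e-9)
  }
})

test_that("degenerate outcome probabilities route every patient one way", {
  cfg <- tiny_config(referral_rate_optometrist = 5, lists_per_theatre_per_week = 0,
                     exam_outcome_probs = c(1, 0, 0, 0))
  run <- simulate_service(cfg, seed = 5)
  ex <- run$patients[!is.na(run$patients$exam_outcome), ]
  expect_true(all(ex$exam_outcome == "not_suitable"))
  expect_true(all(ex$status == "not_suitable"))

  cfg <- tiny_config(referral_rate_optometrist = 5, lists_per_theatre_per_week = 0,
                     exam_outcome_probs = c(0, 0, 0, 1))
  run <- simulate_service(cfg, seed = 5)
  ex <- run$patients[!is.na(run$patients$exam_outcome), ]
  expect_true(all(ex$exam_outcome == "preop_phone"))
  expect_true(all(ex$preop_mode[!is.na(ex$t_preop)] == "phone"))
})

test_that("phone pre-op assessment never touches the pre-surgery room", {
  cfg <- tiny_config(referral_rate_optometrist = 10, lists_per_theatre_per_week = 0,
                     exam_outcome_probs = c(0, 0, 0, 1), warmup_weeks = 0)
  run <- simulate_service(cfg, seed = 8)
  room <- run$resources[run$resources$pool == "presurgery_room", ]
  expect_equal(room$busy_minutes, 0)
  # nurse time is exactly one 10-minute call per completed assessment
  n_done <- sum(!is.na(run$patients$t_preop))
  expect_equal(sum(run$intervals$nurse[, 2] - run$intervals$nurse[, 1]), 10 * n_done)
})

test_that("clinic pre-op assessments queue FIFO on a single nurse", {
  # 100 patients examined in parallel, then 10-minute phone assessments
  # serialised through one nurse: the last listing is 100 calls later
  arr <- tibble::tibble(time = seq(0, 0.99, length.out = 100),
                        source = "optometrist", elderly = FALSE)
  cfg <- tiny_config(referral_rate_optometrist = 0, lists_per_theatre_per_week = 0,
                     exam_outcome_probs = c(0, 0, 0, 1), warmup_weeks = 0,
                     consult_rooms = 100, doctors = 100, nurses = 1)
  run <- simulate_service(cfg, seed = 3, arrivals = arr)
  # exams all run [t, t+30]; the nurse works back-to-back from t = 30
  expect_equal(max(run$patients$t_listed), 30 + 100 * 10)
  expect_equal(sum(!is.na(run$patients$t_preop)), 100)
})

test_that("recovery routing follows anaesthesia type and age", {
  cases <- list(
    list(over = list(p_general_anaesthesia = 1), want = "bed"),
    list(over = list(p_elderly = 0), want = "chair"),
    list(over = list(p_elderly = 1, p_bed_local_elderly = 1), want = "bed")
  )
  for (cs in cases) {
    cfg <- do.call(tiny_config, c(list(referral_rate_optometrist = 10,
                                       lists_per_theatre_per_week = 1), cs$over))
    run <- simulate_service(cfg, seed = 17)
    done <- run$patients[!is.na(run$patients$recovery), ]
    expect_gt(nrow(done), 50)
    expect_true(all(done$recovery == cs$want))
  }
})

test_that("overnight patients keep a bed until 08:00 next morning", {
  cfg <- tiny_config(referral_rate_optometrist = 10, lists_per_theatre_per_week = 1,
                     p_general_anaesthesia = 1, p_overnight = 1, recovery_beds = 6)
  run <- simulate_service(cfg, seed = 9)
  done <- run$patients[!is.na(run$patients$t_discharge) &
                         run$patients$status != "not_suitable", ]
  expect_gt(nrow(done), 50)
  expect_true(all(done$status == "overnight_then_discharged"))
  expect_true(all(done$t_discharge %% 1440 == 480))

  cfg0 <- tiny_config(referral_rate_optometrist = 10, lists_per_theatre_per_week = 1,
                      p_general_anaesthesia = 1, p_overnight = 0)
  run0 <- simulate_service(cfg0, seed = 9)
  st <- run0$patients$status[!is.na(run0$patients$t_surgery)]
  expect_true(all(st == "completed"))
})

test_that("overnight stays occur at the configured binomial rate", {
  cfg <- tiny_config(referral_rate_optometrist = 25, p_general_anaesthesia = 1,
                     p_overnight = 0.05, recovery_beds = 4)
  run <- simulate_service(cfg, seed = 21)
  ops <- run$patients[!is.na(run$patients$t_surgery), ]
  n <- nrow(ops)
  phat <- mean(ops$status == "overnight_then_discharged")
  expect_gt(n, 800)
  expect_lt(abs(phat - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("elderly patients miss surgery more often than others", {
  cfg <- tiny_config(referral_rate_optometrist = 25, p_elderly = 0.5,
                     p_noshow_elderly = 0.2, p_noshow_other = 0.05)
  run <- simulate_service(cfg, seed = 13)
  booked <- run$patients[!is.na(run$patients$t_booked), ]
  # no rebooking in tiny_config: each booked patient attempts exactly once
  rate_e <- mean(booked$status[booked$elderly] == "no_show")
  rate_o <- mean(booked$status[!booked$elderly] == "no_show")
  expect_gt(sum(booked$elderly), 300)
  expect_gt(rate_e, rate_o)
  expect_lt(abs(rate_e - 0.2), 3 * sqrt(0.2 * 0.8 / sum(booked$elderly)))
  expect_lt(abs(rate_o - 0.05), 3 * sqrt(0.05 * 0.95 / sum(!booked$elderly)))
})

test_that("patient timestamps are ordered along the pathway", {
  cfg <- tiny_config(referral_rate_optometrist = 25, p_elderly = 0.5,
                     referral_rate_internal = 5,
                     exam_outcome_probs = c(0.1, 0.4, 0.3, 0.2),
                     p_noshow_elderly = 0.1, p_noshow_other = 0.05,
                     p_unfit_on_day = 0.05, p_noshow_rebooked = 0.5,
                     p_general_anaesthesia = 0.1, p_bed_local_elderly = 0.3)
  run <- simulate_service(cfg, seed = 77)
  p <- run$patients[run$patients$source != "primed", ]
  ord <- function(a, b) {
    both <- !is.na(a) & !is.na(b)
    all(a[both] <= b[both])
  }
  expect_true(ord(p$t_referral, p$t_exam))
  expect_true(ord(p$t_exam, p$t_preop))
  expect_true(ord(p$t_exam, p$t_listed))
  expect_true(ord(p$t_listed, p$t_surgery))
  expect_true(ord(p$t_surgery, p$t_discharge))
  done <- p[!is.na(p$t_discharge), ]
  expect_true(all(done$t_discharge > done$t_referral))
})
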