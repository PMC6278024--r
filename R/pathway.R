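# Referral generation for the patient pathway.

#' Generate a year of cataract referrals
#'
#' Two superposed Poisson streams — community optometrist referrals and
#' internal hospital referrals (e.g. from Diabetes services) — spread over
#' working days, with arrival times uniform over the 08:00-18:00 daytime
#' window. Each patient receives an elderly flag with probability
#' `p_elderly`; internal referrals enter the pathway at the eye-examination
#' step exactly like optometrist referrals, differing only in rate.
#'
#' @param config A validated `service_config`.
#' @param horizon End of the generation window, minutes from run start.
#' @param stream An [rng_stream()] supplying uniforms (the arrivals stream).
#' @return A tibble with one row per referral, sorted by time: `time`
#'   (minutes), `source` (`"optometrist"` or `"internal"`), `elderly`.
#' @examples
#' cfg <- default_parameters()
#' refs <- generate_referrals(cfg, horizon = 2 * 10080, rng_stream(1))
#' head(refs)
#' @export
generate_referrals <- function(config, horizon, stream) {
  config <- validate_config(config)
  wd <- config$working_days_per_week
  n_days <- ceiling(horizon / MIN_PER_DAY)
  days <- seq_len(n_days) - 1L
  days <- days[(days %% 7) < wd]
  if (length(days) == 0L ||
      (config$referral_rate_optometrist == 0 && config$referral_rate_internal == 0)) {
    return(tibble::tibble(time = numeric(), source = character(), elderly = logical()))
  }
  lam_o <- config$referral_rate_optometrist / wd
  lam_i <- config$referral_rate_internal / wd
  nd <- length(days)
  # daily counts, then times within the daytime window, then elderly flags;
  # a fixed draw order keeps the stream reproducible
  n_o <- stats::qpois(stream$draw(nd), lam_o)
  n_i <- stats::qpois(stream$draw(nd), lam_i)
  day_of <- c(rep(days, n_o), rep(days, n_i))
  src <- rep(c("optometrist", "internal"), c(sum(n_o), sum(n_i)))
  n_tot <- length(day_of)
  if (n_tot == 0L) {
    return(tibble::tibble(time = numeric(), source = character(), elderly = logical()))
  }
  times <- day_of * MIN_PER_DAY + DAY_OPEN + stream$draw(n_tot) * (DAY_CLOSE - DAY_OPEN)
  elderly <- stream$draw(n_tot) < config$p_elderly
  out <- tibble::tibble(time = times, source = src, elderly = elderly)
  out <- out[out$time < horizon, , drop = FALSE]
  dplyr::arrange(out, .data$time)
}
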