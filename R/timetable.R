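# Yearly theatre timetable and the calendar used for reporting.
#
# Time is measured in minutes from midnight on the Monday of week 1. The run
# covers `warmup_weeks` of warm-up followed by `weeks_per_year` reporting
# weeks; the reporting window is mapped onto the 12 calendar months of a
# non-leap year starting 1 January (December is truncated to the end of the
# 52-week window). A session belongs to the month of its start time.

MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

# warm-up offset in minutes: the reporting window is [warmup_end, horizon)
warmup_end <- function(config) config$warmup_weeks * MIN_PER_WEEK

run_horizon <- function(config) {
  (config$warmup_weeks + config$weeks_per_year) * MIN_PER_WEEK
}

# month windows of the reporting year, in absolute minutes
month_windows <- function(config) {
  w0 <- warmup_end(config)
  w1 <- run_horizon(config)
  edges <- w0 + c(0, cumsum(MONTH_DAYS)) * MIN_PER_DAY
  edges <- pmin(edges, w1)
  tibble::tibble(month = 1:12, from = edges[1:12], to = edges[2:13])
}

month_of <- function(time, config) {
  mw <- month_windows(config)
  m <- findInterval(time, c(mw$from, mw$to[12]), left.open = FALSE)
  m[time < mw$from[1] | time >= mw$to[12] | m > 12L] <- NA_integer_
  as.integer(m)
}

# scheduled operating minutes (08:00-18:00 on working days) inside [from, to)
weekday_window_minutes <- function(from, to, working_days = 5L) {
  if (to <= from) return(0)
  d0 <- floor(from / MIN_PER_DAY)
  d1 <- ceiling(to / MIN_PER_DAY) - 1
  days <- d0:d1
  days <- days[(days %% 7) < working_days]
  if (length(days) == 0L) return(0)
  lo <- pmax(days * MIN_PER_DAY + DAY_OPEN, from)
  hi <- pmin(days * MIN_PER_DAY + DAY_CLOSE, to)
  sum(pmax(hi - lo, 0))
}

#' Build the theatre session timetable
#'
#' Lays out `theatres x lists_per_theatre_per_week` half-day sessions per
#' week over the whole run (warm-up plus reporting year), spread Mon-Fri
#' with alternating morning (08:00) and afternoon (13:00) starts. Errors if
#' a theatre is asked for more lists than the working week has half-day
#' slots.
#'
#' @param config A validated `service_config`.
#' @param weeks Number of weeks to lay out; defaults to warm-up plus the
#'   reporting year.
#' @return A tibble with one row per session: `session_id`, `theatre`,
#'   `week`, `start` (minutes), `capacity`, and the reporting `month`
#'   (`NA` during warm-up).
#' @examples
#' cfg <- default_parameters()
#' tt <- build_timetable(cfg, weeks = 1)
#' nrow(tt) == cfg$theatres * cfg$lists_per_theatre_per_week
#' @export
build_timetable <- function(config, weeks = NULL) {
  config <- validate_config(config)
  if (is.null(weeks)) weeks <- config$warmup_weeks + config$weeks_per_year
  wd <- config$working_days_per_week
  lists <- config$lists_per_theatre_per_week
  if (lists > 2L * wd) {
    stop("lists_per_theatre_per_week (", lists, ") exceeds available half-day slots (",
         2L * wd, ")", call. = FALSE)
  }
  if (weeks == 0L || lists == 0L || config$theatres == 0L) {
    return(tibble::tibble(
      session_id = integer(), theatre = integer(), week = integer(),
      start = numeric(), capacity = integer(), month = integer()
    ))
  }
  k <- seq_len(lists) - 1L
  pass <- k %/% wd
  day <- k %% wd                      # 0 = Monday
  am <- (day + pass) %% 2L == 0L      # alternate AM/PM, offset on each pass
  start_in_week <- day * MIN_PER_DAY + ifelse(am, 8 * 60, 13 * 60)

  grid <- tidyr::expand_grid(
    week = seq_len(weeks),
    theatre = seq_len(config$theatres),
    slot = seq_len(lists)
  )
  grid$start <- (grid$week - 1) * MIN_PER_WEEK + start_in_week[grid$slot]
  grid <- dplyr::arrange(grid, .data$start, .data$theatre)
  tibble::tibble(
    session_id = seq_len(nrow(grid)),
    theatre = grid$theatre,
    week = grid$week,
    start = grid$start,
    capacity = config$patients_per_list,
    month = month_of(grid$start, config)
  )
}
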