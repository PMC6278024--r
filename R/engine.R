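# Minimal process-oriented discrete event kernel.
#
# Three primitives: an event calendar (binary min-heap keyed by time with a
# stable insertion counter for ties), FIFO resource pools that log busy
# intervals, and reproducible uniform random-number streams (one per
# stochastic purpose, so a change in one parameter never scrambles unrelated
# draws — common random numbers across scenarios).
#
# All mutable state lives in closure environments; the hot paths are plain
# byte-compiled vector operations, which keeps the kernel fast enough for
# full-year runs (~60k events) without compiled code.

MIN_PER_DAY <- 1440
MIN_PER_WEEK <- 10080
DAY_OPEN <- 8 * 60    # daytime operating window 08:00 ...
DAY_CLOSE <- 18 * 60  # ... to 18:00

#' Create an event calendar
#'
#' A stable priority queue of `(time, action)` pairs: events are dispatched
#' in non-decreasing time order, with equal times dispatched in insertion
#' order. `$schedule(time, action)` enqueues a zero-argument function at an
#' absolute time in minutes (an error if `time` is before the current
#' clock — no time travel); `$run_until(horizon)` dispatches every event
#' with `time <= horizon` and returns the final clock; `$now()` reads the
#' clock; `$size()` the number of pending events.
#'
#' @return An environment with closures `schedule`, `run_until`, `now`,
#'   `size`, classed `event_calendar`.
#' @examples
#' cal <- event_calendar()
#' fired <- c()
#' cal$schedule(5, function() fired <<- c(fired, "late"))
#' cal$schedule(3, function() fired <<- c(fired, "early"))
#' cal$run_until(10)
#' fired
#' @export
event_calendar <- function() {
  cap <- 1024L
  tmv <- numeric(cap)     # heap of event times
  sqv <- integer(cap)     # insertion counters (tie-break)
  n <- 0L
  counter <- 0L
  clock <- 0
  acts <- vector("list", cap)  # actions indexed by insertion counter

  schedule <- function(time, action) {
    if (!is.numeric(time) || length(time) != 1L || is.na(time)) {
      stop("event time must be a number", call. = FALSE)
    }
    if (time < clock) {
      stop("cannot schedule an event in the past (time ", time,
           " < clock ", clock, ")", call. = FALSE)
    }
    counter <<- counter + 1L
    if (counter > length(acts)) {
      tmp <- vector("list", 2L * length(acts)); tmp[seq_along(acts)] <- acts
      acts <<- tmp
    }
    acts[[counter]] <<- action
    n <<- n + 1L
    if (n > length(tmv)) {
      tmv <<- c(tmv, numeric(length(tmv)))
      sqv <<- c(sqv, integer(length(sqv)))
    }
    i <- n
    tmv[i] <<- time; sqv[i] <<- counter
    while (i > 1L) {
      p <- i %/% 2L
      # sift up: earlier time wins; equal times keep insertion order
      if (tmv[i] < tmv[p] || (tmv[i] == tmv[p] && sqv[i] < sqv[p])) {
        tt <- tmv[p]; tmv[p] <<- tmv[i]; tmv[i] <<- tt
        ss <- sqv[p]; sqv[p] <<- sqv[i]; sqv[i] <<- ss
        i <- p
      } else break
    }
    invisible(counter)
  }

  pop <- function() {
    id <- sqv[1L]; t <- tmv[1L]
    tmv[1L] <<- tmv[n]; sqv[1L] <<- sqv[n]
    n <<- n - 1L
    i <- 1L
    repeat {
      l <- 2L * i; r <- l + 1L; m <- i
      if (l <= n && (tmv[l] < tmv[m] || (tmv[l] == tmv[m] && sqv[l] < sqv[m]))) m <- l
      if (r <= n && (tmv[r] < tmv[m] || (tmv[r] == tmv[m] && sqv[r] < sqv[m]))) m <- r
      if (m == i) break
      tt <- tmv[m]; tmv[m] <<- tmv[i]; tmv[i] <<- tt
      ss <- sqv[m]; sqv[m] <<- sqv[i]; sqv[i] <<- ss
      i <- m
    }
    a <- acts[[id]]
    acts[id] <<- list(NULL)  # free the closure
    list(time = t, action = a)
  }

  run_until <- function(horizon) {
    if (!is.numeric(horizon) || length(horizon) != 1L || is.na(horizon) || horizon < 0) {
      stop("horizon must be a non-negative number", call. = FALSE)
    }
    while (n > 0L && tmv[1L] <= horizon) {
      ev <- pop()
      clock <<- ev$time
      ev$action()
    }
    clock
  }

  env <- environment()
  structure(
    list(schedule = schedule, run_until = run_until,
         now = function() clock, size = function() n),
    class = "event_calendar", env = env
  )
}

#' Create a reproducible uniform random stream
#'
#' Each stream owns an independent Mersenne-Twister state seeded from its
#' own seed; `$draw(n)` returns `n` uniforms in (0, 1). Draws are buffered
#' in blocks so the global `.Random.seed` is touched rarely and always
#' restored, leaving the caller's RNG untouched.
#'
#' @param seed Integer seed for this stream.
#' @param block Buffer refill size.
#' @return An environment with a `draw(n)` closure, classed `rng_stream`.
#' @export
rng_stream <- function(seed, block = 4096L) {
  state <- NULL
  buf <- numeric(0)
  ptr <- 0L

  refill <- function(nmin) {
    take <- max(block, nmin)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, envir = globalenv())
    fresh <- stats::runif(take)
    state <<- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    buf <<- c(buf[ptr + seq_len(length(buf) - ptr)], fresh)
    ptr <<- 0L
  }

  draw <- function(n = 1L) {
    if (ptr + n > length(buf)) refill(n)
    out <- buf[ptr + seq_len(n)]
    ptr <<- ptr + n
    out
  }

  structure(list(draw = draw, seed = seed), class = "rng_stream")
}

#' Named independent random streams for one simulation run
#'
#' Derives one substream per stochastic purpose (arrivals, outcomes,
#' durations, attendance) from a master seed. The same master seed gives a
#' bit-identical simulation trajectory; because purposes are segregated,
#' changing e.g. a duration parameter does not perturb the arrival pattern,
#' which sharpens scenario contrasts (common random numbers).
#'
#' @param master_seed Integer master seed.
#' @return A named list of [rng_stream()] objects.
#' @export
rng_streams <- function(master_seed) {
  purposes <- c("arrivals", "outcomes", "durations", "attendance")
  seeds <- derive_seeds(master_seed, length(purposes))
  stats::setNames(lapply(seeds, rng_stream), purposes)
}

# Derive n child seeds (< 2^31) from a master seed without disturbing the
# caller's RNG state.
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max, n)
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  seeds
}

#' Create a FIFO resource pool
#'
#' A pool of `capacity` identical units (doctors, recovery chairs, a
#' theatre, ...). `$request(time, on_grant)` grants a unit immediately when
#' one is free — calling `on_grant(grant_time)` — and otherwise queues the
#' request first-come-first-served. `$release(time, grant_time)` returns a
#' unit, logs the busy interval, and hands the unit to the head of the
#' queue. Busy intervals accumulate for utilisation and staff-hours
#' accounting; `$busy_time()` is total busy minutes (capacity-weighted),
#' `$intervals()` the raw log.
#'
#' @param name Pool name.
#' @param capacity Number of units (>= 0).
#' @return An environment-backed object of class `resource_pool`.
#' @examples
#' pool <- resource_pool("chair", 1)
#' pool$request(0, function(t) invisible(t))
#' pool$release(30, 0)
#' pool$busy_time()
#' @export
resource_pool <- function(name, capacity) {
  capacity <- check_count(capacity, paste0("capacity of pool '", name, "'"))
  busy <- 0L
  q_cb <- vector("list", 64L)
  q_head <- 0L  # last served index
  q_tail <- 0L  # last queued index
  iv_a <- numeric(256L); iv_b <- numeric(256L); iv_n <- 0L

  request <- function(time, on_grant) {
    if (busy < capacity) {
      busy <<- busy + 1L
      on_grant(time)
    } else {
      q_tail <<- q_tail + 1L
      if (q_tail > length(q_cb)) {
        tmp <- vector("list", 2L * length(q_cb)); tmp[seq_along(q_cb)] <- q_cb
        q_cb <<- tmp
      }
      q_cb[[q_tail]] <<- on_grant
    }
    invisible(NULL)
  }

  release <- function(time, grant_time) {
    if (busy <= 0L) {
      stop("release without a matching acquire on pool '", name, "'", call. = FALSE)
    }
    iv_n <<- iv_n + 1L
    if (iv_n > length(iv_a)) {
      iv_a <<- c(iv_a, numeric(length(iv_a)))
      iv_b <<- c(iv_b, numeric(length(iv_b)))
    }
    iv_a[iv_n] <<- grant_time; iv_b[iv_n] <<- time
    if (q_head < q_tail) {
      # hand the freed unit straight to the queue head (busy count unchanged)
      q_head <<- q_head + 1L
      cb <- q_cb[[q_head]]
      q_cb[q_head] <<- list(NULL)
      cb(time)
    } else {
      busy <<- busy - 1L
    }
    invisible(NULL)
  }

  structure(
    list(
      name = name, capacity = capacity,
      request = request, release = release,
      busy = function() busy,
      queue_length = function() q_tail - q_head,
      busy_time = function() if (iv_n == 0L) 0 else sum(iv_b[seq_len(iv_n)] - iv_a[seq_len(iv_n)]),
      intervals = function() {
        idx <- seq_len(iv_n)
        cbind(start = iv_a[idx], end = iv_b[idx])
      }
    ),
    class = "resource_pool"
  )
}

#' Fraction of scheduled time a pool was in use
#'
#' `100 * busy_minutes / (capacity * window)`, clamped to \[0, 100\]. The
#' window is scheduled operating time (e.g. weekday daytime minutes), never
#' the wall-clock year.
#'
#' @param pool A [resource_pool()], or total busy minutes as a number (in
#'   which case `capacity` must be given).
#' @param window Scheduled operating minutes (> 0).
#' @param capacity Pool capacity, only when `pool` is a bare number.
#' @return Utilisation in percent.
#' @export
utilisation <- function(pool, window, capacity = NULL) {
  if (!is.numeric(window) || length(window) != 1L || is.na(window) || window <= 0) {
    stop("utilisation window must be > 0 minutes", call. = FALSE)
  }
  if (inherits(pool, "resource_pool")) {
    busy <- pool$busy_time()
    capacity <- pool$capacity
  } else {
    busy <- pool
    if (is.null(capacity)) stop("capacity must be supplied with raw busy minutes", call. = FALSE)
  }
  if (capacity == 0L) return(0)
  min(100, max(0, 100 * busy / (capacity * window)))
}
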