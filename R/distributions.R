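# Activity-duration distribution specs.
#
# Every stochastic activity time in the model (examination, pre-operative
# assessment, surgery, recovery, ...) is described by a small spec list:
# list(family = "lognormal", mean = 20, sd = 5), with all parameters in
# minutes on the natural scale. Sampling is inverse-CDF driven so that a
# single uniform random-number stream feeds all families reproducibly.

DURATION_FAMILIES <- c("constant", "lognormal", "triangular", "exponential")

# pathological draws (possible for heavy-tailed specs after scaling) are
# truncated to this floor, in minutes
DURATION_FLOOR <- 0.1

#' Specify an activity-duration distribution
#'
#' @param family One of `"constant"`, `"lognormal"`, `"triangular"`,
#'   `"exponential"`.
#' @param ... Family parameters, all in minutes: `value` (constant),
#'   `mean` and `sd` on the natural scale (lognormal), `min`, `mode`, `max`
#'   (triangular), `mean` (exponential).
#' @return A validated duration spec (a classed list).
#' @examples
#' duration_spec("lognormal", mean = 20, sd = 5)
#' duration_spec("triangular", min = 5, mode = 10, max = 15)
#' @export
duration_spec <- function(family, ...) {
  spec <- c(list(family = family), list(...))
  validate_duration_spec(spec, "duration")
}

validate_duration_spec <- function(spec, name) {
  if (!is.list(spec) || is.null(spec$family)) {
    stop("duration '", name, "' must be a list with a 'family' field", call. = FALSE)
  }
  if (!spec$family %in% DURATION_FAMILIES) {
    stop("duration '", name, "': unknown family '", spec$family, "' (must be one of ",
         paste(DURATION_FAMILIES, collapse = ", "), ")", call. = FALSE)
  }
  need <- switch(spec$family,
    constant = "value",
    lognormal = c("mean", "sd"),
    triangular = c("min", "mode", "max"),
    exponential = "mean"
  )
  for (p in need) {
    v <- spec[[p]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("duration '", name, "' (", spec$family, "): parameter '", p,
           "' must be a finite number", call. = FALSE)
    }
  }
  if (mean_duration(spec) <= 0) {
    stop("duration '", name, "': mean must be > 0", call. = FALSE)
  }
  if (spec$family == "lognormal" && spec$sd < 0) {
    stop("duration '", name, "': sd must be >= 0", call. = FALSE)
  }
  if (spec$family == "triangular" &&
      !(spec$min <= spec$mode && spec$mode <= spec$max && spec$min < spec$max)) {
    stop("duration '", name, "': triangular requires min <= mode <= max and min < max",
         call. = FALSE)
  }
  structure(spec, class = "duration_spec")
}

#' Expected value of a duration spec, in minutes
#'
#' @param spec A [duration_spec()].
#' @return The distribution mean in minutes.
#' @export
mean_duration <- function(spec) {
  switch(spec$family,
    constant = spec$value,
    lognormal = spec$mean,
    triangular = (spec$min + spec$mode + spec$max) / 3,
    exponential = spec$mean,
    stop("unknown duration family '", spec$family, "'", call. = FALSE)
  )
}

#' Rescale a duration spec by a positive factor
#'
#' Multiplies the scale of the distribution so that the mean (and, for
#' location-scale-like families, the spread) is multiplied by `factor`.
#' Used by scenario duration multipliers.
#'
#' @param spec A [duration_spec()].
#' @param factor Positive multiplier.
#' @return A new duration spec; the input is not modified.
#' @export
scale_duration <- function(spec, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) || factor <= 0) {
    stop("duration multiplier must be a positive number", call. = FALSE)
  }
  out <- unclass(spec)
  switch(spec$family,
    constant = { out$value <- out$value * factor },
    lognormal = { out$mean <- out$mean * factor; out$sd <- out$sd * factor },
    triangular = {
      out$min <- out$min * factor; out$mode <- out$mode * factor; out$max <- out$max * factor
    },
    exponential = { out$mean <- out$mean * factor }
  )
  structure(out, class = "duration_spec")
}

# Inverse-CDF sampler: maps uniforms in (0,1) to minutes. Vectorised over u.
sample_duration_u <- function(spec, u) {
  x <- switch(spec$family,
    constant = rep(spec$value, length(u)),
    lognormal = {
      if (spec$sd == 0) rep(spec$mean, length(u)) else {
        s2 <- log1p((spec$sd / spec$mean)^2)
        stats::qlnorm(u, meanlog = log(spec$mean) - s2 / 2, sdlog = sqrt(s2))
      }
    },
    triangular = {
      rng <- spec$max - spec$min
      fc <- (spec$mode - spec$min) / rng
      ifelse(u < fc,
             spec$min + sqrt(u * rng * (spec$mode - spec$min)),
             spec$max - sqrt((1 - u) * rng * (spec$max - spec$mode)))
    },
    exponential = stats::qexp(u, rate = 1 / spec$mean),
    stop("unknown duration family '", spec$family, "'", call. = FALSE)
  )
  x[x < DURATION_FLOOR] <- DURATION_FLOOR
  x
}

#' Sample an activity duration
#'
#' Draws one or more durations from a spec using a named random stream,
#' truncating pathological draws at a floor of 0.1 minutes.
#'
#' @param spec A [duration_spec()].
#' @param stream A random stream created by [rng_stream()].
#' @param n Number of draws.
#' @return Durations in minutes (length `n`).
#' @export
sample_duration <- function(spec, stream, n = 1L) {
  if (!inherits(spec, "duration_spec")) spec <- validate_duration_spec(spec, "duration")
  sample_duration_u(spec, stream$draw(n))
}

#' @export
print.duration_spec <- function(x, ...) {
  pars <- setdiff(names(x), "family")
  cat("<duration: ", x$family, "(",
      paste(sprintf("%s=%g", pars, unlist(x[pars])), collapse = ", "),
      ") min>\n", sep = "")
  invisible(x)
}
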