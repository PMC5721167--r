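#' Uniformly sampled periodic waveform
#'
#' A `waveform` holds one cardiac cycle of a uniformly sampled periodic
#' signal: sample times starting at 0, the sample values, and the period.
#' The last sample lies strictly before `T`; the signal extends
#' periodically, `v(t + T) = v(t)`. Flows, pressures and lumen areas are
#' all carried in this container (the unit is declared by context).
#'
#' @param t numeric vector of sample times (s), uniformly spaced from 0.
#' @param v numeric vector of values, same length as `t`.
#' @param period cycle duration (s). Defaults to `last time + spacing`.
#' @return an object of class `waveform` with fields `t`, `v`, `T`.
#' @examples
#' wf <- waveform(seq(0, 0.79, by = 0.01), sin(2 * pi * seq(0, 0.79, by = 0.01) / 0.8))
#' cycle_mean(wf)
#' @export
waveform <- function(t, v, period = NULL) {
  t <- as.numeric(t); v <- as.numeric(v)
  if (length(t) != length(v)) stop("t and v must have the same length", call. = FALSE)
  if (length(t) < 2L) stop("a waveform needs at least 2 samples", call. = FALSE)
  stopifnot_finite(t, "waveform times"); stopifnot_finite(v, "waveform values")
  if (abs(t[1L]) > 1e-12) stop("sample times must start at 0", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("sample times must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-9 * max(dt)) {
    stop("sample spacing must be uniform", call. = FALSE)
  }
  h <- mean(dt)
  if (is.null(period)) period <- t[length(t)] + h
  period <- as.numeric(period)
  if (!is.finite(period) || period <= t[length(t)]) {
    stop("period must exceed the last sample time", call. = FALSE)
  }
  structure(list(t = t, v = v, T = period), class = "waveform")
}

is_waveform <- function(x) inherits(x, "waveform")

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples, dt = %.4g s, period = %.4g s\n",
              length(x$t), x$t[2L] - x$t[1L], x$T))
  cat(sprintf("  range [%.4g, %.4g], cycle mean %.4g\n",
              min(x$v), max(x$v), cycle_mean(x)))
  invisible(x)
}

wf_dt <- function(wf) wf$t[2L] - wf$t[1L]

#' Cycle mean of a periodic waveform
#'
#' For a uniformly sampled periodic signal the trapezoidal mean over the
#' periodic closure of one cycle is the arithmetic mean of the samples.
#'
#' @param wf a [waveform].
#' @return scalar mean value over one period.
#' @export
cycle_mean <- function(wf) {
  stopifnot(is_waveform(wf))
  mean(wf$v)
}

#' Integral of a waveform over one period
#'
#' Trapezoidal quadrature on the periodic closure (equals `mean(v) * T`
#' for uniform sampling).
#'
#' @param wf a [waveform].
#' @return scalar integral value (units of `v` times seconds).
#' @export
cycle_integral <- function(wf) {
  stopifnot(is_waveform(wf))
  mean(wf$v) * wf$T
}

#' Evaluate a waveform at arbitrary times by periodic linear interpolation
#'
#' @param wf a [waveform].
#' @param t_new times (s) at which to evaluate; wrapped modulo the period.
#' @return numeric vector of interpolated values.
#' @export
wf_interp <- function(wf, t_new) {
  stopifnot(is_waveform(wf))
  tt <- t_new %% wf$T
  # closed cycle: append the first sample at t = T so interpolation wraps
  stats::approx(c(wf$t, wf$T), c(wf$v, wf$v[1L]), xout = tt, rule = 2)$y
}

#' Resample a waveform onto a uniform grid with n samples per cycle
#'
#' @param wf a [waveform].
#' @param n number of samples in the resampled cycle.
#' @return a [waveform] on `seq(0, T - T/n, length.out = n)`.
#' @export
wf_resample <- function(wf, n) {
  t_new <- seq(0, wf$T, length.out = n + 1L)[seq_len(n)]
  waveform(t_new, wf_interp(wf, t_new), wf$T)
}

# shift a waveform in time (positive tau delays the signal)
wf_shift <- function(wf, tau) {
  waveform(wf$t, wf_interp(wf, wf$t - tau), wf$T)
}
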