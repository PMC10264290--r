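#' Periodic volumetric flow waveform
#'
#' A `flow_waveform` is a tibble with columns `time_s` and `flow_mL_s`
#' describing one cardiac cycle, plus a `period_s` attribute. Samples must
#' start at `time_s = 0`, be strictly increasing, and lie inside `[0, T)`;
#' the waveform is extended periodically, so the value at `T` is the value
#' at `0`.
#'
#' @param times Sample instants in seconds, starting at 0, strictly
#'   increasing, all `< period`.
#' @param flows Volumetric flow in mL/s at each instant.
#' @param period Cycle period T in seconds.
#' @return A `flow_waveform` tibble.
#' @examples
#' wf <- flow_waveform(seq(0, 0.9, by = 0.1), rep(5, 10), period = 1)
#' waveform_mean(wf)
#' @export
flow_waveform <- function(times, flows, period) {
  if (length(times) != length(flows)) {
    abort("`times` and `flows` must have equal length.")
  }
  if (length(times) < 2) abort("A waveform needs at least 2 samples.")
  if (!isTRUE(period > 0)) abort("`period` must be a positive scalar.")
  if (times[1] != 0) abort("`times` must start at 0.")
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  if (times[length(times)] >= period) {
    abort("All `times` must be strictly less than `period`.")
  }
  if (any(!is.finite(flows))) abort("`flows` must be finite.")
  out <- tibble(time_s = as.numeric(times), flow_mL_s = as.numeric(flows))
  structure(out, period_s = as.numeric(period),
            class = c("flow_waveform", class(out)))
}

#' @export
#' @rdname flow_waveform
#' @param x Object to test or query.
is_flow_waveform <- function(x) inherits(x, "flow_waveform")

#' @export
#' @rdname flow_waveform
waveform_period <- function(x) {
  stopifnot(is_flow_waveform(x))
  attr(x, "period_s")
}

# Periodic trapezoidal cycle integral of y(t) sampled on [0, T):
# the wrap interval [t_n, T] closes with y(T) = y(0).
periodic_trapz <- function(times, values, period) {
  t_ext <- c(times, period)
  y_ext <- c(values, values[1])
  sum(diff(t_ext) * (head(y_ext, -1) + tail(y_ext, -1)) / 2)
}

#' Cycle-mean of a periodic waveform
#'
#' Integrates one cycle with the trapezoidal rule, closing the wrap
#' interval periodically, and divides by the period.
#'
#' @param wf A [flow_waveform()].
#' @return Cycle-mean flow in mL/s.
#' @export
waveform_mean <- function(wf) {
  stopifnot(is_flow_waveform(wf))
  periodic_trapz(wf$time_s, wf$flow_mL_s, waveform_period(wf)) /
    waveform_period(wf)
}

#' Resample a waveform onto a uniform grid
#'
#' Linear interpolation with periodic wrap-around. If `dt` does not divide
#' the period to within one part in 1e6 the step is adjusted to the nearest
#' exact divisor (`period / round(period / dt)`).
#'
#' @param wf A [flow_waveform()].
#' @param dt Target timestep in seconds.
#' @return A `flow_waveform` on a uniform grid of step (near) `dt`.
#' @export
waveform_resample <- function(wf, dt) {
  stopifnot(is_flow_waveform(wf), dt > 0)
  period <- waveform_period(wf)
  n <- max(2L, as.integer(round(period / dt)))
  grid <- seq(0, period, length.out = n + 1L)[seq_len(n)]
  t_ext <- c(wf$time_s, period)
  y_ext <- c(wf$flow_mL_s, wf$flow_mL_s[1])
  vals <- approx(t_ext, y_ext, xout = grid, method = "linear")$y
  flow_waveform(grid, vals, period)
}

# Evaluate a waveform at arbitrary times (periodic linear interpolation).
waveform_at <- function(wf, t) {
  period <- waveform_period(wf)
  tt <- t %% period
  t_ext <- c(wf$time_s, period)
  y_ext <- c(wf$flow_mL_s, wf$flow_mL_s[1])
  approx(t_ext, y_ext, xout = tt, method = "linear")$y
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("<flow_waveform: %d samples, T = %.4f s, mean = %.3f mL/s>\n",
              nrow(x), waveform_period(x), waveform_mean(x)))
  NextMethod()
}
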