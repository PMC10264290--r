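#' Forward/reverse decomposition of plane flow
#'
#' Splits the instantaneous plane flow into the forward component
#' `Q_F` (sum over samples with strictly positive normal projection) and
#' the reverse component `Q_R` (magnitude of the sum over strictly
#' negative projections), so `Q = Q_F - Q_R`. Samples with exactly zero
#' projection contribute to neither.
#'
#' @param frame A [plane_frame()].
#' @return One-row tibble: `q_mL_s`, `q_forward_mL_s`, `q_reverse_mL_s`.
#' @export
decompose_flow <- function(frame) {
  n <- plane_normal(frame)
  vn <- frame$vx_m_s * n[1] + frame$vy_m_s * n[2] + frame$vz_m_s * n[3]
  qa <- vn * frame$area_mm2
  qf <- sum(qa[vn > 0])
  qr <- -sum(qa[vn < 0])
  tibble(q_mL_s = sum(qa), q_forward_mL_s = qf, q_reverse_mL_s = qr)
}

#' @rdname decompose_flow
#' @param series A [plane_series()].
#' @return For `flow_decomposition()`: a tibble with one row per frame
#'   (`t_s`, `q_mL_s`, `q_forward_mL_s`, `q_reverse_mL_s`) carrying the
#'   series period as attribute `period_s`.
#' @export
flow_decomposition <- function(series) {
  period <- attr(series, "period_s")
  if (is.null(period)) abort("`series` must be a plane_series.")
  frames <- series_frames(series)
  out <- bind_rows(lapply(frames, decompose_flow))
  out <- mutate(out, t_s = as.numeric(names(frames)), .before = 1)
  attr(out, "period_s") <- period
  out
}

#' Reverse-to-forward flow ratio
#'
#' Instantaneous `R/F = Q_R / Q_F`, and its cycle average
#' `(1/T) * integral(Q_R/Q_F dt)` by periodic trapezoid over the metric
#' grid. Instants with no forward flow leave the ratio undefined: the
#' default policy excludes them (with a warning) and averages over the
#' remaining covered time; `"error"` aborts instead.
#'
#' @param q_forward,q_reverse Instantaneous flows in mL/s.
#' @return `rf_ratio()`: the instantaneous ratio(s).
#' @export
rf_ratio <- function(q_forward, q_reverse) {
  if (any(q_reverse < 0) || any(q_forward < 0)) {
    abort("Decomposed flows must be non-negative.")
  }
  ifelse(q_forward > 0, q_reverse / q_forward, NA_real_)
}

#' @rdname rf_ratio
#' @param decomposition Output of [flow_decomposition()] (or any data
#'   frame with `t_s`, `q_forward_mL_s`, `q_reverse_mL_s`).
#' @param period Cycle period in seconds; defaults to the `period_s`
#'   attribute of `decomposition`.
#' @param zero_forward Policy for instants with `Q_F = 0`: `"exclude"`
#'   (default, warns) or `"error"`.
#' @return `cycle_rf()`: the cycle-averaged ratio (dimensionless).
#' @export
cycle_rf <- function(decomposition, period = NULL,
                     zero_forward = c("exclude", "error")) {
  zero_forward <- match.arg(zero_forward)
  period <- period %||% attr(decomposition, "period_s")
  if (is.null(period)) abort("`period` is required.")
  r <- rf_ratio(decomposition$q_forward_mL_s, decomposition$q_reverse_mL_s)
  tt <- decomposition$t_s
  if (anyNA(r)) {
    if (zero_forward == "error") {
      abort("Instants with zero forward flow: R/F undefined (strict mode).")
    }
    warn(sprintf("%d instant(s) with zero forward flow excluded from R/F.",
                 sum(is.na(r))))
    keep <- !is.na(r)
    tt <- tt[keep]
    r <- r[keep]
    if (length(r) < 2) abort("Too few valid instants for a cycle average.")
    # average over the covered duration only
    return(sum(diff(tt) * (head(r, -1) + tail(r, -1)) / 2) /
             (tt[length(tt)] - tt[1]))
  }
  periodic_trapz(tt, r, period) / period
}

#' False-lumen ejection fraction
#'
#' The cycle-averaged reverse-to-forward flow ratio evaluated on the
#' primary entry tear plane, expressed as a percentage. Elevated values
#' are associated with false-lumen pressurisation and aortic growth.
#'
#' @inheritParams cycle_rf
#' @return FLEF in percent.
#' @export
flef <- function(decomposition, period = NULL,
                 zero_forward = c("exclude", "error")) {
  100 * cycle_rf(decomposition, period, zero_forward)
}
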