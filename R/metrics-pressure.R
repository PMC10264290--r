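#' Paired true/false-lumen pressure traces
#'
#' Validated container for area-averaged static pressure in the true and
#' false lumen on a common uniform-in-spirit time grid spanning one
#' cycle.
#'
#' @param time_s Sample instants in seconds (strictly increasing, from 0,
#'   all `< period`).
#' @param p_tl_mmHg,p_fl_mmHg Lumen pressure traces, mmHg.
#' @param period Cycle period in seconds.
#' @return A `lumen_pair` tibble with a `period_s` attribute.
#' @export
lumen_pair <- function(time_s, p_tl_mmHg, p_fl_mmHg, period) {
  if (length(time_s) != length(p_tl_mmHg) ||
      length(time_s) != length(p_fl_mmHg)) {
    abort("TL and FL traces must share the time grid.")
  }
  if (length(time_s) < 2) abort("At least 2 samples are required.")
  if (time_s[1] != 0 || any(diff(time_s) <= 0) ||
      time_s[length(time_s)] >= period) {
    abort("`time_s` must increase strictly from 0 and stay below `period`.")
  }
  out <- tibble(time_s = time_s, p_tl_mmHg = p_tl_mmHg,
                p_fl_mmHg = p_fl_mmHg)
  structure(out, period_s = as.numeric(period),
            class = unique(c("lumen_pair", class(out))))
}

#' Transmural pressure metrics
#'
#' Transmural pressure is `TMP(t) = P_TL(t) - P_FL(t)`; a positive value
#' means the true lumen is the more pressurised. `tmp_mean` is its cycle
#' average (periodic trapezoid) and `tmp_max` the instantaneous value of
#' largest absolute magnitude with its sign preserved. When several
#' instants tie in magnitude the earliest one wins.
#'
#' @param pair A [lumen_pair()].
#' @return One-row tibble: `tmp_mean_mmHg`, `tmp_max_mmHg`,
#'   `t_max_s` (instant at which the peak occurs).
#' @examples
#' p <- lumen_pair(seq(0, 0.9, 0.1), rep(10, 10), rep(8, 10), 1)
#' tmp_metrics(p)
#' @export
tmp_metrics <- function(pair) {
  if (!inherits(pair, "lumen_pair")) abort("`pair` must be a lumen_pair.")
  period <- attr(pair, "period_s")
  d <- pair$p_tl_mmHg - pair$p_fl_mmHg
  m <- periodic_trapz(pair$time_s, d, period) / period
  i <- which.max(abs(d))  # first index attaining the maximum magnitude
  tibble(tmp_mean_mmHg = m, tmp_max_mmHg = d[i], t_max_s = pair$time_s[i])
}
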