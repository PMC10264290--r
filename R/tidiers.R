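#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidiers for fitted and simulated objects
#'
#' `tidy()` returns per-component tables (outlet parameters and flows,
#' Bland-Altman point pairs); `glance()` one-row model-level summaries
#' (pressures, convergence, agreement limits).
#'
#' @param x A `wk3_sim`, `wk3_fit` or `bland_altman` object.
#' @param ... Unused.
#' @return A tibble.
#' @name dissectflow-tidiers
NULL

#' @rdname dissectflow-tidiers
#' @method tidy wk3_sim
#' @export
tidy.wk3_sim <- function(x, ...) cycle_summary(x)

#' @rdname dissectflow-tidiers
#' @method glance wk3_sim
#' @export
glance.wk3_sim <- function(x, ...) {
  s <- cycle_summary(x)
  tibble(p_sys_mmHg = attr(s, "p_sys_mmHg"),
         p_dia_mmHg = attr(s, "p_dia_mmHg"),
         p_pulse_mmHg = attr(s, "p_pulse_mmHg"),
         total_mean_flow_mL_s = sum(s$mean_flow_mL_s),
         cycles = max(x$cycles$cycle),
         converged = x$converged,
         dt_s = x$dt_s)
}

#' @rdname dissectflow-tidiers
#' @method tidy wk3_fit
#' @export
tidy.wk3_fit <- function(x, ...) x$params

#' @rdname dissectflow-tidiers
#' @method glance wk3_fit
#' @export
glance.wk3_fit <- function(x, ...) {
  tibble(p_sys_mmHg = x$achieved$p_sys_mmHg,
         p_dia_mmHg = x$achieved$p_dia_mmHg,
         p_sys_target_mmHg = x$targets$p_sys_mmHg,
         p_dia_target_mmHg = x$targets$p_dia_mmHg,
         max_flow_deviation = x$max_flow_deviation,
         iterations = max(x$iterations$iteration),
         converged = x$converged)
}

#' @rdname dissectflow-tidiers
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) x$pairs

#' @rdname dissectflow-tidiers
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_difference = x$sd_difference,
         loa_lower = x$loa_lower, loa_upper = x$loa_upper,
         n = nrow(x$pairs))
}
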