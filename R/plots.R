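#' Plots for waveforms, simulations and agreement analyses
#'
#' `autoplot()` methods return ggplot objects: the inflow waveform over
#' one cycle, the final-cycle inlet pressure and outlet flows of a
#' network simulation, and the classic Bland-Altman scatter with bias
#' and limits of agreement. `plot_wss_map()` draws a per-node scalar map
#' (e.g. TAWSS or ECAP) as a coloured point cloud in a chosen plane
#' projection.
#'
#' @param object Object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name dissectflow-plots
NULL

#' @rdname dissectflow-plots
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   labs facet_wrap
#' @method autoplot flow_waveform
#' @export
autoplot.flow_waveform <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$time_s, y = .data$flow_mL_s)) +
    geom_line() +
    labs(x = "time (s)", y = "flow (mL/s)",
         title = sprintf("Inflow waveform, T = %.3f s, mean %.1f mL/s",
                         waveform_period(object), waveform_mean(object)))
}

#' @rdname dissectflow-plots
#' @method autoplot wk3_sim
#' @export
autoplot.wk3_sim <- function(object, ...) {
  p <- object$network$params
  tr <- object$trace
  flows <- tidyr::pivot_longer(
    select(tr, "time_s", dplyr::all_of(paste0("q_", p$outlet))),
    -"time_s", names_to = "outlet", values_to = "flow_mL_s",
    names_prefix = "q_")
  pressure <- select(tr, "time_s", value = "p_inlet_mmHg") |>
    mutate(outlet = "inlet pressure (mmHg)")
  ggplot(flows, aes(x = .data$time_s, y = .data$flow_mL_s,
                    colour = .data$outlet)) +
    geom_line() +
    geom_line(data = pressure,
              aes(y = .data$value), colour = "black",
              linetype = "dashed") +
    labs(x = "time (s)", y = "outlet flow (mL/s); dashed: inlet P (mmHg)",
         title = "Final cycle at periodic steady state")
}

#' @rdname dissectflow-plots
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot(object$pairs, aes(x = .data$mean, y = .data$difference)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = object$bias, linetype = "dotted") +
    geom_hline(yintercept = c(object$loa_lower, object$loa_upper)) +
    labs(x = "pair mean", y = "difference",
         title = sprintf("Bland-Altman: bias %.3g, LoA [%.3g, %.3g]",
                         object$bias, object$loa_lower, object$loa_upper))
}

#' @rdname dissectflow-plots
#' @param nodes Data frame with `x_mm`, `y_mm` and the column `field`.
#' @param field Name of the scalar column to colour by.
#' @export
plot_wss_map <- function(nodes, field = "tawss_Pa") {
  nodes <- as_tibble(nodes)
  if (!field %in% names(nodes)) {
    abort(sprintf("Column `%s` not found.", field))
  }
  ggplot(nodes, aes(x = .data$x_mm, y = .data$y_mm,
                    colour = .data[[field]])) +
    geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c(name = field) +
    labs(x = "x (mm)", y = "y (mm)")
}
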