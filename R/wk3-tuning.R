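#' Scale WK3 parameters from an anchor outlet
#'
#' At periodic steady state a parallel WK3 network splits mean flow in
#' inverse proportion to total resistance, and a common RC time constant
#' across outlets makes the pressure response shape shared. Both
#' regularities let the full parameter table be generated from target
#' flows plus one anchor outlet's resistance and compliance:
#' `R_i = R_a * Q_a / Q_i` and `C_i = C_a * R_a / R_i`.
#'
#' @param targets Data frame with columns `outlet` and `target_flow_mL_s`.
#' @param anchor Name of the anchor outlet (must appear in `targets`).
#' @param anchor_r_total Anchor total resistance, mmHg/(mL/s).
#' @param anchor_compliance Anchor compliance, mL/mmHg.
#' @param rho Proximal fraction(s), recycled across outlets (default 0.056).
#' @return A [wk3_params()] table.
#' @examples
#' tab <- tibble::tibble(outlet = c("BT", "IMA"),
#'                       target_flow_mL_s = c(17.10, 1.93))
#' wk3_from_anchor(tab, "BT", 5.77, 0.235)
#' @export
wk3_from_anchor <- function(targets, anchor, anchor_r_total,
                            anchor_compliance, rho = 0.056) {
  targets <- as_tibble(targets)
  if (!all(c("outlet", "target_flow_mL_s") %in% names(targets))) {
    abort("`targets` needs columns `outlet` and `target_flow_mL_s`.")
  }
  if (!anchor %in% targets$outlet) {
    abort(sprintf("Anchor outlet `%s` not found in `targets`.", anchor))
  }
  if (any(targets$target_flow_mL_s <= 0)) {
    abort("Target flows must be positive to scale resistances.")
  }
  q_a <- targets$target_flow_mL_s[targets$outlet == anchor][1]
  r_tot <- anchor_r_total * q_a / targets$target_flow_mL_s
  compl <- anchor_compliance * anchor_r_total / r_tot
  wk3_params(targets$outlet, r_tot, rep_len(rho, nrow(targets)), compl)
}

#' Calibrate WK3 outlet parameters against flow and pressure targets
#'
#' Tunes the total resistances and compliances of a parallel WK3 network
#' so that re-simulating it with [simulate_network()] reproduces the
#' target per-outlet cycle-mean flows and the target systolic/diastolic
#' inlet pressures.
#'
#' The algorithm exploits the structure of the linear network:
#' \enumerate{
#'   \item Resistances are initialised as `R_i = Pbar0 / Q_i` with
#'     `Pbar0 = P_d + (P_s - P_d) / 3` (a mean-pressure estimate), so the
#'     mean flow split is satisfied by construction and stays satisfied
#'     under any common scaling.
#'   \item Compliance is distributed as `C_i` proportional to `1 / R_i`
#'     (equal RC time constants across outlets).
#'   \item Two global scale factors alternate: the resistance scale is
#'     driven by the ratio of target to simulated mean pressure proxy
#'     `(P_s + 2 P_d) / 3`, and the compliance scale by the ratio of
#'     simulated to target pulse pressure. Each iteration re-simulates to
#'     cyclic periodicity.
#' }
#' Proximal fractions `rho` are configuration, never tuned.
#'
#' @param targets Data frame with columns `outlet`, `target_flow_mL_s`
#'   and optionally `rho` (default 0.056 where absent).
#' @param pressure_targets One-row data frame with `systolic_mmHg` and
#'   `diastolic_mmHg` (e.g. [aortic_pressure_targets()]).
#' @param inflow A [flow_waveform()] whose cycle mean matches the summed
#'   target flows within `flow_consistency_tol`.
#' @param total_compliance_init Starting total compliance in mL/mmHg
#'   (default 1.5, a typical systemic value).
#' @param pressure_tol Absolute tolerance on achieved systolic and
#'   diastolic pressure, mmHg (default 1).
#' @param flow_tol Relative tolerance on achieved mean flows
#'   (default 0.03).
#' @param flow_consistency_tol Allowed relative mismatch between summed
#'   targets and the inflow cycle mean (default 0.005).
#' @param max_iter Iteration budget (default 30).
#' @param dt,convergence,max_cycles Passed to [simulate_network()].
#' @param venous_pressure_mmHg Distal reference pressure (default 0).
#' @return A `wk3_fit` object: `$params` (tuned [wk3_params()] table with
#'   `target_flow_mL_s` and achieved `mean_flow_mL_s`), `$iterations`
#'   (per-iteration pressures and scale factors), `$achieved`
#'   (systolic/diastolic/pulse), `$targets`, `$converged`, `$sim` (final
#'   simulation).
#' @export
tune_wk3 <- function(targets, pressure_targets, inflow,
                     total_compliance_init = 1.5,
                     pressure_tol = 1, flow_tol = 0.03,
                     flow_consistency_tol = 0.005,
                     max_iter = 30L, dt = 1e-3, convergence = 0.01,
                     max_cycles = 50L, venous_pressure_mmHg = 0) {
  targets <- as_tibble(targets)
  if (!all(c("outlet", "target_flow_mL_s") %in% names(targets))) {
    abort("`targets` needs columns `outlet` and `target_flow_mL_s`.")
  }
  if (any(targets$target_flow_mL_s <= 0)) {
    abort("Target flows must be positive.")
  }
  if (!"rho" %in% names(targets)) targets$rho <- 0.056
  p_s <- pressure_targets$systolic_mmHg[1]
  p_d <- pressure_targets$diastolic_mmHg[1]
  if (!isTRUE(p_s > p_d)) {
    abort("Infeasible pressure targets: systolic must exceed diastolic.")
  }
  pp_target <- p_s - p_d
  if (pp_target <= 1e-9) abort("Zero pulse pressure target is infeasible.")
  q_target <- targets$target_flow_mL_s
  q_total <- sum(q_target)
  q_mean_in <- waveform_mean(inflow)
  if (abs(q_mean_in - q_total) / q_total > flow_consistency_tol) {
    abort(sprintf(paste0(
      "Inconsistent spec: summed target flows (%.3f mL/s) and inflow ",
      "cycle mean (%.3f mL/s) differ by more than %.2f%%."),
      q_total, q_mean_in, 100 * flow_consistency_tol))
  }

  p_ven <- venous_pressure_mmHg
  pbar0 <- p_d + (p_s - p_d) / 3
  r_tot <- (pbar0 - p_ven) / q_target
  c_tot <- total_compliance_init
  inv_r <- 1 / r_tot
  proxy_target <- (p_s + 2 * p_d) / 3

  iters <- list()
  converged <- FALSE
  sim <- NULL
  for (it in seq_len(max_iter)) {
    compl <- c_tot * inv_r / sum(inv_r)
    net <- wk3_network(wk3_params(targets$outlet, r_tot, targets$rho, compl),
                       venous_pressure_mmHg = p_ven)
    # start each capacitor at its periodic-steady-state mean so the
    # convergence rule measures periodicity, not the charging transient
    pc0 <- p_ven + (proxy_target - p_ven) * (1 - targets$rho)
    sim <- simulate_network(net, inflow, dt = dt, convergence = convergence,
                            max_cycles = max_cycles, init_pressure = pc0)
    s <- cycle_summary(sim)
    ps_sim <- attr(s, "p_sys_mmHg")
    pd_sim <- attr(s, "p_dia_mmHg")
    pp_sim <- ps_sim - pd_sim
    proxy_sim <- (ps_sim + 2 * pd_sim) / 3
    iters[[it]] <- tibble(iteration = it,
                          p_sys_mmHg = ps_sim, p_dia_mmHg = pd_sim,
                          r_scale = NA_real_, c_scale = NA_real_)
    if (abs(ps_sim - p_s) <= pressure_tol &&
        abs(pd_sim - p_d) <= pressure_tol) {
      converged <- TRUE
      break
    }
    r_scale <- (proxy_target - p_ven) / (proxy_sim - p_ven)
    c_scale <- pp_sim / pp_target
    r_tot <- r_tot * r_scale
    c_tot <- c_tot * c_scale
    iters[[it]]$r_scale <- r_scale
    iters[[it]]$c_scale <- c_scale
  }
  iterations <- bind_rows(iters)
  if (!converged) {
    abort("WK3 tuning did not converge within `max_iter` iterations.",
          class = "dissectflow_no_convergence", iterations = iterations)
  }

  s <- cycle_summary(sim)
  params <- sim$network$params |>
    left_join(tibble(outlet = targets$outlet,
                     target_flow_mL_s = q_target), by = "outlet") |>
    left_join(s, by = "outlet")
  flow_dev <- abs(params$mean_flow_mL_s - params$target_flow_mL_s) /
    params$target_flow_mL_s
  if (any(flow_dev > flow_tol)) {
    warn(sprintf("Largest mean-flow deviation %.2f%% exceeds flow_tol.",
                 100 * max(flow_dev)))
  }
  structure(
    list(params = params, iterations = iterations,
         achieved = tibble(p_sys_mmHg = attr(s, "p_sys_mmHg"),
                           p_dia_mmHg = attr(s, "p_dia_mmHg"),
                           p_pulse_mmHg = attr(s, "p_pulse_mmHg")),
         targets = tibble(p_sys_mmHg = p_s, p_dia_mmHg = p_d,
                          p_pulse_mmHg = pp_target),
         max_flow_deviation = max(flow_dev),
         converged = converged, sim = sim),
    class = "wk3_fit"
  )
}

#' @export
print.wk3_fit <- function(x, ...) {
  cat(sprintf(
    "<wk3_fit: %d outlets tuned in %d iterations; P %0.1f/%0.1f mmHg (target %0.1f/%0.1f)>\n",
    nrow(x$params), max(x$iterations$iteration),
    x$achieved$p_sys_mmHg, x$achieved$p_dia_mmHg,
    x$targets$p_sys_mmHg, x$targets$p_dia_mmHg))
  print(x$params)
  invisible(x)
}
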