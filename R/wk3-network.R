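#' Three-element Windkessel parameter table
#'
#' Builds and validates a WK3 parameter tibble. Each outlet is a proximal
#' resistance `R_p = rho * R_tot` in series with a parallel distal
#' resistance `R_d = (1 - rho) * R_tot` and compliance `C`, referenced to
#' a venous pressure.
#'
#' @param outlet Character vector of outlet names (unique).
#' @param r_total Total resistance, mmHg/(mL/s), positive.
#' @param rho Proximal resistance fraction, strictly inside (0, 1).
#' @param compliance Compliance, mL/mmHg, positive.
#' @return Tibble with columns `outlet`, `r_total_mmHg_per_mL_s`, `rho`,
#'   `c_mL_per_mmHg`, `r_prox_mmHg_per_mL_s`, `r_dist_mmHg_per_mL_s`.
#' @examples
#' wk3_params("BT", 5.77, 0.030, 0.235)
#' @export
wk3_params <- function(outlet, r_total, rho, compliance) {
  n <- length(outlet)
  if (n == 0) abort("At least one outlet is required.")
  if (anyDuplicated(outlet)) abort("Outlet names must be unique.")
  if (length(r_total) != n || length(rho) != n || length(compliance) != n) {
    abort("`r_total`, `rho` and `compliance` must match `outlet` in length.")
  }
  if (any(!is.finite(r_total)) || any(r_total <= 0)) {
    abort("`r_total` must be positive and finite.")
  }
  if (any(!is.finite(rho)) || any(rho <= 0) || any(rho >= 1)) {
    abort("`rho` must lie strictly inside (0, 1).")
  }
  if (any(!is.finite(compliance)) || any(compliance <= 0)) {
    abort("`compliance` must be positive and finite.")
  }
  tibble(
    outlet = as.character(outlet),
    r_total_mmHg_per_mL_s = as.numeric(r_total),
    rho = as.numeric(rho),
    c_mL_per_mmHg = as.numeric(compliance),
    r_prox_mmHg_per_mL_s = as.numeric(rho * r_total),
    r_dist_mmHg_per_mL_s = as.numeric((1 - rho) * r_total)
  )
}

#' Assemble a parallel network of WK3 outlets
#'
#' All outlets share a single inlet node (the aortic root of the lumped
#' model) and drain to a common venous reference pressure. The network has
#' one state variable per outlet: the pressure on its compliance.
#'
#' @param outlets A WK3 parameter table ([wk3_params()] or any data frame
#'   with columns `outlet`, `r_total_mmHg_per_mL_s`, `rho`,
#'   `c_mL_per_mmHg`).
#' @param venous_pressure_mmHg Distal reference pressure (default 0).
#' @return A `wk3_network` object.
#' @export
wk3_network <- function(outlets, venous_pressure_mmHg = 0) {
  outlets <- as_tibble(outlets)
  req <- c("outlet", "r_total_mmHg_per_mL_s", "rho", "c_mL_per_mmHg")
  miss <- setdiff(req, names(outlets))
  if (length(miss) > 0) {
    abort(sprintf("`outlets` is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  params <- wk3_params(outlets$outlet, outlets$r_total_mmHg_per_mL_s,
                       outlets$rho, outlets$c_mL_per_mmHg)
  structure(
    list(params = params,
         venous_pressure_mmHg = as.numeric(venous_pressure_mmHg)),
    class = "wk3_network"
  )
}

#' @export
print.wk3_network <- function(x, ...) {
  cat(sprintf("<wk3_network: %d parallel outlets, P_ven = %g mmHg>\n",
              nrow(x$params), x$venous_pressure_mmHg))
  print(x$params)
  invisible(x)
}

#' Simulate a WK3 network to cyclic periodicity
#'
#' Integrates, for each outlet i, the capacitor-pressure ODE
#' `C_i dPc_i/dt = (P - Pc_i)/Rp_i - (Pc_i - P_ven)/Rd_i`, closed by the
#' inlet node law `sum_i (P - Pc_i)/Rp_i = Q_in(t)`, i.e.
#' `P = (Q_in + sum Pc_i/Rp_i) / sum(1/Rp_i)`. The scheme is the implicit
#' second-order backward differentiation formula (BDF2; backward Euler for
#' the first step), which is unconditionally stable on this linear system.
#' Whole cycles are run until systolic and diastolic inlet pressure both
#' change by less than `convergence` (relative) between consecutive
#' cycles; the final cycle is returned.
#'
#' @param network A [wk3_network()].
#' @param inflow A [flow_waveform()] driving the inlet node.
#' @param dt Timestep in seconds (default 0.001). Adjusted to the nearest
#'   exact divisor of the period when needed.
#' @param convergence Relative per-cycle change threshold on systolic and
#'   diastolic pressure (default 0.01); both must pass in the same cycle.
#' @param max_cycles Cycle budget (default 50); exceeding it is an error
#'   carrying the per-cycle history.
#' @param init_pressure Initial capacitor pressure in mmHg, a scalar or
#'   one value per outlet (default the venous pressure); a diastolic or
#'   steady-state estimate shortens the transient without changing the
#'   converged cycle.
#' @return A `wk3_sim` object: `$trace` (tibble: `time_s`,
#'   `p_inlet_mmHg`, `q_in_mL_s`, then per-outlet flow `q_*` and capacitor
#'   pressure `pc_*` columns for the final cycle), `$cycles` (per-cycle
#'   systolic/diastolic history), `$network`, `$converged`, `$dt_s`,
#'   `$period_s`.
#' @examples
#' net <- wk3_network(wk3_params("out", 10, 0.1, 1))
#' wf <- flow_waveform(seq(0, 0.99, 0.01), rep(10, 100), 1)
#' sim <- simulate_network(net, wf)
#' glance(sim)
#' @export
simulate_network <- function(network, inflow, dt = 1e-3, convergence = 0.01,
                             max_cycles = 50L, init_pressure = NULL) {
  stopifnot(inherits(network, "wk3_network"))
  if (!is_flow_waveform(inflow)) abort("`inflow` must be a flow_waveform.")
  if (!isTRUE(dt > 0)) abort("`dt` must be positive.")
  if (!isTRUE(convergence > 0 && convergence < 1)) {
    abort("`convergence` must lie in (0, 1).")
  }
  period <- waveform_period(inflow)
  n_steps <- as.integer(round(period / dt))
  if (n_steps < 4) abort("`dt` is too coarse for the waveform period.")
  dt_eff <- period / n_steps
  if (abs(dt_eff - dt) / dt > 1e-6) {
    # dt does not divide T: use the nearest exact divisor
    dt <- dt_eff
  } else {
    dt <- dt_eff
  }

  p <- network$params
  p_ven <- network$venous_pressure_mmHg
  rp <- p$r_prox_mmHg_per_mL_s
  rd <- p$r_dist_mmHg_per_mL_s
  cc <- p$c_mL_per_mmHg
  n_out <- nrow(p)
  s_rp <- sum(1 / rp)

  # inflow sampled on the step grid (index k = time (k-1)*dt)
  tgrid <- (seq_len(n_steps) - 1) * dt
  q_grid <- waveform_at(inflow, tgrid)

  init_pressure <- init_pressure %||% p_ven
  if (!length(init_pressure) %in% c(1L, n_out)) {
    abort("`init_pressure` must be a scalar or one value per outlet.")
  }
  pc <- rep_len(init_pressure, n_out)
  pc_prev <- pc
  first_step <- TRUE

  cycles <- list()
  p_s_prev <- NA_real_
  p_d_prev <- NA_real_
  converged <- FALSE

  p_trace <- numeric(n_steps)
  pc_trace <- matrix(0, n_steps, n_out)
  q_trace <- matrix(0, n_steps, n_out)

  for (cycle in seq_len(max_cycles)) {
    for (k in seq_len(n_steps)) {
      # state at end of step k corresponds to time k*dt; inflow evaluated
      # implicitly at the new time level
      q_new <- q_grid[if (k == n_steps) 1L else k + 1L]
      if (first_step) {
        beta <- cc / dt + 1 / rp + 1 / rd
        alpha <- cc * pc / dt + p_ven / rd
      } else {
        beta <- 1.5 * cc / dt + 1 / rp + 1 / rd
        alpha <- cc * (2 * pc - 0.5 * pc_prev) / dt + p_ven / rd
      }
      denom <- s_rp - sum(1 / (beta * rp^2))
      p_node <- (q_new + sum(alpha / (beta * rp))) / denom
      pc_new <- (alpha + p_node / rp) / beta
      pc_prev <- pc
      pc <- pc_new
      first_step <- FALSE
      p_trace[k] <- p_node
      pc_trace[k, ] <- pc_new
      q_trace[k, ] <- (p_node - pc_new) / rp
    }
    p_s <- max(p_trace)
    p_d <- min(p_trace)
    cycles[[cycle]] <- tibble(cycle = cycle, p_sys_mmHg = p_s,
                              p_dia_mmHg = p_d)
    if (cycle > 1) {
      ds <- abs(p_s - p_s_prev) / abs(p_s_prev)
      dd <- abs(p_d - p_d_prev) / abs(p_d_prev)
      if (ds < convergence && dd < convergence) {
        converged <- TRUE
      }
    }
    p_s_prev <- p_s
    p_d_prev <- p_d
    if (converged) break
  }
  cycles <- bind_rows(cycles)
  if (!converged) {
    abort(paste0("Network did not reach cyclic periodicity within ",
                 max_cycles, " cycles."),
          class = "dissectflow_no_convergence",
          cycles = cycles)
  }

  # trace times are the ends of each step, 1*dt .. T (wrap sample at T)
  trace <- tibble(time_s = seq_len(n_steps) * dt,
                  q_in_mL_s = q_grid[c(seq(2, n_steps), 1L)],
                  p_inlet_mmHg = p_trace)
  qcols <- as_tibble(as.data.frame(q_trace))
  names(qcols) <- paste0("q_", p$outlet)
  pccols <- as_tibble(as.data.frame(pc_trace))
  names(pccols) <- paste0("pc_", p$outlet)
  trace <- dplyr::bind_cols(trace, qcols, pccols)

  structure(
    list(trace = trace, cycles = cycles, network = network,
         converged = converged, dt_s = dt, period_s = period),
    class = "wk3_sim"
  )
}

#' Per-cycle summary of a converged network simulation
#'
#' Cycle-mean outlet flows are trapezoidal integrals of the final cycle
#' (the uniform grid covers exactly one period, so this is the sample
#' mean); systolic/diastolic pressures are the extrema of the final-cycle
#' inlet pressure.
#'
#' @param sim A `wk3_sim` from [simulate_network()].
#' @return Tibble with one row per outlet: `outlet`, `mean_flow_mL_s`,
#'   plus attributes `p_sys_mmHg`, `p_dia_mmHg`, `p_pulse_mmHg`
#'   (also available via [glance.wk3_sim()]).
#' @export
cycle_summary <- function(sim) {
  stopifnot(inherits(sim, "wk3_sim"))
  p <- sim$network$params
  qm <- vapply(paste0("q_", p$outlet),
               function(cn) mean(sim$trace[[cn]]), numeric(1))
  out <- tibble(outlet = p$outlet, mean_flow_mL_s = unname(qm))
  attr(out, "p_sys_mmHg") <- max(sim$trace$p_inlet_mmHg)
  attr(out, "p_dia_mmHg") <- min(sim$trace$p_inlet_mmHg)
  attr(out, "p_pulse_mmHg") <- max(sim$trace$p_inlet_mmHg) -
    min(sim$trace$p_inlet_mmHg)
  out
}

#' @export
print.wk3_sim <- function(x, ...) {
  cat(sprintf(
    "<wk3_sim: %d outlets, %d cycles to periodicity, dt = %g ms>\n",
    nrow(x$network$params), max(x$cycles$cycle), 1000 * x$dt_s))
  s <- cycle_summary(x)
  cat(sprintf("  inlet P %0.1f/%0.1f mmHg; outlet mean flows sum %0.2f mL/s\n",
              attr(s, "p_sys_mmHg"), attr(s, "p_dia_mmHg"),
              sum(s$mean_flow_mL_s)))
  invisible(x)
}
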