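test_that("constant inflow settles to the Ohmic operating point", {
  net <- wk3_network(wk3_params("out", 10, 0.1, 1))
  wf <- flow_waveform(seq(0, 0.99, 0.01), rep(10, 100), 1)
  sim <- simulate_network(net, wf, init_pressure = 90)
  g <- glance(sim)
  expect_equal(g$p_sys_mmHg, 100, tolerance = 1e-6)
  expect_equal(g$p_dia_mmHg, 100, tolerance = 1e-6)
  s <- cycle_summary(sim)
  expect_equal(attr(s, "p_pulse_mmHg"), 0, tolerance = 1e-6)
  expect_equal(s$mean_flow_mL_s, 10, tolerance = 1e-8)
})

test_that("node law enforces mass conservation at every step", {
  set.seed(42)
  for (rep in 1:3) {
    n_out <- sample(2:6, 1)
    params <- wk3_params(paste0("o", seq_len(n_out)),
                         r_total = runif(n_out, 2, 50),
                         rho = runif(n_out, 0.03, 0.3),
                         compliance = runif(n_out, 0.02, 0.3))
    sim <- simulate_network(wk3_network(params), sine_inflow(q_mean = 100),
                            init_pressure = 80)
    qsum <- rowSums(as.matrix(
      sim$trace[paste0("q_", params$outlet)]))
    rel <- max(abs(qsum - sim$trace$q_in_mL_s)) / max(abs(qsum))
    expect_lt(rel, 1e-8)
  }
})

test_that("mean flow split follows 1/R_tot, independent of rho, C, waveform", {
  params <- wk3_params(c("a", "b", "c"), c(4, 8, 16),
                       c(0.03, 0.28, 0.056), c(0.3, 0.05, 0.11))
  expected <- 100 * (1 / c(4, 8, 16)) / sum(1 / c(4, 8, 16))
  for (wf in list(sine_inflow(100, 0.5), sine_inflow(100, 0.9, n = 500))) {
    sim <- simulate_network(wk3_network(params), wf,
                            convergence = 1e-3, init_pressure = 80)
    s <- cycle_summary(sim)
    expect_equal(s$mean_flow_mL_s, expected, tolerance = 2e-3)
    # periodic steady state: mean flow equals mean pressure over R_tot
    pbar <- mean(sim$trace$p_inlet_mmHg)
    expect_equal(s$mean_flow_mL_s, pbar / params$r_total_mmHg_per_mL_s,
                 tolerance = 2e-3)
  }
})

test_that("simulated pressure matches the analytic WK3 impedance", {
  r_tot <- 1.0; rho <- 0.1; cc <- 1.2
  w <- 2 * pi / period_study
  wf <- sine_inflow(q_mean = 10, rel_amp = 0.5)
  sim <- simulate_network(wk3_network(wk3_params("o", r_tot, rho, cc)), wf,
                          convergence = 1e-5, max_cycles = 300,
                          init_pressure = 10)
  p <- sim$trace$p_inlet_mmHg
  tt <- sim$trace$time_s
  z <- wk3_impedance(r_tot, rho, cc, w)
  c1 <- 2 * mean(p * exp(-1i * w * tt))          # first-harmonic phasor
  amp_ref <- Mod(5 * z)                          # Q1 = 10 * 0.5
  expect_lt(abs(Mod(c1) - amp_ref) / amp_ref, 1e-3)
  phase_err <- Arg(c1 / (5 * z * exp(-1i * pi / 2))) * 180 / pi
  expect_lt(abs(phase_err), 1)
  expect_equal(mean(p), 10 * r_tot, tolerance = 1e-3)
})

test_that("halving the timestep barely moves the converged extrema", {
  params <- wk3_params(c("a", "b"), c(5, 15), c(0.05, 0.05), c(0.2, 0.07))
  wf <- sine_inflow(q_mean = 60, rel_amp = 0.8)
  g1 <- glance(simulate_network(wk3_network(params), wf, dt = 1e-3,
                                convergence = 1e-4, init_pressure = 50))
  g2 <- glance(simulate_network(wk3_network(params), wf, dt = 5e-4,
                                convergence = 1e-4, init_pressure = 50))
  expect_lt(abs(g1$p_sys_mmHg - g2$p_sys_mmHg) / g2$p_sys_mmHg, 1e-3)
  expect_lt(abs(g1$p_dia_mmHg - g2$p_dia_mmHg) / g2$p_dia_mmHg, 1e-3)
})

test_that("study outlet tables are consistent with a common perfusion pressure", {
  tab <- study_wk3_table("D")
  rq <- tab$r_total_mmHg_per_mL_s * tab$target_flow_mL_s
  expect_lt(max(abs(rq - mean(rq))) / mean(rq), 0.002)
  expect_equal(nrow(tab), 11)
  expect_equal(nrow(study_wk3_table("D_min")), 16)
})

test_that("failure to reach periodicity raises an informative error", {
  net <- wk3_network(wk3_params("slow", 10, 0.1, 20))
  wf <- sine_inflow(q_mean = 10)
  err <- expect_error(
    simulate_network(net, wf, max_cycles = 2L, init_pressure = 0),
    class = "dissectflow_no_convergence")
  expect_s3_class(err$cycles, "tbl_df")
  expect_equal(nrow(err$cycles), 2)
})

test_that("degenerate networks and inputs are rejected", {
  expect_error(wk3_params(character(), numeric(), numeric(), numeric()),
               "At least one")
  expect_error(wk3_params("a", -1, 0.1, 1), "positive")
  expect_error(wk3_params("a", 1, 1.2, 1), "strictly inside")
  params <- wk3_params("a", 1, 0.1, 1)
  expect_identical(params$r_prox_mmHg_per_mL_s +
                     params$r_dist_mmHg_per_mL_s,
                   params$r_total_mmHg_per_mL_s)
})
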