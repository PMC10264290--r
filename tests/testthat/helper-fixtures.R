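# Shared fixtures: small, fast synthetic inputs built in code.

hr_study <- 94
period_study <- 60 / hr_study

# sinusoidal single-harmonic inflow for analytic comparisons
sine_inflow <- function(q_mean = 10, rel_amp = 0.5, period = period_study,
                        n = 640) {
  tt <- seq(0, period, length.out = n + 1)[seq_len(n)]
  flow_waveform(tt, q_mean * (1 + rel_amp * sin(2 * pi * tt / period)),
                period)
}

# closed-form WK3 input impedance at angular frequency w
wk3_impedance <- function(r_total, rho, compliance, w) {
  rp <- rho * r_total
  rd <- (1 - rho) * r_total
  rp + rd / (1 + 1i * w * rd * compliance)
}

# static disc frame with prescribed uniform normal velocity
uniform_frame <- function(vn_m_s, n_points = 100, radius_mm = 20) {
  i <- seq_len(n_points)
  r <- radius_mm * sqrt((i - 0.5) / n_points)
  th <- 2 * pi * i * ((1 + sqrt(5)) / 2)^-2
  plane_frame(
    tibble::tibble(x_mm = r * cos(th), y_mm = r * sin(th), z_mm = 0,
                   vx_m_s = 0, vy_m_s = 0, vz_m_s = vn_m_s,
                   area_mm2 = pi * radius_mm^2 / n_points),
    normal = c(0, 0, 1))
}

case_d_params <- function() {
  tab <- study_wk3_table("D")
  wk3_params(tab$outlet, tab$r_total_mmHg_per_mL_s, tab$rho,
             tab$c_mL_per_mmHg)
}
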