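test_that("registration is exact for identity and pure translation", {
  gen <- gen_plane_series(synth_spec(n_points = 60, n_frames = 4),
                          moving = FALSE)
  fr <- plane_frame(dplyr::filter(tibble::as_tibble(gen$series),
                                  t_s == 0), normal = c(0, 0, 1))
  reg <- register_frame(fr, fr)
  expect_equal(attr(reg, "transform")$rotation, diag(3), tolerance = 1e-12)
  expect_equal(attr(reg, "transform")$translation, c(0, 0, 0),
               tolerance = 1e-12)
  expect_equal(reg$vx_m_s, fr$vx_m_s)

  shifted <- fr
  shifted$x_mm <- fr$x_mm + 3
  shifted$z_mm <- fr$z_mm - 7
  reg2 <- register_frame(shifted, fr)
  expect_equal(attr(reg2, "transform")$rotation, diag(3), tolerance = 1e-9)
  expect_identical(reg2$vz_m_s, shifted$vz_m_s)  # vectors untouched
  expect_equal(reg2$x_mm, fr$x_mm, tolerance = 1e-9)
})

test_that("known rigid motions are recovered to 1e-6 and distances kept", {
  spec <- synth_spec(n_points = 80, n_frames = 6, rotation_deg = 10,
                     translation_mm = 5)
  gen <- gen_plane_series(spec, moving = TRUE)
  reg <- register_series(gen$series, reference = gen$reference)
  trs <- attr(reg, "transforms")
  for (k in seq_along(trs)) {
    applied <- gen$transforms[[k]]
    recovered <- trs[[k]]
    # recovered transform must invert the generator's motion
    expect_equal(recovered$rotation %*% applied$rotation, diag(3),
                 tolerance = 1e-6)
    back <- as.vector(recovered$rotation %*% applied$translation) +
      recovered$translation
    expect_equal(back, c(0, 0, 0), tolerance = 1e-6)
  }
  # isometry: pairwise distances preserved
  f1 <- dplyr::filter(tibble::as_tibble(gen$series),
                      t_s == sort(unique(gen$series$t_s))[2])
  r1 <- dplyr::filter(tibble::as_tibble(reg),
                      t_s == sort(unique(reg$t_s))[2])
  d_orig <- dist(cbind(f1$x_mm, f1$y_mm, f1$z_mm))
  d_reg <- dist(cbind(r1$x_mm, r1$y_mm, r1$z_mm))
  expect_lt(max(abs(d_orig - d_reg)), 1e-9)
})

test_that("collinear point sets are rejected", {
  bad <- plane_frame(tibble::tibble(
    x_mm = 1:5, y_mm = 2 * (1:5), z_mm = 0, vx_m_s = 0, vy_m_s = 0,
    vz_m_s = 1, area_mm2 = 1), normal = c(0, 0, 1))
  expect_error(fit_plane(bad), "collinear")
  expect_error(register_frame(bad, bad), "collinear")
})

test_that("temporal resampling: identity, midpoint, periodic wrap", {
  spec <- synth_spec(n_points = 40, n_frames = 8)
  gen <- gen_plane_series(spec, moving = FALSE)
  native_dt <- period_study / 8
  same <- resample_series(gen$series, native_dt)
  expect_equal(tibble::as_tibble(same), tibble::as_tibble(gen$series))

  # two frames, velocities 0 then 1: linear midpoint is 0.5
  base <- tibble::tibble(point_id = 1:4,
                         x_mm = c(0, 1, 0, 1), y_mm = c(0, 0, 1, 1),
                         z_mm = 0, area_mm2 = 1)
  f0 <- dplyr::mutate(base, vx_m_s = 0, vy_m_s = 0, vz_m_s = 0, t_s = 0)
  f1 <- dplyr::mutate(base, vx_m_s = 0, vy_m_s = 0, vz_m_s = 1, t_s = 0.5)
  ser <- plane_series(dplyr::bind_rows(f0, f1), c(0, 0, 1), period = 1)
  res <- resample_series(ser, 0.25)
  quarter <- dplyr::filter(tibble::as_tibble(res), t_s == 0.25)
  expect_equal(quarter$vz_m_s, rep(0.5, 4))
  # wrap: t = 0.75 interpolates back toward the t = 0 frame
  wrap <- dplyr::filter(tibble::as_tibble(res), t_s == 0.75)
  expect_equal(wrap$vz_m_s, rep(0.5, 4))

  # 16 frames at 94 bpm onto 1 ms: ceil(T / dt) samples per cycle
  gen16 <- gen_plane_series(synth_spec(n_points = 12, n_frames = 16),
                            moving = FALSE)
  res16 <- resample_series(gen16$series, 1e-3)
  expect_equal(length(unique(res16$t_s)), ceiling(period_study / 1e-3))
  # continuity at the wrap within the native inter-frame variation
  v_end <- dplyr::filter(tibble::as_tibble(res16),
                         t_s == max(res16$t_s))$vz_m_s
  v_start <- dplyr::filter(tibble::as_tibble(res16), t_s == 0)$vz_m_s
  expect_equal(v_end, v_start, tolerance = 0.05)
})

test_that("resampling preserves the cycle mean of piecewise-linear signals", {
  base <- tibble::tibble(point_id = 1:3, x_mm = c(0, 1, 0),
                         y_mm = c(0, 0, 1), z_mm = 0, area_mm2 = 1)
  tfr <- seq(0, 0.75, by = 0.25)
  vals <- c(1, 3, 2, 0)
  frames <- purrr::map2(tfr, vals, function(t, v) {
    dplyr::mutate(base, vx_m_s = 0, vy_m_s = 0, vz_m_s = v, t_s = t)
  })
  ser <- plane_series(dplyr::bind_rows(frames), c(0, 0, 1), period = 1)
  res <- resample_series(ser, 0.05)
  # mean of periodic piecewise-linear interpolant, reproduced exactly
  mean_native <- mean(c(vals, vals[1])[-1] / 2 + c(vals, vals[1])[-5] / 2)
  pt1 <- dplyr::filter(tibble::as_tibble(res), point_id == 1)
  expect_equal(mean(pt1$vz_m_s), mean_native, tolerance = 1e-12)
})

test_that("plane flow integrates velocity with correct units", {
  fr <- uniform_frame(0.5, n_points = 400)  # 0.5 m/s over ~1257 mm^2
  expect_equal(plane_flow(fr), 0.5 * sum(fr$area_mm2), tolerance = 1e-12)
  # uniform 0.5 m/s over 400 mm^2 gives 200 mL/s
  fr2 <- plane_frame(tibble::tibble(
    x_mm = runif(50), y_mm = runif(50), z_mm = 0, vx_m_s = 0, vy_m_s = 0,
    vz_m_s = 0.5, area_mm2 = 8), normal = c(0, 0, 1))
  expect_equal(plane_flow(fr2), 200)
  expect_equal(plane_flow(plane_frame(
    dplyr::mutate(tibble::as_tibble(fr2), vz_m_s = 0), c(0, 0, 1))), 0)
})

test_that("Poiseuille profile integrates to pi R^2 vmax / 2", {
  n <- 2000; radius <- 20; vmax <- 1.2
  i <- seq_len(n)
  r <- radius * sqrt((i - 0.5) / n)
  th <- 2 * pi * i * ((1 + sqrt(5)) / 2)^-2
  fr <- plane_frame(tibble::tibble(
    x_mm = r * cos(th), y_mm = r * sin(th), z_mm = 0,
    vx_m_s = 0, vy_m_s = 0, vz_m_s = vmax * (1 - (r / radius)^2),
    area_mm2 = pi * radius^2 / n), normal = c(0, 0, 1))
  q_exact <- pi * radius^2 * vmax / 2
  expect_equal(plane_flow(fr), q_exact, tolerance = 5e-3)
})

test_that("inflow waveform is invariant under joint rigid motion", {
  spec <- synth_spec(n_points = 100, n_frames = 8, seed = 3)
  static <- gen_plane_series(spec, moving = FALSE)
  moving <- gen_plane_series(spec, moving = TRUE)
  wf_static <- inflow_waveform(static$series)
  reg <- register_series(moving$series, reference = static$reference)
  wf_reg <- inflow_waveform(reg)
  expect_equal(wf_reg$flow_mL_s, wf_static$flow_mL_s, tolerance = 1e-9)
  # and matches the generator's ground truth
  truth_q <- static$truth$q_forward_mL_s - static$truth$q_reverse_mL_s
  expect_equal(wf_static$flow_mL_s, truth_q, tolerance = 1e-9)
})

test_that("velocity summaries behave and degenerate input errors", {
  fr <- uniform_frame(0.8, n_points = 50)
  expect_equal(mean_inlet_velocity(fr), 0.8, tolerance = 1e-12)
  spec <- synth_spec(n_points = 50, n_frames = 4)
  gen <- gen_plane_series(spec, forward_speed_m_s = 1.1, moving = FALSE)
  expect_equal(peak_inlet_velocity(gen$series), 1.1, tolerance = 1e-9)
  zero_area <- tibble::as_tibble(fr)
  zero_area$area_mm2 <- 0
  expect_error(plane_frame(zero_area, c(0, 0, 1)), "positive")
})
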