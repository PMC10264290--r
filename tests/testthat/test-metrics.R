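test_that("flow decomposition matches a per-sample brute-force oracle", {
  # symmetric field: half forward, half reverse at equal speed
  df <- tibble::tibble(x_mm = 1:10, y_mm = 0, z_mm = 0,
                       vx_m_s = 0, vy_m_s = 0,
                       vz_m_s = rep(c(1, -1), 5), area_mm2 = 2)
  d <- decompose_flow(plane_frame(df, c(0, 0, 1)))
  expect_equal(d$q_mL_s, 0)
  expect_equal(d$q_forward_mL_s, 10)
  expect_equal(d$q_reverse_mL_s, 10)

  # all forward
  d2 <- decompose_flow(uniform_frame(0.3))
  expect_equal(d2$q_reverse_mL_s, 0)
  expect_equal(d2$q_mL_s, d2$q_forward_mL_s)

  # randomized fields vs brute-force partition; zero projections to neither
  set.seed(5)
  for (rep in 1:5) {
    n <- 200
    fr <- plane_frame(tibble::tibble(
      x_mm = runif(n), y_mm = runif(n), z_mm = 0,
      vx_m_s = rnorm(n), vy_m_s = rnorm(n),
      vz_m_s = sample(c(rnorm(n - 20), rep(0, 20))),
      area_mm2 = runif(n, 0.5, 2)), normal = c(0, 0, 1))
    d3 <- decompose_flow(fr)
    qf <- qr_ <- q <- 0
    for (i in seq_len(n)) {
      vn <- fr$vz_m_s[i]
      contrib <- vn * fr$area_mm2[i]
      q <- q + contrib
      if (vn > 0) qf <- qf + contrib
      if (vn < 0) qr_ <- qr_ - contrib
    }
    expect_equal(d3$q_forward_mL_s, qf, tolerance = 1e-12)
    expect_equal(d3$q_reverse_mL_s, qr_, tolerance = 1e-12)
    expect_equal(d3$q_mL_s, d3$q_forward_mL_s - d3$q_reverse_mL_s,
                 tolerance = 1e-12)
  }
})

test_that("R/F ratio and its cycle average handle constant and zero cases", {
  expect_equal(rf_ratio(10, 10), 1)
  dec <- tibble::tibble(t_s = seq(0, 0.9, 0.1),
                        q_forward_mL_s = 5, q_reverse_mL_s = 1)
  expect_equal(cycle_rf(dec, period = 1), 0.2)
  dec0 <- dplyr::mutate(dec, q_reverse_mL_s = 0)
  expect_equal(cycle_rf(dec0, period = 1), 0)
  expect_equal(flef(dec0, period = 1), 0)

  # zero-forward instants: excluded with warning, or strict error
  decz <- dec
  decz$q_forward_mL_s[3] <- 0
  expect_warning(v <- cycle_rf(decz, period = 1), "zero forward")
  expect_gt(v, 0)
  expect_error(suppressWarnings(
    cycle_rf(decz, period = 1, zero_forward = "error")), "strict")
})

test_that("FLEF recovers the generator's prescribed retrograde fraction", {
  # reverse sector of 5% of forward flow: f / (1 - f) = 0.05
  f <- 0.05 / 1.05
  spec <- synth_spec(n_points = 420, n_frames = 8, reverse_fraction = f)
  gen <- gen_plane_series(spec, moving = FALSE)
  dec <- flow_decomposition(gen$series)
  # constant ratio: cycle value equals the instantaneous value exactly
  realised <- dec$q_reverse_mL_s[1] / dec$q_forward_mL_s[1]
  expect_equal(flef(dec), 100 * realised, tolerance = 1e-10)
  expect_equal(flef(dec), 5, tolerance = 0.01)
  expect_gt(flef(dec), 0)  # any reverse-flow instant forces positivity
})

test_that("transmural pressure metrics: mean, signed peak, antisymmetry", {
  tt <- seq(0, 0.95, 0.05)
  p <- lumen_pair(tt, rep(10, 20), rep(8, 20), 1)
  m <- tmp_metrics(p)
  expect_equal(m$tmp_mean_mmHg, 2)
  expect_equal(m$tmp_max_mmHg, 2)

  # pure sinusoidal difference: zero mean, earliest extremum wins
  d <- sin(2 * pi * tt)
  ps <- lumen_pair(tt, 100 + d, rep(100, 20), 1)
  ms <- tmp_metrics(ps)
  expect_equal(ms$tmp_mean_mmHg, 0, tolerance = 1e-12)
  expect_equal(abs(ms$tmp_max_mmHg), max(abs(d)))
  expect_equal(ms$t_max_s, tt[which.max(abs(d))])

  # piecewise trace with known integral
  d2 <- c(rep(1, 10), rep(-3, 10))
  pp <- lumen_pair(tt, 100 + d2, rep(100, 20), 1)
  mp <- tmp_metrics(pp)
  # trapezoid of the piecewise trace (transitions contribute half weights)
  expect_equal(mp$tmp_mean_mmHg,
               sum(0.05 * (head(c(d2, d2[1]), -1) +
                             tail(c(d2, d2[1]), -1)) / 2),
               tolerance = 1e-12)
  expect_equal(mp$tmp_max_mmHg, -3)

  # antisymmetry under lumen swap
  swap <- lumen_pair(tt, rep(100, 20), 100 + d2, 1)
  msw <- tmp_metrics(swap)
  expect_equal(msw$tmp_mean_mmHg, -mp$tmp_mean_mmHg)
  expect_equal(msw$tmp_max_mmHg, -mp$tmp_max_mmHg)

  expect_error(lumen_pair(tt, rep(1, 19), rep(1, 20), 1), "share")
})

test_that("WSS indices: constant, reversing and mixed analytic cases", {
  tt <- seq(0, period_study, length.out = 129)[1:128]
  h_const <- wss_history(tibble::tibble(
    node = 1, t_s = tt, taux_Pa = 2, tauy_Pa = 0, tauz_Pa = 0),
    period = period_study)
  m <- wss_metrics(h_const)
  expect_equal(m$tawss_Pa, 2, tolerance = 1e-12)
  expect_equal(m$osi, 0, tolerance = 1e-12)
  expect_equal(m$ecap_per_Pa, 0, tolerance = 1e-12)

  tau0 <- 1.7
  h_rev <- wss_history(tibble::tibble(
    node = 1, t_s = tt, taux_Pa = tau0 * sin(2 * pi * tt / period_study),
    tauy_Pa = 0, tauz_Pa = 0), period = period_study)
  mr <- wss_metrics(h_rev)
  expect_equal(mr$osi, 0.5, tolerance = 1e-9)
  expect_equal(mr$tawss_Pa, 2 * tau0 / pi, tolerance = 1e-3)

  # ECAP is OSI / TAWSS by definition
  expect_equal(0.25 / 2, 0.125)
  mixed <- wss_metrics(wss_history(tibble::tibble(
    node = 1, t_s = tt,
    taux_Pa = 1 + 2 * sin(2 * pi * tt / period_study),
    tauy_Pa = 0, tauz_Pa = 0), period = period_study))
  expect_equal(mixed$ecap_per_Pa, mixed$osi / mixed$tawss_Pa)

  # zero-shear node: flagged, OSI and ECAP defined as 0
  mz <- wss_metrics(wss_history(tibble::tibble(
    node = 1, t_s = tt, taux_Pa = 0, tauy_Pa = 0, tauz_Pa = 0),
    period = period_study))
  expect_true(mz$degenerate)
  expect_equal(mz$osi, 0)
  expect_equal(mz$ecap_per_Pa, 0)

  expect_error(wss_history(tibble::tibble(
    node = 1, t_s = c(0, 0.1, 0.15), taux_Pa = 1, tauy_Pa = 0,
    tauz_Pa = 0), period = 1), "uniform")
})

test_that("5 ms sampling agrees with 1 ms within 1% on smooth histories", {
  gen5 <- gen_wss_history(synth_spec(n_nodes = 6, seed = 9), dt_s = 5e-3)
  gen1 <- gen_wss_history(synth_spec(n_nodes = 6, seed = 9), dt_s = 1e-3)
  m5 <- wss_metrics(gen5$history)
  m1 <- wss_metrics(gen1$history)
  expect_equal(m5$tawss_Pa, m1$tawss_Pa, tolerance = 0.01)
  expect_equal(m5$osi, m1$osi, tolerance = 0.01)
})

test_that("OSI stays in [0, 0.5] and integrals match a dense Riemann oracle", {
  set.seed(21)
  tt <- seq(0, 1, length.out = 201)[1:200]
  for (rep in 1:5) {
    a <- rnorm(3); b <- rnorm(3); ph <- runif(3, 0, 2 * pi)
    sig <- function(t) {
      cbind(a[1] + b[1] * sin(2 * pi * t + ph[1]),
            a[2] + b[2] * sin(4 * pi * t + ph[2]),
            a[3] + b[3] * sin(2 * pi * t + ph[3]))
    }
    v <- sig(tt)
    m <- wss_metrics(wss_history(tibble::tibble(
      node = 1, t_s = tt, taux_Pa = v[, 1], tauy_Pa = v[, 2],
      tauz_Pa = v[, 3]), period = 1))
    expect_gte(m$osi, 0)
    expect_lte(m$osi, 0.5)
    expect_gte(m$tawss_Pa, 0)
    expect_gte(m$ecap_per_Pa, 0)
    # dense Riemann oracle on 2e4 midpoints
    td <- seq(0.5 / 2e4, 1 - 0.5 / 2e4, length.out = 2e4)
    vd <- sig(td)
    tawss_oracle <- mean(sqrt(rowSums(vd^2)))
    osi_oracle <- 0.5 * (1 - sqrt(sum(colMeans(vd)^2)) / tawss_oracle)
    expect_equal(m$tawss_Pa, tawss_oracle, tolerance = 1e-3)
    expect_equal(m$osi, osi_oracle, tolerance = 1e-3)
  }
})

test_that("Carreau-Yasuda limits and closed form", {
  model <- blood_viscosity_model()
  expect_equal(carreau_yasuda(0, model), model$mu0)
  expect_equal(carreau_yasuda(1e9, model), model$mu_inf, tolerance = 1e-3)
  g <- c(0.1, 1, 10, 100, 1000)
  manual <- model$mu_inf + (model$mu0 - model$mu_inf) *
    (1 + (model$lambda * g)^model$a)^((model$n - 1) / model$a)
  expect_equal(carreau_yasuda(g, model), manual, tolerance = 1e-12)
  expect_error(carreau_yasuda(-1), "non-negative")
  expect_error(blood_viscosity_model(mu0 = 0.001), "mu0 > mu_inf")
})

test_that("pulsatile Reynolds criterion flags transition", {
  # near-constant viscosity at extreme shear: mu -> mu_inf = 0.0035
  model <- blood_viscosity_model(mu_inf = 0.0035)
  rep1 <- reynolds_check(peak_velocity = 1, diameter = 0.03,
                         heart_rate = 94, model = model,
                         nominal_shear_rate = 1e9)
  expect_equal(rep1$re_peak, 1056 * 1 * 0.03 / 0.0035, tolerance = 1e-3)
  expect_gt(rep1$womersley, 0)

  rep2 <- reynolds_check(re_peak = 11646, re_crit = 6959)
  expect_true(rep2$turbulent)
  rep3 <- reynolds_check(re_peak = 2000, re_crit = 6959)
  expect_false(rep3$turbulent)
})

test_that("Bland-Altman bias and limits of agreement", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  g0 <- glance(ba0)
  expect_equal(g0$bias, 0)
  expect_equal(g0$loa_lower, 0)
  expect_equal(g0$loa_upper, 0)

  ba <- bland_altman(c(1, 3), c(2, 2))
  g <- glance(ba)
  expect_equal(g$bias, 0)
  expect_equal(g$sd_difference, sqrt(2))
  expect_equal(g$loa_upper, 1.96 * sqrt(2))
  expect_equal(g$loa_lower, -1.96 * sqrt(2))
  expect_equal(tidy(ba)$difference, c(-1, 1))

  bac <- bland_altman(c(5, 6, 7) + 0.3, c(5, 6, 7))
  gc <- glance(bac)
  expect_equal(gc$bias, 0.3)
  expect_equal(gc$loa_upper - gc$loa_lower, 0)

  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("velocity errors normalise by mean inlet velocity", {
  expect_equal(unlist(velocity_errors(c(1, 1), c(1, 1), 0.5)),
               c(peak_error_pct = 0, mean_error_pct = 0))
  e <- velocity_errors(rep(1.1, 10), rep(1.0, 10), 0.5)
  expect_equal(e$peak_error_pct, 20, tolerance = 1e-9)
  expect_equal(e$mean_error_pct, 20, tolerance = 1e-9)
  e2 <- velocity_errors(rep(0, 5), rep(1, 5), 1)
  expect_equal(e2$peak_error_pct, -100)
  expect_equal(e2$mean_error_pct, -100)
  expect_error(velocity_errors(1:2, 1:2, 0), "positive")
})
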