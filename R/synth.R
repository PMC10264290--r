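#' Specification for the synthetic-data generators
#'
#' Bundles the physiological and sampling parameters shared by the
#' generators. Defaults emulate the study conditions: heart rate 94 bpm,
#' stroke volume 70 mL (cycle-mean inflow ~110 mL/s), 16 plane
#' timeframes per cycle, a 20 mm-radius inlet disc. All generators are
#' deterministic for a fixed `seed`; noise is optional, zero-mean
#' Gaussian, and ground truths are recorded pre-noise.
#'
#' @param heart_rate Beats per minute (default 94).
#' @param stroke_volume_mL Ejected volume per cycle (default 70).
#' @param n_harmonics Harmonics retained in the inflow waveform
#'   (default 8).
#' @param systolic_fraction Fraction of the cycle occupied by the
#'   systolic lobe (default 0.35).
#' @param disc_radius_mm Radius of the synthetic analysis disc
#'   (default 20).
#' @param n_points Velocity samples per plane frame (default 400).
#' @param n_frames Plane timeframes per cycle (default 16).
#' @param reverse_fraction Area fraction of the disc assigned to the
#'   reverse-flow sector (default 0.15).
#' @param rotation_deg,translation_mm Rigid-motion amplitudes applied to
#'   moving frames (defaults 10 degrees, 5 mm).
#' @param n_nodes WSS nodes per kind (default 20).
#' @param noise_sd Gaussian noise SD on velocities (m/s) and pressures
#'   (mmHg) (default 0, i.e. noise off).
#' @param seed Integer seed (default 1).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(heart_rate = 94, stroke_volume_mL = 70,
                       n_harmonics = 8, systolic_fraction = 0.35,
                       disc_radius_mm = 20, n_points = 400, n_frames = 16,
                       reverse_fraction = 0.15, rotation_deg = 10,
                       translation_mm = 5, n_nodes = 20, noise_sd = 0,
                       seed = 1L) {
  if (!isTRUE(heart_rate > 0)) abort("`heart_rate` must be positive.")
  if (!isTRUE(stroke_volume_mL > 0)) {
    abort("`stroke_volume_mL` must be positive.")
  }
  if (!isTRUE(n_points >= 3)) abort("`n_points` must be at least 3.")
  if (reverse_fraction < 0 || reverse_fraction > 1) {
    abort("`reverse_fraction` must lie in [0, 1].")
  }
  if (!all(is.finite(c(rotation_deg, translation_mm, noise_sd)))) {
    abort("Amplitudes must be finite.")
  }
  structure(
    list(heart_rate = heart_rate, stroke_volume_mL = stroke_volume_mL,
         n_harmonics = n_harmonics, systolic_fraction = systolic_fraction,
         disc_radius_mm = disc_radius_mm, n_points = n_points,
         n_frames = n_frames, reverse_fraction = reverse_fraction,
         rotation_deg = rotation_deg, translation_mm = translation_mm,
         n_nodes = n_nodes, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' Synthetic aortic inflow waveform
#'
#' A truncated Fourier representation of a half-sine systolic lobe
#' (duration `systolic_fraction * T`), rescaled so the cycle mean is
#' exactly `SV * HR / 60`. With `n_harmonics = 0` the waveform collapses
#' to constant flow at the mean. Sampled on a uniform grid of step
#' `dt_sample`.
#'
#' @param spec A [synth_spec()].
#' @param dt_sample Sampling step in seconds (default 0.001).
#' @return A [flow_waveform()] with attribute `mean_mL_s`.
#' @export
gen_inflow <- function(spec, dt_sample = 1e-3) {
  stopifnot(inherits(spec, "synth_spec"))
  period <- 60 / spec$heart_rate
  q_mean <- spec$stroke_volume_mL * spec$heart_rate / 60
  n <- max(8L, as.integer(round(period / dt_sample)))
  tt <- seq(0, period, length.out = n + 1L)[seq_len(n)]
  if (spec$n_harmonics == 0) {
    return(flow_waveform(tt, rep(q_mean, n), period))
  }
  ts <- spec$systolic_fraction * period
  # Fourier coefficients of s(t) = sin(pi t / ts) on [0, ts], 0 elsewhere
  shape <- rep(0, n)
  mean_coef <- 2 * ts / (pi * period)  # a0/... cycle mean of the lobe
  shape <- shape + mean_coef
  for (k in seq_len(spec$n_harmonics)) {
    wk <- 2 * pi * k / period
    # integral of sin(pi t/ts) * exp(-i wk t) over [0, ts], closed form
    b <- pi / ts
    denom <- b^2 - wk^2
    if (abs(denom) < 1e-12) {
      # resonant harmonic: integral of sin(b t) cos(b t) etc.
      re <- 0
      im <- -ts / 2
    } else {
      re <- b * (1 + cos(wk * ts)) / denom
      im <- -b * sin(wk * ts) / denom
    }
    ak <- 2 / period * re
    bk <- -2 / period * im
    shape <- shape + ak * cos(wk * tt) + bk * sin(wk * tt)
  }
  flows <- q_mean * shape / mean_coef
  wf <- flow_waveform(tt, flows, period)
  attr(wf, "mean_mL_s") <- q_mean
  wf
}

# sunflower (Fibonacci) layout: n points uniformly covering a disc
disc_points <- function(n, radius) {
  i <- seq_len(n)
  golden <- (1 + sqrt(5)) / 2
  r <- radius * sqrt((i - 0.5) / n)
  theta <- 2 * pi * i / golden^2
  tibble(x_mm = r * cos(theta), y_mm = r * sin(theta), z_mm = 0,
         area_mm2 = pi * radius^2 / n)
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  k <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + s_ * k + (1 - c_) * (k %*% k)
}

#' Synthetic moving two-lumen plane series with known ground truth
#'
#' Samples a disc with a sunflower layout and prescribes, at each of
#' `n_frames` timepoints, a forward region and a reverse sector of area
#' fraction `reverse_fraction` (points with polar angle inside the
#' sector). Normal speeds follow the systolic shape of the inflow
#' waveform, so the exact forward/reverse flows are known in closed form.
#' Each frame is optionally carried through a known rigid motion
#' (rotation about an in-plane axis plus translation, scaled by a smooth
#' cycle-periodic profile); the exact per-frame transforms are returned.
#'
#' @param spec A [synth_spec()].
#' @param forward_speed_m_s Peak forward normal speed (default 0.8).
#' @param reverse_speed_m_s Peak reverse normal speed (default equal to
#'   `forward_speed_m_s`).
#' @param moving Apply the rigid motion? (default TRUE; FALSE gives
#'   identity transforms.)
#' @return List with `series` (a [plane_series()] in the moved
#'   configuration), `reference` (the static frame), and `truth`: tibble
#'   of per-frame `t_s`, `q_forward_mL_s`, `q_reverse_mL_s`, and
#'   `transforms` (list of rotation/translation per frame).
#' @export
gen_plane_series <- function(spec, forward_speed_m_s = 0.8,
                             reverse_speed_m_s = forward_speed_m_s,
                             moving = TRUE) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  period <- 60 / spec$heart_rate
  pts <- disc_points(spec$n_points, spec$disc_radius_mm)
  theta <- atan2(pts$y_mm, pts$x_mm) + pi  # in [0, 2pi)
  # assign by angular rank so the realised area fraction is exactly
  # round(f * n) / n (equal-area quadrature weights)
  n_rev <- as.integer(round(spec$reverse_fraction * spec$n_points))
  in_reverse <- rank(theta, ties.method = "first") <= n_rev
  n_frames <- spec$n_frames
  tf <- seq(0, period, length.out = n_frames + 1L)[seq_len(n_frames)]
  # smooth strictly positive speed profile (forward flow at every frame)
  profile <- 0.15 + 0.85 * (sin(pi * tf / period))^2
  area <- pi * spec$disc_radius_mm^2
  a_rev <- area * mean(in_reverse)
  a_fwd <- area * mean(!in_reverse)

  frames <- vector("list", n_frames)
  transforms <- vector("list", n_frames)
  motion <- sin(2 * pi * tf / period)  # periodic, zero at t = 0
  axis <- c(1, 0, 0)                   # in-plane axis
  for (k in seq_len(n_frames)) {
    vf <- forward_speed_m_s * profile[k]
    vr <- reverse_speed_m_s * profile[k]
    vz <- ifelse(in_reverse, -vr, vf)
    fr <- mutate(pts, vx_m_s = 0, vy_m_s = 0, vz_m_s = vz,
                 t_s = tf[k], point_id = dplyr::row_number())
    if (moving) {
      ang <- spec$rotation_deg * pi / 180 * motion[k]
      tr <- spec$translation_mm * motion[k] * c(0, 0.6, 0.8)
      rot <- rotation_matrix(axis, ang)
    } else {
      rot <- diag(3)
      tr <- c(0, 0, 0)
    }
    xyz <- cbind(fr$x_mm, fr$y_mm, fr$z_mm) %*% t(rot)
    xyz <- sweep(xyz, 2, tr, "+")
    vel <- cbind(fr$vx_m_s, fr$vy_m_s, fr$vz_m_s) %*% t(rot)
    if (spec$noise_sd > 0) {
      vel <- vel + matrix(stats::rnorm(length(vel), 0, spec$noise_sd),
                          ncol = 3)
    }
    fr$x_mm <- xyz[, 1]; fr$y_mm <- xyz[, 2]; fr$z_mm <- xyz[, 3]
    fr$vx_m_s <- vel[, 1]; fr$vy_m_s <- vel[, 2]; fr$vz_m_s <- vel[, 3]
    frames[[k]] <- fr
    transforms[[k]] <- list(rotation = rot, translation = tr)
  }
  truth <- tibble(
    t_s = tf,
    q_forward_mL_s = forward_speed_m_s * profile * a_fwd,
    q_reverse_mL_s = reverse_speed_m_s * profile * a_rev
  )
  reference <- plane_frame(
    mutate(pts, vx_m_s = 0, vy_m_s = 0,
           vz_m_s = ifelse(in_reverse, -reverse_speed_m_s * profile[1],
                           forward_speed_m_s * profile[1]),
           t_s = 0, point_id = dplyr::row_number()),
    normal = c(0, 0, 1))
  series <- plane_series(bind_rows(frames), normal = c(0, 0, 1),
                         period = period)
  list(series = series, reference = reference, truth = truth,
       transforms = transforms)
}

#' Synthetic WSS histories with analytically known indices
#'
#' Generates three node populations on a uniform grid (default step 5
#' ms): constant-direction nodes (OSI 0), fully reversing sinusoidal
#' nodes (OSI 0.5, TAWSS `(2/pi) tau0`), and partially reversing nodes
#' `tau(t) = (m + a sin(w t)) e` with `0 < m < a`, whose exact indices
#' follow from `mean|m + a sin| = (2/pi) (m asin(m/a) + a cos(asin(m/a)))`.
#'
#' @param spec A [synth_spec()].
#' @param dt_s Sampling step (default 0.005).
#' @param tau0_Pa Oscillation amplitude scale in Pa (default 2).
#' @return List with `history` (a [wss_history()]) and `truth` (tibble:
#'   `node`, `kind`, `tawss_Pa`, `osi`, `ecap_per_Pa`).
#' @export
gen_wss_history <- function(spec, dt_s = 5e-3, tau0_Pa = 2) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed + 1L)
  period <- 60 / spec$heart_rate
  n <- as.integer(round(period / dt_s))
  tt <- seq(0, period, length.out = n + 1L)[seq_len(n)]
  w <- 2 * pi / period
  n_nodes <- spec$n_nodes
  rows <- list()
  truth <- list()
  node_id <- 0L
  rand_dir <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  for (i in seq_len(n_nodes)) {       # constant nodes
    node_id <- node_id + 1L
    dir <- rand_dir()
    mag <- tau0_Pa * stats::runif(1, 0.5, 1.5)
    rows[[node_id]] <- tibble(node = node_id, t_s = tt,
                              taux_Pa = mag * dir[1],
                              tauy_Pa = mag * dir[2],
                              tauz_Pa = mag * dir[3])
    truth[[node_id]] <- tibble(node = node_id, kind = "constant",
                               tawss_Pa = mag, osi = 0)
  }
  for (i in seq_len(n_nodes)) {       # fully reversing sinusoids
    node_id <- node_id + 1L
    dir <- rand_dir()
    amp <- tau0_Pa * stats::runif(1, 0.5, 1.5)
    s <- amp * sin(w * tt)
    rows[[node_id]] <- tibble(node = node_id, t_s = tt,
                              taux_Pa = s * dir[1], tauy_Pa = s * dir[2],
                              tauz_Pa = s * dir[3])
    truth[[node_id]] <- tibble(node = node_id, kind = "reversing",
                               tawss_Pa = 2 * amp / pi, osi = 0.5)
  }
  for (i in seq_len(n_nodes)) {       # partial reversal, closed-form OSI
    node_id <- node_id + 1L
    dir <- rand_dir()
    amp <- tau0_Pa * stats::runif(1, 0.8, 1.2)
    m <- amp * stats::runif(1, 0.1, 0.9)
    s <- m + amp * sin(w * tt)
    rows[[node_id]] <- tibble(node = node_id, t_s = tt,
                              taux_Pa = s * dir[1], tauy_Pa = s * dir[2],
                              tauz_Pa = s * dir[3])
    phi <- asin(m / amp)
    mean_abs <- (2 / pi) * (m * phi + amp * cos(phi))
    truth[[node_id]] <- tibble(node = node_id, kind = "partial",
                               tawss_Pa = mean_abs,
                               osi = 0.5 * (1 - m / mean_abs))
  }
  truth <- mutate(bind_rows(truth), ecap_per_Pa = .data$osi / .data$tawss_Pa)
  list(history = wss_history(bind_rows(rows), period), truth = truth)
}

#' Synthetic paired lumen pressure traces with known transmural pressure
#'
#' True/false-lumen traces share a pulse shape; their difference is
#' `offset + amplitude * sin(2 pi t / T)`, so `TMP_mean = offset` and,
#' for `offset != 0`,
#' `TMP_max = sign(offset) * (|offset| + amplitude)`.
#'
#' @param spec A [synth_spec()].
#' @param offset_mmHg Mean TL-FL offset (default 2).
#' @param amplitude_mmHg Oscillation amplitude (default 1).
#' @param dt_s Sampling step (default 0.005).
#' @return List with `pair` (a [lumen_pair()]) and `truth` (tibble:
#'   `tmp_mean_mmHg`, `tmp_max_mmHg`).
#' @export
gen_pressure_pair <- function(spec, offset_mmHg = 2, amplitude_mmHg = 1,
                              dt_s = 5e-3) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed + 2L)
  period <- 60 / spec$heart_rate
  n <- as.integer(round(period / dt_s))
  tt <- seq(0, period, length.out = n + 1L)[seq_len(n)]
  base <- 90 + 30 * (sin(pi * tt / period))^2   # shared pulse shape
  diff_trace <- offset_mmHg + amplitude_mmHg * sin(2 * pi * tt / period)
  p_tl <- base + diff_trace / 2
  p_fl <- base - diff_trace / 2
  if (spec$noise_sd > 0) {
    p_tl <- p_tl + stats::rnorm(n, 0, spec$noise_sd)
    p_fl <- p_fl + stats::rnorm(n, 0, spec$noise_sd)
  }
  tmp_max <- if (offset_mmHg == 0) amplitude_mmHg else {
    sign(offset_mmHg) * (abs(offset_mmHg) + amplitude_mmHg)
  }
  list(pair = lumen_pair(tt, p_tl, p_fl, period),
       truth = tibble(tmp_mean_mmHg = offset_mmHg, tmp_max_mmHg = tmp_max))
}
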