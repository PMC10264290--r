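#' Velocity samples on an analysis plane
#'
#' A plane frame is a tibble of discretized velocity samples with columns
#' `point_id`, `x_mm`, `y_mm`, `z_mm`, `vx_m_s`, `vy_m_s`, `vz_m_s`,
#' `area_mm2` and `t_s`, plus a unit `normal` attribute. Point ids give
#' the across-frame correspondence needed for registration and temporal
#' interpolation. A series of frames over one cycle is the same tibble
#' with several `t_s` values and a `period_s` attribute.
#'
#' The normal orientation convention: the reference normal points in the
#' direction of bulk systolic flow, so forward/reverse decompositions and
#' the sign of plane flow inherit it.
#'
#' @param df Data frame with the columns above (`point_id` optional; row
#'   order is used when absent).
#' @param normal Length-3 plane normal; normalised internally.
#' @param period For `plane_series()`: cycle period in seconds.
#' @return A `plane_frame` (or `plane_series`) tibble.
#' @export
plane_frame <- function(df, normal) {
  df <- as_tibble(df)
  req <- c("x_mm", "y_mm", "z_mm", "vx_m_s", "vy_m_s", "vz_m_s", "area_mm2")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    abort(sprintf("Plane frame is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (!"point_id" %in% names(df)) df$point_id <- seq_len(nrow(df))
  if (!"t_s" %in% names(df)) df$t_s <- 0
  if (any(df$area_mm2 <= 0)) abort("`area_mm2` must be positive.")
  nv <- sqrt(sum(normal^2))
  if (!isTRUE(nv > 0)) abort("`normal` must be non-zero.")
  structure(df, normal = normal / nv,
            class = unique(c("plane_frame", class(df))))
}

#' @rdname plane_frame
#' @export
plane_series <- function(df, normal, period) {
  out <- plane_frame(df, normal)
  ts <- sort(unique(out$t_s))
  if (!isTRUE(period > 0)) abort("`period` must be positive.")
  if (any(ts < 0) || any(ts >= period)) {
    abort("Frame timestamps must lie in [0, period).")
  }
  structure(out, period_s = as.numeric(period),
            class = unique(c("plane_series", class(out))))
}

plane_normal <- function(frame) attr(frame, "normal")

series_frames <- function(series) {
  split(as_tibble(series), series$t_s)
}

#' Best-fit plane of a point set
#'
#' Centroid plus orthogonal-regression normal: the normal is the singular
#' vector of the centred coordinates with the smallest singular value.
#'
#' @param frame A [plane_frame()] or data frame with `x_mm`, `y_mm`, `z_mm`.
#' @return List with `centroid` (length 3), `normal` (unit length) and
#'   `rms_residual_mm` (out-of-plane RMS distance).
#' @export
fit_plane <- function(frame) {
  xyz <- cbind(frame$x_mm, frame$y_mm, frame$z_mm)
  if (nrow(xyz) < 3) abort("Plane fitting needs at least 3 points.")
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    abort("Degenerate (collinear) point set: plane is undefined.")
  }
  normal <- sv$v[, 3]
  list(centroid = ctr, normal = normal,
       rms_residual_mm = sqrt(mean((sweep(xyz, 2, ctr) %*% normal)^2)))
}

# Kabsch/orthogonal-Procrustes rotation taking centred P onto centred Q.
kabsch_rotation <- function(p_centred, q_centred) {
  h <- crossprod(p_centred, q_centred)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

#' Rigidly register a moving frame onto a reference plane
#'
#' Solves the rigid transform mapping the frame's points onto the
#' reference's corresponding points in the least-squares sense
#' (orthogonal Procrustes on centred coordinates, translation from the
#' centroids). This realises the plane-fit-plus-in-plane-alignment
#' mapping in one step because point correspondence carries both the
#' plane attitude and the residual in-plane rotation. Velocity vectors
#' are rotated by the same rotation; areas are preserved (isometry).
#'
#' @param frame,reference [plane_frame()]s with matching `point_id` sets
#'   and at least 3 non-collinear points.
#' @return The registered `plane_frame` (reference normal attached) with
#'   attribute `transform = list(rotation, translation)` such that
#'   `x_ref = rotation %*% x_frame + translation`.
#' @export
register_frame <- function(frame, reference) {
  frame <- as_tibble(frame)
  refd <- as_tibble(reference)
  if (!setequal(frame$point_id, refd$point_id)) {
    abort("`frame` and `reference` must share the same point ids.")
  }
  frame <- arrange(frame, .data$point_id)
  refd <- arrange(refd, .data$point_id)
  fit_plane(frame)  # validates non-degeneracy
  fit_plane(refd)
  p <- cbind(frame$x_mm, frame$y_mm, frame$z_mm)
  q <- cbind(refd$x_mm, refd$y_mm, refd$z_mm)
  pc <- colMeans(p)
  qc <- colMeans(q)
  rot <- kabsch_rotation(sweep(p, 2, pc), sweep(q, 2, qc))
  tr <- qc - as.vector(rot %*% pc)
  xyz_new <- sweep(p %*% t(rot), 2, tr, "+")
  vel_new <- cbind(frame$vx_m_s, frame$vy_m_s, frame$vz_m_s) %*% t(rot)
  out <- frame
  out$x_mm <- xyz_new[, 1]; out$y_mm <- xyz_new[, 2]; out$z_mm <- xyz_new[, 3]
  out$vx_m_s <- vel_new[, 1]; out$vy_m_s <- vel_new[, 2]
  out$vz_m_s <- vel_new[, 3]
  out <- plane_frame(out, plane_normal(reference) %||% fit_plane(refd)$normal)
  attr(out, "transform") <- list(rotation = rot, translation = tr)
  out
}

#' Register every frame of a moving-plane series
#'
#' @param series A [plane_series()].
#' @param reference Reference frame (default the first frame of the
#'   series).
#' @return A registered `plane_series`; per-frame transforms are kept in
#'   the `transforms` attribute (named by timestamp) for audit.
#' @export
register_series <- function(series, reference = NULL) {
  frames <- series_frames(series)
  normal0 <- plane_normal(series)
  if (is.null(reference)) {
    reference <- plane_frame(frames[[1]], normal0)
  }
  regs <- lapply(frames, register_frame, reference = reference)
  out <- bind_rows(lapply(regs, as_tibble))
  out <- plane_series(out, plane_normal(reference), attr(series, "period_s"))
  attr(out, "transforms") <- lapply(regs, attr, "transform")
  out
}

#' Resample a registered plane series in time
#'
#' Periodic per-point interpolation of the velocity components onto a
#' uniform grid of step `dt` (the last-to-first interval wraps with the
#' period). Point positions and areas are taken from the first frame of
#' the registered series.
#'
#' @param series A registered [plane_series()] with equal point sets in
#'   every frame.
#' @param dt Target timestep in seconds.
#' @param method `"linear"` (default) or `"spline"` (periodic cubic).
#' @return A `plane_series` on the uniform grid.
#' @export
resample_series <- function(series, dt, method = c("linear", "spline")) {
  method <- match.arg(method)
  if (!isTRUE(dt > 0)) abort("`dt` must be positive.")
  period <- attr(series, "period_s")
  frames <- series_frames(series)
  ids <- sort(frames[[1]]$point_id)
  same <- vapply(frames, function(f) identical(sort(f$point_id), ids),
                 logical(1))
  if (!all(same)) {
    abort("Frames have mismatched point sets; run register_series() first.")
  }
  tf <- as.numeric(names(frames))
  # ceil so the realised step never exceeds the requested dt
  n <- max(2L, as.integer(ceiling(period / dt - 1e-9)))
  grid <- seq(0, period, length.out = n + 1L)[seq_len(n)]
  if (length(tf) == length(grid) && max(abs(tf - grid)) < 1e-9 * period) {
    return(series)
  }
  geom <- arrange(frames[[1]], .data$point_id) |>
    select("point_id", "x_mm", "y_mm", "z_mm", "area_mm2")
  vel <- lapply(frames, function(f) {
    f <- arrange(f, .data$point_id)
    cbind(f$vx_m_s, f$vy_m_s, f$vz_m_s)
  })
  t_ext <- c(tf, tf[1] + period)
  interp1 <- function(y) {
    y_ext <- c(y, y[1])
    if (method == "linear") {
      approx(t_ext, y_ext, xout = grid)$y
    } else {
      stats::spline(t_ext, y_ext, xout = grid, method = "periodic")$y
    }
  }
  npts <- nrow(geom)
  vcomp <- array(unlist(vel), dim = c(npts, 3, length(tf)))
  res <- array(0, dim = c(npts, 3, length(grid)))
  for (i in seq_len(npts)) {
    for (j in 1:3) {
      res[i, j, ] <- interp1(vcomp[i, j, ])
    }
  }
  frames_out <- lapply(seq_along(grid), function(k) {
    mutate(geom, vx_m_s = res[, 1, k], vy_m_s = res[, 2, k],
           vz_m_s = res[, 3, k], t_s = grid[k])
  })
  plane_series(bind_rows(frames_out), plane_normal(series), period)
}

#' Plane flow and velocity summaries
#'
#' `plane_flow()` integrates the normal velocity over the plane,
#' `Q = sum((v . n) A)` in mL/s (velocities m/s, areas mm^2).
#' `mean_inlet_velocity()` is the area-weighted mean speed of one frame;
#' `peak_inlet_velocity()` the maximum pointwise speed over a series.
#' `inflow_waveform()` evaluates `plane_flow` frame by frame and returns
#' a [flow_waveform()].
#'
#' @param frame A [plane_frame()]; `series` a [plane_series()].
#' @return Flow in mL/s, velocities in m/s.
#' @export
plane_flow <- function(frame) {
  n <- plane_normal(frame)
  vn <- frame$vx_m_s * n[1] + frame$vy_m_s * n[2] + frame$vz_m_s * n[3]
  sum(vn * frame$area_mm2)
}

#' @rdname plane_flow
#' @export
mean_inlet_velocity <- function(frame) {
  a <- sum(frame$area_mm2)
  if (!isTRUE(a > 0)) abort("Total plane area is zero.")
  speed <- sqrt(frame$vx_m_s^2 + frame$vy_m_s^2 + frame$vz_m_s^2)
  sum(speed * frame$area_mm2) / a
}

#' @rdname plane_flow
#' @param series A [plane_series()].
#' @export
peak_inlet_velocity <- function(series) {
  max(sqrt(series$vx_m_s^2 + series$vy_m_s^2 + series$vz_m_s^2))
}

#' @rdname plane_flow
#' @export
inflow_waveform <- function(series) {
  period <- attr(series, "period_s")
  if (is.null(period)) abort("`series` must be a plane_series.")
  if (sum(series$area_mm2) <= 0) abort("Total plane area is zero.")
  frames <- series_frames(series)
  n <- plane_normal(series)
  q <- vapply(frames, function(f) {
    sum((f$vx_m_s * n[1] + f$vy_m_s * n[2] + f$vz_m_s * n[3]) * f$area_mm2)
  }, numeric(1))
  flow_waveform(as.numeric(names(frames)), unname(q), period)
}

#' Net-flux imbalance diagnostic
#'
#' Measured plane data can exhibit weak velocity divergence; rather than
#' correcting it, this diagnostic reports the net flux through the plane
#' relative to the total unsigned flux, `|Q| / (Q_F + Q_R)`. Values near
#' 0 indicate a balanced (recirculating) field, values near 1 a
#' unidirectional one; compare across frames to spot suspect timepoints.
#'
#' @param frame A [plane_frame()].
#' @return A single proportion in `[0, 1]` (NA for an all-zero field).
#' @export
flux_imbalance <- function(frame) {
  d <- decompose_flow(frame)
  tot <- d$q_forward_mL_s + d$q_reverse_mL_s
  if (tot == 0) return(NA_real_)
  abs(d$q_mL_s) / tot
}

#' Interpolate a plane frame onto target points
#'
#' Optional helper for moving samples onto a solver's point set:
#' inverse-distance weighting over the `k` nearest source points (exact
#' nearest-neighbour value when a target coincides with a source point).
#'
#' @param frame A [plane_frame()].
#' @param target Data frame with `x_mm`, `y_mm`, `z_mm`.
#' @param k Number of neighbours (default 3).
#' @return `target` with interpolated `vx_m_s`, `vy_m_s`, `vz_m_s`.
#' @export
interp_to_points <- function(frame, target, k = 3L) {
  target <- as_tibble(target)
  src <- cbind(frame$x_mm, frame$y_mm, frame$z_mm)
  vel <- cbind(frame$vx_m_s, frame$vy_m_s, frame$vz_m_s)
  k <- min(k, nrow(src))
  out <- matrix(0, nrow(target), 3)
  for (i in seq_len(nrow(target))) {
    d2 <- (src[, 1] - target$x_mm[i])^2 + (src[, 2] - target$y_mm[i])^2 +
      (src[, 3] - target$z_mm[i])^2
    nn <- order(d2)[seq_len(k)]
    if (d2[nn[1]] < 1e-18) {
      out[i, ] <- vel[nn[1], ]
    } else {
      w <- 1 / d2[nn]
      out[i, ] <- colSums(vel[nn, , drop = FALSE] * w) / sum(w)
    }
  }
  mutate(target, vx_m_s = out[, 1], vy_m_s = out[, 2], vz_m_s = out[, 3])
}
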