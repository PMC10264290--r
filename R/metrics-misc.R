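#' Carreau-Yasuda blood viscosity model
#'
#' Shear-thinning apparent viscosity
#' `mu = mu_inf + (mu0 - mu_inf) * (1 + (lambda * g)^a)^((n - 1)/a)`
#' with shear rate `g` in 1/s. `blood_viscosity_model()` returns editable
#' defaults from the blood-rheology literature together with the blood
#' density used throughout (1056 kg/m^3).
#'
#' @param shear_rate Shear rate(s), 1/s, non-negative.
#' @param model List as returned by [blood_viscosity_model()].
#' @return Apparent viscosity in Pa s.
#' @examples
#' carreau_yasuda(0)    # low-shear plateau mu0
#' carreau_yasuda(1e6)  # approaches mu_inf
#' @export
carreau_yasuda <- function(shear_rate, model = blood_viscosity_model()) {
  if (any(shear_rate < 0)) abort("`shear_rate` must be non-negative.")
  with(model, mu_inf + (mu0 - mu_inf) *
         (1 + (lambda * shear_rate)^a)^((n - 1) / a))
}

#' @rdname carreau_yasuda
#' @param mu0,mu_inf Zero- and infinite-shear viscosities, Pa s
#'   (`mu0 > mu_inf > 0`).
#' @param lambda Relaxation time, s.
#' @param a Yasuda transition exponent.
#' @param n Power-law index.
#' @param density_kg_m3 Blood density, kg/m^3.
#' @export
blood_viscosity_model <- function(mu0 = 0.056, mu_inf = 0.00345,
                                  lambda = 3.313, a = 2, n = 0.3568,
                                  density_kg_m3 = 1056) {
  if (!isTRUE(mu0 > mu_inf && mu_inf > 0)) {
    abort("Require mu0 > mu_inf > 0.")
  }
  if (!isTRUE(lambda > 0 && a > 0)) abort("`lambda` and `a` must be > 0.")
  list(mu0 = mu0, mu_inf = mu_inf, lambda = lambda, a = a, n = n,
       density_kg_m3 = density_kg_m3)
}

#' Pulsatile-flow turbulence criterion
#'
#' Estimates the peak Reynolds number `Re_p = rho V D / mu` (viscosity
#' evaluated at a nominal shear rate, by default `V / D`), the Womersley
#' number `alpha = (D/2) sqrt(omega rho / mu)`, and a critical Reynolds
#' number for transition in pulsatile pipe flow modelled as a power law
#' `Re_c = k alpha^b` (optionally times `St^c` with Strouhal number
#' `St = f D / V`). The correlation constants are configuration, not
#' truths; `re_crit` may also be supplied directly (e.g. from an external
#' estimate), overriding the power law.
#'
#' @param peak_velocity Peak velocity V, m/s.
#' @param diameter Characteristic diameter D, m.
#' @param heart_rate Beats per minute.
#' @param model Viscosity model ([blood_viscosity_model()]).
#' @param nominal_shear_rate Shear rate for viscosity evaluation, 1/s
#'   (default `V / D`).
#' @param crit_coef,crit_alpha_exp,crit_strouhal_exp Power-law constants
#'   `k`, `b`, `c` (defaults 169, 0.83, -0.27; set
#'   `crit_strouhal_exp = 0` to drop the Strouhal factor).
#' @param re_peak,re_crit Directly supplied values overriding the
#'   computed ones.
#' @return One-row tibble: `re_peak`, `re_crit`, `womersley`,
#'   `viscosity_Pa_s`, `turbulent` (`re_peak > re_crit`).
#' @export
reynolds_check <- function(peak_velocity = NULL, diameter = NULL,
                           heart_rate = NULL,
                           model = blood_viscosity_model(),
                           nominal_shear_rate = NULL,
                           crit_coef = 169, crit_alpha_exp = 0.83,
                           crit_strouhal_exp = -0.27,
                           re_peak = NULL, re_crit = NULL) {
  need_geom <- is.null(re_peak) || is.null(re_crit)
  if (need_geom) {
    if (is.null(peak_velocity) || is.null(diameter) || is.null(heart_rate)) {
      abort("Provide peak_velocity, diameter and heart_rate (or both re_peak and re_crit).")
    }
    if (any(c(peak_velocity, diameter, heart_rate) <= 0)) {
      abort("Velocity, diameter and heart rate must be positive.")
    }
  }
  rho <- model$density_kg_m3
  mu <- NA_real_
  alpha <- NA_real_
  if (!is.null(peak_velocity) && !is.null(diameter) &&
      !is.null(heart_rate)) {
    g <- nominal_shear_rate %||% (peak_velocity / diameter)
    mu <- carreau_yasuda(g, model)
    omega <- 2 * pi * heart_rate / 60
    alpha <- (diameter / 2) * sqrt(omega * rho / mu)
    if (is.null(re_peak)) re_peak <- rho * peak_velocity * diameter / mu
    if (is.null(re_crit)) {
      st <- (heart_rate / 60) * diameter / peak_velocity
      re_crit <- crit_coef * alpha^crit_alpha_exp *
        if (crit_strouhal_exp != 0) st^crit_strouhal_exp else 1
    }
  }
  tibble(re_peak = re_peak, re_crit = re_crit, womersley = alpha,
         viscosity_Pa_s = mu, turbulent = re_peak > re_crit)
}

#' Bland-Altman agreement analysis
#'
#' Pairwise agreement between two measurement sets: per-pair mean and
#' difference `a - b`, the bias (mean difference) and the limits of
#' agreement at bias +/- 1.96 sample standard deviations of the
#' differences.
#'
#' @param values_a,values_b Numeric vectors of equal length (>= 2).
#' @return A `bland_altman` object; see [tidy.bland_altman()] and
#'   [glance.bland_altman()].
#' @examples
#' ba <- bland_altman(c(1, 3), c(2, 2))
#' glance(ba)
#' @export
bland_altman <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    abort("`values_a` and `values_b` must have equal length.")
  }
  if (length(values_a) < 2) abort("At least 2 pairs are required.")
  d <- values_a - values_b
  bias <- mean(d)
  s <- sd(d)
  structure(
    list(pairs = tibble(mean = (values_a + values_b) / 2, difference = d),
         bias = bias, loa_lower = bias - 1.96 * s,
         loa_upper = bias + 1.96 * s, sd_difference = s),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman: %d pairs, bias %.4g, limits of agreement [%.4g, %.4g]>\n",
    nrow(x$pairs), x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Peak and mean velocity-magnitude errors
#'
#' Pointwise discrepancies between modelled and measured velocity
#' magnitude on co-registered plane samples, expressed as a percentage
#' of the mean inlet velocity (signed; positive when the model
#' overestimates): peak error
#' `(max|v_model| - max|v_meas|) / v_inlet * 100` and mean error
#' `mean(|v_model| - |v_meas|) / v_inlet * 100`.
#'
#' @param v_model,v_measured Numeric vectors (velocity magnitudes, m/s)
#'   or plane frames; frames are reduced to their pointwise speeds.
#' @param mean_inlet_velocity Normaliser, m/s, positive.
#' @return One-row tibble: `peak_error_pct`, `mean_error_pct`.
#' @export
velocity_errors <- function(v_model, v_measured, mean_inlet_velocity) {
  speed <- function(v) {
    if (is.data.frame(v)) sqrt(v$vx_m_s^2 + v$vy_m_s^2 + v$vz_m_s^2)
    else abs(v)
  }
  vm <- speed(v_model)
  vo <- speed(v_measured)
  if (length(vm) != length(vo)) {
    abort("Model and measured samples must be co-registered (equal length).")
  }
  if (!isTRUE(mean_inlet_velocity > 0)) {
    abort("`mean_inlet_velocity` must be positive.")
  }
  tibble(
    peak_error_pct = (max(vm) - max(vo)) / mean_inlet_velocity * 100,
    mean_error_pct = mean(vm - vo) / mean_inlet_velocity * 100
  )
}
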