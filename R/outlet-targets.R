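#' Flow fractions within a group of branch measurements
#'
#' Given mean measured flows for the branches of an outlet group, computes
#' the proportion of the group's flow leaving each branch,
#' `phi = Q_b / sum(Q)`. These fractions redistribute the (more reliable)
#' inter-plane flow loss of the group across its branches, reducing the
#' impact of per-branch measurement uncertainty.
#'
#' @param measurements Data frame of branch measurements, one row per
#'   branch, with at least the column named by `flow`.
#' @param flow Column holding the measured mean flow in mL/s
#'   (default `measured_flow_mL_s`).
#' @return The input tibble with a `phi` column; fractions sum to 1.
#' @examples
#' branch_fractions(tibble::tibble(
#'   outlet = c("BT", "LCC", "LSA"),
#'   measured_flow_mL_s = c(10, 5, 5)))
#' @export
branch_fractions <- function(measurements, flow = "measured_flow_mL_s") {
  measurements <- as_tibble(measurements)
  if (!flow %in% names(measurements)) {
    abort(sprintf("Column `%s` not found in `measurements`.", flow))
  }
  q <- measurements[[flow]]
  if (length(q) == 0) abort("`measurements` must have at least one row.")
  if (any(!is.finite(q))) abort("Measured flows must be finite.")
  if (any(q < 0)) abort("Measured flows must be non-negative.")
  total <- sum(q)
  if (total <= 0) {
    abort("All measured flows are zero: the flow split is undefined.")
  }
  mutate(measurements, phi = q / total)
}

#' Target mean flows from fractions and the group flow loss
#'
#' Distributes the mean flow loss measured between planes bracketing the
#' group, `Q_loss`, across the branches in proportion to their fractions:
#' `Q_target = phi * Q_loss`.
#'
#' @param fractions Data frame with a `phi` column (e.g. from
#'   [branch_fractions()]).
#' @param group_flow_loss Inter-plane mean flow loss of the group, mL/s.
#' @param tol Allowed deviation of `sum(phi)` from 1 (default 1e-6).
#' @return The input tibble with a `target_flow_mL_s` column; targets sum
#'   to `group_flow_loss`.
#' @export
target_flows <- function(fractions, group_flow_loss, tol = 1e-6) {
  fractions <- as_tibble(fractions)
  if (!"phi" %in% names(fractions)) abort("`fractions` needs a `phi` column.")
  if (!isTRUE(group_flow_loss >= 0)) {
    abort("`group_flow_loss` must be non-negative.")
  }
  if (abs(sum(fractions$phi) - 1) > tol) {
    abort("`phi` must sum to 1 (deviation exceeds tolerance).")
  }
  mutate(fractions, target_flow_mL_s = .data$phi * group_flow_loss)
}

#' Aortic inlet pressure targets from a brachial cuff measurement
#'
#' Diastolic pressure is nearly constant along the arterial tree, so the
#' aortic diastolic target equals the brachial measurement. Systolic
#' pressure amplifies peripherally; the aortic systolic target is the
#' empirical back-transform `P_s = 0.83 * P's + 0.15 * P'd`. Values are
#' kept at full precision; use [format_pressure_targets()] for the
#' integer-mmHg presentation.
#'
#' @param brachial_systolic,brachial_diastolic Brachial cuff pressures in
#'   mmHg; systolic must exceed diastolic, both positive.
#' @return One-row tibble with brachial and aortic systolic, diastolic and
#'   pulse pressures (mmHg).
#' @examples
#' aortic_pressure_targets(138, 81)
#' @export
aortic_pressure_targets <- function(brachial_systolic, brachial_diastolic) {
  if (!isTRUE(brachial_diastolic > 0)) {
    abort("Brachial diastolic pressure must be positive.")
  }
  if (!isTRUE(brachial_systolic > brachial_diastolic)) {
    abort("Brachial systolic pressure must exceed diastolic pressure.")
  }
  p_s <- 0.83 * brachial_systolic + 0.15 * brachial_diastolic
  p_d <- brachial_diastolic
  tibble(
    brachial_systolic_mmHg = brachial_systolic,
    brachial_diastolic_mmHg = brachial_diastolic,
    systolic_mmHg = p_s,
    diastolic_mmHg = p_d,
    pulse_mmHg = p_s - p_d
  )
}

#' @rdname aortic_pressure_targets
#' @param targets Output of [aortic_pressure_targets()].
#' @return For `format_pressure_targets()`: the same tibble rounded to
#'   integer mmHg, with the pulse recomputed from the rounded values.
#' @export
format_pressure_targets <- function(targets) {
  targets <- as_tibble(targets)
  out <- mutate(targets,
                across(c("systolic_mmHg", "diastolic_mmHg"), round))
  mutate(out, pulse_mmHg = .data$systolic_mmHg - .data$diastolic_mmHg)
}

#' Target flows for grouped minor branches from literature values
#'
#' Minor branches (intercostal/subcostal/lumbar segmentals, the inferior
#' mesenteric artery) are below 4D-flow resolution, so their per-branch
#' mean flows come from published Doppler measurements. Each group's
#' target is the sum of its members' flows.
#'
#' @param branch_flows Data frame with columns `branch`, `group` and
#'   `flow_mL_s` (one row per individual branch).
#' @return Tibble with one row per group: `group`, `n_branches`,
#'   `target_flow_mL_s`.
#' @export
minor_group_targets <- function(branch_flows) {
  branch_flows <- as_tibble(branch_flows)
  req <- c("branch", "group", "flow_mL_s")
  miss <- setdiff(req, names(branch_flows))
  if (length(miss) > 0) {
    abort(sprintf("`branch_flows` is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (nrow(branch_flows) == 0) abort("`branch_flows` has no rows.")
  bad <- branch_flows$branch[!is.finite(branch_flows$flow_mL_s)]
  if (length(bad) > 0) {
    abort(sprintf("Missing literature flow for branch(es): %s",
                  paste(bad, collapse = ", ")))
  }
  if (any(branch_flows$flow_mL_s < 0)) abort("Branch flows must be >= 0.")
  branch_flows |>
    group_by(.data$group) |>
    summarise(n_branches = n(),
              target_flow_mL_s = sum(.data$flow_mL_s),
              .groups = "drop")
}
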