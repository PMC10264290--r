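#' Packaged study fixture
#'
#' The package ships the worked example it was built around: a chronic
#' type-B aortic dissection case with two model variants, `D` (major
#' branches only, 11 outlets) and `D_min` (major plus grouped minor
#' branches, 16 outlets). `study_wk3_table()` returns target and
#' simulated mean outlet flows with the calibrated WK3 parameters;
#' `study_pressure_table()` the brachial measurement and derived aortic
#' inlet targets; `study_config()` the full configuration (heart rate 94
#' bpm, solver and metric settings, minor-branch groups);
#' `study_minor_branches()` the per-branch literature flows, distributed
#' equally within each group.
#'
#' @param case `"D"`, `"D_min"` or `"both"` (default).
#' @return Tibbles (or, for `study_config()`, a nested list).
#' @examples
#' study_wk3_table("D")
#' study_pressure_table()
#' @export
study_wk3_table <- function(case = c("both", "D", "D_min")) {
  case <- match.arg(case)
  path <- system.file("extdata", "study_wk3_table.csv",
                      package = "dissectflow", mustWork = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (case != "both") tab <- filter(tab, .data$case == !!case)
  tab
}

#' @rdname study_wk3_table
#' @export
study_pressure_table <- function() {
  cfg <- study_config()
  targets <- aortic_pressure_targets(cfg$study$brachial_systolic_mmHg,
                                     cfg$study$brachial_diastolic_mmHg)
  rounded <- format_pressure_targets(targets)
  tibble(
    row = c("brachial_measurement", "aortic_inlet_target"),
    systolic_mmHg = c(targets$brachial_systolic_mmHg,
                      rounded$systolic_mmHg),
    diastolic_mmHg = c(targets$brachial_diastolic_mmHg,
                       rounded$diastolic_mmHg),
    pulse_mmHg = c(targets$brachial_systolic_mmHg -
                     targets$brachial_diastolic_mmHg,
                   rounded$pulse_mmHg)
  )
}

#' @rdname study_wk3_table
#' @export
study_config <- function() {
  path <- system.file("extdata", "study_config.yaml",
                      package = "dissectflow", mustWork = TRUE)
  read_study_config(path)
}

#' @rdname study_wk3_table
#' @export
study_minor_branches <- function() {
  cfg <- study_config()
  g <- cfg$minor_groups
  bind_rows(lapply(names(g), function(nm) {
    n <- g[[nm]]$n_branches
    tibble(branch = if (n == 1) nm else paste0(nm, "_", seq_len(n)),
           group = nm, lumen = g[[nm]]$lumen,
           flow_mL_s = g[[nm]]$group_flow_mL_s / n)
  }))
}
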