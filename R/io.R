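#' Read and write package file formats
#'
#' Plain-text interchange formats with units embedded in column names;
#' all round trips preserve full numeric precision.
#' \itemize{
#'   \item Waveforms: CSV with `time_s`, `flow_mL_s` (plus a `# period_s=`
#'     comment header).
#'   \item Plane frames: CSV with `point_id`, `x_mm`, `y_mm`, `z_mm`,
#'     `vx_m_s`, `vy_m_s`, `vz_m_s`, `area_mm2`, `t_s`.
#'   \item WK3 tables: CSV with `outlet`, `r_total_mmHg_per_mL_s`, `rho`,
#'     `c_mL_per_mmHg` (derived resistances recomputed on read).
#' }
#'
#' @param path File path.
#' @param wf,frame,series,params Objects to write.
#' @name dissectflow-io
NULL

fmt_full <- function(x) {
  vapply(x, function(v) format(v, digits = 17, scientific = FALSE),
         character(1))
}

#' @rdname dissectflow-io
#' @export
write_waveform_csv <- function(wf, path) {
  stopifnot(is_flow_waveform(wf))
  writeLines(c(sprintf("# period_s=%s",
                       format(waveform_period(wf), digits = 17)),
               sub("\n+$", "", readr::format_csv(as_tibble(wf)))), path)
  invisible(path)
}

#' @rdname dissectflow-io
#' @export
read_waveform_csv <- function(path) {
  first <- readLines(path, n = 1)
  period <- NA_real_
  if (grepl("^# period_s=", first)) {
    period <- as.numeric(sub("^# period_s=", "", first))
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("time_s", "flow_mL_s") %in% names(df))) {
    abort("Waveform CSV needs columns `time_s` and `flow_mL_s`.")
  }
  if (is.na(period)) {
    # fall back: assume the last sample spacing continues to the period
    period <- df$time_s[nrow(df)] + diff(tail(df$time_s, 2))
  }
  flow_waveform(df$time_s, df$flow_mL_s, period)
}

#' @rdname dissectflow-io
#' @param normal Plane normal for `read_plane_series_csv()`.
#' @param period Cycle period for `read_plane_series_csv()`.
#' @export
write_plane_series_csv <- function(series, path) {
  readr::write_csv(as_tibble(series), path)
  invisible(path)
}

#' @rdname dissectflow-io
#' @export
read_plane_series_csv <- function(path, normal, period) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  plane_series(df, normal = normal, period = period)
}

#' @rdname dissectflow-io
#' @export
write_wk3_table <- function(params, path) {
  readr::write_csv(as_tibble(params), path)
  invisible(path)
}

#' @rdname dissectflow-io
#' @export
read_wk3_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("outlet", "r_total_mmHg_per_mL_s", "rho", "c_mL_per_mmHg")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    abort(sprintf("WK3 table is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  bad <- which(df$r_total_mmHg_per_mL_s <= 0 | df$c_mL_per_mmHg <= 0 |
                 df$rho <= 0 | df$rho >= 1)
  if (length(bad) > 0) {
    abort(sprintf("Invalid WK3 parameters at row(s): %s",
                  paste(bad, collapse = ", ")))
  }
  wk3_params(df$outlet, df$r_total_mmHg_per_mL_s, df$rho, df$c_mL_per_mmHg)
}

config_required_keys <- c("study", "solver", "metrics", "viscosity",
                          "seeds", "minor_groups", "rho_defaults")

#' Read a study configuration file
#'
#' YAML configuration with explicit units in key names. The schema is
#' validated: all of `study`, `solver`, `metrics`, `viscosity`, `seeds`,
#' `minor_groups`, `rho_defaults` must be present and unknown top-level
#' keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return Nested list with an added `config_hash` attribute (MD5 of the
#'   file) for provenance.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  miss <- setdiff(config_required_keys, names(cfg))
  if (length(miss) > 0) {
    abort(sprintf("Config is missing section(s): %s",
                  paste(miss, collapse = ", ")))
  }
  unknown <- setdiff(names(cfg), config_required_keys)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config section(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  for (k in c("heart_rate_bpm", "brachial_systolic_mmHg",
              "brachial_diastolic_mmHg")) {
    if (is.null(cfg$study[[k]])) {
      abort(sprintf("Config `study` section is missing `%s`.", k))
    }
  }
  attr(cfg, "config_hash") <- unname(tools::md5sum(path))
  cfg
}

#' @rdname read_study_config
#' @param cfg Configuration list.
#' @export
write_study_config <- function(cfg, path) {
  yaml::write_yaml(cfg[config_required_keys], path)
  invisible(path)
}

#' Export per-node surface maps as legacy VTK polydata
#'
#' Writes an ASCII legacy-VTK polydata file with the node coordinates as
#' points (each a VERTEX cell) and the requested columns as named
#' POINT_DATA scalar arrays, readable by standard VTK-based viewers.
#'
#' @param df Data frame with `x_mm`, `y_mm`, `z_mm` and the columns in
#'   `fields`.
#' @param path Output path (conventionally `.vtk`).
#' @param fields Character vector of scalar columns to export (default:
#'   `tawss_Pa`, `osi`, `ecap_per_Pa` where present).
#' @return The path, invisibly.
#' @export
export_vtk_polydata <- function(df, path,
                                fields = intersect(
                                  c("tawss_Pa", "osi", "ecap_per_Pa"),
                                  names(df))) {
  df <- as_tibble(df)
  req <- c("x_mm", "y_mm", "z_mm")
  if (!all(req %in% names(df))) {
    abort("`df` needs columns x_mm, y_mm, z_mm.")
  }
  miss <- setdiff(fields, names(df))
  if (length(miss) > 0) {
    abort(sprintf("Field column(s) not found: %s",
                  paste(miss, collapse = ", ")))
  }
  n <- nrow(df)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "dissectflow surface maps",
               "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  writeLines(paste(fmt_full(df$x_mm), fmt_full(df$y_mm),
                   fmt_full(df$z_mm)), con)
  writeLines(sprintf("VERTICES %d %d", n, 2 * n), con)
  writeLines(paste(1, seq_len(n) - 1), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  for (f in fields) {
    writeLines(c(sprintf("SCALARS %s double 1", f),
                 "LOOKUP_TABLE default"), con)
    writeLines(fmt_full(df[[f]]), con)
  }
  invisible(path)
}

#' Write a JSON metrics report
#'
#' Serialises a named list of scalar metrics (plus run provenance:
#' package version, timestamp and optionally a config hash) to JSON.
#'
#' @param metrics Named list of scalars or small tables.
#' @param path Output path.
#' @param config_hash Optional provenance hash (see
#'   [read_study_config()]).
#' @return The path, invisibly.
#' @export
write_metrics_json <- function(metrics, path, config_hash = NULL) {
  payload <- list(
    package = "dissectflow",
    version = as.character(utils::packageVersion("dissectflow")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config_hash = config_hash,
    metrics = metrics
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
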