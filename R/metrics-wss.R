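#' Wall shear stress vector history
#'
#' Long-format container for per-node WSS vectors sampled on a uniform
#' grid over one cycle: columns `node`, `t_s`, `taux_Pa`, `tauy_Pa`,
#' `tauz_Pa`, plus a `period_s` attribute. Sampling every 5 ms is the
#' conventional post-processing cadence; the indices are robust to it
#' (see [wss_metrics()]).
#'
#' @param df Data frame with the columns above.
#' @param period Cycle period in seconds.
#' @return A `wss_history` tibble.
#' @export
wss_history <- function(df, period) {
  df <- as_tibble(df)
  req <- c("node", "t_s", "taux_Pa", "tauy_Pa", "tauz_Pa")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    abort(sprintf("`df` is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  ts <- sort(unique(df$t_s))
  if (length(ts) < 2) abort("At least 2 time samples are required.")
  steps <- diff(ts)
  if (max(steps) - min(steps) > 1e-9 * max(steps)) {
    abort("WSS histories must be sampled on a uniform grid.")
  }
  if (ts[1] != 0 || ts[length(ts)] >= period) {
    abort("Samples must lie in [0, period).")
  }
  structure(df, period_s = as.numeric(period),
            class = unique(c("wss_history", class(df))))
}

#' TAWSS, OSI and ECAP per node
#'
#' Time-averaged wall shear stress `TAWSS = (1/T) integral |tau| dt`,
#' oscillatory shear index
#' `OSI = 0.5 (1 - |integral tau dt| / integral |tau| dt)` and
#' endothelial cell activation potential `ECAP = OSI / TAWSS`. Integrals
#' use the trapezoidal rule with periodic closure. Nodes with zero
#' unsigned integral (no shear at all) are degenerate: OSI and ECAP are
#' defined as 0 there and flagged.
#'
#' @param history A [wss_history()].
#' @return Tibble per node: `node`, `tawss_Pa`, `osi`, `ecap_per_Pa`,
#'   `degenerate`.
#' @examples
#' h <- wss_history(tibble::tibble(
#'   node = 1, t_s = seq(0, 0.95, 0.05),
#'   taux_Pa = 2, tauy_Pa = 0, tauz_Pa = 0), period = 1)
#' wss_metrics(h)
#' @export
wss_metrics <- function(history) {
  if (!inherits(history, "wss_history")) {
    abort("`history` must be a wss_history.")
  }
  period <- attr(history, "period_s")
  one <- function(f) {
    f <- arrange(f, .data$t_s)
    tt <- f$t_s
    mag <- sqrt(f$taux_Pa^2 + f$tauy_Pa^2 + f$tauz_Pa^2)
    int_mag <- periodic_trapz(tt, mag, period)
    vint <- c(periodic_trapz(tt, f$taux_Pa, period),
              periodic_trapz(tt, f$tauy_Pa, period),
              periodic_trapz(tt, f$tauz_Pa, period))
    tawss <- int_mag / period
    if (int_mag <= 0) {
      return(tibble(tawss_Pa = 0, osi = 0, ecap_per_Pa = 0,
                    degenerate = TRUE))
    }
    # clamp roundoff: |vector integral| <= unsigned integral analytically
    osi <- min(max(0.5 * (1 - sqrt(sum(vint^2)) / int_mag), 0), 0.5)
    tibble(tawss_Pa = tawss, osi = osi, ecap_per_Pa = osi / tawss,
           degenerate = FALSE)
  }
  history |>
    as_tibble() |>
    group_by(.data$node) |>
    dplyr::group_modify(~ one(.x)) |>
    ungroup()
}

#' Flag nodes above an ECAP threshold
#'
#' ECAP at or above 1.4 1/Pa marks endothelium with critical thrombotic
#' susceptibility (low, oscillatory shear).
#'
#' @param metrics Output of [wss_metrics()].
#' @param threshold ECAP threshold in 1/Pa (default 1.4).
#' @return `metrics` with a logical `ecap_critical` column.
#' @export
ecap_exceeds <- function(metrics, threshold = 1.4) {
  mutate(as_tibble(metrics), ecap_critical = .data$ecap_per_Pa >= threshold)
}
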