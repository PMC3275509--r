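#' Peak tension at knotting
#'
#' P0 is the maximum force over the first 5 s of the record, evaluated at the
#' trace's own (full) acquisition rate. The 5 s window captures the post-knot
#' peak while excluding later decay (< 0.7% decline at 8%/min).
#'
#' @param trace A [tension_trace()] spanning at least 5 s.
#' @param window_s Width of the search window, s.
#' @return Peak tension, N.
#' @export
detect_p0 <- function(trace, window_s = 5) {
  stopifnot(inherits(trace, "tension_trace"))
  i <- trace$times <= window_s
  if (!any(i) || max(trace$times) < window_s)
    stop("validation error: trace must span at least ", window_s, " s")
  max(trace$forces[i])
}

#' Time at which tension first falls to half the peak
#'
#' Scans the trace for the first sample at or below `p0 / 2`; the crossing
#' time is linearly interpolated between the bracketing samples (first
#' crossing wins). If the threshold is never reached within the record the
#' result is censored: the record length in minutes is returned as a lower
#' bound, mirroring the "> 60 min" convention.
#'
#' @param trace A [tension_trace()].
#' @param p0 Peak tension, N (> 0).
#' @return List with `time_min` and logical `censored`.
#' @export
half_tension_time <- function(trace, p0) {
  stopifnot(inherits(trace, "tension_trace"))
  if (!is.numeric(p0) || p0 <= 0) stop("p0 must be > 0")
  thr <- p0 / 2
  below <- which(trace$forces <= thr)
  if (!length(below))
    return(list(time_min = trace_duration(trace) / 60, censored = TRUE))
  j <- below[1L]
  if (j == 1L) return(list(time_min = trace$times[1L] / 60, censored = FALSE))
  t0 <- trace$times[j - 1L]; t1 <- trace$times[j]
  f0 <- trace$forces[j - 1L]; f1 <- trace$forces[j]
  tc <- if (f0 == f1) t1 else t0 + (f0 - thr) / (f0 - f1) * (t1 - t0)
  list(time_min = tc / 60, censored = FALSE)
}

#' Decompose a trace into its three phases
#'
#' Computes the per-suture phase metrics: P0 (peak over the first 5 s at full
#' rate), P1 (mean force over the fixed 55-65 s window — the rapid cutting
#' phase is defined as exactly one minute), Pplat (mean force over the final
#' 60 s of the record), the derived percentages, and the half-tension time.
#' P1, Pplat and the half-time are evaluated on the trace decimated to
#' `analysis_hz` (the relaxation varies on a minutes scale; the full rate is
#' used only for P0).
#'
#' @param trace A [tension_trace()] spanning at least 61 s.
#' @param analysis_hz Decimation rate for segmentation, Hz.
#' @param record_s Nominal full record length, s. Pplat (and the
#'   plateau-to-peak ratio) are only reported when the trace spans it; pass
#'   `NULL` to use the trace's own duration.
#' @return One-row tibble with columns `suture_id`, `tissue`, `p0`, `p1`,
#'   `pplat`, `rcp_loss_pct`, `plateau_ratio_pct`, `half_time_min`,
#'   `half_time_censored`, `pplat_available`, `monotone_warning`.
#' @export
segment_phases <- function(trace, analysis_hz = 1, record_s = 3600) {
  stopifnot(inherits(trace, "tension_trace"))
  dur <- trace_duration(trace)
  if (dur < 61)
    stop("validation error: trace must span at least 61 s (got ",
         round(dur, 1), " s)")
  p0 <- detect_p0(trace)
  dec <- if (trace$sampling_hz > analysis_hz)
    resample_trace(trace, analysis_hz) else trace
  p1 <- mean(dec$forces[dec$times >= 55 & dec$times <= 65])
  if (is.null(record_s)) record_s <- dur
  pplat_available <- dur >= record_s - 1 / analysis_hz
  pplat <- if (pplat_available)
    mean(dec$forces[dec$times > max(dec$times) - 60 + 1e-9]) else NA_real_
  # tolerance of roughly one quantization step for non-monotone flagging
  monotone_warning <- is.finite(p1) && p1 > p0 + 2e-3
  if (monotone_warning)
    warning("non-monotone trace: P1 (", signif(p1, 4), " N) exceeds P0 (",
            signif(p0, 4), " N) for ", trace$suture_id)
  ht <- half_tension_time(dec, p0)
  tibble::tibble(
    suture_id = trace$suture_id, tissue = trace$tissue,
    p0 = p0, p1 = p1, pplat = pplat,
    rcp_loss_pct = 100 * (p0 - p1) / p0,
    plateau_ratio_pct = if (pplat_available) 100 * pplat / p0 else NA_real_,
    half_time_min = ht$time_min, half_time_censored = ht$censored,
    pplat_available = pplat_available, monotone_warning = monotone_warning)
}

#' Phase metrics for a list of traces
#'
#' @param traces List of [tension_trace()]s.
#' @param ... Passed to [segment_phases()].
#' @return Tibble with one row per trace.
#' @export
analyze_traces <- function(traces, ...) {
  do.call(rbind, lapply(traces, segment_phases, ...))
}
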