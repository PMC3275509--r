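#' Evaluate the relaxation model
#'
#' The declining phase is modelled as `y(t) = d + a * exp(-b * t^c)` with `t`
#' in minutes since the start of the fit window, so that `y(0) = a + d`
#' anchors the amplitude `a` at the above-plateau gap at the 1-minute
#' transition (a = P1 - Pplat, d = Pplat).
#'
#' @param a Amplitude above the plateau, N.
#' @param b Decay rate per minute.
#' @param c Time exponent (c = 1 gives pure exponential decay of the gap).
#' @param d Plateau tension, N.
#' @param t Time in minutes since the window start, >= 0.
#' @return Model tension, N.
#' @export
#' @examples
#' model_eval(1, 0.1, 1, 0.5, 0)          # 1.5
#' model_eval(1, 0.1, 1, 0.5, log(2)/0.1) # 1.0: gap halved
model_eval <- function(a, b, c, d, t) {
  if (any(t < 0)) stop("domain error: t must be >= 0 (minutes)")
  d + a * exp(-b * t^c)
}

#' Starting values for the relaxation fit
#'
#' `d0` is the mean of the last decile of forces; `a0` the first-point force
#' above `d0` (floored at a small positive value); `c0 = 1`; `b0` the
#' log-gap slope between the first point and the point nearest mid-window,
#' floored at 1e-3 per minute. A non-decaying trace yields a flat-curve
#' guess with a diagnostic flag.
#'
#' @param times_min Times in minutes from the window start, >= 10 points
#'   spanning >= 10 min.
#' @param forces Forces, N.
#' @return List with `a0`, `b0`, `c0`, `d0` and logical `flat`.
#' @export
initial_guess <- function(times_min, forces) {
  n <- length(forces)
  if (n < 10L || diff(range(times_min)) < 10)
    stop("validation error: need >= 10 points spanning >= 10 min")
  eps <- 1e-6
  d0 <- mean(forces[times_min >= stats::quantile(times_min, 0.9)])
  a0 <- forces[1L] - d0
  flat <- a0 <= eps
  if (flat) return(list(a0 = eps, b0 = 1e-3, c0 = 1, d0 = max(d0, 0),
                        flat = TRUE))
  mid <- which.min(abs(times_min - (times_min[1L] + diff(range(times_min)) / 2)))
  g1 <- max(forces[1L] - d0, eps)
  gm <- max(forces[mid] - d0, eps)
  b0 <- (log(g1) - log(gm)) / max(times_min[mid] - times_min[1L], eps)
  list(a0 = a0, b0 = max(b0, 1e-3), c0 = 1, d0 = max(d0, 0), flat = FALSE)
}

#' Fit the relaxation model to the constant declining phase
#'
#' Bounded nonlinear least squares of `d + a*exp(-b*t^c)` against the trace
#' over the fit window (default: 60 s to the record end), with the trace
#' decimated to `analysis_hz` first and time measured in minutes from the
#' window start. Bounds: `a` in `(0, 2*P0]`, `b` in `[1e-4, 10]`, `d` in
#' `[0, max force in window]`; `c` is fixed at 1 unless `free_c`, then
#' bounded in `[0.2, 3]`. The Levenberg-Marquardt step is delegated to
#' [minpack.lm::nlsLM] (convergence: relative cost change < 1e-10 or 500
#' iterations); on non-convergence the best iterate is returned with
#' `converged = FALSE`.
#'
#' @param trace A [tension_trace()].
#' @param window Numeric `c(start_s, end_s)`; `NA` end means the record end.
#' @param free_c Free the time exponent `c`? Default `FALSE` (the declining
#'   phase loses a constant fraction of its gap per minute, i.e. c = 1).
#' @param analysis_hz Decimation rate, Hz.
#' @return An object of class `relaxation_fit`: fields `a`, `b`, `c`, `d`,
#'   `r_fit` (Pearson correlation of fitted vs measured force over the
#'   window), `window`, `window_min` (window length in minutes), `converged`,
#'   `n_points`, `suture_id`, `tissue`, `flat_guess`.
#' @export
fit_relaxation <- function(trace, window = c(60, NA), free_c = FALSE,
                           analysis_hz = 1) {
  stopifnot(inherits(trace, "tension_trace"))
  dec <- if (trace$sampling_hz > analysis_hz)
    resample_trace(trace, analysis_hz) else trace
  w0 <- window[1L]
  w1 <- if (is.na(window[2L])) max(dec$times) else window[2L]
  if (w0 < 0 || w1 <= w0 || w0 < min(trace$times) - 1 ||
      w1 > max(trace$times) + 1 / analysis_hz)
    stop("validation error: fit window must lie within the trace")
  i <- dec$times >= w0 & dec$times <= w1
  if (sum(i) < 10L)
    stop("validation error: fewer than 10 points in the fit window")
  tm <- (dec$times[i] - w0) / 60
  y <- dec$forces[i]
  p0 <- if (max(trace$times) >= 5) detect_p0(trace) else max(trace$forces)
  g <- initial_guess(tm, y)
  dat <- data.frame(tm = tm, y = y)
  lower <- c(a = 1e-8, b = 1e-4, d = 0)
  upper <- c(a = 2 * p0, b = 10, d = max(y))
  start <- list(a = min(max(g$a0, 1e-8), 2 * p0), b = min(max(g$b0, 1e-4), 10),
                d = min(max(g$d0, 0), max(y)))
  if (free_c) {
    fml <- y ~ d + a * exp(-b * tm^c)
    lower <- c(lower, c = 0.2); upper <- c(upper, c = 3)
    start$c <- 1
  } else {
    fml <- y ~ d + a * exp(-b * tm)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = dat, start = start,
                      lower = lower[names(start)], upper = upper[names(start)],
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    est <- unlist(start); converged <- FALSE
    yhat <- model_eval(est[["a"]], est[["b"]],
                       if (free_c) est[["c"]] else 1, est[["d"]], tm)
  } else {
    est <- coef(fit)
    converged <- isTRUE(fit$convInfo$isConv)
    yhat <- as.numeric(fitted(fit))
  }
  r_fit <- if (sd(y) > 0 && sd(yhat) > 0) cor(yhat, y) else NA_real_
  structure(list(a = unname(est["a"]), b = unname(est["b"]),
                 c = if (free_c) unname(est["c"]) else 1,
                 d = unname(est["d"]),
                 r_fit = r_fit, window = c(w0, w1),
                 window_min = (w1 - w0) / 60,
                 converged = converged, n_points = sum(i),
                 suture_id = trace$suture_id, tissue = trace$tissue,
                 flat_guess = g$flat),
            class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf(paste0("<relaxation_fit> %s (%s): a=%.4g b=%.4g c=%.3g d=%.4g",
                     "  r=%.5f  [%gs, %gs] %s\n"),
              x$suture_id, x$tissue, x$a, x$b, x$c, x$d, x$r_fit,
              x$window[1], x$window[2],
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Per-minute percent decline of the above-plateau gap
#'
#' For `c = 1` the gap above the plateau shrinks by the constant fraction
#' `1 - exp(-b)` each minute. For `c != 1` the decline is not constant and
#' the geometric-mean per-minute decline over the fit window is returned:
#' `100 * (1 - (gap(t_end)/gap(t_start))^(1/(t_end - t_start)))`.
#'
#' @param fit A converged [fit_relaxation()] result.
#' @return Percent decline per minute.
#' @export
#' @examples
#' # b = -log(0.92) corresponds to an 8%/min decline
#' f <- structure(list(a = 1, b = -log(0.92), c = 1, d = 0.5,
#'                     window_min = 59, converged = TRUE),
#'                class = "relaxation_fit")
#' decline_per_minute(f)
decline_per_minute <- function(fit) {
  stopifnot(inherits(fit, "relaxation_fit"))
  if (!isTRUE(fit$converged))
    warning("decline_per_minute on a non-converged fit")
  if (fit$a <= 0) stop("undefined: non-positive gap at the window start")
  if (fit$c == 1) return(100 * (1 - exp(-fit$b)))
  te <- fit$window_min
  ratio <- exp(-fit$b * te^fit$c)  # gap(t_end)/gap(0)
  if (ratio <= 0) stop("undefined: non-positive gap at the window end")
  100 * (1 - ratio^(1 / te))
}

#' Half-tension time implied by the fitted model
#'
#' Solves `d + a*exp(-b*t^c) = p0/2` for `t` (minutes since the 1-minute
#' transition) and adds the 1-minute rapid-phase offset. Censored when the
#' plateau `d` already exceeds the threshold (the model never crosses); if
#' the threshold exceeds `a + d` the curve starts below half-peak and the
#' 1-minute boundary is returned with a flag — the measured-trace crossing
#' from [half_tension_time()] takes precedence there.
#'
#' @param fit A converged [fit_relaxation()] result.
#' @param p0 Peak tension, N.
#' @return List with `time_min`, `censored`, and `boundary` (crossing at or
#'   before the window start).
#' @export
half_time_from_fit <- function(fit, p0) {
  stopifnot(inherits(fit, "relaxation_fit"))
  if (!is.numeric(p0) || p0 <= 0) stop("p0 must be > 0")
  if (!isTRUE(fit$converged)) warning("half_time_from_fit on a non-converged fit")
  thr <- p0 / 2
  offset <- fit$window[1L] / 60  # rapid-phase duration, min
  if (fit$d >= thr)
    return(list(time_min = offset + fit$window_min, censored = TRUE,
                boundary = FALSE))
  if (thr >= fit$a + fit$d)
    return(list(time_min = offset, censored = FALSE, boundary = TRUE))
  if (fit$c == 1) {
    tm <- log(fit$a / (thr - fit$d)) / fit$b
  } else {
    f <- function(t) model_eval(fit$a, fit$b, fit$c, fit$d, t) - thr
    hi <- fit$window_min
    while (f(hi) > 0 && hi < 1e6) hi <- hi * 2
    tm <- uniroot(f, c(0, hi), tol = 1e-6 * max(hi, 1))$root
  }
  list(time_min = tm + offset, censored = FALSE, boundary = FALSE)
}

#' Fit the relaxation model to a list of traces
#'
#' Convenience wrapper producing one row per trace with the fitted
#' parameters, fit quality, per-minute decline, and the model-implied
#' half-tension time.
#'
#' @param traces List of [tension_trace()]s.
#' @param free_c,analysis_hz Passed to [fit_relaxation()].
#' @return Tibble with columns `suture_id`, `tissue`, `a`, `b`, `c`, `d`,
#'   `r_fit`, `converged`, `decline_pct_per_min`, `half_time_min`,
#'   `half_time_censored`.
#' @export
fit_traces <- function(traces, free_c = FALSE, analysis_hz = 1) {
  rows <- lapply(traces, function(tr) {
    f <- fit_relaxation(tr, free_c = free_c, analysis_hz = analysis_hz)
    p0 <- detect_p0(tr)
    ht <- half_time_from_fit(f, p0)
    dec <- tryCatch(decline_per_minute(f), error = function(e) NA_real_)
    tibble::tibble(suture_id = f$suture_id, tissue = f$tissue,
                   a = f$a, b = f$b, c = f$c, d = f$d, r_fit = f$r_fit,
                   converged = f$converged, decline_pct_per_min = dec,
                   half_time_min = ht$time_min,
                   half_time_censored = ht$censored)
  })
  do.call(rbind, rows)
}
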