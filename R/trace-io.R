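#' Construct a suture tension trace
#'
#' A `tension_trace` holds one suture's force-versus-time record together with
#' its acquisition metadata. Time is measured in seconds from completion of
#' the knot; force is in newtons.
#'
#' @param suture_id Character identifier for the suture.
#' @param tissue One of [tissue_levels()].
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing, starting in `[0, 1)`.
#' @param forces Numeric vector of tensions in newtons, same length as
#'   `times`, all finite and non-negative.
#' @param sampling_hz Nominal acquisition rate in Hz.
#' @param meta Named list of free-form annotations (animal id, sensor
#'   resolution, seed, ...).
#'
#' @return An object of class `tension_trace`.
#' @export
tension_trace <- function(suture_id, tissue, times, forces, sampling_hz,
                          meta = list()) {
  if (!is.character(suture_id) || length(suture_id) != 1L)
    stop("`suture_id` must be a single string")
  if (!is.character(tissue) || length(tissue) != 1L || !tissue %in% TISSUES)
    stop("format error: unknown tissue '", paste(tissue, collapse = ","),
         "' (expected one of ", paste(TISSUES, collapse = ", "), ")")
  times <- as.numeric(times); forces <- as.numeric(forces)
  if (length(times) != length(forces))
    stop("validation error: times and forces differ in length")
  if (length(times) < 2L)
    stop("validation error: a trace needs at least 2 samples")
  if (anyNA(times) || any(!is.finite(times)) || any(diff(times) <= 0))
    stop("validation error: non-monotone time column")
  if (times[1L] < 0 || times[1L] >= 1)
    stop("validation error: first sample time must lie in [0, 1) s, got ",
         times[1L])
  bad <- which(!is.finite(forces) | forces < 0)
  if (length(bad))
    stop("validation error: negative or non-finite force at row ", bad[1L],
         " (", forces[bad[1L]], " N)")
  if (!is.numeric(sampling_hz) || length(sampling_hz) != 1L || sampling_hz <= 0)
    stop("validation error: sampling_hz must be a positive number")
  if (!is.list(meta)) stop("`meta` must be a list")
  structure(
    list(suture_id = suture_id, tissue = tissue,
         times = times, forces = forces,
         sampling_hz = as.numeric(sampling_hz), meta = meta),
    class = "tension_trace"
  )
}

#' @export
print.tension_trace <- function(x, ...) {
  dur <- trace_duration(x)
  cat(sprintf("<tension_trace> %s (%s): %d samples @ %g Hz, %.1f s, %.3f-%.3f N\n",
              x$suture_id, x$tissue, length(x$times), x$sampling_hz, dur,
              min(x$forces), max(x$forces)))
  invisible(x)
}

# nominal record length in seconds (last stamp plus one effective period)
trace_duration <- function(trace) {
  dt <- median(diff(trace$times))
  max(trace$times) + dt
}

#' Convert grams-force to newtons
#'
#' The sensor's resolution is quoted in grams-force; analysis is carried out
#' in newtons throughout (1 gf = 9.80665e-3 N).
#'
#' @param value Force in grams-force.
#' @return Force in newtons.
#' @export
#' @examples
#' gforce_to_newton(0.077)  # the sensor quantization step
gforce_to_newton <- function(value) {
  if (any(!is.finite(value))) stop("`value` must be finite")
  value * 9.80665e-3
}

#' Read a tension trace from a delimited text file
#'
#' The file format is a `#`-prefixed `key=value` metadata header (which must
#' include `tissue`, and usually `suture_id` and `sampling_hz`) followed by a
#' two-column CSV body with columns `time_s,force_N`.
#'
#' @param path Path to a trace file written by [write_trace()] (or compatible).
#' @return A validated [tension_trace()]; metadata keys are preserved verbatim.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- character(); repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  meta <- list()
  for (ln in hdr) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1L, eq - 1L)]] <- substr(kv, eq + 1L, nchar(kv))
  }
  if (is.null(meta$tissue))
    stop("format error: header lacks a 'tissue' key: ", path)
  body <- data.table::fread(path, skip = length(hdr), header = TRUE,
                            data.table = FALSE)
  if (!all(c("time_s", "force_N") %in% names(body)))
    stop("format error: body must have columns time_s,force_N: ", path)
  suture_id <- if (!is.null(meta$suture_id)) meta$suture_id else
    sub("\\.[^.]*$", "", basename(path))
  hz <- if (!is.null(meta$sampling_hz)) as.numeric(meta$sampling_hz) else
    1 / median(diff(body$time_s))
  keep <- setdiff(names(meta), c("tissue", "suture_id", "sampling_hz"))
  tension_trace(suture_id = suture_id, tissue = meta$tissue,
                times = body$time_s, forces = body$force_N,
                sampling_hz = hz, meta = meta[keep])
}

#' Write a tension trace to a delimited text file
#'
#' Produces a file readable by [read_trace()]: `#`-prefixed `key=value`
#' header, then a `time_s,force_N` CSV body written with full precision
#' (>= 6 significant digits).
#'
#' @param trace A [tension_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "tension_trace"))
  hdr <- c(sprintf("# tissue=%s", trace$tissue),
           sprintf("# suture_id=%s", trace$suture_id),
           sprintf("# sampling_hz=%.10g", trace$sampling_hz))
  for (k in names(trace$meta))
    hdr <- c(hdr, sprintf("# %s=%s", k, format(trace$meta[[k]])))
  ok <- tryCatch({ writeLines(hdr, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write to ", path)
  data.table::fwrite(data.table::data.table(time_s = trace$times,
                                            force_N = trace$forces),
                     path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Decimate a trace to a lower sampling rate by block means
#'
#' Non-overlapping blocks of `sampling_hz / target_hz` consecutive samples are
#' averaged; the reported time of each output sample is the mean time of its
#' block, so for a locally linear signal the output force sits exactly on the
#' signal at the reported time. A trailing partial block is dropped. No
#' interpolation or upsampling is performed.
#'
#' @param trace A [tension_trace()].
#' @param target_hz Target rate in Hz; must divide `sampling_hz`.
#' @return A [tension_trace()] at `target_hz`.
#' @export
resample_trace <- function(trace, target_hz) {
  stopifnot(inherits(trace, "tension_trace"))
  if (!is.numeric(target_hz) || target_hz <= 0)
    stop("`target_hz` must be positive")
  if (target_hz > trace$sampling_hz * (1 + 1e-9))
    stop("unsupported: target_hz (", target_hz,
         ") exceeds acquisition rate (", trace$sampling_hz, " Hz); ",
         "upsampling is not performed")
  k <- trace$sampling_hz / target_hz
  if (abs(k - round(k)) > 1e-8)
    stop("unsupported: target_hz must divide sampling_hz (ratio ", k, ")")
  k <- as.integer(round(k))
  if (k == 1L) return(trace)
  n <- length(trace$times)
  nb <- n %/% k
  if (nb < 2L) stop("validation error: fewer than 2 output samples")
  idx <- seq_len(nb * k)
  tm <- .colMeans(trace$times[idx],  k, nb)
  fm <- .colMeans(trace$forces[idx], k, nb)
  tension_trace(trace$suture_id, trace$tissue, tm, pmax(fm, 0), target_hz,
                meta = trace$meta)
}
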