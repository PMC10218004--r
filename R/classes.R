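#' Waveform container
#'
#' A sampled acoustic (or other) signal with its sampling rate.
#'
#' @param samples numeric vector of amplitudes (arbitrary units).
#' @param fs sampling rate in Hz.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, fs) {
  stopifnot(is.numeric(samples), length(fs) == 1L, fs > 0)
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Envelope (or envelope-derivative) series
#'
#' @param values numeric vector; amplitude (a.u.) for `kind = "envelope"`,
#'   amplitude per second for `kind = "derivative"`.
#' @param fs sampling rate in Hz (100 Hz after extraction by default).
#' @param kind `"envelope"` or `"derivative"`.
#' @return An object of class `envelope_series`.
#' @export
envelope_series <- function(values, fs, kind = c("envelope", "derivative")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(values), fs > 0)
  if (kind == "envelope" && any(values < 0))
    stop("envelope values must be non-negative")
  structure(list(values = as.numeric(values), fs = as.numeric(fs), kind = kind),
            class = "envelope_series")
}

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("<envelope_series [%s]: %d samples @ %g Hz>\n",
              x$kind, length(x$values), x$fs))
  invisible(x)
}

#' Sparse acoustic-landmark events
#'
#' Event times and magnitudes for a landmark series (peakRate: local maxima
#' of the envelope rate-of-change; peakEnv: local maxima of the envelope).
#'
#' @param times event times in seconds, strictly increasing.
#' @param magnitudes positive event magnitudes (envelope units for peakEnv,
#'   envelope units per second for peakRate).
#' @param kind `"peakRate"` or `"peakEnv"`.
#' @param duration total duration in seconds of the signal the events live in.
#' @param utterances optional data.frame with columns `start`, `end` (seconds)
#'   giving the utterance segmentation of the stimulus.
#' @return A data.frame of class `landmark_events` with columns `time_s`,
#'   `magnitude`, `kind`, and attributes `duration` and `utterances`.
#' @export
landmark_events <- function(times, magnitudes, kind = "peakRate",
                            duration = NULL, utterances = NULL) {
  stopifnot(length(times) == length(magnitudes))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("event times must be strictly increasing")
  if (any(magnitudes <= 0)) stop("event magnitudes must be positive")
  if (is.null(duration)) duration <- if (length(times)) max(times) else 0
  out <- data.frame(time_s = as.numeric(times),
                    magnitude = as.numeric(magnitudes),
                    kind = rep_len(kind, length(times)))
  attr(out, "duration") <- as.numeric(duration)
  attr(out, "utterances") <- utterances
  class(out) <- c("landmark_events", "data.frame")
  out
}

#' @export
print.landmark_events <- function(x, ...) {
  kinds <- unique(x$kind)
  cat(sprintf("<landmark_events: %d %s events over %.2f s>\n",
              nrow(x), paste(kinds, collapse = "/"), attr(x, "duration")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("... %d more\n", nrow(x) - 5L))
  invisible(x)
}

#' Continuous response time series (channels x samples)
#'
#' @param data numeric vector (single channel) or channels-by-samples matrix.
#' @param fs sampling rate in Hz.
#' @return An object of class `response_series`.
#' @export
response_series <- function(data, fs) {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1L)
  stopifnot(is.numeric(data), fs > 0)
  if (!all(is.finite(data))) stop("response data must be finite")
  structure(list(data = data, fs = as.numeric(fs)), class = "response_series")
}

#' @export
print.response_series <- function(x, ...) {
  cat(sprintf("<response_series: %d channel(s) x %d samples @ %g Hz>\n",
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Evoked-response kernel over a lag window
#'
#' Per-lag response waveform (a temporal response function), defined on a
#' regular lag grid `lag_window[1]..lag_window[2]` seconds relative to an
#' event at lag 0.
#'
#' @param values numeric vector of kernel values (response units per unit
#'   input); length must equal `round(diff(lag_window) * fs) + 1`.
#' @param lag_window length-2 numeric, lag window in seconds (default
#'   `c(-0.15, 0.45)`).
#' @param fs sampling rate in Hz.
#' @return An object of class `trf_kernel`.
#' @export
trf_kernel <- function(values, lag_window = c(-0.15, 0.45), fs) {
  n_expect <- round(diff(lag_window) * fs) + 1L
  if (length(values) != n_expect)
    stop(sprintf("kernel length %d does not match lag window (expected %d)",
                 length(values), n_expect))
  if (!all(is.finite(values))) stop("kernel values must be finite")
  structure(list(values = as.numeric(values),
                 lag_window = as.numeric(lag_window),
                 fs = as.numeric(fs)),
            class = "trf_kernel")
}

#' Lag grid of a kernel, in seconds
#' @param kernel a `trf_kernel`.
#' @return numeric vector of lags in seconds.
#' @export
kernel_lags <- function(kernel) {
  seq(kernel$lag_window[1], by = 1 / kernel$fs,
      length.out = length(kernel$values))
}

#' @export
print.trf_kernel <- function(x, ...) {
  cat(sprintf("<trf_kernel: %d lags, %g..%g s @ %g Hz>\n",
              length(x$values), x$lag_window[1], x$lag_window[2], x$fs))
  if (!is.null(attr(x, "ridge")))
    cat(sprintf("  ridge: %g\n", attr(x, "ridge")))
  invisible(x)
}

#' @export
coef.trf_kernel <- function(object, ...) {
  stats::setNames(object$values, sprintf("lag_%.4f", kernel_lags(object)))
}

#' @export
plot.trf_kernel <- function(x, ...) {
  graphics::plot(kernel_lags(x), x$values, type = "l",
                 xlab = "lag (s)", ylab = "kernel value", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Event input series s(t)
#'
#' Model input: scaled event magnitudes as single-sample impulses at event
#' samples, zeros otherwise.
#'
#' @param s numeric vector of input values (>= 0).
#' @param fs sampling rate in Hz.
#' @param event_samples integer sample indices of the (possibly jittered)
#'   impulses.
#' @param event_times_s original, unjittered event times in seconds (the
#'   times all phase analyses must use).
#' @return An object of class `event_input`.
#' @export
event_input_series <- function(s, fs, event_samples = which(s > 0),
                               event_times_s = (event_samples - 1) / fs) {
  stopifnot(all(s >= 0), fs > 0)
  structure(list(s = as.numeric(s), fs = as.numeric(fs),
                 event_samples = as.integer(event_samples),
                 event_times_s = as.numeric(event_times_s)),
            class = "event_input")
}

#' @export
print.event_input <- function(x, ...) {
  cat(sprintf("<event_input: %d impulses in %d samples @ %g Hz>\n",
              length(x$event_samples), length(x$s), x$fs))
  invisible(x)
}
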