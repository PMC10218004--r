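#' Extract the broad amplitude envelope of a waveform
#'
#' Rectification, low-pass filtering, and downsampling, in that order.  The
#' low-pass is a zero-phase (noncausal forward-backward) 4th-order
#' Butterworth at `cutoff`, applied spectrally; downsampling is linear
#' interpolation onto the `target_fs` grid.  Output duration is preserved to
#' within one output sample.
#'
#' @param w a [waveform()].
#' @param cutoff low-pass cutoff in Hz (default 10).
#' @param target_fs output sampling rate in Hz (default 100).
#' @param rectify `"full"` (absolute value, default) or `"half"`
#'   (positive part).
#' @param order one-pass Butterworth order (default 4).
#' @return An [envelope_series()] of kind `"envelope"` at `target_fs`.
#' @export
extract_envelope <- function(w, cutoff = 10, target_fs = 100,
                             rectify = c("full", "half"), order = 4L) {
  stopifnot(inherits(w, "waveform"))
  rectify <- match.arg(rectify)
  if (w$fs <= 2 * cutoff)
    stop(sprintf("waveform fs (%g Hz) violates Nyquist for a %g Hz cutoff",
                 w$fs, cutoff))
  if (target_fs < 2 * cutoff)
    stop(sprintf("target_fs (%g Hz) violates Nyquist for a %g Hz cutoff",
                 target_fs, cutoff))
  x <- if (rectify == "full") abs(w$samples) else pmax(w$samples, 0)
  lp <- fft_filter(x, w$fs,
                   function(f) butter_lowpass_gain2(f, cutoff, order),
                   pad_s = 1)
  dur <- length(x) / w$fs
  n_out <- max(1L, round(dur * target_fs))
  t_out <- (seq_len(n_out) - 1) / target_fs
  v <- resample_at(lp, w$fs, t_out)
  envelope_series(pmax(v, 0), target_fs, kind = "envelope")
}

#' First temporal derivative of an envelope
#'
#' First difference scaled by the sampling rate, aligned to the left sample
#' (the final sample is zero so the series length is preserved).
#'
#' @param env an [envelope_series()] of kind `"envelope"`.
#' @return An [envelope_series()] of kind `"derivative"` at the same rate.
#' @export
envelope_derivative <- function(env) {
  stopifnot(inherits(env, "envelope_series"))
  if (env$kind != "envelope") stop("input must be of kind 'envelope'")
  d <- c(diff(env$values) * env$fs, 0)
  envelope_series(d, env$fs, kind = "derivative")
}

#' Detect peakEnv and peakRate landmarks
#'
#' peakEnv events are local maxima of the amplitude envelope; peakRate
#' events are local maxima of the positive part of its first derivative
#' (amplitude rises; negative-slope peaks are discarded).  Each event
#' carries its magnitude.  Peaks must exceed a prominence of
#' `min_prominence` times the series maximum, which suppresses numerical
#' ripple; the threshold is exposed because there is no canonical value.
#'
#' @param env envelope series (kind `"envelope"`).
#' @param denv derivative series aligned with `env`; computed from `env`
#'   when omitted.
#' @param min_prominence minimum peak prominence as a fraction of the series
#'   maximum (default 0.02).
#' @return list with elements `peakEnv` and `peakRate`, each a
#'   [landmark_events()] object.
#' @export
detect_landmarks <- function(env, denv = NULL, min_prominence = 0.02) {
  stopifnot(inherits(env, "envelope_series"), env$kind == "envelope")
  if (is.null(denv)) denv <- envelope_derivative(env)
  stopifnot(inherits(denv, "envelope_series"), denv$kind == "derivative")
  if (denv$fs != env$fs || length(denv$values) != length(env$values))
    stop("env and denv must be aligned at the same rate")
  dur <- length(env$values) / env$fs

  mk <- function(x, kind) {
    top <- max(x)
    if (top <= 0) {
      return(landmark_events(numeric(0), numeric(0), kind, duration = dur))
    }
    idx <- find_peaks(x, min_prominence * top)
    landmark_events((idx - 1) / env$fs, x[idx], kind, duration = dur)
  }
  list(peakEnv = mk(env$values, "peakEnv"),
       peakRate = mk(pmax(denv$values, 0), "peakRate"))
}

#' Time-stretch a signal or event train
#'
#' Uniformly stretches the time axis by `factor`.  For waveforms and
#' envelopes this is envelope-domain resampling: duration is multiplied by
#' `factor`, amplitudes are preserved, and envelope-derivative magnitudes
#' scale by `1/factor`.
#'
#' @param x a `waveform`, `envelope_series`, or `landmark_events` object.
#' @param factor stretch factor (> 0); 3 triples the duration.
#' @param ... passed to methods.
#' @return Object of the same class as `x`.
#' @export
time_stretch <- function(x, factor, ...) UseMethod("time_stretch")

#' @rdname time_stretch
#' @export
time_stretch.waveform <- function(x, factor, ...) {
  if (factor <= 0) stop("stretch factor must be > 0")
  n_out <- max(1L, round(length(x$samples) * factor))
  t_out <- (seq_len(n_out) - 1) / x$fs / factor
  waveform(resample_at(x$samples, x$fs, t_out), x$fs)
}

#' @rdname time_stretch
#' @export
time_stretch.envelope_series <- function(x, factor, ...) {
  if (factor <= 0) stop("stretch factor must be > 0")
  n_out <- max(1L, round(length(x$values) * factor))
  t_out <- (seq_len(n_out) - 1) / x$fs / factor
  v <- resample_at(x$values, x$fs, t_out)
  if (x$kind == "derivative") v <- v / factor
  envelope_series(if (x$kind == "envelope") pmax(v, 0) else v, x$fs, x$kind)
}
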