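#' Log-spaced frequency band specification
#'
#' Band centers `fmin * 2^(k * step_octaves)` up to `fmax` (0.67-9 Hz in
#' 0.1-octave steps by default), with a common half-width in octaves: 0.1
#' ("narrow", spectral precision) or 0.5 ("wide", temporal precision).
#'
#' @param fmin,fmax lowest/highest band center in Hz.
#' @param step_octaves spacing of centers in octaves (default 0.1).
#' @param half_width band half-width in octaves (0.1 narrow, 0.5 wide).
#' @return An object of class `band_spec` with element `centers`.
#' @export
make_band_spec <- function(fmin = 0.67, fmax = 9, step_octaves = 0.1,
                           half_width = 0.1) {
  if (fmin <= 0 || fmin >= fmax) stop("need 0 < fmin < fmax")
  if (half_width <= 0) stop("half_width must be > 0")
  k <- 0:floor(log2(fmax / fmin) / step_octaves + 1e-9)
  structure(list(centers = fmin * 2^(k * step_octaves),
                 step_octaves = step_octaves, half_width = half_width),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec: %d centers %.3g..%.3g Hz, +/-%g octave>\n",
              length(x$centers), min(x$centers), max(x$centers),
              x$half_width))
  invisible(x)
}

# Zero-phase Butterworth band design for one center frequency.
# Passband edges sit at center * 2^(+/- half_width); stopband edges at
# center * 2^(+/- (half_width + 0.5)).  The order n and -3dB width w0 are
# the smallest/widest meeting <= 3 dB passband ripple and >= 24 dB stopband
# attenuation on the DOUBLED (forward-backward) response.
band_filter_design <- function(center, half_width, stop_offset = 0.5,
                               pass_ripple_db = 3, stop_atten_db = 24) {
  bp <- center * (2^half_width - 2^(-half_width))
  bs <- center * (2^(half_width + stop_offset) - 2^(-(half_width + stop_offset)))
  ep <- 10^(pass_ripple_db / 20) - 1     # max B^2n at passband edge
  es <- 10^(stop_atten_db / 20) - 1      # min B^2n at stopband edge
  for (n in 1:25) {
    lo <- bp / ep^(1 / (2 * n))
    hi <- bs / es^(1 / (2 * n))
    if (lo <= hi)
      return(list(order = n, f0 = center, w0 = sqrt(lo * hi),
                  pass_edges = center * 2^c(-half_width, half_width),
                  stop_edges = center * 2^c(-(half_width + stop_offset),
                                            half_width + stop_offset)))
  }
  stop(sprintf("no feasible Butterworth design for band at %.3g Hz", center))
}

# zero-phase gain of a designed band at frequencies f (Hz)
band_gain <- function(design, f) {
  butter_bandpass_gain2(f, design$f0, design$w0, design$order)
}

#' Time-frequency decomposition into band-limited phase and amplitude
#'
#' Per band: zero-phase (noncausal forward-backward) Butterworth band-pass
#' filtering followed by the Hilbert transform; phase and amplitude are the
#' angle and absolute value of the analytic signal.  Filters are applied
#' spectrally with 5 s reflection padding (trimmed afterwards); each band's
#' design is checked against the ripple (3 dB) and stopband-attenuation
#' (24 dB at +/-`half_width + 0.5` octaves) contract at design time.
#'
#' @param x a [response_series()] (channel 1), [envelope_series()],
#'   [waveform()], or numeric vector.
#' @param spec a [make_band_spec()].
#' @param fs sampling rate in Hz (taken from `x` when it carries one).
#' @param pad_s reflection padding in seconds (default 5).
#' @return An object of class `tf_phase_map`: list with `phase` and
#'   `amplitude` (bands x time matrices), `centers`, `fs`, `band_spec`.
#' @export
tf_decompose <- function(x, spec, fs = NULL, pad_s = 5) {
  stopifnot(inherits(spec, "band_spec"))
  if (inherits(x, "response_series")) { v <- x$data[1, ]; fs <- x$fs }
  else if (inherits(x, "envelope_series")) { v <- x$values; fs <- x$fs }
  else if (inherits(x, "waveform")) { v <- x$samples; fs <- x$fs }
  else { v <- as.numeric(x); if (is.null(fs)) stop("fs required") }
  top <- max(spec$centers) * 2^(spec$half_width + 0.5)
  if (fs <= 2 * top)
    stop(sprintf("fs = %g Hz cannot support the band at %.3g Hz (stopband %.3g Hz)",
                 fs, max(spec$centers), top))
  nb <- length(spec$centers)
  n <- length(v)
  ph <- matrix(NA_real_, nb, n)
  am <- matrix(NA_real_, nb, n)
  p <- reflect_pad(v, round(pad_s * fs))
  np <- length(p$x)
  nfft <- stats::nextn(np, c(2L, 3L, 5L))
  f <- fft_freqs(nfft, fs)
  z <- stats::fft(c(p$x, rep(0, nfft - np)))
  h <- numeric(nfft)                    # analytic-signal doubling mask
  h[1] <- 1
  if (nfft %% 2 == 0) { h[nfft / 2 + 1] <- 1; h[2:(nfft / 2)] <- 2 }
  else h[2:((nfft + 1) / 2)] <- 2
  for (b in seq_len(nb)) {
    des <- band_filter_design(spec$centers[b], spec$half_width)
    y <- stats::fft(z * band_gain(des, f) * h, inverse = TRUE) / nfft
    y <- y[(p$pad + 1L):(p$pad + n)]
    ph[b, ] <- Arg(y)
    am[b, ] <- Mod(y)
  }
  structure(list(phase = ph, amplitude = am, centers = spec$centers,
                 fs = fs, band_spec = spec),
            class = "tf_phase_map")
}

#' @export
print.tf_phase_map <- function(x, ...) {
  cat(sprintf("<tf_phase_map: %d bands x %d samples @ %g Hz>\n",
              nrow(x$phase), ncol(x$phase), x$fs))
  invisible(x)
}

#' Select events by minimum gaps to their neighbours
#'
#' Keeps events whose gap to the preceding event is at least `min_gap_pre`
#' and to the following event at least `min_gap_post`; the first and last
#' events are treated as having infinite outer gaps.  Used to isolate
#' phase dynamics from interference by neighbouring phase-resetting events
#' (e.g. post-gap 0.5 s for the spectral analysis; pre 0.2 s / post 1.04 s
#' for the temporal analysis).
#'
#' @param events a [landmark_events()] train (sorted).
#' @param min_gap_pre,min_gap_post minimum gaps in seconds.
#' @return A filtered [landmark_events()] object.
#' @export
select_events <- function(events, min_gap_pre = 0, min_gap_post = 0) {
  stopifnot(inherits(events, "landmark_events"))
  n <- nrow(events)
  if (n == 0L) return(events)
  gap_pre <- c(Inf, diff(events$time_s))
  gap_post <- c(diff(events$time_s), Inf)
  keep <- gap_pre >= min_gap_pre & gap_post >= min_gap_post
  out <- events[keep, , drop = FALSE]
  attr(out, "duration") <- attr(events, "duration")
  attr(out, "utterances") <- attr(events, "utterances")
  class(out) <- class(events)
  out
}

#' Epoch band phases (and amplitudes) around events
#'
#' Copies (never recomputes) the per-band phase in a fixed window around
#' each event sample.  Events whose window would leave the recording are
#' dropped and counted in the `dropped` attribute.
#'
#' @param tf a [tf_decompose()] output.
#' @param events a [landmark_events()] train (times in seconds from signal
#'   start).
#' @param window length-2 numeric window in seconds relative to the event,
#'   e.g. `c(-0.5, 0.5)`.
#' @param amplitude also epoch the band amplitudes (default FALSE).
#' @return An object of class `epoched_phases`: list with `phase`
#'   (events x bands x time array), optional `amplitude`, `times` (window
#'   axis, seconds), `centers`, `fs`, `event_times`, and attribute
#'   `dropped`.
#' @export
epoch_phases <- function(tf, events, window, amplitude = FALSE) {
  stopifnot(inherits(tf, "tf_phase_map"), inherits(events, "landmark_events"))
  fs <- tf$fs
  n <- ncol(tf$phase)
  i0 <- round(window[1] * fs)
  i1 <- round(window[2] * fs)
  rel <- i0:i1
  ev_idx <- round(events$time_s * fs) + 1L
  ok <- (ev_idx + i0) >= 1L & (ev_idx + i1) <= n
  dropped <- sum(!ok)
  ev_idx <- ev_idx[ok]
  if (!length(ev_idx)) stop("no usable events: all epochs leave the recording")
  nb <- nrow(tf$phase)
  arr <- array(NA_real_, c(length(ev_idx), nb, length(rel)))
  amp <- if (amplitude) array(NA_real_, dim(arr)) else NULL
  for (e in seq_along(ev_idx)) {
    cols <- ev_idx[e] + rel
    arr[e, , ] <- tf$phase[, cols]
    if (amplitude) amp[e, , ] <- tf$amplitude[, cols]
  }
  out <- structure(list(phase = arr, amplitude = amp, times = rel / fs,
                        centers = tf$centers, fs = fs,
                        event_times = events$time_s[ok], window = window),
                   class = "epoched_phases")
  attr(out, "dropped") <- dropped
  out
}

#' @export
print.epoched_phases <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf("<epoched_phases: %d events x %d bands x %d samples (%g..%g s)%s>\n",
              d[1], d[2], d[3], x$window[1], x$window[2],
              if (attr(x, "dropped")) sprintf(", %d dropped", attr(x, "dropped"))
              else ""))
  invisible(x)
}
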