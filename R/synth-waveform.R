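#' Generate an amplitude-modulated waveform from an event train
#'
#' End-to-end fixture for the acoustic pipeline: a sinusoidal carrier is
#' amplitude-modulated by a sum of asymmetric rise/decay bumps, one per
#' event, so that each well-separated event produces exactly one peakRate
#' (during the rise, at the event time) and one peakEnv (at the bump peak,
#' `rise/2` later).  Bump amplitude equals the event magnitude; the rise is
#' centered on the event time so the detected peakRate lands on it.
#'
#' Rise/decay default to syllable-like timescales (150/300 ms) slow enough
#' that a 10 Hz envelope low-pass leaves the bump shape (and hence the
#' peakRate magnitude) essentially untouched.  Events closer together than
#' the rise time trigger a warning: their bumps overlap and landmark counts
#' may merge.
#'
#' @param events a [landmark_events()] train driving the bumps.
#' @param fs output sampling rate in Hz (>= 1000).
#' @param carrier_freq carrier frequency in Hz.
#' @param rise,decay bump rise and decay times in seconds (half-raised-cosine
#'   segments).
#' @return A [waveform()] spanning the train's duration.
#' @export
generate_am_waveform <- function(events, fs = 4000, carrier_freq = 220,
                                 rise = 0.15, decay = 0.30) {
  stopifnot(inherits(events, "landmark_events"))
  if (fs < 1000) stop("fs must be >= 1000 Hz")
  dur <- attr(events, "duration")
  n <- max(1L, round(dur * fs))
  env <- numeric(n)
  if (nrow(events)) {
    if (nrow(events) > 1L && any(diff(events$time_s) < rise))
      warning("events closer than the bump rise time: landmarks may merge")
    n_rise <- round(rise * fs)
    n_decay <- round(decay * fs)
    bump <- c((1 - cos(pi * seq_len(n_rise) / n_rise)) / 2,
              (1 + cos(pi * seq_len(n_decay) / n_decay)) / 2)
    for (j in seq_len(nrow(events))) {
      # rise centered on the event time
      i0 <- round((events$time_s[j] - rise / 2) * fs)
      idx <- i0 + seq_along(bump)
      ok <- idx >= 1L & idx <= n
      env[idx[ok]] <- env[idx[ok]] + events$magnitude[j] * bump[ok]
    }
  }
  carrier <- sin(2 * pi * carrier_freq * (seq_len(n) - 1) / fs)
  waveform(env * carrier, fs)
}
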