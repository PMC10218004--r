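#' Specification of a synthetic evoked-response kernel
#'
#' Parameterizes a stereotyped biphasic (plus late rebound) evoked-response
#' waveform standing in for a data-estimated temporal response function:
#' a sum of Gaussian deflections with given latencies, amplitudes and
#' widths, supported on `[0, duration]` within the lag window.  The default
#' shape has its main deflection complete within ~350 ms and dominant
#' spectral content in the theta range (4-8 Hz).
#'
#' @param duration kernel support duration in seconds (default 0.35).
#' @param lag_window lag window in seconds relative to the event
#'   (default `c(-0.15, 0.45)`).
#' @param peak_latencies latencies of the Gaussian deflections, seconds.
#' @param peak_amplitudes signed amplitudes of the deflections.
#' @param peak_widths Gaussian SDs of the deflections, seconds.
#' @param amplitude overall scale factor (0 gives an all-zero kernel).
#' @param fs sampling rate in Hz.
#' @return An object of class `synthetic_kernel_spec`.
#' @export
synthetic_kernel_spec <- function(duration = 0.35,
                                  lag_window = c(-0.15, 0.45),
                                  peak_latencies = c(0.07, 0.16, 0.26),
                                  peak_amplitudes = c(1, -0.90, 0.35),
                                  peak_widths = c(0.026, 0.040, 0.054),
                                  amplitude = 1,
                                  fs = 400) {
  if (duration <= 0) stop("duration must be > 0")
  if (lag_window[1] > 0 || lag_window[2] < duration)
    stop("lag_window must span the kernel support [0, duration]")
  structure(list(duration = duration, lag_window = lag_window,
                 peak_latencies = peak_latencies,
                 peak_amplitudes = peak_amplitudes,
                 peak_widths = peak_widths,
                 amplitude = amplitude, fs = fs),
            class = "synthetic_kernel_spec")
}

#' Generate a synthetic evoked-response kernel
#'
#' @param spec a [synthetic_kernel_spec()].
#' @return A [trf_kernel()] whose support lies within `[0, spec$duration]`
#'   and is zero elsewhere in the lag window.
#' @export
generate_synthetic_kernel <- function(spec = synthetic_kernel_spec()) {
  stopifnot(inherits(spec, "synthetic_kernel_spec"))
  lags <- seq(spec$lag_window[1], spec$lag_window[2], by = 1 / spec$fs)
  v <- numeric(length(lags))
  for (j in seq_along(spec$peak_latencies)) {
    v <- v + spec$peak_amplitudes[j] *
      exp(-(lags - spec$peak_latencies[j])^2 / (2 * spec$peak_widths[j]^2))
  }
  # hard support: zero outside [0, duration]
  v[lags < 0 | lags > spec$duration] <- 0
  v <- v * spec$amplitude
  trf_kernel(v, spec$lag_window, spec$fs)
}
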