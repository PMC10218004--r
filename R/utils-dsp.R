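# Shared DSP internals: spectral zero-phase Butterworth filtering, analytic
# signal extraction, peak finding with prominence, FFT helpers.

# Frequency axis (Hz, signed) for an FFT of length n at rate fs.
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  f <- k / n * fs
  f[f > fs / 2] <- f[f > fs / 2] - fs
  f
}

# Squared magnitude response of an analog-prototype Butterworth low-pass,
# i.e. the zero-phase (forward-backward) gain.  `n` is the one-pass order.
butter_lowpass_gain2 <- function(f, cutoff, n) {
  1 / (1 + (abs(f) / cutoff)^(2 * n))
}

# Zero-phase band-pass gain: squared magnitude of an order-n Butterworth
# band-pass with geometric center f0 and -3dB width w0 (Hz).
butter_bandpass_gain2 <- function(f, f0, w0, n) {
  af <- abs(f)
  b <- ifelse(af == 0, Inf, (af^2 - f0^2) / (af * w0))
  1 / (1 + b^(2 * n))
}

# Reflection padding: mirror `pad` samples at each end (less if x is short).
reflect_pad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad <= 0L) return(list(x = x, pad = 0L))
  list(x = c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)])), pad = pad)
}

# Apply a frequency-domain gain function to x with reflection padding,
# optionally returning the analytic (Hilbert) signal of the filtered series.
# gain_fun(f) must accept the signed frequency axis in Hz.
fft_filter <- function(x, fs, gain_fun, pad_s = 5, analytic = FALSE) {
  p <- reflect_pad(x, round(pad_s * fs))
  xp <- p$x
  n <- length(xp)
  nfft <- stats::nextn(n, c(2L, 3L, 5L))
  f <- fft_freqs(nfft, fs)
  z <- stats::fft(c(xp, rep(0, nfft - n)))
  g <- gain_fun(f)
  y <- z * g
  if (analytic) {
    h <- numeric(nfft)
    h[1] <- 1                       # DC
    if (nfft %% 2 == 0) {
      h[nfft / 2 + 1] <- 1          # Nyquist
      h[2:(nfft / 2)] <- 2
    } else {
      h[2:((nfft + 1) / 2)] <- 2
    }
    y <- y * h
  }
  out <- stats::fft(y, inverse = TRUE) / nfft
  out <- out[(p$pad + 1L):(p$pad + length(x))]
  if (analytic) out else Re(out)
}

# Local maxima of x with a minimum prominence (absolute units).
# Prominence of a peak: its height minus the higher of the two lowest points
# separating it from higher terrain (or from the series edge) on each side.
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # strict rise then fall; plateaus resolved to their first sample
  s <- sign(d)
  s[s == 0] <- 1  # treat flat as rising so plateau end counts as the peak
  cand <- which(diff(s) < 0) + 1L
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    pk <- x[i]
    lmin <- pk; k <- i
    while (k > 1L && x[k] <= pk) { k <- k - 1L; lmin <- min(lmin, x[k]) }
    rmin <- pk; k <- i
    while (k < n && x[k] <= pk) { k <- k + 1L; rmin <- min(rmin, x[k]) }
    keep[j] <- (pk - max(lmin, rmin)) >= min_prominence
  }
  cand[keep]
}

# Linear resampling of x (rate fs) onto times t (seconds, 0-based).
resample_at <- function(x, fs, t) {
  stats::approx(x = (seq_along(x) - 1) / fs, y = x, xout = t, rule = 2)$y
}

# Root-mean-square.
rms <- function(x) sqrt(mean(x^2))

# Deterministic stream of sub-seeds derived from one integer seed.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(NA_integer_, n))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# set.seed that tolerates NULL (no-op).
seed_if <- function(seed) if (!is.null(seed) && !is.na(seed)) set.seed(seed)
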