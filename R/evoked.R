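#' Noise and randomization configuration
#'
#' Holds the measurement-noise model and the randomization grid used when
#' simulating MEG-like responses: amplitude noise with a 1/f magnitude
#' spectrum at a given signal-to-noise ratio, Gaussian temporal jitter of
#' event latencies, and the number of temporal x amplitude noise iterations
#' of the randomization ensemble (64 x 40 = 2560 by default).
#'
#' `snr` is an amplitude (RMS) ratio, RMS(signal)/RMS(noise).  The
#' simulated recordings target a signal-to-noise POWER ratio of 1/10 (the
#' usual dB convention), i.e. an amplitude ratio of `1/sqrt(10)`, which is
#' the default; pass `snr = 0.1` for a literal amplitude reading.  Jitter
#' SD defaults to 10 ms (regular speech); the slow condition uses 30 ms.
#'
#' @param snr signal-to-noise amplitude ratio (> 0), default `1/sqrt(10)`
#'   (power ratio 1/10).
#' @param spectral_exponent exponent a of the noise magnitude spectrum
#'   1/f^a (default 1).
#' @param jitter_sd SD of the Gaussian temporal jitter, seconds.
#' @param n_temporal number of temporal-noise iterations (default 64).
#' @param n_amplitude number of amplitude-noise iterations (default 40).
#' @param seed integer seed for the ensemble (optional).
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(snr = 1 / sqrt(10), spectral_exponent = 1, jitter_sd = 0.010,
                         n_temporal = 64L, n_amplitude = 40L, seed = NULL) {
  if (snr <= 0) stop("snr must be > 0")
  if (n_temporal < 1L || n_amplitude < 1L) stop("iteration counts must be >= 1")
  structure(list(snr = snr, spectral_exponent = spectral_exponent,
                 jitter_sd = jitter_sd, n_temporal = as.integer(n_temporal),
                 n_amplitude = as.integer(n_amplitude), seed = seed),
            class = "noise_config")
}

# cache for FIR noise-shaping filters, keyed by (fs, exponent, length)
.pink_cache <- new.env(parent = emptyenv())

# Linear-phase FIR fit to a 1/f^a magnitude target via frequency-sampling
# design (signal::fir2).  Target follows f^(-a) from f_floor up to fs/2,
# held constant below f_floor to avoid the DC singularity.  The relative
# magnitude error of the design is < 1% over the analysis range.
pink_fir <- function(fs, exponent = 1, order = 4096L, f_floor = 0.1) {
  key <- sprintf("%g_%g_%d", fs, exponent, order)
  if (!is.null(.pink_cache[[key]])) return(.pink_cache[[key]])
  fgrid <- seq(0, 1, length.out = 2048L)
  d <- pmax(fgrid * fs / 2, f_floor)^(-exponent)
  h <- as.numeric(signal::fir2(order, fgrid, d / max(d)))
  .pink_cache[[key]] <- h
  h
}

#' Generate 1/f ("pink") noise
#'
#' Gaussian white noise shaped by a linear-phase FIR filter fit to a 1/f^a
#' magnitude target (a = `exponent`), normalized to unit RMS.
#'
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @param exponent magnitude-spectrum exponent (default 1: magnitude ~ 1/f).
#' @param seed integer seed (optional).
#' @return numeric vector of length `n` with RMS 1.
#' @export
pink_noise <- function(n, fs, exponent = 1, seed = NULL) {
  seed_if(seed)
  h <- pink_fir(fs, exponent)
  m <- length(h)                          # 2*half_order + 1
  w <- stats::rnorm(n + m - 1L)
  nfft <- stats::nextn(n + 2L * (m - 1L), c(2L, 3L, 5L))
  y <- Re(stats::fft(stats::fft(c(w, rep(0, nfft - length(w)))) *
                     stats::fft(c(h, rep(0, nfft - m))), inverse = TRUE)) / nfft
  half <- (m - 1L) %/% 2L
  y <- y[(half + 1L):(half + n)]          # remove linear-phase delay
  y / rms(y)
}

#' Add 1/f noise to a response at a given SNR
#'
#' The noise realization is scaled so that the realized amplitude-RMS ratio
#' RMS(signal)/RMS(noise) equals `snr` exactly.  A zero signal receives
#' unit-RMS noise.
#'
#' @param resp a [response_series()] (the noiseless signal).
#' @param noise a [noise_config()] or a single numeric SNR.
#' @param seed integer seed (optional; defaults to the config seed).
#' @return A [response_series()] of the same dimensions.
#' @export
add_pink_noise <- function(resp, noise = noise_config(), seed = NULL) {
  stopifnot(inherits(resp, "response_series"))
  if (is.numeric(noise)) noise <- noise_config(snr = noise)
  if (is.null(seed)) seed <- noise$seed
  seeds <- derive_seeds(if (is.null(seed)) NULL else seed, nrow(resp$data))
  out <- resp$data
  for (ch in seq_len(nrow(resp$data))) {
    x <- resp$data[ch, ]
    nz <- pink_noise(length(x), resp$fs, noise$spectral_exponent,
                     seed = if (is.na(seeds[ch])) NULL else seeds[ch])
    sig_rms <- rms(x)
    scale <- if (sig_rms > 0) sig_rms / noise$snr else 1
    out[ch, ] <- x + nz * scale
  }
  response_series(out, resp$fs)
}

#' Convolve an event input series with an evoked-response kernel
#'
#' Linear, shift-equivariant convolution respecting the kernel's lag
#' window: a kernel with a negative lag start begins before the event
#' sample.  Output has the length of the input.
#'
#' @param input an [event_input_series()].
#' @param kernel a [trf_kernel()] sampled at the same rate.
#' @return A single-channel [response_series()].
#' @export
convolve_kernel <- function(input, kernel) {
  stopifnot(inherits(input, "event_input"), inherits(kernel, "trf_kernel"))
  if (input$fs != kernel$fs)
    stop(sprintf("sampling rate mismatch: input %g Hz, kernel %g Hz",
                 input$fs, kernel$fs))
  s <- input$s
  k <- kernel$values
  n <- length(s)
  L <- length(k)
  l0 <- round(kernel$lag_window[1] * kernel$fs)
  nfft <- stats::nextn(n + L, c(2L, 3L, 5L))
  yf <- Re(stats::fft(stats::fft(c(s, rep(0, nfft - n))) *
                      stats::fft(c(k, rep(0, nfft - L))), inverse = TRUE)) / nfft
  idx <- seq_len(n) - l0
  y <- numeric(n)
  ok <- idx >= 1L & idx <= n + L - 1L
  y[ok] <- yf[idx[ok]]
  response_series(y, input$fs)
}

#' Estimate a temporal response function by time-lagged ridge regression
#'
#' Least-squares (optionally ridge-penalized) solution of the time-delayed
#' linear encoding model mapping the event input series to the response,
#' over a regular lag grid.  Normal equations are assembled from FFT-based
#' auto- and cross-correlations (the lagged design matrix is Toeplitz).
#' With `ridge = NULL` the penalty is chosen by generalization error on a
#' held-out final third of the samples.
#'
#' @param stimulus an [event_input_series()].
#' @param response a [response_series()] aligned with the stimulus (same fs
#'   and length; channel 1 is used).
#' @param lag_window lag window in seconds (default `c(-0.15, 0.45)`).
#' @param ridge relative ridge penalty (scaled by the mean design energy);
#'   0 for plain least squares, `NULL` (default) for held-out selection.
#' @return A [trf_kernel()] with attributes `ridge` (relative penalty used)
#'   and `cv_mse` (held-out error per candidate, when selected).
#' @export
estimate_trf <- function(stimulus, response, lag_window = c(-0.15, 0.45),
                         ridge = NULL) {
  stopifnot(inherits(stimulus, "event_input"),
            inherits(response, "response_series"))
  if (stimulus$fs != response$fs) stop("stimulus/response fs mismatch")
  s <- stimulus$s
  y <- response$data[1, ]
  if (length(s) != length(y)) stop("stimulus and response lengths differ")
  fs <- stimulus$fs
  l0 <- round(lag_window[1] * fs)
  l1 <- round(lag_window[2] * fs)
  L <- l1 - l0 + 1L

  normal_eq <- function(s, y) {
    n <- length(s)
    nfft <- stats::nextn(n + L + 1L, c(2L, 3L, 5L))
    sf <- stats::fft(c(s, rep(0, nfft - n)))
    ac <- Re(stats::fft(sf * Conj(sf), inverse = TRUE)) / nfft
    cc <- Re(stats::fft(Conj(sf) * stats::fft(c(y, rep(0, nfft - n))),
                        inverse = TRUE)) / nfft
    lag_idx <- function(l) ifelse(l >= 0, l + 1L, nfft + l + 1L)
    list(XtX = stats::toeplitz(ac[seq_len(L)]),
         Xty = cc[lag_idx(l0:l1)])
  }
  solve_ridge <- function(ne, lam_rel) {
    lam <- lam_rel * mean(diag(ne$XtX))
    A <- ne$XtX + diag(lam, L)
    b <- try(solve(A, ne$Xty), silent = TRUE)
    if (inherits(b, "try-error")) {
      if (lam_rel == 0)
        stop("rank-deficient lagged design with ridge = 0; ",
             "supply a positive ridge penalty")
      stop("ridge solve failed")
    }
    b
  }

  cv_mse <- NULL
  if (is.null(ridge)) {
    n <- length(s)
    cut <- floor(2 * n / 3)
    ne_tr <- normal_eq(s[1:cut], y[1:cut])
    grid <- 10^seq(-8, 2, by = 1)
    test_idx <- (cut + 1L):n
    blocks <- split(test_idx, cut(seq_along(test_idx), 20L, labels = FALSE))
    block_mse <- vapply(grid, function(g) {
      b <- try(solve_ridge(ne_tr, g), silent = TRUE)
      if (inherits(b, "try-error")) return(rep(Inf, 20L))
      k <- trf_kernel(b, lag_window, fs)
      pred <- convolve_kernel(event_input_series(s, fs), k)$data[1, ]
      vapply(blocks, function(ix) mean((y[ix] - pred[ix])^2), numeric(1))
    }, numeric(20L))
    cv_mse <- colMeans(block_mse)
    # smallest penalty whose held-out error is within one SE of the best:
    # when the criterion cannot distinguish, prefer the least-biased kernel
    best <- which.min(cv_mse)
    se_best <- stats::sd(block_mse[, best]) / sqrt(20)
    ridge <- grid[which(cv_mse <= cv_mse[best] + se_best)[1]]
    names(cv_mse) <- format(grid)
  }
  ne <- normal_eq(s, y)
  b <- solve_ridge(ne, ridge)
  out <- trf_kernel(b, lag_window, fs)
  attr(out, "ridge") <- ridge
  attr(out, "cv_mse") <- cv_mse
  out
}

#' Iteration grid of a randomization ensemble
#'
#' One row per realization: every combination of temporal-noise iteration
#' and amplitude-noise iteration (default 64 x 40 = 2560 rows).
#'
#' @param noise a [noise_config()].
#' @return data.frame with columns `temporal_iter`, `amplitude_iter`.
#' @export
ensemble_grid <- function(noise) {
  data.frame(temporal_iter = rep(seq_len(noise$n_temporal),
                                 each = noise$n_amplitude),
             amplitude_iter = rep(seq_len(noise$n_amplitude),
                                  noise$n_temporal))
}

# elementwise accumulation of (possibly nested) numeric outputs
acc_add <- function(acc, x) {
  if (is.null(acc)) return(x)
  if (is.list(x)) return(mapply(acc_add, acc, x, SIMPLIFY = FALSE))
  acc + x
}
acc_scale <- function(acc, k) {
  if (is.list(acc)) return(lapply(acc, acc_scale, k = k))
  acc * k
}

#' Run a randomized simulation ensemble and average an analysis over it
#'
#' For each of `n_temporal` jitter realizations of the event input, the
#' model's predicted response is computed once; each of `n_amplitude` 1/f
#' noise realizations is then added and `callback` (a pure function of a
#' [response_series()]) is evaluated.  Numeric (or nested-list-of-numeric)
#' callback outputs are averaged over all `n_temporal * n_amplitude`
#' realizations.  Deterministic given `seed`.
#'
#' @param events a [landmark_events()] train (analysis uses these original,
#'   unjittered times; jitter affects only the simulated input placement).
#' @param model a [trf_kernel()] (evoked-response model) or
#'   [oscillator_params()] (entrainment model).
#' @param noise a [noise_config()].
#' @param fs simulation rate in Hz (default 400).
#' @param callback function of one argument (the noisy predicted
#'   [response_series()]) returning a numeric array or nested list thereof.
#' @param scale_range magnitude scaling range for the model input.
#' @param seed integer seed (defaults to `noise$seed`).
#' @return list with `average` (averaged callback output), `n_realizations`,
#'   and `grid` (the iteration grid).
#' @export
run_randomized_ensemble <- function(events, model, noise, fs = 400,
                                    callback, scale_range = c(0.5, 1),
                                    seed = noise$seed) {
  stopifnot(inherits(events, "landmark_events"), inherits(noise, "noise_config"))
  grid <- ensemble_grid(noise)
  nt <- noise$n_temporal
  na <- noise$n_amplitude
  seeds <- derive_seeds(if (is.null(seed)) 1L else seed, nt * (na + 1L))
  acc <- NULL
  for (ti in seq_len(nt)) {
    input <- build_event_input(events, fs, scale_range = scale_range,
                               jitter_sd = noise$jitter_sd,
                               seed = seeds[ti])
    pred <- predict_model_response(model, input)
    for (ai in seq_len(na)) {
      resp <- add_pink_noise(pred, noise, seed = seeds[nt + (ti - 1L) * na + ai])
      acc <- acc_add(acc, callback(resp))
    }
  }
  list(average = acc_scale(acc, 1 / (nt * na)),
       n_realizations = nt * na, grid = grid)
}

# dispatch the forward simulation for either model class
predict_model_response <- function(model, input) {
  if (inherits(model, "trf_kernel")) {
    convolve_kernel(input, model)
  } else if (inherits(model, "oscillator_params")) {
    traj <- simulate_oscillator(input, model)
    response_series(traj$pred, input$fs)
  } else stop("model must be a trf_kernel or oscillator_params object")
}

#' Generate a synthetic MEG-like response from an event train
#'
#' Ground-truth generator for testing: jittered, magnitude-scaled event
#' train convolved with an evoked-response kernel, plus 1/f noise.  The
#' original (unjittered) event times are retained in the `events`
#' attribute, as phase analyses must use them.
#'
#' @param events a [landmark_events()] train.
#' @param kernel a [trf_kernel()]; must be sampled at `fs`.
#' @param noise a [noise_config()], or `NULL` to skip noise.
#' @param fs sampling rate in Hz.
#' @param scale_range magnitude scaling range (`NULL` to use raw magnitudes).
#' @param seed integer seed.
#' @return A [response_series()] with attribute `events`.
#' @export
generate_synthetic_response <- function(events, kernel, noise = noise_config(),
                                        fs = 400, scale_range = c(0.5, 1),
                                        seed = NULL) {
  if (kernel$fs != fs)
    stop(sprintf("kernel fs (%g) does not match requested fs (%g)",
                 kernel$fs, fs))
  jit <- if (is.null(noise)) 0 else noise$jitter_sd
  seeds <- derive_seeds(if (is.null(seed)) NULL else seed, 2L)
  input <- build_event_input(events, fs, scale_range = scale_range,
                             jitter_sd = jit,
                             seed = if (is.na(seeds[1])) NULL else seeds[1])
  resp <- convolve_kernel(input, kernel)
  if (!is.null(noise))
    resp <- add_pink_noise(resp, noise,
                           seed = if (is.na(seeds[2])) NULL else seeds[2])
  attr(resp, "events") <- events
  resp
}
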