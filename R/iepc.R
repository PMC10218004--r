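#' Inter-event phase coherence (IEPC)
#'
#' Mean resultant length of the unit phasors across events, per frequency
#' band and time point:
#' \deqn{IEPC(\varphi, t) = \frac{1}{N}\left|\sum_{k=1}^{N}
#'   e^{i\,ph_k(\varphi,t)}\right|}
#' where N is the number of events and `ph_k` the band phase in epoch k.
#'
#' @param epochs an [epoch_phases()] output with at least 2 events.
#' @return An object of class `iepc_map`: list with `values` (bands x time,
#'   in 0..1), `centers`, `times`, `n_events`, `fs`.
#' @export
iepc <- function(epochs) {
  stopifnot(inherits(epochs, "epoched_phases"))
  n <- dim(epochs$phase)[1]
  if (n < 2L) stop("IEPC requires at least 2 events")
  z <- exp(1i * epochs$phase)
  vals <- Mod(colMeans(z, dims = 1))     # collapses the event dimension
  structure(list(values = vals, centers = epochs$centers,
                 times = epochs$times, n_events = n, fs = epochs$fs),
            class = "iepc_map")
}

#' @export
print.iepc_map <- function(x, ...) {
  cat(sprintf("<iepc_map: %d bands x %d time points, N = %d events>\n",
              nrow(x$values), ncol(x$values), x$n_events))
  invisible(x)
}

#' @export
plot.iepc_map <- function(x, ...) {
  graphics::image(x$times, seq_along(x$centers), t(x$values),
                  xlab = "time rel. event (s)", ylab = "band",
                  axes = FALSE, ...)
  graphics::axis(1)
  at <- pretty(seq_along(x$centers))
  at <- at[at >= 1 & at <= length(x$centers)]
  graphics::axis(2, at = at, labels = sprintf("%.2g", x$centers[at]))
  graphics::box()
  invisible(x)
}

#' Theoretical IEPC baseline for uniform phases
#'
#' Monte-Carlo expectation of the mean resultant length of `n_events`
#' angles sampled from the uniform (zero-concentration von Mises)
#' distribution: the chance level an observed IEPC must exceed.
#'
#' @param n_events number of angles per draw (>= 2).
#' @param n_mc number of Monte-Carlo draws (default 10000).
#' @param seed integer seed.
#' @return The Monte-Carlo mean, with the SD of the resultant across draws
#'   as attribute `"sd"`.
#' @export
iepc_baseline <- function(n_events, n_mc = 10000L, seed = NULL) {
  if (n_events < 2) stop("n_events must be >= 2")
  seed_if(seed)
  ph <- matrix(stats::runif(n_events * n_mc, -pi, pi), n_events, n_mc)
  r <- Mod(colMeans(exp(1i * ph)))
  structure(mean(r), sd = stats::sd(r))
}

#' Cerebro-acoustic phase coherence (CAC)
#'
#' Consistency over time of the phase difference between a neural band
#' signal and the same-band speech envelope, per utterance:
#' \deqn{CAC(\varphi) = \frac{1}{T}\left|\sum_{t=1}^{T}
#'   e^{i\,(ph(\varphi,t) - ph_s(\varphi,t))}\right|}
#' Slow-speech utterances are split into `slow_split` equal parts before
#' calculation and the resulting values averaged, equating the number of
#' time points entering the analysis across rate conditions.
#'
#' @param neural_tf [tf_decompose()] of the neural response.
#' @param envelope_tf [tf_decompose()] of the speech envelope, processed
#'   with the same band spec and aligned time axis.
#' @param utterances data.frame with columns `start`, `end` (seconds).
#' @param slow_split number of equal parts per utterance (1 for regular
#'   speech, 3 for slow speech).
#' @return An object of class `cac_profile`: list with `values` (per-band
#'   average over utterances), `per_utterance` (utterances x bands matrix),
#'   `centers`.
#' @export
cac <- function(neural_tf, envelope_tf, utterances, slow_split = 1L) {
  stopifnot(inherits(neural_tf, "tf_phase_map"),
            inherits(envelope_tf, "tf_phase_map"))
  if (!isTRUE(all.equal(neural_tf$centers, envelope_tf$centers)))
    stop("band specs differ between neural and envelope maps")
  if (neural_tf$fs != envelope_tf$fs ||
      ncol(neural_tf$phase) != ncol(envelope_tf$phase))
    stop("neural and envelope time axes are not aligned")
  fs <- neural_tf$fs
  dphi <- neural_tf$phase - envelope_tf$phase
  n <- ncol(dphi)
  min_cycle <- 1 / min(neural_tf$centers)
  per_utt <- matrix(NA_real_, nrow(utterances), nrow(dphi))
  for (u in seq_len(nrow(utterances))) {
    i0 <- max(1L, round(utterances$start[u] * fs) + 1L)
    i1 <- min(n, round(utterances$end[u] * fs))
    if ((i1 - i0 + 1) / fs < min_cycle * slow_split)
      warning(sprintf("utterance %d shorter than one cycle of the lowest band", u))
    parts <- if (slow_split <= 1L) list(i0:i1)
             else split(i0:i1, cut(seq_len(i1 - i0 + 1L), slow_split,
                                   labels = FALSE))
    vals <- vapply(parts, function(idx)
      Mod(rowMeans(exp(1i * dphi[, idx, drop = FALSE]))),
      numeric(nrow(dphi)))
    per_utt[u, ] <- rowMeans(matrix(vals, nrow = nrow(dphi)))
  }
  structure(list(values = colMeans(per_utt), per_utterance = per_utt,
                 centers = neural_tf$centers),
            class = "cac_profile")
}

#' @export
print.cac_profile <- function(x, ...) {
  cat(sprintf("<cac_profile: %d bands, %d utterances>\n",
              length(x$values), nrow(x$per_utterance)))
  invisible(x)
}

#' Spectral IEPC profile over a one-cycle post-event window
#'
#' Averages an IEPC map over the post-event window conforming to one cycle
#' of an oscillator matched to the speech rate (0-170 ms at the regular
#' rate, 0-500 ms at the slow rate), yielding a per-band profile.
#'
#' @param x an [iepc()] map.
#' @param window length-2 numeric window in seconds, e.g. `c(0, 0.5)`;
#'   alternatively supply `condition`.
#' @param condition `"regular"` or `"slow"` to use the canonical one-cycle
#'   window (0.17 / 0.5 s).
#' @return list with `centers` and `profile` (per-band mean IEPC), class
#'   `spectral_profile`.
#' @export
spectral_profile <- function(x, window = NULL,
                             condition = c("regular", "slow")) {
  stopifnot(inherits(x, "iepc_map"))
  if (is.null(window)) {
    condition <- match.arg(condition)
    window <- c(0, if (condition == "regular") 0.17 else 0.5)
  }
  idx <- which(x$times >= window[1] & x$times <= window[2])
  if (!length(idx)) stop("window outside the epoch")
  structure(list(centers = x$centers,
                 profile = rowMeans(x$values[, idx, drop = FALSE]),
                 window = window),
            class = "spectral_profile")
}

#' Peaks of a spectral IEPC profile
#'
#' Local maxima of the (lightly smoothed) per-band profile exceeding
#' `baseline + 2 * sd`, with a prominence of at least `2 * sd` (a local
#' maximum must also rise above its surroundings by more than the
#' estimation noise).  Smoothing is a running mean over `smooth` adjacent
#' bands.
#'
#' @param profile a [spectral_profile()] (or numeric vector with a
#'   `centers` argument).
#' @param baseline chance-level IEPC (e.g. [iepc_baseline()]).
#' @param sd ensemble/baseline SD; 0 to threshold at the baseline alone.
#' @param smooth odd number of bands for the running mean (default 3).
#' @param centers band centers when `profile` is a bare vector.
#' @return data.frame with columns `center` (Hz) and `value`, one row per
#'   peak, ordered by frequency.
#' @export
profile_peaks <- function(profile, baseline = 0, sd = 0, smooth = 3L,
                          centers = NULL) {
  if (inherits(profile, "spectral_profile")) {
    centers <- profile$centers
    y <- profile$profile
  } else y <- as.numeric(profile)
  if (smooth > 1L)
    y <- stats::filter(y, rep(1 / smooth, smooth), sides = 2) |> as.numeric()
  thr <- baseline + 2 * sd
  idx <- find_peaks(ifelse(is.na(y), -Inf, y), min_prominence = 2 * sd)
  idx <- idx[y[idx] > thr]
  data.frame(center = centers[idx], value = y[idx])
}

#' Temporal IEPC profile in a band range, against the chance baseline
#'
#' Averages an IEPC map across the bands inside `band_range` (default half
#' an octave around 1.9 Hz, the slow-speech rate) and compares the time
#' course to the theoretical uniform-phase baseline: time points exceeding
#' `baseline + 2 SD` are flagged.
#'
#' @param x an [iepc()] map (built from long-gap selected events).
#' @param band_range length-2 numeric frequency range in Hz.
#' @param n_mc,seed Monte-Carlo settings for [iepc_baseline()].
#' @return list of class `temporal_profile` with `times`, `course`,
#'   `baseline`, `baseline_sd`, `exceed` (logical per time point).
#' @export
temporal_profile <- function(x, band_range = 1.9 * 2^c(-0.25, 0.25),
                             n_mc = 5000L, seed = 1L) {
  stopifnot(inherits(x, "iepc_map"))
  rows <- which(x$centers >= band_range[1] & x$centers <= band_range[2])
  if (!length(rows)) stop("no bands inside band_range")
  course <- colMeans(x$values[rows, , drop = FALSE])
  bl <- iepc_baseline(x$n_events, n_mc = n_mc, seed = seed)
  thr <- as.numeric(bl) + 2 * attr(bl, "sd")
  structure(list(times = x$times, course = course,
                 baseline = as.numeric(bl), baseline_sd = attr(bl, "sd"),
                 exceed = course > thr),
            class = "temporal_profile")
}

#' IEPC by event-magnitude quantile
#'
#' Splits events into `n_quantiles` magnitude quantiles (stable assignment
#' by event order for ties) and computes, within each quantile, the average
#' IEPC across the bands inside `band` (theta, 4-8 Hz by default), each
#' band averaged over the time points of one cycle (1/center) after the
#' event.
#'
#' @param epochs an [epoch_phases()] output.
#' @param magnitudes event magnitudes aligned with the epochs (defaults to
#'   none: must be supplied).
#' @param n_quantiles number of quantiles (default 5).
#' @param band frequency range in Hz (default `c(4, 8)`).
#' @return list of class `quantile_iepc` with `iepc` (per-quantile mean),
#'   `boundaries` (magnitude quantile boundaries), `n_per_quantile`.
#' @export
quantile_iepc <- function(epochs, magnitudes, n_quantiles = 5L,
                          band = c(4, 8)) {
  stopifnot(inherits(epochs, "epoched_phases"))
  n <- dim(epochs$phase)[1]
  if (length(magnitudes) != n)
    stop("magnitudes must match the number of epochs")
  if (n < 2 * n_quantiles) stop("too few events for the requested quantiles")
  if (n < 10 * n_quantiles)
    warning("fewer than 10 events per quantile; estimates will be unstable")
  rows <- which(epochs$centers >= band[1] & epochs$centers <= band[2])
  if (!length(rows)) stop("no bands inside the requested range")
  rk <- rank(magnitudes, ties.method = "first")
  q <- floor((rk - 1) * n_quantiles / n) + 1L
  vals <- numeric(n_quantiles)
  for (qq in seq_len(n_quantiles)) {
    sel <- which(q == qq)
    z <- exp(1i * epochs$phase[sel, , , drop = FALSE])
    m <- Mod(colMeans(z, dims = 1))     # bands x time
    per_band <- vapply(rows, function(b) {
      idx <- which(epochs$times >= 0 &
                   epochs$times <= 1 / epochs$centers[b])
      mean(m[b, idx])
    }, numeric(1))
    vals[qq] <- mean(per_band)
  }
  structure(list(iepc = vals,
                 boundaries = stats::quantile(magnitudes,
                                              probs = seq(0, 1, length.out = n_quantiles + 1)),
                 n_per_quantile = tabulate(q, n_quantiles)),
            class = "quantile_iepc")
}
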