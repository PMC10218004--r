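#' Specification of a synthetic peakRate event train
#'
#' Defines the statistics of an acoustic-edge (peakRate) event train with
#' speech-like structure: utterances separated by silent periods, and a
#' quasi-periodic syllabic pacemaker within utterances.  Defaults follow
#' the regular-speech condition: typical event frequency 5.7 Hz with an
#' instantaneous-frequency SD of 2.9 Hz; the slow condition uses 1.9 Hz
#' with SD 1.0 Hz (or, canonically, a 3x time stretch of a regular train).
#'
#' The pacemaker model reflects how natural speech is timed: syllables are
#' locally quasi-periodic at a slowly drifting rate, with most events close
#' to the local grid and a broad dispersion built from discrete phenomena.
#' Four components shape the instantaneous-frequency distribution while
#' preserving local periodicity:
#' \itemize{
#'   \item a slowly drifting local rate `mean_rate * exp(d)`, `d` an AR(1)
#'     log-rate process (SD `rate_drift_sd`, per-event coefficient
#'     `rate_drift_ar`) - articulation rate varies smoothly within phrases;
#'   \item small non-accumulating Gaussian timing jitter of on-grid events
#'     (SD `timing_jitter` of the local interval);
#'   \item timing outliers: with probability `outlier_prob` an event is
#'     displaced with the larger SD `outlier_jitter` (syllables whose
#'     acoustic edge is off the rhythmic grid);
#'   \item skipped beats: with probability `skip_prob` a grid position
#'     produces no event (reduced or merged syllables); the grid phase is
#'     preserved, so long intervals fall at multiples of the local period.
#' }
#' All dispersion components scale with `rate_sd / mean_rate`, so the
#' defaults realize the broad, right-skewed frequency distribution of
#' speech; `rate_sd = 0` gives a strict pacemaker.  `mean_rate` is realized
#' as the modal (typical) instantaneous event frequency; the median and
#' arithmetic mean of 1/interval sit below and above it respectively, and
#' the event count per unit speech time is slightly below `mean_rate`,
#' as in natural speech.
#'
#' @param mean_rate typical instantaneous event frequency (Hz).
#' @param rate_sd target SD of the instantaneous event frequency (Hz).
#' @param duration total stimulus duration in seconds (utterances +
#'   silences).
#' @param silence_range min/max silent period between utterances, seconds.
#' @param utterance_range min/max utterance duration, seconds.
#' @param timing_jitter,outlier_jitter,outlier_prob,skip_prob,rate_drift_sd,rate_drift_ar
#'   pacemaker dispersion parameters (see Details); defaults are calibrated
#'   to the speech statistics above.
#' @param magnitude_meanlog,magnitude_sdlog log-normal parameters for event
#'   magnitudes, which are clipped to (0, 1].
#' @param refractory minimum spacing between events, seconds; default
#'   scales with the rate (`0.114 / mean_rate`, i.e. 20 ms at 5.7 Hz),
#'   as uniform time stretching scales minimal gaps too.
#' @param seed integer seed (optional).
#' @return An object of class `event_train_spec`.
#' @export
event_train_spec <- function(mean_rate = 5.7, rate_sd = 2.9, duration = 390,
                             silence_range = c(0.5, 1.1),
                             utterance_range = c(10, 60),
                             timing_jitter = 0.06,
                             outlier_jitter = 0.33,
                             outlier_prob = 0.22,
                             skip_prob = 0.12,
                             rate_drift_sd = 0.13,
                             rate_drift_ar = 0.9,
                             magnitude_meanlog = log(0.2),
                             magnitude_sdlog = 0.5,
                             refractory = NULL,
                             seed = NULL) {
  if (mean_rate <= 0) stop("mean_rate must be > 0")
  if (rate_sd < 0) stop("rate_sd must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  if (silence_range[1] > silence_range[2]) stop("silence_range min > max")
  if (utterance_range[1] > utterance_range[2]) stop("utterance_range min > max")
  if (is.null(refractory)) refractory <- 0.114 / mean_rate
  structure(list(mean_rate = mean_rate, rate_sd = rate_sd, duration = duration,
                 silence_range = silence_range,
                 utterance_range = utterance_range,
                 timing_jitter = timing_jitter,
                 outlier_jitter = outlier_jitter,
                 outlier_prob = outlier_prob,
                 skip_prob = skip_prob,
                 rate_drift_sd = rate_drift_sd,
                 rate_drift_ar = rate_drift_ar,
                 magnitude_meanlog = magnitude_meanlog,
                 magnitude_sdlog = magnitude_sdlog,
                 refractory = refractory, seed = seed),
            class = "event_train_spec")
}

# reference coefficient of variation the dispersion defaults are calibrated
# to (the speech statistics: 2.9/5.7 and 1.0/1.9 are both ~0.52)
.ref_cv <- 1.0 / 1.9

#' Generate a synthetic peakRate event train
#'
#' Fills the requested duration with utterances (uniform duration within
#' `utterance_range`) separated by silences (uniform within
#' `silence_range`).  Events within an utterance follow the quasi-periodic
#' pacemaker of [event_train_spec()]; magnitudes are log-normal, clipped to
#' (0, 1].  Deterministic given `spec$seed`.  A duration too short to fit
#' a single interval yields an empty train (not an error).
#'
#' @param spec an [event_train_spec()].
#' @return A [landmark_events()] object (kind `"peakRate"`) with an
#'   `utterances` attribute (data.frame of start/end times).
#' @export
generate_event_train <- function(spec) {
  stopifnot(inherits(spec, "event_train_spec"))
  seed_if(spec$seed)
  scale <- (spec$rate_sd / spec$mean_rate) / .ref_cv
  j_core <- spec$timing_jitter * scale
  j_out <- spec$outlier_jitter * scale
  p_out <- if (scale > 0) spec$outlier_prob else 0
  p_skip <- spec$skip_prob * min(scale, 1)
  s_d <- spec$rate_drift_sd * scale
  times <- numeric(0)
  utt <- list()
  t0 <- 0
  d <- stats::rnorm(1, 0, s_d)
  while (t0 < spec$duration) {
    utt_len <- stats::runif(1, spec$utterance_range[1], spec$utterance_range[2])
    utt_end <- min(t0 + utt_len, spec$duration)
    grid_t <- t0
    repeat {
      d <- spec$rate_drift_ar * d +
        sqrt(1 - spec$rate_drift_ar^2) * stats::rnorm(1, 0, s_d)
      r <- spec$mean_rate * exp(d)
      grid_t <- grid_t + 1 / r
      if (grid_t > utt_end) break
      if (p_skip > 0 && stats::runif(1) < p_skip) next  # skipped beat
      jsd <- if (p_out > 0 && stats::runif(1) < p_out) j_out else j_core
      tk <- grid_t + stats::rnorm(1, 0, jsd / r)
      if (tk > t0 && tk <= utt_end) times <- c(times, tk)
    }
    utt[[length(utt) + 1L]] <- c(t0, utt_end)
    t0 <- utt_end + stats::runif(1, spec$silence_range[1], spec$silence_range[2])
  }
  utterances <- do.call(rbind, utt)
  utterances <- data.frame(start = utterances[, 1], end = utterances[, 2])
  times <- sort(times)
  if (length(times) > 1L)
    times <- times[c(TRUE, diff(times) > spec$refractory)]
  if (!length(times)) {
    return(landmark_events(numeric(0), numeric(0), kind = "peakRate",
                           duration = spec$duration, utterances = utterances))
  }
  mags <- stats::rlnorm(length(times), spec$magnitude_meanlog,
                        spec$magnitude_sdlog)
  mags <- pmin(mags, 1)
  landmark_events(times, mags, kind = "peakRate",
                  duration = spec$duration, utterances = utterances)
}

#' Instantaneous event frequencies of a train
#'
#' Reciprocal inter-event intervals, restricted to within-utterance pairs
#' when an utterance segmentation is available (intervals spanning silent
#' periods are not speech-rate samples).
#'
#' @param events a [landmark_events()] object.
#' @param utterances optional utterance segmentation (data.frame with
#'   `start`, `end`); defaults to the train's own.
#' @return numeric vector of instantaneous frequencies in Hz.
#' @export
instantaneous_frequency <- function(events, utterances = attr(events, "utterances")) {
  t <- events$time_s
  if (length(t) < 2L) return(numeric(0))
  iv <- diff(t)
  keep <- rep(TRUE, length(iv))
  if (!is.null(utterances)) {
    uid <- findInterval(t, utterances$start)
    keep <- uid[-length(uid)] == uid[-1]
  }
  1 / iv[keep]
}

#' Time-stretch a landmark event train
#'
#' Scales event times by `factor` and peakRate magnitudes by `1/factor`
#' (rates of change slow down proportionally when the envelope time axis is
#' stretched; peakEnv magnitudes are amplitude measures and are preserved).
#' This is the canonical construction of a slow-speech train from a regular
#' one, mirroring the effect of uniform time stretching on the envelope.
#'
#' @param x a `landmark_events` object.
#' @param factor stretch factor (> 0); 3 slows to one-third rate.
#' @param ... unused.
#' @return A `landmark_events` object.
#' @export
time_stretch.landmark_events <- function(x, factor, ...) {
  if (factor <= 0) stop("stretch factor must be > 0")
  mag <- ifelse(x$kind == "peakRate", x$magnitude / factor, x$magnitude)
  utt <- attr(x, "utterances")
  if (!is.null(utt)) utt <- data.frame(start = utt$start * factor,
                                       end = utt$end * factor)
  landmark_events(x$time_s * factor, mag, kind = x$kind,
                  duration = attr(x, "duration") * factor, utterances = utt)
}
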