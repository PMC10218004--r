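#' Default configuration for the full model-comparison pipeline
#'
#' Collects every constant the pipeline needs: per-condition event
#' statistics and oscillator frequencies (5.7 Hz regular / 1.9 Hz slow),
#' temporal jitter (10 / 30 ms), one-cycle analysis windows (170 / 500 ms),
#' the noise model (1/f noise at a 1/10 power signal-to-noise ratio), the randomization grid (64 x 40), the
#' filter-bank definitions, and the event-selection gaps.  The slow-speech
#' stimulus is derived from the regular train by a 3x time stretch with
#' 1/3 magnitudes (mirroring uniform slowing of the envelope); set
#' `slow_mode = "independent"` to draw it from the slow statistics instead.
#'
#' @param fast use the reduced 8 x 5 randomization grid and a half-length
#'   stimulus, for quick runs (default FALSE: 64 x 40 and 6.5 min).
#' @param conditions which conditions to run.
#' @param seed master seed; every random stage derives its seed from it.
#' @return A list of class `edge_track_config`.
#' @export
edge_track_config <- function(fast = FALSE,
                              conditions = c("regular", "slow"),
                              seed = 1L) {
  cfg <- list(
    conditions = list(
      regular = list(rate_mean = 5.7, rate_sd = 2.9, osc_freq = 5.7,
                     jitter_sd = 0.010, cycle_window = 0.170),
      slow = list(rate_mean = 1.9, rate_sd = 1.0, osc_freq = 1.9,
                  jitter_sd = 0.030, cycle_window = 0.500)
    ),
    run_conditions = match.arg(conditions, c("regular", "slow"),
                               several.ok = TRUE),
    duration_regular = if (fast) 195 else 390,
    slow_mode = "stretched",
    stretch_factor = 3,
    fs = 400,
    snr = 1 / sqrt(10),
    spectral_exponent = 1,
    n_temporal = if (fast) 8L else 64L,
    n_amplitude = if (fast) 5L else 40L,
    coupling_fraction = 0.7,
    scale_range = c(0.5, 1),
    bands = list(narrow = list(fmin = 0.67, fmax = 9, step = 0.1,
                               half_width = 0.1),
                 wide = list(half_octave = 0.25, half_width = 0.5)),
    spectral_window = c(-0.5, 0.5),
    spectral_gap_post = NULL,   # NULL: one cycle of the condition rate
    temporal_window = c(-0.5, 1.2),
    temporal_gaps = c(0.2, 1.04),
    n_subjects = 12L,
    profile = if (fast) "fast" else "full",
    seed = seed
  )
  class(cfg) <- "edge_track_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every constant against its allowed range and rejects unknown
#' keys; violations are returned (with their paths) rather than raised.
#'
#' @param config an [edge_track_config()] (possibly modified).
#' @return character vector of diagnostics; empty when the configuration
#'   is valid.
#' @export
validate_config <- function(config) {
  d <- character(0)
  known <- names(edge_track_config())
  extra <- setdiff(names(config), known)
  if (length(extra))
    d <- c(d, sprintf("unknown key(s): %s", paste(extra, collapse = ", ")))
  for (cn in names(config$conditions)) {
    cc <- config$conditions[[cn]]
    if (!is.numeric(cc$osc_freq) || cc$osc_freq <= 0)
      d <- c(d, sprintf("conditions$%s$osc_freq: oscillator frequency must be > 0", cn))
    else if (config$fs <= 2 * cc$osc_freq)
      d <- c(d, sprintf("conditions$%s$osc_freq: fs must exceed 2F", cn))
    if (cc$rate_mean <= 0)
      d <- c(d, sprintf("conditions$%s$rate_mean: must be > 0", cn))
    if (cc$jitter_sd < 0)
      d <- c(d, sprintf("conditions$%s$jitter_sd: must be >= 0", cn))
    if (cc$cycle_window <= 0 ||
        cc$cycle_window > diff(range(config$spectral_window)))
      d <- c(d, sprintf("conditions$%s$cycle_window: outside the spectral window", cn))
  }
  nb <- config$bands$narrow
  if (nb$fmax * 2^(nb$half_width + 0.5) >= config$fs / 2)
    d <- c(d, "bands$narrow$fmax: Nyquist violation at fs (stopband edge >= fs/2)")
  if (config$snr <= 0) d <- c(d, "snr: must be > 0")
  if (config$n_temporal < 1 || config$n_amplitude < 1)
    d <- c(d, "n_temporal/n_amplitude: must be >= 1")
  if (config$coupling_fraction < 0 || config$coupling_fraction > 1)
    d <- c(d, "coupling_fraction: must be in [0, 1]")
  if (config$duration_regular <= 0) d <- c(d, "duration_regular: must be > 0")
  if (config$stretch_factor <= 0) d <- c(d, "stretch_factor: must be > 0")
  d
}

#' Run the full two-model, two-rate comparison on synthetic speech
#'
#' Orchestrates the complete workflow: synthesize the peakRate event trains
#' for each speech-rate condition, simulate both models (oscillatory
#' entrainment and evoked-response convolution) over the randomization
#' ensemble, and compute the IEPC statistics that discriminate them —
#' the narrow-band spectral profile over the one-cycle post-event window
#' (with peak detection) and, for slow speech, the wide-band temporal
#' profile around the speech rate with its chance-baseline exceedances.
#' All randomness derives from `config$seed`.
#'
#' @param config an [edge_track_config()].
#' @return An object of class `edge_track_report` (see `summary` and
#'   `print` methods); per condition and model it holds the averaged IEPC
#'   maps, the spectral profile and its peaks, and the temporal profile.
#' @export
run_full_comparison <- function(config = edge_track_config()) {
  diag <- validate_config(config)
  if (length(diag)) stop("invalid config:\n  ", paste(diag, collapse = "\n  "))
  fs <- config$fs
  seeds <- derive_seeds(config$seed, 4L + 2L * length(config$run_conditions))
  ev_reg <- generate_event_train(event_train_spec(
    mean_rate = config$conditions$regular$rate_mean,
    rate_sd = config$conditions$regular$rate_sd,
    duration = config$duration_regular, seed = seeds[1]))
  trains <- list(regular = ev_reg)
  if ("slow" %in% config$run_conditions) {
    trains$slow <- if (config$slow_mode == "stretched") {
      time_stretch(ev_reg, config$stretch_factor)
    } else {
      generate_event_train(event_train_spec(
        mean_rate = config$conditions$slow$rate_mean,
        rate_sd = config$conditions$slow$rate_sd,
        duration = config$duration_regular * config$stretch_factor,
        seed = seeds[2]))
    }
  }
  kernel <- generate_synthetic_kernel(synthetic_kernel_spec(fs = fs))
  narrow <- make_band_spec(config$bands$narrow$fmin, config$bands$narrow$fmax,
                           config$bands$narrow$step,
                           config$bands$narrow$half_width)
  out <- list()
  si <- 4L
  for (cond in config$run_conditions) {
    cc <- config$conditions[[cond]]
    events <- trains[[cond]]
    wide <- make_band_spec(cc$osc_freq * 2^(-config$bands$wide$half_octave),
                           cc$osc_freq * 2^(config$bands$wide$half_octave),
                           config$bands$narrow$step,
                           config$bands$wide$half_width)
    gap_post <- if (is.null(config$spectral_gap_post)) cc$cycle_window
                else config$spectral_gap_post
    sel_spec <- select_events(events, min_gap_post = gap_post)
    sel_temp <- select_events(events, min_gap_pre = config$temporal_gaps[1],
                              min_gap_post = config$temporal_gaps[2])
    do_temporal <- cond == "slow"
    callback <- function(resp) {
      tfn <- tf_decompose(resp, narrow)
      epn <- epoch_phases(tfn, sel_spec, config$spectral_window)
      res <- list(spectral = iepc(epn)$values,
                  n_spectral = dim(epn$phase)[1])
      if (do_temporal) {
        tfw <- tf_decompose(resp, wide)
        epw <- epoch_phases(tfw, sel_temp, config$temporal_window)
        res$temporal <- iepc(epw)$values
        res$n_temporal <- dim(epw$phase)[1]
      }
      res
    }
    models <- list(
      osc = oscillator_params(cc$osc_freq, fs = fs,
                              fraction = config$coupling_fraction),
      er = kernel)
    cond_out <- list(events = events, models = list())
    for (mn in names(models)) {
      si <- si + 1L
      noise <- noise_config(snr = config$snr,
                            spectral_exponent = config$spectral_exponent,
                            jitter_sd = cc$jitter_sd,
                            n_temporal = config$n_temporal,
                            n_amplitude = config$n_amplitude,
                            seed = seeds[si])
      ens <- run_randomized_ensemble(events, models[[mn]], noise, fs = fs,
                                     callback = callback,
                                     scale_range = config$scale_range)
      avg <- ens$average
      n_spec <- round(avg$n_spectral)
      t_spec <- (round(config$spectral_window[1] * fs):round(config$spectral_window[2] * fs)) / fs
      spec_map <- structure(list(values = avg$spectral, centers = narrow$centers,
                                 times = t_spec, n_events = n_spec, fs = fs),
                            class = "iepc_map")
      bl <- iepc_baseline(n_spec, seed = 1L)
      prof <- spectral_profile(spec_map, window = c(0, cc$cycle_window))
      peaks <- profile_peaks(prof, baseline = as.numeric(bl), sd = attr(bl, "sd"))
      m_out <- list(spectral_iepc = spec_map, profile = prof, peaks = peaks,
                    baseline = bl, n_realizations = ens$n_realizations)
      if (do_temporal) {
        n_temp <- round(avg$n_temporal)
        t_temp <- (round(config$temporal_window[1] * fs):round(config$temporal_window[2] * fs)) / fs
        temp_map <- structure(list(values = avg$temporal, centers = wide$centers,
                                   times = t_temp, n_events = n_temp, fs = fs),
                              class = "iepc_map")
        m_out$temporal <- temporal_profile(
          temp_map, band_range = cc$osc_freq * 2^c(-config$bands$wide$half_octave,
                                                   config$bands$wide$half_octave))
        m_out$temporal_iepc <- temp_map
      }
      cond_out$models[[mn]] <- m_out
    }
    out[[cond]] <- cond_out
  }
  structure(list(config = config, conditions = out, kernel = kernel),
            class = "edge_track_report")
}

#' @export
summary.edge_track_report <- function(object, ...) {
  rows <- list()
  for (cond in names(object$conditions)) {
    cc <- object$config$conditions[[cond]]
    for (mn in names(object$conditions[[cond]]$models)) {
      m <- object$conditions[[cond]]$models[[mn]]
      pk <- m$peaks
      last_ex <- NA_real_
      if (!is.null(m$temporal)) {
        ex <- m$temporal$times[m$temporal$exceed & m$temporal$times > 0]
        last_ex <- if (length(ex)) max(ex) else 0
      }
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, model = mn,
        n_peaks = nrow(pk),
        lower_peak_hz = if (nrow(pk)) min(pk$center) else NA_real_,
        upper_peak_hz = if (nrow(pk)) max(pk$center) else NA_real_,
        last_exceedance_s = last_ex,
        n_realizations = m$n_realizations)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.edge_track_report <- function(x, ...) {
  cat("<edge_track_report>\n")
  print(summary(x))
  invisible(x)
}
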