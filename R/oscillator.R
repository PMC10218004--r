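#' Build the model input series s(t) from an event train
#'
#' Places each event's magnitude as a single-sample impulse at its
#' (optionally jittered) sample, zeros elsewhere.  Magnitudes are min-max
#' scaled within the condition to `scale_range` (default 0.5..1, so the
#' weakest edge still drives half the phase correction of the strongest);
#' when all magnitudes are equal the degenerate min-max maps them all to
#' the upper bound.  Temporal jitter (Gaussian, SD `jitter_sd`) is applied
#' to impulse placement only and rounded to the nearest sample; the
#' returned object retains the original unjittered times for analysis.
#'
#' @param events a [landmark_events()] train.
#' @param fs sampling rate in Hz.
#' @param scale_range length-2 numeric scaling range, or `NULL` to use raw
#'   magnitudes.
#' @param jitter_sd SD of Gaussian temporal jitter in seconds (0 = none).
#' @param duration series duration in seconds (defaults to the train's).
#' @param seed integer seed (optional).
#' @return An [event_input_series()].
#' @export
build_event_input <- function(events, fs, scale_range = c(0.5, 1),
                              jitter_sd = 0, duration = attr(events, "duration"),
                              seed = NULL) {
  stopifnot(inherits(events, "landmark_events"))
  n <- max(1L, round(duration * fs))
  s <- numeric(n)
  if (!nrow(events))
    return(event_input_series(s, fs, integer(0), numeric(0)))
  mag <- events$magnitude
  if (!is.null(scale_range)) {
    rng <- range(mag)
    if (rng[1] == rng[2]) {
      mag <- rep(scale_range[2], length(mag))
    } else {
      mag <- scale_range[1] +
        (mag - rng[1]) / (rng[2] - rng[1]) * diff(scale_range)
    }
  }
  seed_if(seed)
  t_place <- events$time_s
  if (jitter_sd > 0)
    t_place <- t_place + stats::rnorm(length(t_place), 0, jitter_sd)
  idx <- round(t_place * fs) + 1L
  ok <- idx >= 1L & idx <= n
  # coincident (or jitter-collided) samples: keep the larger magnitude
  for (j in which(ok)) s[idx[j]] <- max(s[idx[j]], mag[j])
  event_input_series(s, fs, event_samples = idx[ok],
                     event_times_s = events$time_s[ok])
}

#' Coupled-oscillator model parameters
#'
#' A phase-amplitude oscillator with a limit-cycle amplitude attractor at
#' r = 1, natural frequency `freq`, and event-driven phase correction
#' toward theta = 0:
#' \deqn{d\theta/dt = 2\pi F - c\, s(t)\, r \sin\theta}
#' \deqn{dr/dt = r(1 - r^2) + c\, s(t) \cos\theta}
#'
#' The coupling `c` defaults to the calibrated value of
#' [calibrate_coupling()] at `fraction` (70%): a unit single-sample event
#' arriving at theta = +/- pi/2 with r = 1 corrects phase by
#' `fraction * pi`, i.e. that fraction of the maximal phase shift (pi).
#'
#' @param freq natural frequency F in Hz (5.7 regular / 1.9 slow speech).
#' @param coupling coupling strength c in 1/s; `NULL` to calibrate from
#'   `fraction`.
#' @param fs simulation rate in Hz (default 400; must exceed 2F).
#' @param fraction fraction of the maximal phase shift for calibration.
#' @param theta0 initial phase in radians.
#' @param r0 initial amplitude (> 0).
#' @return An object of class `oscillator_params`.
#' @export
oscillator_params <- function(freq, coupling = NULL, fs = 400, fraction = 0.7,
                              theta0 = 0, r0 = 1) {
  if (freq <= 0) stop("freq must be > 0")
  if (fs <= 2 * freq) stop("fs must exceed 2 * freq")
  if (r0 <= 0) stop("r0 must be > 0")
  if (is.null(coupling)) coupling <- calibrate_coupling(fraction, fs)
  if (coupling < 0) stop("coupling must be >= 0")
  structure(list(freq = freq, coupling = coupling, fs = fs,
                 fraction = fraction, theta0 = theta0, r0 = r0),
            class = "oscillator_params")
}

#' Calibrate the oscillator coupling strength
#'
#' Returns the coupling `c` such that a single-sample unit-magnitude event
#' (s = 1 for one sample of width 1/fs) arriving at theta = pi/2 with
#' r = 1 shifts the phase by `fraction` of the maximal phase shift, taken
#' as pi radians (the largest meaningful correction distance).  Under
#' forward-Euler integration the per-event kick is `c * s * r * sin(theta)
#' / fs`, giving the closed form `c = fraction * pi * fs`.
#'
#' @param fraction fraction of the maximal phase shift in (0, 1]; 0 gives
#'   no coupling.
#' @param fs simulation rate in Hz.
#' @return Coupling strength in 1/s.
#' @export
calibrate_coupling <- function(fraction = 0.7, fs = 400) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  fraction * pi * fs
}

#' Simulate the coupled-oscillator entrainment model
#'
#' Forward-Euler integration at the input's sampling rate.  With no input
#' the phase advances by exactly `2 pi F / fs` per step and the amplitude
#' converges monotonically to the r = 1 attractor from any r0 in (0, 2);
#' events kick the phase toward 0 (phase correction) and perturb the
#' amplitude by `c s cos(theta) / fs`.  The predicted response is
#' `cos(theta) * r`.
#'
#' @param input an [event_input_series()] (s >= 0; the same rate as
#'   `params$fs`).
#' @param params an [oscillator_params()].
#' @return An object of class `oscillator_trajectory`: list with `theta`
#'   (radians, wrapped to (-pi, pi]), `r`, `pred`, `fs`, `params`.
#' @export
simulate_oscillator <- function(input, params) {
  stopifnot(inherits(params, "oscillator_params"))
  if (inherits(input, "event_input")) {
    s <- input$s
    if (input$fs != params$fs)
      stop(sprintf("input fs (%g) != params fs (%g)", input$fs, params$fs))
  } else s <- as.numeric(input)
  fs <- params$fs
  dt <- 1 / fs
  n <- length(s)
  theta <- numeric(n)
  r <- numeric(n)
  th <- params$theta0
  rr <- params$r0
  w <- 2 * pi * params$freq
  cc <- params$coupling
  for (i in seq_len(n)) {
    th_new <- th + (w - cc * s[i] * rr * sin(th)) * dt
    rr <- rr + (rr * (1 - rr^2) + cc * s[i] * cos(th)) * dt
    th <- th_new
    if (rr < 0) {            # (-r, theta) and (r, theta + pi) are the same
      rr <- -rr              # state: normalize so the amplitude stays >= 0
      th <- th + pi          # (cos(theta) * r, and both equations, are
    }                        # invariant under this flip)
    if (!is.finite(th) || !is.finite(rr))
      stop(sprintf(paste0("oscillator state non-finite at step %d ",
                          "(t = %.3f s; F = %g, c = %g, r0 = %g)"),
                   i, i * dt, params$freq, cc, params$r0))
    theta[i] <- th
    r[i] <- rr
  }
  pred <- cos(theta) * r
  theta_w <- ((theta + pi) %% (2 * pi)) - pi
  theta_w[theta_w == -pi] <- pi
  structure(list(theta = theta_w, theta_unwrapped = theta, r = r,
                 pred = pred, fs = fs, params = params),
            class = "oscillator_trajectory")
}

#' @export
print.oscillator_trajectory <- function(x, ...) {
  cat(sprintf("<oscillator_trajectory: %d samples @ %g Hz, F = %g Hz, c = %g>\n",
              length(x$theta), x$fs, x$params$freq, x$params$coupling))
  invisible(x)
}

#' @export
plot.oscillator_trajectory <- function(x, max_s = 10, ...) {
  n <- min(length(x$pred), round(max_s * x$fs))
  t <- (seq_len(n) - 1) / x$fs
  graphics::plot(t, x$pred[seq_len(n)], type = "l", xlab = "time (s)",
                 ylab = expression(cos(theta) %.% r), ...)
  invisible(x)
}

#' Entrainment map over oscillator frequency and coupling grids
#'
#' For every (F, c) pair, simulates the oscillator on the given input and
#' scores entrainment as the circular concentration (mean resultant
#' length), at event times, of the predicted response's phase in the
#' narrow band at the oscillator's own frequency -- the same quantity the
#' downstream coherence analyses see.  (The raw state angle is unsuitable:
#' strong event kicks drive amplitude sign flips whose pi jumps scatter it
#' even when the band-limited response is cleanly locked.)  At c = 0 the
#' score sits near chance for every F; at very high c entrainment spreads
#' across all frequencies; at intermediate calibrated c only oscillators
#' near the stimulus rate entrain.
#'
#' @param input an [event_input_series()].
#' @param F_grid numeric vector of natural frequencies (Hz).
#' @param c_grid numeric vector of coupling strengths (1/s).
#' @param fs simulation rate (defaults to the input's).
#' @return matrix of entrainment scores, `length(F_grid)` x
#'   `length(c_grid)`, with dimnames.
#' @export
scan_coupling <- function(input, F_grid, c_grid, fs = input$fs) {
  stopifnot(inherits(input, "event_input"),
            length(F_grid) > 0, length(c_grid) > 0)
  ev <- input$event_samples
  out <- matrix(NA_real_, length(F_grid), length(c_grid),
                dimnames = list(format(F_grid), format(c_grid)))
  for (i in seq_along(F_grid)) for (j in seq_along(c_grid)) {
    p <- oscillator_params(F_grid[i], coupling = c_grid[j], fs = fs)
    traj <- simulate_oscillator(input, p)
    spec <- make_band_spec(F_grid[i] * 2^-0.05, F_grid[i], 0.1, 0.1)
    tfm <- tf_decompose(traj$pred, spec, fs = fs)
    out[i, j] <- Mod(mean(exp(1i * tfm$phase[1, ev])))
  }
  out
}
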