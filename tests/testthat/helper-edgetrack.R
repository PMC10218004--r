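# shared test helpers

# dominant frequency (Hz) of a real signal by FFT peak, excluding DC
dominant_freq <- function(x, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x))[2:floor(n / 2)]
  ((2:floor(n / 2)) - 1)[which.max(sp)] * fs / n
}

# modal instantaneous frequency via a log-scale density estimate
modal_frequency <- function(events) {
  f <- instantaneous_frequency(events)
  d <- stats::density(log(f))
  exp(d$x[which.max(d$y)])
}

# build an epoched_phases object directly from a phase array
# (events x bands x time), bypassing filtering — for statistics oracles
make_epochs <- function(phase, centers, fs = 400,
                        window = c(0, (dim(phase)[3] - 1) / fs)) {
  times <- seq(window[1], by = 1 / fs, length.out = dim(phase)[3])
  structure(list(phase = phase, amplitude = NULL, times = times,
                 centers = centers, fs = fs,
                 event_times = seq_len(dim(phase)[1]), window = window),
            class = "epoched_phases")
}

# wrap angles to (-pi, pi]
wrap_pi <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

# a small deterministic well-separated event train
sparse_train <- function(n = 10, gap = 1.2, mag = NULL, duration = NULL) {
  times <- gap * seq_len(n)
  if (is.null(mag)) mag <- seq(0.3, 0.9, length.out = n)
  if (is.null(duration)) duration <- max(times) + gap
  landmark_events(times, mag, duration = duration)
}
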