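test_that("band ladders are log-spaced with the stated extent", {
  spec <- make_band_spec()
  expect_equal(spec$centers[1], 0.67)
  expect_equal(length(spec$centers), floor(log2(9 / 0.67) / 0.1) + 1L)
  expect_equal(unique(round(spec$centers[-1] / spec$centers[-38], 12)),
               round(2^0.1, 12))
  expect_lte(max(spec$centers), 9)
  expect_error(make_band_spec(5, 2), "fmin")
})

test_that("band designs meet the ripple and attenuation contract", {
  for (center in c(0.67, 1.9, 5.7, 9)) {
    for (hw in c(0.1, 0.5)) {
      des <- edgetrack:::band_filter_design(center, hw)
      gp <- edgetrack:::band_gain(des, des$pass_edges)
      gs <- edgetrack:::band_gain(des, des$stop_edges)
      expect_true(all(-20 * log10(gp) <= 3 + 1e-9))     # passband ripple
      expect_true(all(-20 * log10(gs) >= 24 - 1e-9))    # stopband attenuation
    }
  }
})

test_that("a sinusoid at a band center passes with flat amplitude and true phase", {
  fs <- 400
  spec <- make_band_spec()
  f0 <- spec$centers[20]
  t <- (0:(40 * fs - 1)) / fs
  tf <- tf_decompose(response_series(sin(2 * pi * f0 * t), fs), spec)
  mid <- (10 * fs):(30 * fs)
  amp <- tf$amplitude[20, mid]
  expect_lt((max(amp) - min(amp)) / mean(amp), 0.05)
  dph <- wrap_pi(diff(tf$phase[20, mid]))
  expect_equal(mean(dph) * fs / (2 * pi), f0, tolerance = 1e-3)
  # one octave away: attenuated by at least 24 dB
  b_oct <- which.min(abs(spec$centers - 2 * f0))
  ratio_db <- 20 * log10(mean(tf$amplitude[b_oct, mid]) / mean(amp))
  expect_lt(ratio_db, -24)
})

test_that("band-filtered white noise concentrates energy as the design predicts", {
  fs <- 400
  set.seed(2)
  x <- rnorm(30 * fs)
  spec <- make_band_spec(fmin = 2, fmax = 2.1, half_width = 0.1)
  tf <- tf_decompose(response_series(x, fs), spec, pad_s = 0)
  des <- edgetrack:::band_filter_design(2, 0.1)
  n <- length(x)
  fr <- (0:(n - 1)) / n * fs
  fr[fr > fs / 2] <- fr[fr > fs / 2] - fs
  g2 <- edgetrack:::band_gain(des, abs(fr))^2
  expected <- sum(g2[abs(abs(fr) - 2) < 2 * des$w0]) / sum(g2)
  y <- tf$amplitude[1, ] * exp(1i * tf$phase[1, ])
  spy <- Mod(stats::fft(Re(y)))^2
  observed <- sum(spy[abs(abs(fr) - 2) < 2 * des$w0]) / sum(spy)
  expect_equal(observed, expected, tolerance = 0.05)
})

test_that("phase maps are amplitude-scale invariant and zero-phase symmetric", {
  fs <- 400
  spec <- make_band_spec(fmin = 1, fmax = 8, step_octaves = 0.5)
  set.seed(3)
  x <- rnorm(10 * fs)
  t1 <- tf_decompose(response_series(x, fs), spec)
  t2 <- tf_decompose(response_series(7 * x, fs), spec)
  expect_equal(t1$phase, t2$phase, tolerance = 1e-10)
  # symmetric impulse in, symmetric band response out (no group delay)
  n <- 8001
  pulse <- exp(-((seq_len(n) - 4001) / 40)^2)
  tp <- tf_decompose(pulse, spec, fs = fs)
  re <- Re(tp$amplitude[4, ] * exp(1i * tp$phase[4, ]))
  expect_lt(max(abs(re - rev(re))), 1e-8)
})

test_that("decomposition rejects unsupported rates", {
  spec <- make_band_spec()
  expect_error(tf_decompose(rnorm(100), spec, fs = 25), "band")
})

test_that("epoching copies phases exactly and drops edge events", {
  fs <- 400
  spec <- make_band_spec(fmin = 2, fmax = 6, step_octaves = 0.5)
  set.seed(4)
  tf <- tf_decompose(response_series(rnorm(20 * fs), fs), spec)
  ev <- landmark_events(c(0.01, 5, 10, 19.99), rep(1, 4), duration = 20)
  ep <- epoch_phases(tf, ev, window = c(-0.5, 0.5))
  expect_equal(dim(ep$phase)[1], 2L)           # two edge events dropped
  expect_equal(attr(ep, "dropped"), 2L)
  expect_equal(dim(ep$phase)[3], round(1 * fs) + 1L)
  i5 <- round(5 * fs) + 1L
  expect_identical(ep$phase[1, , ], tf$phase[, (i5 - 200):(i5 + 200)])
  expect_error(epoch_phases(tf, landmark_events(0.01, 1, duration = 20),
                            window = c(-0.5, 0.5)), "usable")
})

test_that("gap-based event selection matches a brute-force filter", {
  set.seed(5)
  ev <- generate_event_train(event_train_spec(1.9, 1.0, duration = 120,
                                              seed = 5))
  sel <- select_events(ev, min_gap_pre = 0.2, min_gap_post = 1.04)
  t <- ev$time_s
  keep <- vapply(seq_along(t), function(i) {
    pre <- if (i == 1) Inf else t[i] - t[i - 1]
    post <- if (i == length(t)) Inf else t[i + 1] - t[i]
    pre >= 0.2 && post >= 1.04
  }, logical(1))
  expect_equal(sel$time_s, t[keep])
  # evenly spaced events closer than the post gap: nothing survives
  dense <- landmark_events(seq(1, 5, by = 0.15), rep(1, 27), duration = 6)
  expect_equal(nrow(select_events(dense, min_gap_post = 0.5)), 1L)  # last only
  # worked example: gaps 0.3 / 1.2 / 1.1 with thresholds (0.2, 1.04):
  # the event preceded by 0.3 s and followed by 1.2 s survives, the first
  # (followed by only 0.3 s) does not
  ex <- landmark_events(cumsum(c(1, 0.3, 1.2, 1.1)), rep(1, 4), duration = 5)
  kept <- select_events(ex, min_gap_pre = 0.2, min_gap_post = 1.04)
  expect_true(1.3 %in% kept$time_s)
  expect_false(1.0 %in% kept$time_s)
})
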