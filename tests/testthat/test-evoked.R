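test_that("convolution places the kernel at events and superposes linearly", {
  fs <- 400
  k <- generate_synthetic_kernel(synthetic_kernel_spec(fs = fs))
  inp <- build_event_input(landmark_events(2, 1, duration = 6), fs,
                           scale_range = NULL)
  y <- convolve_kernel(inp, k)$data[1, ]
  i0 <- round(2 * fs) + 1L + round(-0.15 * fs)
  expect_equal(y[i0:(i0 + length(k$values) - 1L)], k$values,
               tolerance = 1e-12)
  # far-apart events superpose
  inp2 <- build_event_input(landmark_events(c(1, 4), c(0.4, 0.9),
                                            duration = 6), fs,
                            scale_range = NULL)
  y2 <- convolve_kernel(inp2, k)$data[1, ]
  ya <- convolve_kernel(build_event_input(landmark_events(1, 0.4, duration = 6),
                                          fs, scale_range = NULL), k)$data[1, ]
  yb <- convolve_kernel(build_event_input(landmark_events(4, 0.9, duration = 6),
                                          fs, scale_range = NULL), k)$data[1, ]
  expect_equal(y2, ya + yb, tolerance = 1e-12)
  expect_error(convolve_kernel(event_input_series(numeric(10), 200), k),
               "mismatch")
})

test_that("a strictly periodic train yields comb lines weighted by the kernel", {
  fs <- 400
  k <- generate_synthetic_kernel(synthetic_kernel_spec(fs = fs))
  times <- seq(1, 59, by = 1 / 1.9)
  inp <- build_event_input(landmark_events(times, rep(1, length(times)),
                                           duration = 60), fs,
                           scale_range = NULL)
  y <- convolve_kernel(inp, k)$data[1, ]
  n <- length(y)
  sp <- Mod(stats::fft(y))[1:(n %/% 2)]
  fr <- (0:(n %/% 2 - 1)) * fs / n
  line <- function(f) max(sp[abs(fr - f) < 0.05])
  bg <- function(f) stats::median(sp[abs(fr - f) < 0.4 & abs(fr - f) > 0.1])
  for (h in 1.9 * (1:3)) expect_gt(line(h), 10 * bg(h))
})

test_that("1/f noise has unit RMS, the right slope, and exact SNR scaling", {
  nz <- pink_noise(40000, 400, seed = 3)
  expect_equal(sqrt(mean(nz^2)), 1, tolerance = 1e-12)
  sp <- Mod(stats::fft(nz))[1:20000]
  fr <- (0:19999) * 400 / 40000
  sel <- fr > 0.5 & fr < 40
  slope <- stats::coef(stats::lm(log(sp[sel]) ~ log(fr[sel])))[2]
  expect_lt(abs(slope + 1), 0.15)

  resp <- response_series(sin(2 * pi * 3 * (0:7999) / 400), 400)
  noisy <- add_pink_noise(resp, noise_config(snr = 0.1), seed = 4)
  realized <- sqrt(mean(resp$data^2)) /
    sqrt(mean((noisy$data - resp$data)^2))
  expect_equal(realized, 0.1, tolerance = 2e-3)

  # very high SNR returns the signal essentially unchanged
  clean <- add_pink_noise(resp, noise_config(snr = 1e6), seed = 5)
  expect_lt(sqrt(mean((clean$data - resp$data)^2)) /
              sqrt(mean(resp$data^2)), 1e-3)

  # zero signal still yields finite, unit-RMS noise
  z <- add_pink_noise(response_series(numeric(4000), 400),
                      noise_config(snr = 0.1), seed = 6)
  expect_true(all(is.finite(z$data)))
  expect_equal(sqrt(mean(z$data^2)), 1, tolerance = 1e-9)
})

test_that("TRF estimation is exact without noise and shrinks under ridge", {
  fs <- 400
  k <- generate_synthetic_kernel(synthetic_kernel_spec(fs = fs))
  set.seed(10)
  times <- sort(runif(120, 1, 55))
  times <- times[c(TRUE, diff(times) > 0.05)]
  ev <- landmark_events(times, runif(length(times), 0.3, 1), duration = 60)
  inp <- build_event_input(ev, fs, scale_range = NULL)
  resp <- convolve_kernel(inp, k)
  fit <- estimate_trf(inp, resp, ridge = 0)
  expect_lt(sqrt(mean((fit$values - k$values)^2)), 1e-6)

  # pure-noise response: coefficient norm decreases as the penalty grows
  noise_resp <- response_series(pink_noise(length(inp$s), fs, seed = 11), fs)
  norms <- vapply(c(1e-4, 1e-2, 1, 100), function(g)
    sqrt(sum(estimate_trf(inp, noise_resp, ridge = g)$values^2)), numeric(1))
  expect_true(all(diff(norms) < 0))

  # rank-deficient design (no events) needs regularization
  empty <- event_input_series(numeric(2000), fs)
  expect_error(estimate_trf(empty, response_series(rnorm(2000), fs),
                            ridge = 0), "ridge")
})

test_that("the randomization grid enumerates temporal x amplitude iterations", {
  g <- ensemble_grid(noise_config())
  expect_equal(nrow(g), 2560L)
  expect_equal(length(unique(g$temporal_iter)), 64L)
  expect_equal(length(unique(g$amplitude_iter)), 40L)
  g1 <- ensemble_grid(noise_config(n_temporal = 1, n_amplitude = 1))
  expect_equal(nrow(g1), 1L)
})

test_that("a 1 x 1 ensemble equals a single evaluation and runs are reproducible", {
  fs <- 400
  k <- generate_synthetic_kernel(synthetic_kernel_spec(fs = fs))
  ev <- sparse_train(8, gap = 1, duration = 10)
  nc <- noise_config(snr = 1, n_temporal = 1, n_amplitude = 1, seed = 21)
  out1 <- run_randomized_ensemble(ev, k, nc, fs = fs,
                                  callback = function(r) mean(r$data^2))
  out2 <- run_randomized_ensemble(ev, k, nc, fs = fs,
                                  callback = function(r) mean(r$data^2))
  expect_identical(out1$average, out2$average)
  expect_equal(out1$n_realizations, 1L)
  expect_true(is.numeric(out1$average) && length(out1$average) == 1L)
})

test_that("ensemble averaging shrinks Monte-Carlo error like 1/sqrt(n)", {
  fs <- 400
  k <- generate_synthetic_kernel(synthetic_kernel_spec(fs = fs))
  ev <- generate_event_train(event_train_spec(5.7, 2.9, duration = 25,
                                              seed = 30))
  spec <- make_band_spec(4, 8, step_octaves = 0.3, half_width = 0.1)
  sel <- select_events(ev, min_gap_post = 0.2)
  cb <- function(resp) {
    ep <- epoch_phases(tf_decompose(resp, spec), sel, c(-0.1, 0.2))
    mean(iepc(ep)$values)
  }
  run_size <- function(nt, na, seed) {
    run_randomized_ensemble(ev, k, noise_config(snr = 0.3, n_temporal = nt,
                                                n_amplitude = na, seed = seed),
                            fs = fs, callback = cb)$average
  }
  small <- vapply(1:6, function(s) run_size(5, 5, 100 + s), numeric(1))
  large <- vapply(1:6, function(s) run_size(10, 10, 200 + s), numeric(1))
  ratio <- stats::sd(small) / stats::sd(large)
  expect_gt(ratio, 1.2)   # expected 2, wide band for 6-run estimates
})
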