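test_that("IEPC hits its closed-form limits and matches a direct sum", {
  # identical epochs: perfect coherence
  ph <- array(rep(runif(2 * 4, -pi, pi), each = 6), c(6, 2, 4))
  m <- iepc(make_epochs(ph, centers = c(2, 4)))
  expect_equal(max(abs(m$values - 1)), 0, tolerance = 1e-12)
  # balanced phases cancel exactly
  ph2 <- array(0, c(8, 1, 2))
  ph2[, 1, ] <- seq(-pi, pi - 2 * pi / 8, length.out = 8)
  m2 <- iepc(make_epochs(ph2, centers = 3))
  expect_lt(max(m2$values), 1e-12)
  # oracle equivalence on a small random case
  set.seed(6)
  ph3 <- array(runif(5 * 2 * 3, -pi, pi), c(5, 2, 3))
  m3 <- iepc(make_epochs(ph3, centers = c(2, 4)))
  direct <- apply(ph3, c(2, 3), function(v) Mod(mean(exp(1i * v))))
  expect_equal(m3$values, direct, tolerance = 1e-12)
  expect_error(iepc(make_epochs(ph3[1, , , drop = FALSE], centers = c(2, 4))),
               "2 events")
})

test_that("IEPC is invariant to a global phase rotation", {
  set.seed(7)
  ph <- array(runif(10 * 3 * 5, -pi, pi), c(10, 3, 5))
  m1 <- iepc(make_epochs(ph, centers = c(1, 2, 4)))
  m2 <- iepc(make_epochs(wrap_pi(ph + 1.234), centers = c(1, 2, 4)))
  expect_equal(m1$values, m2$values, tolerance = 1e-12)
})

test_that("uniform-phase IEPC matches the Monte-Carlo chance level", {
  bl <- iepc_baseline(100, n_mc = 20000, seed = 8)
  set.seed(9)
  reps <- replicate(300, {
    ph <- array(runif(100, -pi, pi), c(100, 1, 1))
    iepc(make_epochs(ph, centers = 2))$values[1, 1]
  })
  se <- sqrt(attr(bl, "sd")^2 / 300 + attr(bl, "sd")^2 / 20000)
  expect_lt(abs(mean(reps) - as.numeric(bl)), 3 * se)
})

test_that("the chance baseline decreases with N, is exact at N = 2, and is reproducible", {
  b10 <- iepc_baseline(10, seed = 1)
  b100 <- iepc_baseline(100, seed = 1)
  b1000 <- iepc_baseline(1000, seed = 1)
  expect_gt(as.numeric(b10), as.numeric(b100))
  expect_gt(as.numeric(b100), as.numeric(b1000))
  # N = 2: E|cos(delta/2)| under a uniform phase difference, by quadrature
  exact <- stats::integrate(function(d) abs(cos(d / 2)) / (2 * pi),
                            0, 2 * pi)$value
  b2 <- iepc_baseline(2, n_mc = 2e5, seed = 2)
  expect_lt(abs(as.numeric(b2) - exact),
            3 * attr(b2, "sd") / sqrt(2e5))
  expect_identical(iepc_baseline(50, seed = 3), iepc_baseline(50, seed = 3))
})

make_phase_map <- function(phase, centers, fs = 100) {
  structure(list(phase = phase, amplitude = abs(phase) * 0 + 1,
                 centers = centers, fs = fs,
                 band_spec = NULL),
            class = "tf_phase_map")
}

test_that("CAC is 1 for locked phases and chance-level for independent ones", {
  fs <- 100
  n <- 3000
  centers <- c(1.9, 5.7)
  utt <- data.frame(start = c(0, 12), end = c(10, 28))
  base <- matrix(runif(2 * n, -pi, pi), 2, n)
  expect_equal(cac(make_phase_map(base, centers),
                   make_phase_map(base, centers), utt)$values,
               c(1, 1))
  shifted <- wrap_pi(base + 0.8)
  expect_equal(cac(make_phase_map(shifted, centers),
                   make_phase_map(base, centers), utt)$values,
               c(1, 1), tolerance = 1e-12)
  # independent uniform phases: per-utterance CAC follows the uniform null
  set.seed(11)
  vals <- replicate(60, {
    a <- matrix(runif(2 * n, -pi, pi), 2, n)
    b <- matrix(runif(2 * n, -pi, pi), 2, n)
    cac(make_phase_map(a, centers), make_phase_map(b, centers),
        data.frame(start = 0, end = 10))$values
  })
  T_len <- 10 * fs
  bl <- iepc_baseline(T_len, n_mc = 5000, seed = 12)
  se <- attr(bl, "sd") / sqrt(length(vals))
  expect_lt(abs(mean(vals) - as.numeric(bl)), 3 * se + 1e-3)
})

test_that("slow utterances are split into thirds before averaging", {
  fs <- 100
  n <- 3000
  # phase difference consistent within each third, but different across
  # thirds: splitting must recover full coherence
  dphi <- rep(c(0.3, 1.7, -2.0), each = 1000)
  a <- matrix(runif(n, -pi, pi), 1, n)
  b <- wrap_pi(a - rep(dphi, each = 1))
  utt <- data.frame(start = 0, end = 30)
  whole <- cac(make_phase_map(b, 2), make_phase_map(a, 2), utt, slow_split = 1)
  split3 <- cac(make_phase_map(b, 2), make_phase_map(a, 2), utt, slow_split = 3)
  expect_lt(whole$values, 0.8)
  expect_equal(as.numeric(split3$values), 1, tolerance = 1e-9)
})

test_that("cluster permutation finds injected effects and nothing in flat maps", {
  # 12 replicates: a sign-flip null with fewer has too coarse a p grid to
  # reach the 0.01 cluster threshold
  set.seed(13)
  nb <- 10; nt <- 60; R <- 12
  times <- seq(-0.5, 0.68, length.out = nt)
  flat <- array(0.2, c(R, nb, nt))
  res0 <- cluster_perm_test(flat + array(rnorm(R * nb * nt, 0, 1e-6),
                                         c(R, nb, nt)),
                            times = times, n_perm = 100, seed = 1)
  expect_equal(sum(res0$clusters$significant), 0L)
  # inject a consistent post-event elevation in bands 4-6
  maps <- array(0.2 + rnorm(R * nb * nt, 0, 0.02), c(R, nb, nt))
  block_b <- 4:6; block_t <- which(times > 0 & times < 0.4)
  maps[, block_b, block_t] <- maps[, block_b, block_t] + 0.15
  res <- cluster_perm_test(maps, times = times, n_perm = 999, seed = 2)
  sig <- res$clusters[res$clusters$significant & res$clusters$sign > 0, ]
  expect_equal(nrow(sig), 1L)
  lab <- res$labels == sig$id
  inside <- mean(lab[block_b, block_t])
  expect_gt(inside, 0.9)
  expect_error(cluster_perm_test(maps[1:3, , ], times = times), "replicates")
})

test_that("model comparison recovers exact and mixed predictors", {
  set.seed(14)
  osc <- sin(seq(0, 3, length.out = 40))
  er <- exp(-seq(0, 3, length.out = 40))
  cmp <- compare_models(er, osc, er)
  expect_equal(cmp$correlations$er, 1)
  expect_equal(cmp$betas$er, 1, tolerance = 1e-9)
  expect_equal(cmp$betas$osc, 0, tolerance = 1e-9)
  # noise only: correlations centred on zero
  obs_noise <- matrix(rnorm(12 * 40), 12, 40)
  cmp_n <- compare_models(obs_noise, osc, er)
  expect_lt(abs(mean(cmp_n$correlations$er)), 0.25)
  expect_lt(abs(mean(cmp_n$correlations$osc)), 0.25)
  # mixture recovery within 10%
  obs <- t(replicate(12, 0.3 * osc + 0.7 * er + rnorm(40, 0, 0.01)))
  cmp_m <- compare_models(obs, osc, er)
  expect_lt(abs(mean(cmp_m$betas$osc) - 0.3), 0.03)
  expect_lt(abs(mean(cmp_m$betas$er) - 0.7), 0.07)
  expect_true(cmp_m$tests$beta_er$p.value < 0.001)
  # degenerate constant profile: correlation undefined, reported as NA
  cmp_d <- compare_models(rep(1, 40), osc, er)
  expect_true(is.na(cmp_d$correlations$er))
})

test_that("quantile IEPC rises with magnitude when alignment scales with it", {
  set.seed(15)
  n <- 250
  mags <- runif(n, 0.1, 1)
  # phase concentration grows with magnitude: kappa ~ magnitude
  ph <- array(NA_real_, c(n, 2, 20))
  for (i in seq_len(n)) {
    sdev <- 2.5 * (1 - mags[i]) + 0.1
    ph[i, , ] <- wrap_pi(matrix(rnorm(40, 0, sdev), 2, 20))
  }
  ep <- make_epochs(ph, centers = c(4.5, 6), fs = 40, window = c(0, 0.475))
  q <- quantile_iepc(ep, mags, n_quantiles = 5, band = c(4, 8))
  expect_equal(stats::cor(q$iepc, 1:5, method = "spearman"), 1)
  expect_equal(sum(q$n_per_quantile), n)
  # equal magnitudes: quantiles statistically indistinguishable
  ph_u <- array(runif(n * 2 * 20, -pi, pi), c(n, 2, 20))
  epu <- make_epochs(ph_u, centers = c(4.5, 6), fs = 40, window = c(0, 0.475))
  qu <- quantile_iepc(epu, rep(0.5, n), n_quantiles = 5)
  expect_lt(max(qu$iepc) - min(qu$iepc), 0.15)
})

test_that("ERPs recover the kernel under true alignment and degrade otherwise", {
  fs <- 400
  k <- generate_synthetic_kernel(synthetic_kernel_spec(fs = fs))
  ev <- sparse_train(40, gap = 1.1, mag = rep(1, 40))
  resp <- generate_synthetic_response(ev, k, noise = noise_config(snr = 3),
                                      fs = fs, scale_range = NULL, seed = 16)
  erp <- erp_average(resp, ev, window = c(-0.1, 0.3))
  k_peak_lag <- kernel_lags(k)[which.max(k$values)]
  erp_peak_lag <- erp$times[which.max(erp$erp)]
  expect_lt(abs(erp_peak_lag - k_peak_lag), 0.03)
  # later, variably lagged alignment (peakEnv-like): smearing shrinks the
  # average peak (no baseline correction, which a misaligned response
  # window would contaminate)
  set.seed(17)
  ev_late <- landmark_events(ev$time_s + runif(40, 0.05, 0.3),
                             ev$magnitude, duration = attr(ev, "duration"))
  cmpn <- erp_compare(resp, ev, ev_late, window = c(-0.1, 0.3),
                      baseline = NULL)
  expect_gt(cmpn$peak_ratio, 1)
  # random alignment: ERP near zero
  set.seed(18)
  ev_rand <- landmark_events(sort(runif(40, 1, 40)), rep(1, 40),
                             duration = attr(ev, "duration"))
  erp_r <- erp_average(resp, ev_rand, window = c(-0.1, 0.3))
  expect_lt(max(abs(erp_r$erp)), 0.5 * max(abs(erp$erp)))
  expect_error(erp_average(resp, landmark_events(numeric(0), numeric(0),
                                                 duration = 40)), "events")
})

test_that("spectral profiles and peaks behave on flat and structured input", {
  vals <- matrix(0.2, 10, 41)
  m <- structure(list(values = vals, centers = seq(1, 8, length.out = 10),
                      times = seq(-0.1, 0.5, length.out = 41), n_events = 50,
                      fs = 400), class = "iepc_map")
  pr <- spectral_profile(m, window = c(0, 0.5))
  expect_equal(length(pr$profile), 10L)
  expect_equal(nrow(profile_peaks(pr, baseline = 0.19, sd = 0.02)), 0L)
  # a genuine peak above threshold is found at the right band
  vals2 <- vals
  vals2[5, ] <- 0.35; vals2[6, ] <- 0.5; vals2[7, ] <- 0.35
  m2 <- m; m2$values <- vals2
  pk <- profile_peaks(spectral_profile(m2, window = c(0, 0.5)),
                      baseline = 0.2, sd = 0.02)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$center, m$centers[6])
})

test_that("temporal profiles flag exceedances only where coherence is real", {
  set.seed(19)
  nb <- 5; nt <- 200; n_ev <- 100
  fs <- 200
  ph <- array(runif(n_ev * nb * nt, -pi, pi), c(n_ev, nb, nt))
  post <- 81:120   # strong alignment only in this window
  for (b in 1:nb) ph[, b, post] <- matrix(rnorm(n_ev * 40, 0, 0.3), n_ev, 40)
  ep <- make_epochs(ph, centers = seq(1.6, 2.3, length.out = nb), fs = fs,
                    window = c(-0.4, (nt - 1) / fs - 0.4))
  m <- iepc(ep)
  tp <- temporal_profile(m, band_range = c(1.5, 2.4), seed = 20)
  expect_true(all(tp$exceed[post]))
  expect_false(any(tp$exceed[1:60]))
})
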