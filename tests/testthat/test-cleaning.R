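test_that("bad-channel detection follows the variance and saturation rules", {
  set.seed(2)
  n <- 600
  x <- matrix(rnorm(n * 5), n, 5)
  ts <- channel_ts(x, fs = 10, unit = "conc")
  expect_equal(detect_bad_channels(ts), rep(FALSE, 5))

  x2 <- x; x2[, 3] <- 1.5
  expect_equal(which(detect_bad_channels(channel_ts(x2, fs = 10, unit = "conc"))),
               3L)

  x3 <- x; x3[, 2] <- rnorm(n, 0, 15)  # 225x variance, ceiling is 100x
  expect_equal(which(detect_bad_channels(channel_ts(x3, fs = 10, unit = "conc"))),
               2L)

  flat_all <- channel_ts(matrix(1, n, 3), fs = 10, unit = "conc")
  expect_error(detect_bad_channels(flat_all), "unrecoverable")
})

test_that("channel interpolation uses Gaussian distance weights within the probeset", {
  n <- 200
  set.seed(4)
  s <- matrix(rnorm(n * 3), n, 3)

  # equidistant neighbors: replacement is the plain average
  lay <- toy_layout(rbind(c(0, 0), c(40, 0), c(20, 30)))
  ts <- channel_ts(s, fs = 10, unit = "conc")
  out <- interpolate_channels(ts, c(FALSE, FALSE, TRUE), lay, sigma = 25)
  expect_equal(out$data[[1]][, 3], (s[, 1] + s[, 2]) / 2, tolerance = 1e-12)
  expect_false(any(out$bad))
  expect_equal(attr(out, "interpolated"), 3L)

  # hand-computed weights for stated coordinates
  lay2 <- toy_layout(rbind(c(0, 0), c(30, 0), c(10, 20)))
  d1 <- sqrt(10^2 + 20^2); d2 <- sqrt(20^2 + 20^2)
  w <- exp(-c(d1, d2)^2 / (2 * 25^2)); w <- w / sum(w)
  out2 <- interpolate_channels(ts, c(FALSE, FALSE, TRUE), lay2, sigma = 25)
  expect_equal(out2$data[[1]][, 3], s[, 1] * w[1] + s[, 2] * w[2],
               tolerance = 1e-12)

  # untouched when nothing is flagged
  out3 <- interpolate_channels(ts, rep(FALSE, 3), lay)
  expect_identical(out3$data, ts$data)

  # isolated probeset: channel stays flagged with a warning
  lay3 <- toy_layout(rbind(c(0, 0), c(40, 0), c(500, 500)),
                     probeset = c("a", "a", "b"))
  expect_warning(out4 <- interpolate_channels(ts, c(FALSE, FALSE, TRUE), lay3),
                 "no good neighbor")
  expect_true(out4$bad[3])
})

test_that("TDDR repairs baseline-step artifacts and preserves clean signals", {
  fs <- 10
  tt <- seq(0, 240, 1 / fs)
  clean <- sin(2 * pi * 0.05 * tt)

  const <- tddr(rep(2.5, 1000), fs)
  expect_equal(const$signal, rep(2.5, 1000))

  # step/spike artifacts of 10x amplitude: RMSE halved at least
  for (s in 1:5) {
    set.seed(s)
    x <- clean + rnorm(length(tt), 0, 0.05)
    for (a in sample(100:2300, 5)) {
      x[a:length(x)] <- x[a:length(x)] + sample(c(-1, 1), 1) * 10
    }
    r <- tddr(x, fs)
    expect_lt(sqrt(mean((r$signal - clean)^2)),
              0.5 * sqrt(mean((x - clean)^2)))
  }

  # artifact-free: output tracks input
  set.seed(31)
  x <- clean + rnorm(length(tt), 0, 0.1)
  r <- tddr(x, fs)
  expect_gt(cor(r$signal, x), 0.95)
})

test_that("TDDR never inflates RMSE materially on artifact-free session signals", {
  lay <- probe_layout()
  cfg <- sim_config(noise = list(white_sd = 0.3, drift_sd = 0.3,
                                 cardiac_amp = 0.2, cardiac_hz = 1.1,
                                 resp_amp = 0.2, resp_hz = 0.25,
                                 mayer_amp = 0.25, mayer_hz = 0.1,
                                 spike_rate_per_min = 0, spike_amp = 0,
                                 global_sd = 0))
  # TDDR pins the net displacement of the low-frequency part to zero,
  # which re-shapes energy below the analysis band; fidelity is judged
  # where the chain consumes the output, i.e. within the band-pass band,
  # pooled over seeds.
  rin <- rout <- numeric(20)
  for (s in 1:20) {
    ev <- simulate_design(n_trials = 10, block = 10, seed = 800 + s)
    sim <- simulate_session_signal(ev, lay, cfg, seed = 900 + s)
    j <- 7  # an lIFG channel
    x <- sim$ts$data$O2Hb[, j]
    truth_b <- bandpass(sim$truth$amplitude[j] * sim$truth$regressor, cfg$fs)
    rin[s] <- sqrt(mean((bandpass(x, cfg$fs) - truth_b)^2))
    rout[s] <- sqrt(mean((bandpass(tddr(x, cfg$fs)$signal, cfg$fs) - truth_b)^2))
  }
  expect_lt(mean(rout), 1.05 * mean(rin))
})

test_that("CBSI closed forms and exact anti-correlation", {
  set.seed(9)
  o <- rnorm(500)
  # already maximally anti-correlated (alpha = 1)
  cb <- cbsi(o, -o)
  expect_equal(cb$o2hb, o - mean(o), tolerance = 1e-12)
  # alpha = 1/2 closed form
  cb2 <- cbsi(o, -2 * o)
  expect_equal(cb2$o2hb, o - mean(o), tolerance = 1e-12)
  # arbitrary pair: corrected series correlate at exactly -1,
  # and corrected_hhb = -corrected_o2hb / alpha
  h <- rnorm(500)
  cb3 <- cbsi(o, h)
  expect_equal(cor(cb3$o2hb, cb3$hhb), -1, tolerance = 1e-12)
  expect_equal(cb3$hhb, -cb3$o2hb / cb3$alpha, tolerance = 1e-12)
  expect_error(cbsi(o, rep(1, 500), channel = 12), "channel 12")
})

test_that("band-pass contract: DC rejected, passband preserved, high frequency rejected", {
  fs <- 10
  tt <- seq(0, 2400, 1 / fs)
  dc <- bandpass(rep(3, length(tt)), fs)
  expect_lt(max(abs(dc)), 1e-6 * 3)

  inband <- sin(2 * pi * 0.05 * tt)
  y <- bandpass(inband, fs)
  g_in <- sd(y[5000:19000]) / sd(inband[5000:19000])
  expect_gt(g_in, 0.9); expect_lt(g_in, 1.1)

  outband <- sin(2 * pi * 1 * tt)
  g_out <- sd(bandpass(outband, fs)[5000:19000]) / sd(outband[5000:19000])
  expect_lt(g_out, 0.1)

  expect_error(bandpass(rnorm(10), fs), "too short")
  expect_error(bandpass(rnorm(100), fs, low = 0.2, high = 0.1), "low < high")
})

test_that("global-signal reduction removes shared components exactly", {
  lay <- probe_layout()
  n <- 300
  nc <- nrow(lay$channels)
  shared <- sin(seq_len(n) / 10)
  x <- matrix(shared, n, nc)
  ts <- channel_ts(x, fs = 10, unit = "conc", channels = lay$channels$channel)
  out <- global_signal_reduction(ts, lay)
  expect_lt(max(abs(out$data[[1]])), 1e-10)

  zero <- channel_ts(matrix(0, n, nc), fs = 10, unit = "conc",
                     channels = lay$channels$channel)
  expect_equal(max(abs(global_signal_reduction(zero, lay)$data[[1]])), 0)

  # additive shared component: reduction(s + g) == reduction(s)
  set.seed(12)
  s <- matrix(rnorm(n * nc), n, nc)
  ts_s <- channel_ts(s, fs = 10, unit = "conc", channels = lay$channels$channel)
  ts_sg <- channel_ts(s + shared, fs = 10, unit = "conc",
                      channels = lay$channels$channel)
  expect_equal(global_signal_reduction(ts_sg, lay)$data[[1]],
               global_signal_reduction(ts_s, lay)$data[[1]],
               tolerance = 1e-10)
})

test_that("a localized bump on well-separated channels survives global reduction", {
  lay <- toy_layout(rbind(c(0, 0), c(120, 0), c(0, 120), c(120, 120)))
  n <- 200
  x <- matrix(0, n, 4)
  bump <- exp(-((seq_len(n) - 100) / 10)^2)
  x[, 1] <- bump
  ts <- channel_ts(x, fs = 10, unit = "conc")
  out <- global_signal_reduction(ts, lay, sigma = 40)
  expect_gt(max(out$data[[1]][, 1]), 0.5 * max(bump))
})

test_that("z-transform standardizes each channel with sample sd", {
  ts <- channel_ts(matrix(c(1, 2, 3), 3, 1), fs = 1, unit = "conc")
  expect_equal(as.vector(zscore_channels(ts)$data[[1]]), c(-1, 0, 1))

  set.seed(6)
  x <- matrix(rnorm(2000), 500, 4)
  z1 <- zscore_channels(channel_ts(x, fs = 10, unit = "conc"))
  expect_true(all(abs(colMeans(z1$data[[1]])) < 1e-10))
  expect_true(all(abs(apply(z1$data[[1]], 2, sd) - 1) < 1e-10))
  z2 <- zscore_channels(z1)
  expect_equal(z2$data[[1]], z1$data[[1]], tolerance = 1e-12)

  bad <- x; bad[, 2] <- 7
  expect_error(zscore_channels(channel_ts(bad, fs = 10, unit = "conc",
                                          channels = c(4, 9, 14, 19))),
               "channel 9")
})

test_that("cleaning chain is deterministic, NaN-free and standardized", {
  lay <- probe_layout()
  cfg <- sim_config()
  ev <- simulate_design(n_trials = 10, block = 10, seed = 21)
  sim <- simulate_session_signal(ev, lay, cfg, seed = 22)
  r1 <- run_cleaning_chain(sim$ts, lay)
  r2 <- run_cleaning_chain(sim$ts, lay)
  expect_identical(r1$ts$data, r2$ts$data)
  z <- r1$ts$data[[1]]
  expect_false(anyNA(z))
  expect_true(all(abs(colMeans(z)) < 1e-10))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-10))
  expect_equal(r1$ts$unit, "z")
})

test_that("cleaning chain reports an injected dead channel and repairs it", {
  lay <- probe_layout()
  cfg <- sim_config()
  ev <- simulate_design(n_trials = 10, block = 10, seed = 31)
  sim <- simulate_session_signal(ev, lay, cfg, seed = 32)
  sim$ts$data$O2Hb[, 5] <- 0.123  # dead channel
  sim$ts$data$HHb[, 5] <- -0.04
  r <- run_cleaning_chain(sim$ts, lay)
  expect_true(5 %in% r$report$interpolated_pass1)
  expect_false(anyNA(r$ts$data[[1]]))
})

test_that("on artifact-free input the chain matches its linear-stage equivalent", {
  lay <- probe_layout()
  cfg <- sim_config()
  ev <- simulate_design(n_trials = 10, block = 10, seed = 41)
  pred <- forward_model_contrast(ev, lay, cfg)
  sim <- simulate_session_signal(ev, lay, cfg, seed = 43, noise_scale = 0)
  got <- process_session(sim$ts, ev, lay)$contrasts
  m <- merge(pred, got, by = c("phase", "roi"))
  expect_true(all(abs(m$value.y - m$value.x) <= 0.05 * abs(m$value.x)))
})
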