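fs <- 1250

test_that("waveform score follows the squared-ratio definition", {
  expect_equal(waveform_score(rep(2, 32), rep(2, 32)), 1)
  expect_equal(waveform_score(rep(0, 32), rep(1, 32)), 0)
  expect_equal(waveform_score(rep(4, 32), rep(2, 32)), 4)
  expect_equal(waveform_score(rep(4, 32), rep(2, 32), sqrt_variant = TRUE), 2)
  expect_error(waveform_score(rep(1, 32), rep(0, 32)), "positive")
  # amplitude-scaling invariance (template and spread scale together)
  w <- rnorm(32); s <- abs(rnorm(32)) + 0.5
  expect_equal(waveform_score(3 * w, 3 * s), waveform_score(w, s))
})

test_that("unit QC gates on score, refractoriness and polarity", {
  set.seed(70)
  tmpl <- -80 * exp(-((1:32) - 10)^2 / (2 * 2^2)) +
    30 * exp(-((1:32) - 20)^2 / (2 * 5^2))
  sdw <- abs(tmpl) * 0.5 + 10
  clean <- cumsum(rexp(2000, 5)) # Poisson 5 Hz
  expect_true(qc_unit(clean, tmpl, sdw)$pass)
  # 10% doublets at 1 ms
  dbl <- sort(c(clean, clean[seq(1, 2000, by = 10)] + 0.001))
  r <- qc_unit(dbl, tmpl, sdw)
  expect_false(r$pass)
  expect_true("refractory_violation" %in% r$reasons)
  rp <- qc_unit(clean, -tmpl, sdw)
  expect_true("positive_polarity" %in% rp$reasons)
  rs <- qc_unit(clean, tmpl * 0.05, sdw)
  expect_true("waveform_score" %in% rs$reasons)
  expect_error(qc_unit(1, tmpl, sdw), "2 spikes")
})

test_that("trough-to-peak latency classifies wide and narrow templates", {
  wide <- -80 * exp(-((1:32) - 10)^2 / (2 * 1.8^2)) +
    35 * exp(-((1:32) - 22)^2 / (2 * 5^2))
  narrow <- -80 * exp(-((1:32) - 10)^2 / (2 * 1.8^2)) +
    35 * exp(-((1:32) - 14)^2 / (2 * 2.5^2))
  expect_equal(trough_to_peak_latency(wide), 0.6, tolerance = 0.02)
  # the negative lobe skews the narrow bump's maximum slightly rightward
  expect_lt(trough_to_peak_latency(narrow), 0.3)
  expect_gt(trough_to_peak_latency(narrow), 0.15)
  expect_identical(classify_cell_type(wide, threshold_ms = 0.40), "pyr")
  expect_identical(classify_cell_type(narrow, threshold_ms = 0.40), "int")
  # monotone decay after the trough -> no peak -> unclassified
  expect_identical(classify_cell_type(seq(-1, 2, length.out = 32)[32:1], 0.4),
                   "unclassified")
  # fitted threshold separates a bimodal latency set
  set.seed(71)
  lats <- c(rnorm(300, 0.25, 0.05), rnorm(300, 0.65, 0.08))
  thr <- fit_latency_threshold(lats)
  expect_gte(thr, 0.35)
  expect_lte(thr, 0.50)
  lab <- ifelse(lats > thr, "pyr", "int")
  expect_gte(mean(lab == rep(c("int", "pyr"), each = 300)), 0.98)
  # scaling invariance of latency
  expect_equal(trough_to_peak_latency(5 * wide), trough_to_peak_latency(wide))
})

test_that("occupancy normalisation removes phase-dwell bias from coherence", {
  set.seed(72)
  n <- 300 * fs
  phi <- cumsum(2 * pi * 8 / fs * rep(1, n))
  ph <- ((phi + 0.5 * sin(phi)) * 180 / pi) %% 360    # asymmetric dwell
  # occupancy-following spikes: uniform over samples
  idx <- sample(n, 5000)
  co <- phase_coherence((idx - 1) / fs, ph, fs)
  expect_lt(co$mvl, 0.05)
  raw_mvl <- Mod(mean(exp(1i * ph[idx] * pi / 180)))
  expect_gt(raw_mvl, 0.15)
  expect_true(co$sufficient)
  # perfectly locked spikes
  i180 <- which(abs(ph - 180) < 3)
  co2 <- phase_coherence((i180 - 1) / fs, ph, fs)
  expect_gt(co2$mvl, 0.95)
  expect_equal(co2$mean_phase, 180, tolerance = 2)
  # rotation: mean phase rotates, mvl unchanged
  co3 <- phase_coherence((i180 - 1) / fs, (ph + 90) %% 360, fs)
  expect_equal(co3$mvl, co2$mvl, tolerance = 1e-9)
  expect_equal(co3$mean_phase, 270, tolerance = 2)
  # uniform phase, uniform spikes: mvl near the n^-1/2 null scale
  ph_u <- (seq_len(n) * 360 * 7.3 / fs) %% 360
  co4 <- phase_coherence((sample(n, 5000) - 1) / fs, ph_u, fs)
  expect_lt(co4$mvl, 0.05)
  # insufficient spikes flagged
  co5 <- phase_coherence((1:100) / fs, ph, fs)
  expect_false(co5$sufficient)
})

test_that("spike-shift surrogates detect coupling and stay calibrated", {
  set.seed(73)
  n <- 150 * fs
  gph <- (cumsum(rep(2 * pi * 40 / fs, n)) * 180 / pi) %% 360
  tph <- (seq_len(n) * 360 * 8 / fs) %% 360
  gamp <- abs(hipplamina:::bandpass_low(rnorm(n), 1, 5, fs))
  # von Mises kappa = 2 locked unit
  lam <- exp(2 * cos((gph - 180) * pi / 180))
  spk <- which(runif(n) < 0.002 * lam)
  res <- spike_shift_surrogate_test((spk - 1) / fs, gph, tph, gamp, fs,
                                    n_surrogates = 1000, seed = 5)
  expect_lt(res$p, 0.01)
  # determinism
  res2 <- spike_shift_surrogate_test((spk - 1) / fs, gph, tph, gamp, fs,
                                     n_surrogates = 1000, seed = 5)
  expect_identical(res$p, res2$p)
  # unlocked unit: p is not extreme
  spk0 <- sample(n, 400)
  res0 <- spike_shift_surrogate_test((spk0 - 1) / fs, gph, tph, gamp, fs,
                                     n_surrogates = 500, seed = 5)
  expect_gt(res0$p, 0.01)
})

test_that("trough-triggered rates show locking and stay flat for Poisson units", {
  set.seed(74)
  n <- 400 * fs
  t <- seq_len(n) / fs
  x <- sin(2 * pi * 40 * t) + 0.3 * rnorm(n)
  bs <- envelope_phase(bandpass(x, 20, 45, fs), band = c(20, 45))
  cyc <- data.frame(t0 = seq(0.2, 399, by = 0.125))
  cyc$t1 <- cyc$t0 + 0.125
  # unit locked near gamma troughs (von Mises kappa = 2 at 180 deg), with
  # rate riding the envelope so the deepest (triggered) troughs dominate
  lam <- exp(2 * cos((bs$phase - 180) * pi / 180)) * bs$envelope^2
  spk <- (which(runif(n) < 0.004 * lam) - 1) / fs
  r <- trough_triggered_rates(spk, bs, cyc, fs)
  expect_equal(r$time[which.max(r$rate)], 0, tolerance = 0.0021)
  # periodicity at the 25-ms gamma period
  ac <- acf(r$rate, lag.max = 20, plot = FALSE)$acf
  expect_gt(ac[13], 0.3)                         # 12 bins x 2 ms = 24 ms
  # unmodulated Poisson unit: flat trace
  spk0 <- sort(runif(4000, 0, 400))
  r0 <- trough_triggered_rates(spk0, bs, cyc, fs, zscore = TRUE)
  expect_lt(max(abs(r0$rate)), 3.5)
  # empty spike train: all-zero trace
  r_e <- trough_triggered_rates(numeric(), bs, cyc, fs)
  expect_true(all(r_e$rate == 0))
  expect_error(trough_triggered_rates(spk, bs, cyc[0, ], fs), "quantile|troughs")
})
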