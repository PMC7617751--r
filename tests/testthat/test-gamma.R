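fs <- 1250

test_that("Morlet spectrogram localises tones with L1-normalised kernels", {
  t <- seq(0, 20, by = 1 / fs)
  sp <- morlet_spectrogram(sin(2 * pi * 60 * t), fs)
  mean_amp <- colMeans(sp$amplitude)
  expect_equal(sp$freqs[which.max(mean_amp)],
               sp$freqs[which.min(abs(sp$freqs - 60))])
  # linearity: scaling the signal scales the amplitude
  sp3 <- morlet_spectrogram(3 * sin(2 * pi * 60 * t), fs)
  expect_equal(sp3$amplitude, 3 * sp$amplitude, tolerance = 1e-9)
  # equal-amplitude tones give equal peaks (within 10%) under L1 kernels
  sp2 <- morlet_spectrogram(sin(2 * pi * 30 * t) + sin(2 * pi * 150 * t), fs)
  m2 <- colMeans(sp2$amplitude)
  a30 <- m2[which.min(abs(sp2$freqs - 30))]
  a150 <- m2[which.min(abs(sp2$freqs - 150))]
  expect_lt(abs(a150 / a30 - 1), 0.1)
  expect_error(morlet_spectrogram(rnorm(100), fs, freqs = c(40, 700)), "Nyquist")
})

test_that("theta-gamma profiles are flat under phase-independent amplitude", {
  set.seed(60)
  n <- 200 * fs
  ph <- (seq_len(n) * 360 * 8 / fs) %% 360
  amp <- matrix(abs(rnorm(n * 3, 10)), n, 3)
  prof <- theta_gamma_profile(list(amplitude = amp, freqs = c(30, 60, 120)), ph)
  expect_lt(max(prof$normalized) , 1.1)
  expect_true(all(prof$normalized >= 1))
  expect_error(theta_gamma_profile(list(amplitude = amp, freqs = 1:3),
                                   rep(NA_real_, n)), "no valid")
})

test_that("injected theta-nested bursts are recovered at their frequency and phase", {
  spec <- session_spec(seed = 61, duration_awake = 120, duration_rest = 30,
                       theta_asym = 0,
                       gamma_bursts = list(rad = list(freq = 40, phase = 120,
                                                      amp = 25)))
  sess <- generate_session(spec)
  rec <- sess$rec
  tr <- sess$truth
  n_aw <- round(120 * fs)
  dec <- masked_emd(rec$data[tr$layers[["pyr"]], seq_len(n_aw)], fs)
  cy <- delineate_cycles(dec$imfs[, 6], dec$residue, fs)
  ph <- interpolated_phase(cy, n_aw, fs)
  sp <- morlet_spectrogram(rec$data[tr$layers[["rad"]], seq_len(n_aw)], fs)
  prof <- theta_gamma_profile(sp, ph)
  i40 <- which.min(abs(prof$freqs - 40))
  # frequency of the strongest modulation within one bin of 40 Hz
  expect_lte(abs(which.max(apply(prof$normalized, 1, max)) - i40), 1)
  # phase bin of the injected burst within one 10-degree bin
  pk_phase <- prof$phase_centers[which.max(prof$amplitude[i40, ])]
  expect_lte(min(abs(pk_phase - 125), 360 - abs(pk_phase - 125)), 10)
  # profile stable under bin refinement
  prof72 <- theta_gamma_profile(sp, ph, n_phase_bins = 72)
  pk72 <- prof72$phase_centers[which.max(prof72$amplitude[i40, ])]
  expect_lte(min(abs(pk72 - pk_phase), 360 - abs(pk72 - pk_phase)), 10)
  # burst main frequency from the top-quartile bursts
  bs <- envelope_phase(bandpass(rec$data[tr$layers[["rad"]], seq_len(n_aw)],
                                20, 45, fs), band = c(20, 45))
  bmf <- burst_main_frequency(bs, cy, sp, fs)
  expect_equal(bmf$peak_freq, sp$freqs[which.min(abs(sp$freqs - 40))])
  expect_gt(bmf$n_bursts, 40)
  # amplitude-scaling invariance of the burst spectrum peak
  bs2 <- envelope_phase(5 * bs$values, band = c(20, 45))
  sp_sc <- list(amplitude = 5 * sp$amplitude, freqs = sp$freqs)
  bmf2 <- burst_main_frequency(bs2, cy, sp_sc, fs)
  expect_equal(bmf2$peak_freq, bmf$peak_freq)
})

test_that("phase-shuffled amplitude flattens the profile", {
  set.seed(62)
  n <- 100 * fs
  ph <- (seq_len(n) * 360 * 8 / fs) %% 360
  # amplitude locked to phase 90
  amp <- matrix(1 + exp(2 * cos((ph - 90) * pi / 180)), n, 1)
  prof <- theta_gamma_profile(list(amplitude = amp, freqs = 40), ph)
  expect_gt(max(prof$normalized), 2)
  prof_sh <- theta_gamma_profile(list(amplitude = amp, freqs = 40),
                                 sample(ph))
  expect_lt(max(prof_sh$normalized), 1.1)
})

test_that("spatial ICA isolates weak fast gamma from strong mid gamma", {
  set.seed(63)
  n <- 60 * fs
  t <- seq_len(n) / fs
  s_mid <- sin(2 * pi * 60 * t) * (1 + 0.3 * sin(2 * pi * 0.5 * t))
  s_fast <- 0.3 * sin(2 * pi * 150 * t) * (1 + 0.4 * sin(2 * pi * 0.7 * t + 1))
  ok <- 0
  for (r in 1:5) {
    A <- matrix(runif(10, 0.3, 1.5), 5, 2)
    X <- A %*% rbind(s_mid, s_fast) + matrix(rnorm(5 * n, sd = 0.05), 5)
    rec <- recording(X, fs, seq(0, 200, by = 50))
    ica <- ica_fast_gamma(rec, target_ch = 3, seed = r)
    if (!is.null(ica$component) && abs(cor(ica$component, s_fast)) >= 0.9)
      ok <- ok + 1
    # gain invariance on the first repetition
    if (r == 1) {
      rec2 <- recording(X * runif(5, 0.5, 2), fs, rec$depths)
      ica2 <- ica_fast_gamma(rec2, target_ch = 3, seed = r)
      expect_gte(abs(cor(ica2$component, s_fast)), 0.9)
      expect_gt(cor(ica$component,
                    bandpass(X[3, ], 100, 250, fs)), 0)  # sign alignment
    }
  }
  expect_gte(ok, 4)
  # channels without supra-100-Hz structure return an empty result
  slow_only <- outer(runif(5, 0.5, 2), sin(2 * pi * 40 * t)) +
    outer(runif(5, 0.5, 1), sin(2 * pi * 9 * t)) +
    matrix(rnorm(5 * n, sd = 0.01), 5)
  icas <- ica_fast_gamma(recording(slow_only, fs, seq(0, 200, by = 50)), 3)
  expect_null(icas$component)
  expect_error(ica_fast_gamma(recording(slow_only[1:2, ], fs, c(0, 50)), 1),
               "3 channels")
})

test_that("speed modulation slope matches exact log-linear designs", {
  set.seed(64)
  speed <- runif(600, 1, 30)
  qb <- cut(speed, quantile(speed, seq(0, 1, 1 / 6)), include.lowest = TRUE,
            labels = FALSE)
  expect_equal(speed_modulation_index(2^qb, speed)$slope, 1, tolerance = 0.01)
  expect_equal(speed_modulation_index(2^(-qb), speed)$slope, -1,
               tolerance = 0.01)
  expect_lt(abs(speed_modulation_index(runif(600, 1, 2), speed)$slope), 0.05)
  expect_error(speed_modulation_index(runif(60), rep(5, 60)), "constant")
})
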