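fs <- 1250

test_that("decimation passes DC, preserves in-band sinusoids, enforces integer factors", {
  # constant input stays constant, at the filter's DC gain (an even-order
  # Chebyshev-I pass-band rests -Rp dB below unity at DC; forward-backward
  # filtering applies it twice)
  y_dc <- decimate_lfp(rep(3, 16000), 20000, 1250)
  bf <- signal::cheby1(8, 0.05, 0.8 / 16)
  dc_gain2 <- (sum(bf$b) / sum(bf$a))^2
  expect_equal(mean(y_dc), 3 * dc_gain2, tolerance = 1e-3)
  expect_lt(sd(y_dc), 0.02)
  expect_identical(length(decimate_lfp(rnorm(20000), 20000, 1250)), 1250L)

  t_raw <- seq(0, 2, by = 1 / 20000)
  y <- decimate_lfp(sin(2 * pi * 10 * t_raw), 20000, 1250)
  t_dec <- (seq_along(y) - 1) / 1250
  ref <- sin(2 * pi * 10 * t_dec)
  inner <- 200:2300
  # amplitude within the Chebyshev pass-band ripple contract (~1%)
  fit <- lm(y[inner] ~ ref[inner] - 1)
  expect_gt(coef(fit)[1], 0.985)
  expect_lt(coef(fit)[1], 1.005)
  expect_gt(cor(y[inner], ref[inner]), 0.9999)

  expect_error(decimate_lfp(rnorm(100), 20000, 1300), "not an integer")
})

test_that("band-pass filter has unit pass-band and strong stop-band, zero phase", {
  t <- seq(0, 10, by = 1 / fs)
  s30 <- sin(2 * pi * 30 * t)
  inner <- 2000:10000
  expect_gt(max(abs(bandpass(s30, 20, 45, fs)[inner])), 0.95)
  expect_lt(max(abs(bandpass(s30, 100, 250, fs)[inner])), 0.05)
  expect_equal(bandpass(numeric(1000) , 20, 45, fs), numeric(1000))
  # zero-phase: filtered in-band sine is phase-aligned with the input
  expect_gt(cor(bandpass(s30, 20, 45, fs)[inner], s30[inner]), 0.999)
  expect_error(bandpass(s30, 100, 700, fs), "Nyquist")
  # linearity: scaling input scales output
  y1 <- bandpass(s30, 20, 45, fs)
  expect_equal(bandpass(3.5 * s30, 20, 45, fs), 3.5 * y1, tolerance = 1e-6)
})

test_that("analytic envelope and phase follow the peak-zero convention", {
  t <- seq(0, 10, by = 1 / fs)
  x <- cos(2 * pi * 8 * t)
  bs <- envelope_phase(x)
  inner <- 500:12000
  expect_true(all(bs$envelope >= 0))
  expect_lt(max(abs(bs$envelope[inner] - 1)), 0.01)
  expect_true(all(bs$phase >= 0 & bs$phase < 360))
  peaks <- which(diff(sign(diff(x))) < 0) + 1L
  peaks <- peaks[peaks > 500 & peaks < 12000]
  ph_pk <- bs$phase[peaks]
  expect_lt(max(pmin(ph_pk, 360 - ph_pk)), 2)   # 0 deg at peaks
  # amplitude-modulated sine: envelope tracks the modulator
  a <- 1 + 0.5 * sin(2 * pi * 0.5 * t)
  bs2 <- envelope_phase(a * sin(2 * pi * 40 * t))
  expect_lt(max(abs(bs2$envelope[inner] - a[inner]) / a[inner]), 0.02)
  # scaling input scales envelope
  bs3 <- envelope_phase(2 * x)
  expect_equal(bs3$envelope, 2 * bs$envelope, tolerance = 1e-9)
  expect_error(envelope_phase(c(1, 2, 3)), "4 samples")
})

test_that("triggered averaging aligns, cancels random phases, and drops edge events", {
  t <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 8 * t)
  peaks <- (which(diff(sign(diff(x))) < 0) + 1L)
  peaks <- peaks[peaks > fs & peaks < length(x) - fs]
  ta <- triggered_average(x, (peaks - 1) / fs, c(0.05, 0.05), fs = fs)
  expect_equal(which.max(ta$values[1, ]), which.min(abs(ta$time)))
  expect_equal(ta$n_events, length(peaks))
  # k identical segments average to the segment exactly
  seg_trigs <- (c(2000, 2000 + 1250, 2000 + 2500) - 1) / fs  # 8 Hz-periodic
  ta2 <- triggered_average(x, seg_trigs, c(0.02, 0.02), fs = fs)
  i0 <- 2000 + round(-0.02 * fs):round(0.02 * fs)
  expect_equal(ta2$values[1, ], x[i0], tolerance = 1e-10)
  # random-phase triggers cancel
  set.seed(1)
  ta3 <- triggered_average(x, runif(10000, 1, 19), c(0.1, 0.1), fs = fs)
  expect_lt(max(abs(ta3$values)), 0.05)
  # single trigger reproduces the raw segment; out-of-range dropped
  ta4 <- triggered_average(x, c(-5, 2, 50), c(0.1, 0.1), fs = fs)
  expect_equal(ta4$n_events, 1L)
  expect_equal(ta4$n_dropped, 2L)
  expect_equal(ta4$values[1, ], x[2501 + round(-0.1 * fs):round(0.1 * fs)])
  expect_error(triggered_average(x, c(-10, 100), c(0.1, 0.1), fs = fs),
               "no usable triggers")
})

test_that("recording container validates and round-trips through disk", {
  mat <- matrix(rnorm(40), 4)
  rec <- recording(mat, 1250, c(0, 50, 100, 150), session_id = "s1",
                   subject_id = "m1")
  path <- tempfile(fileext = ".lamrec")
  write_recording(rec, path)
  rec2 <- read_recording(path)
  expect_equal(rec2$data, mat)
  expect_equal(rec2$fs, 1250)
  expect_equal(rec2$depths, c(0, 50, 100, 150))
  expect_equal(rec2$subject_id, "m1")
  expect_true(file.exists(paste0(path, ".json")))

  expect_error(recording(mat, 1250, c(0, 50, 100)), "rows")
  expect_error(recording(mat, 1250, c(0, 50, 50, 100)), "increasing")
  expect_error(recording(matrix(c(NA, rnorm(39)), 4), 1250, c(0, 50, 100, 150)),
               "NA")
  bad <- tempfile()
  saveRDS(list(fs = 1250), bad)
  expect_error(read_recording(bad), "lfp")
  bad2 <- tempfile()
  saveRDS(list(lfp = mat, depths = c(0, 50, 100, 150)), bad2)
  expect_error(read_recording(bad2), "fs")
})

test_that("decimate-upsample round trip reconstructs band-limited signals", {
  n <- 20000                      # 4 s at 5 kHz; tones periodic in the window
  t <- (seq_len(n) - 1) / 5000
  x <- sin(2 * pi * 50 * t) + 0.5 * sin(2 * pi * 200 * t)
  y <- decimate_lfp(x, 5000, 1250)
  m <- length(y)
  # band-limited (sinc) upsampling by spectrum zero-padding
  Y <- fft(y)
  Z <- complex(length.out = n)
  half <- m %/% 2
  Z[1:half] <- Y[1:half]
  Z[(n - half + 1):n] <- Y[(half + 1):m]
  up <- Re(fft(Z, inverse = TRUE)) / m
  inner <- 2000:18000
  # 1.5%: the Chebyshev pass-band ripple alone contributes up to ~1.1%
  expect_lt(sqrt(mean((up[inner] - x[inner])^2)) / sd(x), 0.015)
})
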