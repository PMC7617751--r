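#' Specification of a synthetic laminar session
#'
#' Parameterises the generator that emulates the laminar statistical
#' structure of a CA1-to-dentate-gyrus probe recording: depth-dependent
#' theta amplitude and phase (reversal across the fissure, amplitude
#' maximum at the fissure), sharp waves with polarity reversal across the
#' pyramidal layer and concurrent pyramidal-channel ripples, two
#' dentate-spike classes with molecular-layer sinks and a granular source,
#' layer-specific theta-nested gamma bursts, 1/f background noise, and
#' spike trains with von Mises phase coupling. All waveform templates are
#' parametric (Gaussian-windowed sinusoids, Gaussian deflections).
#'
#' @param seed RNG seed (the generator is fully deterministic given it).
#' @param n_channels,spacing probe geometry (spacing in um).
#' @param fs sampling rate (Hz).
#' @param duration_awake,duration_rest epoch durations (s); awake first.
#' @param layer_depths named depth vector (um) for the eight landmarks.
#' @param theta_freq,theta_asym theta frequency (Hz) and waveform asymmetry
#'   (phase-distortion coefficient; 0 = symmetric).
#' @param ripple_freq,ripple_amp,ripple_sigma ripple frequency (Hz), peak
#'   amplitude (uV) and Gaussian envelope sd (s).
#' @param swr_rate,ds_rate event rates during rest (Hz; `ds_rate` is per
#'   class).
#' @param gamma_bursts named list (by layer) of `list(freq, phase, amp)`:
#'   burst centre frequency (Hz), preferred pyramidal theta phase (deg) and
#'   amplitude (uV).
#' @param units list of unit definitions
#'   (`layer, cell_type, rate, theta_kappa, theta_phase, swr_gain`), or
#'   `NULL` for a small default population.
#' @param noise_scale 1/f noise SD (uV); `noise_alpha` its spectral
#'   exponent.
#' @return A `session_spec` list.
#' @export
session_spec <- function(seed = 1, n_channels = 32, spacing = 50, fs = 1250,
                         duration_awake = 360, duration_rest = 240,
                         layer_depths = c(pyr = 300, rad = 500, "l-m" = 650,
                                          hf = 700, omol = 800, mmol = 900,
                                          imol = 1000, gr = 1150),
                         theta_freq = 8, theta_asym = 0.3,
                         ripple_freq = 140, ripple_amp = 60,
                         ripple_sigma = 0.012,
                         swr_rate = 0.25, ds_rate = 0.25,
                         gamma_bursts = list(
                           rad = list(freq = 40, phase = 90, amp = 25),
                           "l-m" = list(freq = 70, phase = 40, amp = 20),
                           pyr = list(freq = 150, phase = 200, amp = 12)),
                         units = NULL, noise_scale = 15, noise_alpha = 1) {
  if (any(diff(layer_depths) <= 0))
    stop("layer_depths must be strictly increasing")
  if (swr_rate < 0 || ds_rate < 0) stop("rates must be >= 0")
  if (is.null(units)) {
    units <- list(
      list(layer = "pyr", cell_type = "pyr", rate = 2, theta_kappa = 1,
           theta_phase = 190, swr_gain = 6),
      list(layer = "pyr", cell_type = "pyr", rate = 1.5, theta_kappa = 0.8,
           theta_phase = 170, swr_gain = 8),
      list(layer = "pyr", cell_type = "int", rate = 12, theta_kappa = 0.6,
           theta_phase = 150, swr_gain = 3),
      list(layer = "rad", cell_type = "int", rate = 8, theta_kappa = 0.8,
           theta_phase = 110, swr_gain = 0.5),
      list(layer = "gr", cell_type = "pyr", rate = 1, theta_kappa = 0.5,
           theta_phase = 60, swr_gain = 1))
  }
  for (u in units)
    if (u$rate < 0 || u$theta_kappa < 0) stop("unit rates and kappa must be >= 0")
  structure(as.list(environment()), class = "session_spec")
}

# Depth-parameterised laminar profiles (uV as functions of depth in um).
# Theta: amplitude maximum at the fissure with a secondary molecular-layer
# bump; phase reverses (~180 deg) across the fissure and keeps drifting
# (~70 deg) across the molecular layers toward the granular layer.
# Sharp wave: CA1 component (oriens-positive, radiatum-negative) plus a
# delayed dentate component (inner-molecular sink, infragranular source).
laminar_profiles <- function(spec) {
  ld <- spec$layer_depths
  g <- function(d, mu, sig) exp(-(d - mu)^2 / (2 * sig^2))
  sig_f <- function(d, mu, sl) 1 / (1 + exp(-(d - mu) / sl))
  list(
    theta_amp = function(d) 30 + 270 * g(d, ld[["hf"]], 150) +
      80 * g(d, (ld[["mmol"]] + ld[["imol"]]) / 2, 100),
    theta_off = function(d) 40 * sig_f(d, (ld[["rad"]] + ld[["l-m"]]) / 2, 80) +
      140 * sig_f(d, ld[["hf"]], 25) +
      70 * sig_f(d, ld[["mmol"]] + 20, 60),
    sharp_wave = function(d) 30 * g(d, ld[["pyr"]] - 100, 60) -
      250 * g(d, ld[["rad"]], 80),
    sharp_wave_dg = function(d) -90 * g(d, ld[["imol"]], 60) +
      50 * g(d, ld[["gr"]] + 30, 70),
    ripple = function(d) spec$ripple_amp * g(d, ld[["pyr"]], 80),
    ds1 = function(d) 160 * g(d, ld[["gr"]], 80) - 120 * g(d, ld[["omol"]], 60),
    ds2 = function(d) 160 * g(d, ld[["gr"]], 80) - 120 * g(d, ld[["mmol"]], 60))
}

# 1/f^alpha noise, sd-normalised.
pink_noise <- function(n, alpha, scale) {
  X <- fft(rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                 # symmetric frequency index
  X <- X / f^(alpha / 2)
  X[1] <- 0
  x <- Re(fft(X, inverse = TRUE) / n)
  x / sd(x) * scale
}

# Poisson event times within [t0, t1] with a minimum gap and edge margin.
poisson_times <- function(rate, t0, t1, min_gap, margin = 1) {
  if (rate <= 0 || t1 - t0 <= 2 * margin) return(numeric())
  tt <- t0 + margin + cumsum(rexp(ceiling((t1 - t0) * rate * 3) + 10,
                                  rate) + min_gap)
  tt[tt < t1 - margin]
}

#' Generate a synthetic laminar session
#'
#' Builds the LFP matrix (1/f noise + depth-profiled theta + sharp-wave
#' ripple events + two dentate-spike classes + theta-phase-gated gamma
#' bursts) and phase-coupled spike trains, returning the recording together
#' with complete ground truth.
#'
#' @param spec a [session_spec()].
#' @return list with `rec` (a `laminar_recording`) and `truth`: `swr`
#'   (event times), `ds` (times and classes), `layers` (landmark channel
#'   map), `channel_layers` (per-channel label or `NA`), `theta_phase`
#'   (per-sample true pyramidal theta phase, `NA` during rest), `theta_dzc`
#'   (descending zero-crossing times), `epochs`, `units` (definitions plus
#'   `spike_times`, `mean_waveform`, `sd_waveform`), `speed` (per-sample
#'   cm/s during awake), `dg_channels`, `burst_series`.
#' @export
generate_session <- function(spec) {
  set.seed(spec$seed)
  fs <- spec$fs
  depths <- (seq_len(spec$n_channels) - 1L) * spec$spacing
  prof <- laminar_profiles(spec)
  ld <- spec$layer_depths
  n_aw <- round(spec$duration_awake * fs)
  n_rs <- round(spec$duration_rest * fs)
  n <- n_aw + n_rs

  # --- theta (awake): wandering frequency, asymmetric (phase-distorted) wave
  fmod <- bandpass_low(rnorm(n_aw), 0.01, 0.1, fs)
  fmod <- fmod / max(abs(fmod), 1e-9) * 0.7
  phi <- cumsum(2 * pi * (spec$theta_freq + fmod) / fs)
  ph_d <- phi + spec$theta_asym * sin(phi)      # distorted phase (radians)
  theta_phase_true <- c((ph_d * 180 / pi) %% 360, rep(NA_real_, n_rs))
  cosd <- cos(ph_d)
  dzc <- which(cosd[-n_aw] > 0 & cosd[-1] <= 0)  # descending zero-crossings

  data <- matrix(0, spec$n_channels, n)
  for (ch in seq_len(spec$n_channels)) {
    x <- pink_noise(n, spec$noise_alpha, spec$noise_scale)
    x[seq_len(n_aw)] <- x[seq_len(n_aw)] + prof$theta_amp(depths[ch]) *
      cos(ph_d + prof$theta_off(depths[ch]) * pi / 180)
    data[ch, ] <- x
  }

  add_event <- function(t0, course, profile_vals) {
    i0 <- round(t0 * fs) + 1L
    idx <- i0 + seq_along(course) - ceiling(length(course) / 2)
    ok <- idx >= 1L & idx <= n
    data[, idx[ok]] <<- data[, idx[ok]] + outer(profile_vals, course[ok])
  }

  rest0 <- spec$duration_awake
  rest1 <- rest0 + spec$duration_rest

  # --- sharp-wave ripples (rest)
  swr_t <- poisson_times(spec$swr_rate, rest0, rest1, min_gap = 0.8)
  tt <- seq(-0.25, 0.25, by = 1 / fs)
  for (t0 in swr_t) {
    a <- runif(1, 0.8, 1.2)
    add_event(t0, a * exp(-tt^2 / (2 * 0.030^2)), prof$sharp_wave(depths))
    add_event(t0, a * exp(-(tt - 0.008)^2 / (2 * 0.025^2)),
              prof$sharp_wave_dg(depths))
    add_event(t0, a * exp(-tt^2 / (2 * spec$ripple_sigma^2)) *
                cos(2 * pi * spec$ripple_freq * tt), prof$ripple(depths))
  }

  # --- dentate spikes (rest), two classes
  ds1_t <- poisson_times(spec$ds_rate, rest0, rest1, min_gap = 0.3)
  ds2_t <- poisson_times(spec$ds_rate, rest0, rest1, min_gap = 0.3)
  tt_ds <- seq(-0.06, 0.06, by = 1 / fs)
  for (t0 in ds1_t)
    add_event(t0, runif(1, 0.8, 1.2) * exp(-tt_ds^2 / (2 * 0.008^2)),
              prof$ds1(depths))
  for (t0 in ds2_t)
    add_event(t0, runif(1, 0.8, 1.2) * exp(-tt_ds^2 / (2 * 0.008^2)),
              prof$ds2(depths))

  # --- theta-nested gamma bursts (awake), centred at a preferred phase
  burst_series <- list()
  for (layer in names(spec$gamma_bursts)) {
    gb <- spec$gamma_bursts[[layer]]
    pref <- gb$phase * pi / 180
    k <- seq(ceiling((ph_d[1] - pref) / (2 * pi)),
             floor((ph_d[n_aw] - pref) / (2 * pi)))
    centers <- round(approx(ph_d, seq_len(n_aw), xout = pref + 2 * pi * k,
                            ties = "ordered")$y)
    centers <- centers[!is.na(centers)]
    centers <- centers[runif(length(centers)) < 0.9]
    sig_b <- 1.5 / gb$freq
    half_b <- ceiling(4 * sig_b * fs)
    ker <- exp(-((-half_b:half_b) / fs)^2 / (2 * sig_b^2)) *
      cos(2 * pi * gb$freq * (-half_b:half_b) / fs)
    series <- numeric(n_aw)
    for (c0 in centers) {
      idx <- c0 + seq_along(ker) - half_b - 1L
      ok <- idx >= 1L & idx <= n_aw
      series[idx[ok]] <- series[idx[ok]] + runif(1, 0.7, 1.3) * ker[ok]
    }
    burst_series[[layer]] <- series
    spatial <- gb$amp * exp(-(depths - ld[[layer]])^2 / (2 * 60^2))
    nz <- which(spatial > 0.01 * gb$amp)
    data[nz, seq_len(n_aw)] <- data[nz, seq_len(n_aw)] +
      outer(spatial[nz], series)
  }

  # --- speed (awake): smoothed positive trace
  sp <- bandpass_low(rnorm(n_aw), 0.01, 0.5, fs)
  speed <- pmax(0.5, 12 + 8 * sp / max(abs(sp)))

  # --- units: inhomogeneous Poisson with von Mises theta coupling + SWR gain
  in_swr <- rep(FALSE, n)
  for (t0 in swr_t) {
    idx <- round((t0 + c(-0.05, 0.05)) * fs) + 1L
    in_swr[max(1, idx[1]):min(n, idx[2])] <- TRUE
  }
  units <- lapply(spec$units, function(u) {
    rate <- rep(u$rate, n)
    if (u$theta_kappa > 0)
      rate[seq_len(n_aw)] <- rate[seq_len(n_aw)] *
        exp(u$theta_kappa * cos(ph_d - u$theta_phase * pi / 180)) /
        besselI(u$theta_kappa, 0)
    rate[in_swr] <- rate[in_swr] * u$swr_gain
    idx <- which(runif(n) < pmin(rate / fs, 0.5))
    st <- (idx - 1L + runif(length(idx))) / fs
    if (length(st) > 1L) st <- st[c(TRUE, diff(st) > 0.0025)]
    wide <- u$cell_type == "pyr"
    i <- seq_len(32)
    wf <- -80 * exp(-(i - 10)^2 / (2 * 1.8^2)) +
      35 * exp(-(i - 10 - (if (wide) 12 else 4))^2 /
                 (2 * (if (wide) 5 else 2.5)^2))
    c(u, list(spike_times = st, mean_waveform = wf,
              sd_waveform = abs(wf) * 0.4 + 7))
  })

  # --- truth tables
  landmark_ch <- vapply(ld, function(d) which.min(abs(depths - d)), 0L)
  channel_layers <- rep(NA_character_, spec$n_channels)
  for (ch in seq_len(spec$n_channels)) {
    dd <- abs(ld - depths[ch])
    if (min(dd) <= 60) channel_layers[ch] <- names(ld)[which.min(dd)]
  }
  dg_channels <- which(depths >= ld[["imol"]] & depths <= ld[["gr"]] + 150)

  rec <- recording(data, fs, depths, layer_labels = channel_layers,
                   session_id = sprintf("synth-%d", spec$seed),
                   subject_id = sprintf("subj-%d", spec$seed))
  ds_all <- data.frame(t_peak = c(ds1_t, ds2_t),
                       ds_class = rep(c("DS1", "DS2"),
                                      c(length(ds1_t), length(ds2_t))))
  list(rec = rec,
       truth = list(
         swr = data.frame(t_peak = swr_t),
         ds = ds_all[order(ds_all$t_peak), ],
         layers = landmark_ch, channel_layers = channel_layers,
         theta_phase = theta_phase_true, theta_dzc = (dzc - 1L) / fs,
         epochs = data.frame(kind = c("awake", "rest"),
                             t_start = c(0, rest0), t_end = c(rest0, rest1)),
         units = units, speed = speed, dg_channels = dg_channels,
         burst_series = burst_series))
}

#' Generate a simulated tetrode descent
#'
#' Samples the laminar model at arbitrary depths: for each depth step, a
#' short single-channel recording is generated from the same spatial
#' profiles (own noise realisation, shared event/theta statistics), for
#' projection-trajectory tests. Ground truth includes SWR peak times and
#' theta descending zero-crossings so waveform features can be extracted
#' without a pyramidal reference channel.
#'
#' @param spec a [session_spec()] (durations and rates are reused).
#' @param depth_steps numeric vector of tetrode depths (um) within the
#'   probe depth range.
#' @return list of per-step lists (`rec`, `truth`), in step order; empty
#'   list for no steps.
#' @export
generate_tetrode_descent <- function(spec, depth_steps) {
  if (!length(depth_steps)) return(list())
  rng <- range((seq_len(spec$n_channels) - 1L) * spec$spacing)
  if (any(depth_steps < rng[1] | depth_steps > rng[2]))
    stop("depth steps outside the probe depth range")
  lapply(seq_along(depth_steps), function(i) {
    s2 <- spec
    s2$seed <- spec$seed + 1000L * i
    tetrode_session(s2, depth_steps[i])
  })
}

# Internal: single-tetrode recording at one depth.
tetrode_session <- function(spec, depth) {
  set.seed(spec$seed)
  fs <- spec$fs
  prof <- laminar_profiles(spec)
  n_aw <- round(spec$duration_awake * fs)
  n_rs <- round(spec$duration_rest * fs)
  n <- n_aw + n_rs
  fmod <- bandpass_low(rnorm(n_aw), 0.01, 0.1, fs)
  fmod <- fmod / max(abs(fmod), 1e-9) * 0.7
  phi <- cumsum(2 * pi * (spec$theta_freq + fmod) / fs)
  ph_d <- phi + spec$theta_asym * sin(phi)
  x <- pink_noise(n, spec$noise_alpha, spec$noise_scale)
  x[seq_len(n_aw)] <- x[seq_len(n_aw)] + prof$theta_amp(depth) *
    cos(ph_d + prof$theta_off(depth) * pi / 180)
  rest0 <- spec$duration_awake
  rest1 <- rest0 + spec$duration_rest
  swr_t <- poisson_times(spec$swr_rate, rest0, rest1, min_gap = 0.8)
  tt <- seq(-0.25, 0.25, by = 1 / fs)
  for (t0 in swr_t) {
    a <- runif(1, 0.8, 1.2)
    course <- a * (exp(-tt^2 / (2 * 0.030^2)) * prof$sharp_wave(depth) +
                     exp(-(tt - 0.008)^2 / (2 * 0.025^2)) *
                     prof$sharp_wave_dg(depth) +
                     exp(-tt^2 / (2 * spec$ripple_sigma^2)) *
                     cos(2 * pi * spec$ripple_freq * tt) * prof$ripple(depth))
    i0 <- round(t0 * fs) + 1L
    idx <- i0 + seq_along(tt) - ceiling(length(tt) / 2)
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + course[ok]
  }
  cosd <- cos(ph_d)
  dzc <- which(cosd[-n_aw] > 0 & cosd[-1] <= 0)
  rec <- recording(matrix(x, 1L), fs, depth,
                   session_id = sprintf("tetrode-%d", spec$seed),
                   subject_id = sprintf("subj-%d", spec$seed))
  list(rec = rec,
       truth = list(swr = data.frame(t_peak = swr_t),
                    theta_dzc = (dzc - 1L) / fs, depth = depth))
}
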