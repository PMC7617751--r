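#' Canonical gamma bands
#'
#' Slow gamma 20-45 Hz, mid gamma 50-100 Hz, fast gamma 100-250 Hz, plus a
#' beta option (12-20 Hz).
#'
#' @param name one of `"slow"`, `"mid"`, `"fast"`, `"beta"`.
#' @return numeric pair `(lo, hi)` in Hz.
#' @export
gamma_band <- function(name = c("slow", "mid", "fast", "beta")) {
  switch(match.arg(name),
         slow = c(20, 45), mid = c(50, 100), fast = c(100, 250),
         beta = c(12, 20))
}

#' Complex Morlet wavelet amplitude spectrogram
#'
#' Convolves the signal with L1-normalised complex Morlet kernels so that
#' amplitudes are comparable across frequencies (the kernel scale does not
#' leak into the output). Default frequency axis: 24 logarithmically spaced
#' frequencies from 18 to 310 Hz.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param freqs frequency vector (Hz), all below Nyquist.
#' @param n_cycles wavelet width in cycles (default 6).
#' @return list with `amplitude` (samples x frequencies matrix) and `freqs`.
#' @export
morlet_spectrogram <- function(x, fs,
                               freqs = exp(seq(log(18), log(310), length.out = 24)),
                               n_cycles = 6) {
  if (any(freqs >= fs / 2)) stop("frequencies must be below Nyquist")
  n <- length(x)
  amp <- matrix(0, n, length(freqs))
  halfs <- ceiling(4 * n_cycles / (2 * pi * freqs) * fs)
  nfft <- nextn(n + 2L * max(halfs) + 1L, 2)
  X <- fft(c(x, numeric(nfft - n)))
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    sig_t <- n_cycles / (2 * pi * f)
    half <- halfs[j]
    tt <- (-half:half) / fs
    ker <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sig_t^2))
    ker <- ker / sum(Mod(ker))                      # L1 normalisation
    K <- fft(c(ker, complex(real = numeric(nfft - length(ker)))))
    conv <- fft(X * K, inverse = TRUE) / nfft
    amp[, j] <- Mod(conv[(half + 1L):(half + n)])   # centre-aligned
  }
  list(amplitude = amp, freqs = freqs)
}

#' Theta-phase-resolved gamma amplitude profile
#'
#' Averages each spectrogram frequency row within theta-phase bins
#' (invalid-phase samples excluded) and additionally reports the matrix with
#' each frequency row normalised to its own minimum.
#'
#' @param spec spectrogram from [morlet_spectrogram()].
#' @param theta_phase per-sample theta phase in degrees (`NA` = invalid).
#' @param n_phase_bins number of phase bins (default 36, i.e. 10 deg).
#' @return A `theta_gamma_profile`: list with `freqs`, `phase_centers`,
#'   `amplitude` (freqs x bins), `normalized` (row / row-minimum).
#' @export
theta_gamma_profile <- function(spec, theta_phase, n_phase_bins = 36) {
  ok <- !is.na(theta_phase)
  if (!any(ok)) stop("no valid theta phase samples")
  bins <- pmin(floor(theta_phase[ok] / (360 / n_phase_bins)) + 1L, n_phase_bins)
  A <- spec$amplitude[ok, , drop = FALSE]
  prof <- t(rowsum(A, bins) / as.numeric(table(factor(bins, 1:n_phase_bins))))
  centers <- (seq_len(n_phase_bins) - 0.5) * 360 / n_phase_bins
  structure(
    list(freqs = spec$freqs, phase_centers = centers, amplitude = prof,
         normalized = prof / apply(prof, 1L, min)),
    class = "theta_gamma_profile")
}

# Seeded symmetric FastICA (tanh contrast) on a channels x samples matrix;
# returns sources (components x samples) and the unmixing applied to
# whitened data.
fastica_sources <- function(X, n_comp = nrow(X), seed = 1, max_iter = 200,
                            tol = 1e-5, max_fit_samples = 60000L) {
  Xc <- X - rowMeans(X)
  cv <- tcrossprod(Xc) / ncol(Xc)
  eg <- eigen(cv, symmetric = TRUE)
  keep <- which(eg$values > 1e-12 * eg$values[1])[seq_len(min(n_comp, sum(eg$values > 0)))]
  Kw <- diag(1 / sqrt(eg$values[keep]), length(keep)) %*% t(eg$vectors[, keep, drop = FALSE])
  Z <- Kw %*% Xc                                     # whitened
  # the unmixing matrix is estimated on a uniform time subsample, then
  # applied to the full-length whitened data
  Zf <- if (ncol(Z) > max_fit_samples)
    Z[, round(seq(1, ncol(Z), length.out = max_fit_samples)), drop = FALSE]
  else Z
  p <- nrow(Z)
  set.seed(seed)
  W <- matrix(rnorm(p * p), p, p)
  sym_decorr <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorr(W)
  for (it in seq_len(max_iter)) {
    G <- tanh(W %*% Zf)
    gp <- 1 - G^2
    W1 <- sym_decorr(G %*% t(Zf) / ncol(Zf) - diag(rowMeans(gp)) %*% W)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  list(sources = W %*% Z, W = W, whitening = Kw)
}

#' ICA-based isolation of fast gamma
#'
#' Applies independent component analysis to the channels within 200 um of
#' a target channel and returns the component whose Welch spectral peak
#' (evaluated above 25 Hz) lies above 100 Hz, sign-aligned to correlate
#' positively with the target channel's fast-gamma band. Spatial unmixing
#' separates genuine fast gamma from the high-frequency tail of mid gamma.
#'
#' @param rec a `laminar_recording`.
#' @param target_ch target channel index.
#' @param radius_um channel inclusion radius (default 200).
#' @param seed RNG seed for the ICA initialisation.
#' @return list with `component` (series or `NULL`), `peak_freq`,
#'   `channels`, `all_peaks` (per-component spectral peaks).
#' @export
ica_fast_gamma <- function(rec, target_ch, radius_um = 200, seed = 1) {
  sel <- which(abs(rec$depths - rec$depths[target_ch]) <= radius_um)
  if (length(sel) < 3L)
    stop("need at least 3 channels within ", radius_um, " um of the target")
  Xs <- rec$data[sel, , drop = FALSE]
  ica <- fastica_sources(Xs, seed = seed)
  peaks <- apply(ica$sources, 1L, function(s) {
    psd <- welch_psd(s, rec$fs, window_s = min(4, floor(length(s) / rec$fs)))
    hf <- psd$freq >= 5                  # global peak, excluding slow drift
    psd$freq[hf][which.max(psd$psd[hf])]
  })
  # variance each component contributes back to the recorded channels,
  # so noise-floor components cannot masquerade as fast gamma
  WK <- ica$W %*% ica$whitening
  A <- t(WK) %*% solve(tcrossprod(WK))
  tot_var <- sum(apply(Xs, 1L, var))
  share <- vapply(seq_len(nrow(ica$sources)), function(i)
    sum(A[, i]^2) * var(ica$sources[i, ]) / tot_var, 0)
  fast <- which(peaks > 100 & share >= 0.01)
  if (!length(fast))
    return(list(component = NULL, peak_freq = NA_real_, channels = sel,
                all_peaks = peaks))
  pw <- vapply(fast, function(i) {
    s <- ica$sources[i, ]
    psd <- welch_psd(s, rec$fs, window_s = min(4, floor(length(s) / rec$fs)))
    band_power(psd, 100, min(250, rec$fs / 2 - 1))
  }, 0)
  best <- fast[which.max(pw)]
  comp <- ica$sources[best, ]
  ref <- bandpass(rec$data[target_ch, ], 100, min(250, rec$fs / 2 - 1), rec$fs)
  if (cor(comp, ref) < 0) comp <- -comp
  list(component = comp, peak_freq = peaks[best], channels = sel,
       all_peaks = peaks)
}

#' Main frequency of theta-nested gamma bursts
#'
#' Locates the band-envelope maximum within each valid theta cycle, keeps
#' the top quartile of those burst peaks, averages the broadband wavelet
#' spectrogram in a 40-ms window centred on each retained peak, and reports
#' the peak frequency of the resulting mean spectrum (optionally normalised
#' by the spectrogram's overall SD, for cross-subject averaging).
#'
#' @param band_sig a `band_signal` for the gamma band of interest.
#' @param cycles valid `theta_cycles`.
#' @param spec broadband spectrogram from [morlet_spectrogram()].
#' @param fs sampling rate (Hz).
#' @param normalize_sd divide the mean spectrum by the spectrogram SD.
#' @return list with `spectrum`, `freqs`, `peak_freq`, `n_bursts`.
#' @export
burst_main_frequency <- function(band_sig, cycles, spec, fs = 1250,
                                 normalize_sd = TRUE) {
  v <- cycles[cycles$valid, , drop = FALSE]
  env <- band_sig$envelope
  n <- length(env)
  pk_idx <- integer(nrow(v)); pk_amp <- numeric(nrow(v))
  for (r in seq_len(nrow(v))) {
    a <- max(1L, round(v$t_zc_pre[r] * fs) + 1L)
    b <- min(n, round(v$t_zc_post[r] * fs) + 1L)
    j <- a + which.max(env[a:b]) - 1L
    pk_idx[r] <- j; pk_amp[r] <- env[j]
  }
  keep <- pk_amp >= quantile(pk_amp, 0.75)
  pk_idx <- pk_idx[keep]
  if (length(pk_idx) < 8L)
    warning("fewer than 8 retained gamma bursts; spectrum will be noisy")
  half <- round(0.020 * fs)
  acc <- numeric(length(spec$freqs)); cnt <- 0L
  for (j in pk_idx) {
    a <- j - half; b <- j + half
    if (a < 1L || b > nrow(spec$amplitude)) next
    acc <- acc + colMeans(spec$amplitude[a:b, , drop = FALSE])
    cnt <- cnt + 1L
  }
  spectrum <- acc / max(cnt, 1L)
  if (normalize_sd) spectrum <- spectrum / sd(spec$amplitude)
  list(spectrum = spectrum, freqs = spec$freqs,
       peak_freq = spec$freqs[which.max(spectrum)], n_bursts = cnt)
}

#' Speed modulation of per-cycle gamma amplitude
#'
#' Theta cycles are divided into six equally populated speed quantiles; the
#' mean amplitude per quantile is divided by its across-bin mean,
#' log2-transformed, and regressed on bin index. The slope (log2 units per
#' quantile bin) is the modulation index.
#'
#' @param amplitude per-cycle gamma amplitude (>= 60 cycles).
#' @param speed per-cycle running speed (cm/s).
#' @param n_bins number of speed quantiles (default 6).
#' @return list with `slope`, `bin_means`, `normalized` (log2 curve).
#' @export
speed_modulation_index <- function(amplitude, speed, n_bins = 6) {
  if (length(amplitude) != length(speed)) stop("length mismatch")
  if (sd(speed) == 0) stop("constant speed: quantile bins are undefined")
  qs <- quantile(speed, probs = seq(0, 1, length.out = n_bins + 1L))
  bin <- cut(speed, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
  if (length(unique(bin)) < n_bins)
    warning("tied speeds collapsed some quantile bins")
  bm <- tapply(amplitude, bin, mean)
  norm <- log2(bm / mean(bm))
  idx <- as.numeric(names(bm))
  list(slope = unname(coef(lm(norm ~ idx))[2]), bin_means = bm,
       normalized = norm)
}
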