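#' Waveform isolation score
#'
#' Mean over samples of the squared ratio of the mean waveform to the
#' per-sample across-spike standard deviation; quantifies template
#' amplitude relative to spike-to-spike variability. A square-root variant
#' is available.
#'
#' @param mean_w mean spike waveform (numeric, conventionally 32 samples).
#' @param sd_w per-sample SD across spikes (strictly positive).
#' @param sqrt_variant return the square root of the mean of squares.
#' @return scalar score; the multi-unit gate is 0.75.
#' @export
waveform_score <- function(mean_w, sd_w, sqrt_variant = FALSE) {
  if (length(mean_w) != length(sd_w)) stop("length mismatch")
  if (any(sd_w <= 0)) stop("sd_w must be strictly positive at every sample")
  sc <- mean((mean_w / sd_w)^2)
  if (sqrt_variant) sqrt(sc) else sc
}

#' Post-sorting unit quality control
#'
#' A unit fails when its waveform score is below 0.75, when more than 2% of
#' its inter-spike intervals are shorter than 2 ms (refractory violations),
#' or when its template polarity is positive (likely non-somatic).
#'
#' @param spike_times sorted spike times (s), >= 2 spikes.
#' @param mean_w,sd_w template waveform and per-sample SD.
#' @param score_gate,isi_gate,isi_ms gate parameters.
#' @param sqrt_variant passed to [waveform_score()].
#' @return list with `pass` and character vector `reasons` (empty if pass).
#' @export
qc_unit <- function(spike_times, mean_w, sd_w, score_gate = 0.75,
                    isi_gate = 0.02, isi_ms = 2, sqrt_variant = FALSE) {
  if (length(spike_times) < 2L) stop("need at least 2 spikes")
  reasons <- character()
  if (waveform_score(mean_w, sd_w, sqrt_variant) < score_gate)
    reasons <- c(reasons, "waveform_score")
  if (mean(diff(sort(spike_times)) < isi_ms / 1000) > isi_gate)
    reasons <- c(reasons, "refractory_violation")
  if (abs(max(mean_w)) > abs(min(mean_w)))
    reasons <- c(reasons, "positive_polarity")
  list(pass = !length(reasons), reasons = reasons)
}

#' Trough-to-peak latency of a spike template
#'
#' The waveform (sampled at `fs`, conventionally 20 kHz) is upsampled by a
#' factor of 100 with quadratic interpolation; latency is the time from the
#' global trough to the subsequent maximum.
#'
#' @param mean_w template waveform.
#' @param fs waveform sampling rate (Hz).
#' @return latency in ms, or `NA` when no peak follows the trough.
#' @export
trough_to_peak_latency <- function(mean_w, fs = 20000) {
  n <- length(mean_w)
  u <- seq_len(n)
  uu <- seq(1, n, by = 0.01)                # 100x upsampling
  w <- quad_interp(u, mean_w, uu)
  i_tr <- which.min(w)
  if (i_tr >= length(w)) return(NA_real_)
  post <- w[(i_tr + 1L):length(w)]
  i_pk <- i_tr + which.max(post)
  if (w[i_pk] <= w[i_tr] || i_pk <= i_tr) return(NA_real_)
  (uu[i_pk] - uu[i_tr]) / fs * 1000
}

#' Classify a unit as putative pyramidal cell or interneuron
#'
#' Wide templates (trough-to-peak latency above the threshold) are
#' pyramidal cells, narrow ones interneurons. The threshold is either
#' supplied or fitted with [fit_latency_threshold()] on a latency
#' collection.
#'
#' @param mean_w template waveform.
#' @param threshold_ms classification threshold in ms.
#' @param fs waveform sampling rate (Hz).
#' @return `"pyr"`, `"int"`, or `"unclassified"` (no post-trough peak).
#' @export
classify_cell_type <- function(mean_w, threshold_ms, fs = 20000) {
  lat <- trough_to_peak_latency(mean_w, fs)
  if (is.na(lat)) return("unclassified")
  if (lat > threshold_ms) "pyr" else "int"
}

#' Fit the pyramidal/interneuron latency threshold
#'
#' Two-component Gaussian mixture on a collection of trough-to-peak
#' latencies; the threshold is the interior intersection of the component
#' densities.
#'
#' @param latencies numeric vector of latencies (ms).
#' @return threshold in ms.
#' @export
fit_latency_threshold <- function(latencies) {
  gmm1d_threshold(gmm1d(latencies))
}

# 64-bin phase machinery shared by coherence and its surrogate test.
phase_bin64 <- function(phase, n_bins = 64) {
  pmin(floor((phase %% 360) / (360 / n_bins)) + 1L, n_bins)
}

#' Occupancy-normalised spike-phase coherence
#'
#' The 64-bin histogram of spike phases is divided bin-wise by the phase
#' occupancy histogram of all (gated) samples, correcting for the waveform
#' asymmetry of theta (and for any non-uniform phase dwell time), then
#' renormalised to a probability distribution. Coherence is the mean vector
#' length over bin centres weighted by that probability; the circular mean
#' of the same weights is the preferred phase.
#'
#' @param spike_times spike times (s).
#' @param phase per-sample oscillation phase in degrees (`NA` = invalid).
#' @param fs sampling rate of `phase` (Hz).
#' @param gate optional logical sample mask (e.g. gamma envelope above its
#'   75th percentile, or within-ripple samples).
#' @param min_spikes minimum gated spikes for a reliable estimate
#'   (default 250).
#' @param n_bins phase bins (default 64).
#' @return A `coherence_result`: list with `phase_hist` (sums to 1), `mvl`,
#'   `mean_phase` (deg), `n_spikes_used`, `sufficient`.
#' @export
phase_coherence <- function(spike_times, phase, fs, gate = NULL,
                            min_spikes = 250, n_bins = 64) {
  n <- length(phase)
  valid <- !is.na(phase)
  if (!is.null(gate)) valid <- valid & gate
  idx <- round(spike_times * fs) + 1L
  idx <- idx[idx >= 1L & idx <= n]
  idx <- idx[valid[idx]]
  occ <- tabulate(phase_bin64(phase[valid], n_bins), n_bins)
  spk <- tabulate(phase_bin64(phase[idx], n_bins), n_bins)
  p <- ifelse(occ > 0, spk / occ, 0)
  if (sum(p) == 0) p <- rep(1 / n_bins, n_bins) else p <- p / sum(p)
  centers <- ((seq_len(n_bins) - 0.5) * 360 / n_bins) * pi / 180
  vec <- sum(p * exp(1i * centers))
  structure(
    list(phase_hist = p, mvl = Mod(vec),
         mean_phase = (Arg(vec) * 180 / pi) %% 360,
         n_spikes_used = length(idx), sufficient = length(idx) >= min_spikes),
    class = "coherence_result")
}

#' Spike-shift surrogate test for phase coupling
#'
#' Each surrogate reassigns every spike to a random sample whose theta
#' phase (within one 10-degree bin) and gamma amplitude (within one decile)
#' match the spike's own sample, and recomputes the occupancy-normalised
#' coherence. The p-value is the fraction of surrogate coherences that
#' match or exceed the observed one.
#'
#' @param spike_times spike times (s).
#' @param phase coherence phase series (deg; the oscillation being tested).
#' @param theta_phase per-sample theta phase (deg) used for matching.
#' @param gamma_amplitude per-sample gamma amplitude used for matching.
#' @param fs sampling rate (Hz).
#' @param gate optional logical sample mask applied throughout.
#' @param n_surrogates surrogate draws (default 10000).
#' @param seed RNG seed.
#' @param n_bins coherence phase bins (default 64).
#' @return list with `p`, `observed_mvl`, `surrogate_mvl`, `n_spikes`.
#' @export
spike_shift_surrogate_test <- function(spike_times, phase, theta_phase,
                                       gamma_amplitude, fs, gate = NULL,
                                       n_surrogates = 10000, seed = 1,
                                       n_bins = 64) {
  n <- length(phase)
  valid <- !is.na(phase) & !is.na(theta_phase) & !is.na(gamma_amplitude)
  if (!is.null(gate)) valid <- valid & gate
  vsamp <- which(valid)
  idx <- round(spike_times * fs) + 1L
  idx <- idx[idx >= 1L & idx <= n]
  idx <- idx[valid[idx]]
  if (length(vsamp) < 10L * length(idx))
    warning("matching pool smaller than 10x spike count; surrogates may repeat")

  # matching grid: 36 theta-phase bins (10 deg) x amplitude deciles
  tp_bin <- phase_bin64(theta_phase[vsamp], 36)
  dec_br <- unique(quantile(gamma_amplitude[vsamp], probs = seq(0, 1, 0.1)))
  am_bin <- cut(gamma_amplitude[vsamp], breaks = dec_br, include.lowest = TRUE,
                labels = FALSE)
  n_dec <- length(dec_br) - 1L
  cell_of <- function(tp, am) (am - 1L) * 36L + tp
  pools <- split(seq_along(vsamp), cell_of(tp_bin, am_bin))

  # per-sample weight (1/occupancy of its coherence-phase bin) and unit vector
  cb <- phase_bin64(phase[vsamp], n_bins)
  occ <- tabulate(cb, n_bins)
  wgt <- 1 / occ[cb]
  centers <- ((seq_len(n_bins) - 0.5) * 360 / n_bins) * pi / 180
  zvec <- exp(1i * centers)[cb]
  stat <- function(sel) {
    v <- sum(wgt[sel] * zvec[sel]) / sum(wgt[sel])
    Mod(v)
  }

  spk_local <- match(idx, vsamp)
  obs <- stat(spk_local)

  # candidate pool per spike: same cell +/- 1 phase bin and +/- 1 decile
  spike_pool <- lapply(spk_local, function(s) {
    tp <- tp_bin[s]; am <- am_bin[s]
    tps <- ((tp - 2L):(tp)) %% 36L + 1L      # tp-1, tp, tp+1 circular
    ams <- max(1L, am - 1L):min(n_dec, am + 1L)
    cells <- as.character(outer(tps, ams, cell_of))
    unlist(pools[cells], use.names = FALSE)
  })
  empty <- lengths(spike_pool) == 0L
  if (any(empty)) {
    warning("empty matching pool for ", sum(empty),
            " spikes; widened to the full valid set")
    spike_pool[empty] <- list(seq_along(vsamp))
  }

  set.seed(seed)
  M <- vapply(spike_pool, function(p)
    if (length(p) == 1L) rep.int(p, n_surrogates)
    else sample(p, n_surrogates, replace = TRUE),
    integer(n_surrogates))
  if (is.null(dim(M))) M <- matrix(M, nrow = n_surrogates)
  W <- matrix(wgt[M], nrow = n_surrogates)
  Zr <- matrix(Re(zvec)[M], nrow = n_surrogates)
  Zi <- matrix(Im(zvec)[M], nrow = n_surrogates)
  sw <- rowSums(W)
  surr <- sqrt(rowSums(W * Zr)^2 + rowSums(W * Zi)^2) / sw
  list(p = mean(surr >= obs), observed_mvl = obs, surrogate_mvl = surr,
       n_spikes = length(spk_local))
}

#' Oscillation-trough-triggered firing rate
#'
#' One trigger per theta cycle (or per ripple event): the deepest trough of
#' the band-filtered signal within the cycle/event, keeping only the top
#' quartile by trough depth. Spike trains are binned at 2 ms over +/-100 ms
#' around the retained troughs and averaged to a rate trace.
#'
#' @param spike_times spike times (s).
#' @param band_sig `band_signal` of the oscillation.
#' @param intervals two-column matrix or data.frame of interval start/end
#'   times (s): valid theta cycles (`t_zc_pre`,`t_zc_post`) or ripple events
#'   (`t_onset`,`t_offset`).
#' @param fs sampling rate (Hz).
#' @param window half-window (s, default 0.1).
#' @param bin_s bin width (s, default 0.002).
#' @param zscore z-score the trace against its own mean/SD.
#' @return list with `time` (s), `rate` (Hz), `n_triggers`.
#' @export
trough_triggered_rates <- function(spike_times, band_sig, intervals,
                                   fs = 1250, window = 0.1, bin_s = 0.002,
                                   zscore = FALSE) {
  iv <- as.matrix(intervals[, 1:2])
  x <- band_sig$values
  n <- length(x)
  tr_t <- numeric(nrow(iv)); tr_d <- numeric(nrow(iv))
  for (r in seq_len(nrow(iv))) {
    a <- max(1L, round(iv[r, 1] * fs) + 1L)
    b <- min(n, round(iv[r, 2] * fs) + 1L)
    j <- a + which.min(x[a:b]) - 1L
    tr_t[r] <- (j - 1L) / fs
    tr_d[r] <- -x[j]
  }
  keep <- tr_d >= quantile(tr_d, 0.75)
  tr_t <- tr_t[keep]
  if (!length(tr_t)) stop("no retained troughs")
  if (length(tr_t) < 20L)
    warning("fewer than 20 retained troughs; rate trace will be noisy")
  edges <- seq(-window, window, by = bin_s)
  counts <- numeric(length(edges) - 1L)
  for (t0 in tr_t) {
    rel <- spike_times - t0
    rel <- rel[rel >= -window & rel < window]
    counts <- counts + tabulate(floor((rel + window) / bin_s) + 1L,
                                length(counts))
  }
  rate <- counts / (length(tr_t) * bin_s)
  if (zscore) rate <- (rate - mean(rate)) / max(sd(rate), 1e-12)
  list(time = edges[-length(edges)] + bin_s / 2, rate = rate,
       n_triggers = length(tr_t))
}
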