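#' Ripple-band score of a channel
#'
#' Ratio of Welch power in the ripple band (100-250 Hz) to power in a
#' surrounding band (70-300 Hz), estimated with 4-second Hann windows at 50%
#' overlap. Used to pick the CA1 pyramidal-layer reference channel.
#'
#' @param x channel voltage series (>= 8 s).
#' @param fs sampling rate (Hz).
#' @return dimensionless score in (0, 1].
#' @export
ripple_band_score <- function(x, fs) {
  if (length(x) < 8 * fs)
    stop("ripple_band_score needs at least 8 s of signal")
  psd <- welch_psd(x, fs, window_s = 4, overlap = 0.5)
  band_power(psd, 100, 250) / band_power(psd, 70, 300)
}

#' Select the pyramidal-layer reference channel
#'
#' Returns the channel with the highest ripple-band score; ties break toward
#' the lower (more dorsal) index.
#'
#' @param rec a `laminar_recording`.
#' @return integer channel index (1-based).
#' @export
select_reference_channel <- function(rec) {
  scores <- apply(rec$data, 1L, ripple_band_score, fs = rec$fs)
  which.max(scores)   # which.max takes the first maximum: low-index tie-break
}

#' Cycle count from unwrapped phase span
#'
#' @param phase_onset,phase_offset unwrapped phase (degrees) at event onset
#'   and offset; `phase_offset >= phase_onset`.
#' @return number of cycles, `(phase_offset - phase_onset) / 360`.
#' @export
count_cycles <- function(phase_onset, phase_offset) {
  if (any(phase_offset < phase_onset))
    stop("negative phase span: offset phase is before onset phase")
  (phase_offset - phase_onset) / 360
}

#' Mean intra-event oscillation frequency
#'
#' @param n_cycles number of cycles within the event.
#' @param duration event duration in seconds (> 0).
#' @return frequency in Hz, `n_cycles / duration`.
#' @export
event_mean_frequency <- function(n_cycles, duration) {
  if (any(duration <= 0)) stop("duration must be positive")
  n_cycles / duration
}

# Strict local maxima indices of a numeric vector.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
}

# Greedy peak dedup: keep highest, drop any other peak within `win` samples.
dedup_peaks <- function(idx, height, win) {
  if (length(idx) <= 1L) return(idx)
  ord <- order(height, decreasing = TRUE)
  kept <- integer()
  for (i in ord) {
    if (!length(kept) || all(abs(idx[i] - idx[kept]) > win))
      kept <- c(kept, i)
  }
  sort(idx[kept])
}

#' Detect sharp-wave ripple events
#'
#' Detection pipeline on the (optionally referenced) pyramidal channel:
#' band-pass 80-250 Hz plus a 200-500 Hz control band (4th-order
#' Butterworth, zero phase); candidate events at envelope peaks above five
#' times the overall envelope median, with a 20-ms peak merge keeping the
#' highest peak; onset/offset where the envelope drops below half the
#' detection threshold. Each candidate must then pass four checks:
#' ripple power on the detection channel at least twice that on the
#' reference channel (skipped without a reference), mean intra-event
#' frequency above 100 Hz, at least four complete ripple cycles, and
#' ripple-band power at least twice the control-band power.
#'
#' @param rec a `laminar_recording`.
#' @param detect_ch detection channel index (1-based).
#' @param ref_ch reference channel index, or `NULL` for tetrode-style
#'   recordings where no referencing is applied.
#' @return data.frame of class `swr_events` with columns `t_peak`, `t_onset`,
#'   `t_offset`, `n_cycles`, `mean_freq`, `peak_env`, `channel`. Empty (zero
#'   rows) when nothing crosses threshold.
#' @export
detect_swr <- function(rec, detect_ch, ref_ch = NULL) {
  fs <- rec$fs
  if (!is.null(ref_ch) && ref_ch == detect_ch)
    stop("detection and reference channel must differ")
  x <- rec$data[detect_ch, ]
  d <- if (is.null(ref_ch)) x else x - rec$data[ref_ch, ]

  rip <- bandpass(d, 80, 250, fs)
  ctl <- bandpass(d, 200, 500, fs)
  bs <- envelope_phase(rip, band = c(80, 250), source_channel = detect_ch)
  env <- bs$envelope
  env_ctl <- Mod(analytic_signal(ctl))

  thr <- 5 * median(env)
  pk <- local_maxima(env)
  pk <- pk[env[pk] > thr]
  empty <- data.frame(t_peak = numeric(), t_onset = numeric(),
                      t_offset = numeric(), n_cycles = numeric(),
                      mean_freq = numeric(), peak_env = numeric(),
                      channel = integer())
  class(empty) <- c("swr_events", "data.frame")
  if (!length(pk)) return(empty)
  pk <- dedup_peaks(pk, env[pk], win = round(0.020 * fs))

  # per-channel ripple envelopes for the 2x reference-power check
  env_det_ch <- NULL; env_ref_ch <- NULL
  if (!is.null(ref_ch)) {
    env_det_ch <- Mod(analytic_signal(bandpass(x, 80, 250, fs)))
    env_ref_ch <- Mod(analytic_signal(bandpass(rec$data[ref_ch, ], 80, 250, fs)))
  }

  half <- thr / 2
  n <- length(env)
  below <- env < half
  rows <- lapply(pk, function(p) {
    on <- p
    while (on > 1L && !below[on - 1L]) on <- on - 1L
    off <- p
    while (off < n && !below[off + 1L]) off <- off + 1L
    span <- on:off
    ncyc <- count_cycles(bs$phase_unwrapped[on], bs$phase_unwrapped[off])
    dur <- (off - on) / fs
    mf <- if (dur > 0) event_mean_frequency(ncyc, dur) else 0
    # check 1: detection-channel ripple power >= 2x reference-channel power
    if (!is.null(ref_ch)) {
      if (mean(env_det_ch[span])^2 < 2 * mean(env_ref_ch[span])^2) return(NULL)
    }
    if (mf <= 100) return(NULL)                       # check 2
    if (ncyc < 4) return(NULL)                        # check 3
    if (mean(env[span])^2 < 2 * mean(env_ctl[span])^2) return(NULL)  # check 4
    data.frame(t_peak = (p - 1L) / fs, t_onset = (on - 1L) / fs,
               t_offset = (off - 1L) / fs, n_cycles = ncyc, mean_freq = mf,
               peak_env = env[p], channel = detect_ch)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  class(out) <- c("swr_events", "data.frame")
  out
}

#' Detect dentate spikes
#'
#' Per dentate-gyrus channel: subtract the top-of-probe reference, filter
#' 1-200 Hz (4th-order Butterworth, zero phase), take positive peaks above
#' seven times the median absolute value, and discard artifact peaks above
#' the 75th percentile of the peak distribution plus 20 times its
#' interquartile range. Candidates from all channels are pooled and
#' deduplicated within 50-ms windows, keeping the highest peak.
#'
#' Callers should restrict the recording to sleep/rest epochs beforehand.
#'
#' @param rec a `laminar_recording`.
#' @param dg_channels integer vector of dentate-gyrus channel indices.
#' @param top_ref index of the reference channel at the top of the probe.
#' @return data.frame of class `ds_events` with columns `t_peak`, `channel`,
#'   `peak_amp`, `ds_class` (initially `"unclassified"`).
#' @export
detect_dentate_spikes <- function(rec, dg_channels, top_ref) {
  if (!length(dg_channels)) stop("`dg_channels` is empty")
  fs <- rec$fs
  all_idx <- integer(); all_amp <- numeric(); all_ch <- integer()
  for (ch in dg_channels) {
    d <- rec$data[ch, ] - rec$data[top_ref, ]
    f <- bandpass_low(d, 1, 200, fs)
    thr <- 7 * median(abs(f))
    pk <- local_maxima(f)
    pk <- pk[f[pk] > thr]
    if (!length(pk)) next
    amps <- f[pk]
    art <- quantile(amps, 0.75) + 20 * (quantile(amps, 0.75) - quantile(amps, 0.25))
    keep <- amps <= art
    all_idx <- c(all_idx, pk[keep])
    all_amp <- c(all_amp, amps[keep])
    all_ch <- c(all_ch, rep.int(ch, sum(keep)))
  }
  if (!length(all_idx)) {
    out <- data.frame(t_peak = numeric(), channel = integer(),
                      peak_amp = numeric(), ds_class = character())
    class(out) <- c("ds_events", "data.frame")
    return(out)
  }
  ord <- order(all_amp, decreasing = TRUE)
  win <- round(0.050 * fs)
  kept <- integer()
  for (i in ord)
    if (!length(kept) || all(abs(all_idx[i] - all_idx[kept]) > win))
      kept <- c(kept, i)
  kept <- kept[order(all_idx[kept])]
  out <- data.frame(t_peak = (all_idx[kept] - 1L) / fs,
                    channel = all_ch[kept], peak_amp = all_amp[kept],
                    ds_class = "unclassified")
  class(out) <- c("ds_events", "data.frame")
  out
}

# Band-pass that tolerates a very low lower edge (1 Hz at 1250 Hz): uses a
# 4th-order Butterworth band-pass; falls back to low-pass + high-pass in
# cascade for numerical stability of filtfilt at extreme band ratios.
bandpass_low <- function(x, lo, hi, fs, order = 4) {
  lp <- signal::butter(order, hi / (fs / 2), type = "low")
  hp <- signal::butter(order, lo / (fs / 2), type = "high")
  filtfilt_pad(hp, filtfilt_pad(lp, x))
}
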