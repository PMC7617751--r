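#' Anti-aliased decimation of a wide-band trace
#'
#' Applies an 8th-order Chebyshev type I low-pass (zero-phase) before
#' subsampling, the standard decimation contract for LFP preprocessing
#' (wide-band acquisition, e.g. 20 kHz, down to an analysis rate of 1250 Hz).
#'
#' @param x numeric vector sampled at `fs_raw`.
#' @param fs_raw input sampling rate (Hz).
#' @param target_fs output sampling rate (Hz); `fs_raw` must be an integer
#'   multiple.
#' @return numeric vector of length `ceiling(length(x) / factor)`.
#' @export
decimate_lfp <- function(x, fs_raw, target_fs) {
  factor <- fs_raw / target_fs
  if (abs(factor - round(factor)) > 1e-9)
    stop(sprintf("decimation factor %g Hz / %g Hz is not an integer",
                 fs_raw, target_fs))
  factor <- as.integer(round(factor))
  if (factor == 1L) return(x)
  bf <- signal::cheby1(8, 0.05, 0.8 / factor)
  y <- filtfilt_pad(bf, x)
  y[seq(1, length(x), by = factor)]
}

# Zero-phase filtering with odd-reflection end padding, so constants and
# near-edge samples pass without boundary transients.
filtfilt_pad <- function(bf, x) {
  n <- length(x)
  padlen <- min(n - 1L, 300L)
  pre <- 2 * x[1] - x[(padlen + 1L):2]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  y <- c(pre, x, post)
  y <- signal::filter(bf, y)
  y <- rev(signal::filter(bf, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth by default, applied forward and backward
#' (`filtfilt`) so phases and latencies are preserved.
#'
#' @param x numeric vector.
#' @param lo,hi band edges in Hz, `0 < lo < hi < fs/2`.
#' @param fs sampling rate (Hz).
#' @param order filter order (default 4).
#' @return filtered numeric vector, same length as `x`.
#' @export
bandpass <- function(x, lo, hi, fs, order = 4) {
  if (hi >= fs / 2)
    stop(sprintf("upper band edge %g Hz must be below Nyquist (%g Hz)",
                 hi, fs / 2))
  if (lo <= 0 || lo >= hi) stop("need 0 < lo < hi")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  filtfilt_pad(bf, x)
}

# Analytic signal via FFT (positive-frequency doubling).
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous envelope and phase of a band-limited trace
#'
#' Computes the analytic signal by the Hilbert transform. Phase convention,
#' fixed package-wide: 0 deg at oscillation peaks, 90 deg at the descending
#' zero-crossing, 180 deg at troughs, 270 deg ascending.
#'
#' @param x band-limited numeric vector (>= 4 samples).
#' @param band optional numeric pair `(lo, hi)` Hz recorded as metadata.
#' @param source_channel optional channel index recorded as metadata.
#' @return A `band_signal`: list with `values`, `envelope` (>= 0), `phase`
#'   (degrees in `[0, 360)`), `phase_unwrapped` (degrees, nondecreasing trend),
#'   `band`, `source_channel`.
#' @export
envelope_phase <- function(x, band = NULL, source_channel = NULL) {
  if (length(x) < 4L) stop("need at least 4 samples for the analytic signal")
  a <- analytic_signal(x)
  ph <- Arg(a) * 180 / pi          # 0 at peak for a cosine-like oscillation
  structure(
    list(values = as.numeric(x), envelope = Mod(a), phase = ph %% 360,
         phase_unwrapped = unwrap_deg(ph), band = band,
         source_channel = source_channel),
    class = "band_signal")
}

# Unwrap a phase sequence given in degrees.
unwrap_deg <- function(p) {
  d <- diff(p)
  d <- d - 360 * round(d / 360)
  cumsum(c(p[1], d))
}

#' Event-triggered average
#'
#' Averages signal segments aligned to trigger times. Triggers whose window
#' falls outside the recording are dropped (not padded) and counted in
#' `n_dropped`.
#'
#' @param x numeric vector, matrix (channels x samples), or
#'   `laminar_recording`.
#' @param triggers trigger times in seconds.
#' @param window numeric pair `c(pre, post)` in seconds (both positive;
#'   the window spans `t - pre` to `t + post`).
#' @param fs sampling rate (Hz); taken from `x` when it is a recording.
#' @param trigger_kind optional label, e.g. `"ripple_peak"`.
#' @return A `triggered_average`: list with `values` (channels x samples
#'   matrix; one row for vector input), `time` (seconds relative to trigger),
#'   `window`, `n_events`, `n_dropped`, `trigger_kind`.
#' @export
triggered_average <- function(x, triggers, window, fs = NULL,
                              trigger_kind = NULL) {
  if (inherits(x, "laminar_recording")) {
    fs <- x$fs
    mat <- x$data
  } else if (is.matrix(x)) {
    mat <- x
  } else {
    mat <- matrix(as.numeric(x), nrow = 1L)
  }
  if (is.null(fs)) stop("`fs` required for plain numeric input")
  pre <- round(window[1] * fs)
  post <- round(window[2] * fs)
  n <- ncol(mat)
  centers <- round(triggers * fs) + 1L
  ok <- centers - pre >= 1L & centers + post <= n
  if (!any(ok)) stop("no usable triggers inside the recording")
  centers <- centers[ok]
  offs <- (-pre):post
  acc <- matrix(0, nrow(mat), length(offs))
  for (c0 in centers) acc <- acc + mat[, c0 + offs, drop = FALSE]
  structure(
    list(values = acc / length(centers), time = offs / fs,
         window = c(pre = window[1], post = window[2]),
         n_events = length(centers), n_dropped = sum(!ok),
         trigger_kind = trigger_kind),
    class = "triggered_average")
}

#' Welch power spectral density estimate
#'
#' Hann-windowed averaged periodogram (default 4-s segments, 50% overlap),
#' the estimator used for ripple-band scores and layer power profiles.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param window_s segment length in seconds.
#' @param overlap fractional overlap between segments.
#' @return list with `freq` (Hz) and `psd` (power density, x-units^2/Hz).
#' @export
welch_psd <- function(x, fs, window_s = 4, overlap = 0.5) {
  nper <- round(window_s * fs)
  if (length(x) < nper)
    stop(sprintf("signal too short for Welch estimate: %d samples < one %g-s window",
                 length(x), window_s))
  step <- max(1L, round(nper * (1 - overlap)))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  u <- sum(w^2)
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  nf <- nper %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(fft(seg))^2
    acc <- acc + P[seq_len(nf)]
  }
  psd <- acc / (length(starts) * u * fs)
  # one-sided: double everything except DC (and Nyquist for even nper)
  inner <- 2:(nf - if (nper %% 2 == 0) 1L else 0L)
  psd[inner] <- 2 * psd[inner]
  list(freq = (seq_len(nf) - 1L) * fs / nper, psd = psd)
}

# Integrated band power from a Welch estimate.
band_power <- function(psd, lo, hi) {
  sel <- psd$freq >= lo & psd$freq <= hi
  df <- psd$freq[2] - psd$freq[1]
  sum(psd$psd[sel]) * df
}
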