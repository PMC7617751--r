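#' Masked empirical mode decomposition
#'
#' Decomposes an LFP trace into six intrinsic mode functions (IMFs) and a
#' residue using the mask-sift procedure: for each mask frequency, sinusoidal
#' masks at four phases are added to the running residual, the first IMF of
#' each masked signal is extracted by sifting, the mask subtracted, and the
#' four estimates averaged. Mask frequencies default to 350, 200, 70, 40, 30
#' and 7 Hz with mask amplitude three times the standard deviation of the
#' input; with these parameters IMF-6 isolates theta (5-12 Hz).
#'
#' The decomposition is complete by construction: the IMFs plus the residue
#' sum to the input exactly.
#'
#' @param x LFP series at `fs` (>= 2 s of samples).
#' @param fs sampling rate (Hz), nominally 1250.
#' @param mask_freqs mask frequencies in Hz, high to low.
#' @param mask_amp_sd mask amplitude as a multiple of `sd(x)`.
#' @param max_sift maximum sifting iterations per mask phase.
#' @return An `imf_set`: list with `imfs` (samples x 6 matrix), `residue`,
#'   `mask_freqs`, `mask_amp_sd`, `fs`. The theta component is `imfs[, 6]`.
#' @export
masked_emd <- function(x, fs = 1250,
                       mask_freqs = c(350, 200, 70, 40, 30, 7),
                       mask_amp_sd = 3, max_sift = 8) {
  n <- length(x)
  if (n < 2 * fs) stop("masked_emd needs at least 2 s of signal")
  s <- sd(x)
  imfs <- matrix(0, n, length(mask_freqs))
  colnames(imfs) <- paste0("imf", seq_along(mask_freqs))
  if (s == 0) {
    out <- list(imfs = imfs, residue = x, mask_freqs = mask_freqs,
                mask_amp_sd = mask_amp_sd, fs = fs)
    class(out) <- "imf_set"
    return(out)
  }
  amp <- mask_amp_sd * s
  tt <- (seq_len(n) - 1) / fs
  resid <- as.numeric(x)
  phases <- (0:3) * pi / 2
  for (k in seq_along(mask_freqs)) {
    acc <- numeric(n)
    for (ph in phases) {
      mask <- amp * cos(2 * pi * mask_freqs[k] * tt + ph)
      acc <- acc + sift_first_imf(resid + mask, max_sift) - mask
    }
    imfs[, k] <- acc / 4
    resid <- resid - imfs[, k]
  }
  out <- list(imfs = imfs, residue = resid, mask_freqs = mask_freqs,
              mask_amp_sd = mask_amp_sd, fs = fs)
  class(out) <- "imf_set"
  out
}

local_minima <- function(x) local_maxima(-x)

# Cubic-spline envelope through extrema, endpoints clamped to the nearest
# extremum value.
envelope_through <- function(idx, x) {
  n <- length(x)
  v <- x[idx]
  if (idx[1] != 1L) { idx <- c(1L, idx); v <- c(v[1], v) }
  if (idx[length(idx)] != n) { idx <- c(idx, n); v <- c(v, v[length(v)]) }
  spline(idx, v, xout = seq_len(n), method = "natural")$y
}

# Extract the first IMF of z by sifting: subtract the mean of the upper and
# lower spline envelopes until the residual mean-envelope energy is small.
sift_first_imf <- function(z, max_iter = 8, tol = 0.05) {
  h <- z
  for (i in seq_len(max_iter)) {
    mx <- local_maxima(h)
    mn <- local_minima(h)
    if (length(mx) < 2L || length(mn) < 2L) break
    m <- (envelope_through(mx, h) + envelope_through(mn, h)) / 2
    h <- h - m
    if (sum(m^2) < tol * sum(h^2)) break
  }
  h
}

#' Delineate theta cycles from the theta IMF
#'
#' Local extrema of the theta IMF are retained when their magnitude exceeds
#' the envelope of the decomposition residue at that time (low-amplitude
#' gate). Each retained peak-trough-peak triplet is a candidate cycle,
#' validated by requiring half-cycle (peak-trough and trough-peak) intervals
#' of 31-100 ms and a peak-to-peak interval of 71-200 ms. Each cycle carries
#' five control points: the (ascending) zero-crossing before the peak, the
#' peak, the descending zero-crossing, the trough, and the zero-crossing
#' after the trough.
#'
#' @param theta_imf theta component from [masked_emd()].
#' @param residue decomposition residue (same length).
#' @param fs sampling rate (Hz).
#' @return data.frame of class `theta_cycles` with columns `t_zc_pre`,
#'   `t_peak`, `t_zc_desc`, `t_trough`, `t_zc_post` (seconds) and `valid`.
#' @export
delineate_cycles <- function(theta_imf, residue, fs = 1250) {
  n <- length(theta_imf)
  gate <- Mod(analytic_signal(residue))
  pk <- local_maxima(theta_imf)
  tr <- local_minima(theta_imf)
  pk <- pk[abs(theta_imf[pk]) > gate[pk]]
  tr <- tr[abs(theta_imf[tr]) > gate[tr]]
  ext <- rbind(data.frame(i = pk, type = 1L), data.frame(i = tr, type = -1L))
  ext <- ext[order(ext$i), ]
  empty <- data.frame(t_zc_pre = numeric(), t_peak = numeric(),
                      t_zc_desc = numeric(), t_trough = numeric(),
                      t_zc_post = numeric(), valid = logical())
  class(empty) <- c("theta_cycles", "data.frame")
  if (nrow(ext) < 3L) return(empty)

  zc_between <- function(a, b) {
    # sub-sample zero-crossing of theta_imf between samples a and b
    seg <- theta_imf[a:b]
    sc <- which(seg[-length(seg)] * seg[-1] <= 0 & seg[-length(seg)] != 0)
    if (!length(sc)) return(NA_real_)
    j <- a + sc[1] - 1L
    frac <- theta_imf[j] / (theta_imf[j] - theta_imf[j + 1L])
    (j - 1L + frac) / fs
  }

  rows <- list()
  for (e in seq_len(nrow(ext) - 2L)) {
    if (!(ext$type[e] == 1L && ext$type[e + 1L] == -1L && ext$type[e + 2L] == 1L))
      next
    p1 <- ext$i[e]; t0 <- ext$i[e + 1L]; p2 <- ext$i[e + 2L]
    ht1 <- (t0 - p1) / fs; ht2 <- (p2 - t0) / fs; pp <- (p2 - p1) / fs
    valid <- ht1 >= 0.031 && ht1 <= 0.100 && ht2 >= 0.031 && ht2 <= 0.100 &&
      pp >= 0.071 && pp <= 0.200
    a <- max(1L, if (e > 1L) ext$i[e - 1L] else 1L)
    zc_pre <- zc_between(a, p1)
    zc_desc <- zc_between(p1, t0)
    zc_post <- zc_between(t0, p2)
    if (anyNA(c(zc_pre, zc_desc, zc_post))) valid <- FALSE
    rows[[length(rows) + 1L]] <-
      data.frame(t_zc_pre = zc_pre, t_peak = (p1 - 1L) / fs,
                 t_zc_desc = zc_desc, t_trough = (t0 - 1L) / fs,
                 t_zc_post = zc_post, valid = valid)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  class(out) <- c("theta_cycles", "data.frame")
  out
}

#' Continuous interpolated theta phase
#'
#' Linear interpolation of phase between cycle control points, with the
#' package phase convention: peak = 0 deg, descending zero-crossing = 90,
#' trough = 180, ascending zero-crossing = 270; the zero-crossing preceding
#' the peak carries the previous cycle's 270 (i.e. -90). Samples outside
#' valid cycles are `NA`.
#'
#' @param cycles a `theta_cycles` data.frame from [delineate_cycles()].
#' @param n_samples length of the output phase series.
#' @param fs sampling rate (Hz).
#' @return numeric vector of phases in degrees `[0, 360)`, `NA` where no
#'   valid cycle covers the sample.
#' @export
interpolated_phase <- function(cycles, n_samples, fs = 1250) {
  v <- cycles[cycles$valid, , drop = FALSE]
  if (!nrow(v)) stop("no valid theta cycles")
  phase <- rep(NA_real_, n_samples)
  t_all <- (seq_len(n_samples) - 1L) / fs
  key_phase <- c(-90, 0, 90, 180, 270)
  for (r in seq_len(nrow(v))) {
    kt <- as.numeric(v[r, c("t_zc_pre", "t_peak", "t_zc_desc",
                            "t_trough", "t_zc_post")])
    sel <- which(t_all >= kt[1] & t_all <= kt[5])
    if (!length(sel)) next
    phase[sel] <- approx(kt, key_phase, xout = t_all[sel], ties = "ordered")$y
  }
  phase %% 360
}
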