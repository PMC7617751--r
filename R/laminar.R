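#' Current source density of a laminar LFP profile
#'
#' Second spatial difference across equally spaced channels,
#' `CSD[n] = -(LFP[n-1] - 2 LFP[n] + LFP[n+1])`, so current sinks are
#' negative. Edge channels are dropped. To standardise spatial resolution
#' across probes, the profile is then smoothed along depth with a Gaussian
#' kernel (default sd 50 um, truncated at 4 sd).
#'
#' @param profile channels x samples LFP matrix (or a column vector).
#' @param spacing inter-channel spacing in micrometers.
#' @param smoothing_sd Gaussian smoothing sd in micrometers; 0 disables.
#' @return A `csd_profile`: list with `values` ((channels-2) x samples
#'   matrix), `channels` (source row indices retained), `spacing`,
#'   `smoothing_sd`.
#' @export
csd <- function(profile, spacing = 50, smoothing_sd = 50) {
  profile <- as.matrix(profile)
  nch <- nrow(profile)
  if (nch < 3L) stop("CSD needs at least 3 channels")
  v <- -(profile[1:(nch - 2L), , drop = FALSE] -
           2 * profile[2:(nch - 1L), , drop = FALSE] +
           profile[3:nch, , drop = FALSE])
  if (smoothing_sd > 0 && nrow(v) > 1L) {
    sig <- smoothing_sd / spacing
    half <- max(1L, floor(4 * sig))
    k <- dnorm(-half:half, sd = sig)
    sm <- v
    for (j in seq_len(nrow(v))) {
      lo <- max(1L, j - half); hi <- min(nrow(v), j + half)
      w <- k[(lo - j + half + 1L):(hi - j + half + 1L)]
      sm[j, ] <- crossprod(w / sum(w), v[lo:hi, , drop = FALSE])
    }
    v <- sm
  }
  structure(list(values = v, channels = 2:(nch - 1L), spacing = spacing,
                 smoothing_sd = smoothing_sd),
            class = "csd_profile")
}

# Per-event laminar CSD vectors at event peak samples.
event_csd_vectors <- function(rec, t_peaks, ch_from, ch_to) {
  idx <- round(t_peaks * rec$fs) + 1L
  idx <- pmin(pmax(idx, 1L), ncol(rec$data))
  spacing <- rec_spacing(rec)
  sapply(idx, function(i) {
    csd(rec$data[ch_from:ch_to, i, drop = FALSE], spacing = spacing)$values[, 1]
  })  # (channels-2) x events
}

#' Classify dentate spikes into DS1 and DS2
#'
#' Computes each event's laminar CSD vector (pyramidal channel to the
#' deepest dentate-gyrus channel, at the event peak), projects the vectors
#' onto their first principal component, and splits the projections with a
#' two-component Gaussian mixture. The class whose mean CSD has its primary
#' sink (minimum) on the shallower channel -- further from the hilus -- is
#' DS1. If both class sinks coincide, every event is labelled DS1 (no
#' granular-layer channel in the recording).
#'
#' @param events a `ds_events` data.frame from [detect_dentate_spikes()].
#' @param rec a `laminar_recording`.
#' @param pyr_ch pyramidal-layer channel index.
#' @param dg_deep deepest dentate-gyrus channel index.
#' @return `events` with `ds_class` filled in (`"DS1"`/`"DS2"`, or
#'   `"unclassified"` for fewer than two events).
#' @export
classify_ds <- function(events, rec, pyr_ch, dg_deep) {
  if (nrow(events) < 2L) {
    events$ds_class <- rep("unclassified", nrow(events))
    return(events)
  }
  V <- t(event_csd_vectors(rec, events$t_peak, pyr_ch, dg_deep))  # events x ch
  pc1 <- prcomp(V, center = TRUE, scale. = FALSE)$x[, 1]
  fit <- gmm1d(pc1)
  lab <- gmm1d_classify(fit, pc1)
  sink1 <- which.min(colMeans(V[lab == 1L, , drop = FALSE]))
  sink2 <- which.min(colMeans(V[lab == 2L, , drop = FALSE]))
  if (sink1 == sink2) {
    events$ds_class <- "DS1"
  } else {
    ds1_lab <- if (sink1 < sink2) 1L else 2L   # shallower sink = DS1
    events$ds_class <- ifelse(lab == ds1_lab, "DS1", "DS2")
  }
  events
}

#' Landmark anatomical layers from electrophysiological signatures
#'
#' Maps layers to channels using established laminar signatures: `pyr` has
#' the highest ripple-band power; `rad` the strongest current sink at the
#' ripple-envelope peak; `hf` (hippocampal fissure) the highest theta power;
#' `l-m` sits 40-50 um above the fissure; `omol` and `mmol` are the deepest
#' DS1 and DS2 current sinks; `imol` carries the secondary sharp-wave sink
#' below the fissure; `gr` the strongest dentate-spike current source
#' beneath the molecular layers. Landmarks whose event sets are missing are
#' omitted; a landmark violating the dorsoventral ordering is dropped with a
#' warning.
#'
#' @param rec a `laminar_recording`.
#' @param swr_events `swr_events` data.frame (or `NULL`).
#' @param ds_events classified `ds_events` data.frame (or `NULL`).
#' @param theta_cycles optional `theta_cycles` (not required; theta power is
#'   estimated spectrally).
#' @return named integer vector of channel indices (class `layer_map`),
#'   subset of `c("pyr","rad","l-m","hf","omol","mmol","imol","gr")`.
#' @export
landmark_layers <- function(rec, swr_events = NULL, ds_events = NULL,
                            theta_cycles = NULL) {
  fs <- rec$fs
  nch <- n_channels(rec)
  spacing <- rec_spacing(rec)
  psds <- apply(rec$data, 1L, welch_psd, fs = fs, simplify = FALSE)
  rip_pow <- vapply(psds, band_power, numeric(1), lo = 100, hi = 250)
  theta_pow <- vapply(psds, band_power, numeric(1), lo = 5, hi = 12)

  lm_map <- c(pyr = which.max(rip_pow))
  hf <- which.max(theta_pow)
  lm_map["hf"] <- hf
  # l-m: channel 40-50 um above the fissure (nearest to 45 um above)
  target <- rec$depths[hf] - 45
  lm_map["l-m"] <- which.min(abs(rec$depths - target))

  if (!is.null(swr_events) && nrow(swr_events)) {
    ta <- triggered_average(rec, swr_events$t_peak, c(0.25, 0.25),
                            trigger_kind = "ripple_peak")
    cs <- csd(ta$values, spacing = spacing)
    at0 <- cs$values[, which.min(abs(ta$time))]
    # rad: strongest sink between pyr and the fissure
    cand <- which(cs$channels > lm_map["pyr"] & cs$channels < hf)
    if (length(cand))
      lm_map["rad"] <- cs$channels[cand[which.min(at0[cand])]]
    # imol: secondary sharp-wave sink below the fissure
    cand <- which(cs$channels > hf)
    if (length(cand))
      lm_map["imol"] <- cs$channels[cand[which.min(at0[cand])]]
  }

  if (!is.null(ds_events) && nrow(ds_events) &&
      any(ds_events$ds_class %in% c("DS1", "DS2"))) {
    ds_sink <- function(cls) {
      ev <- ds_events[ds_events$ds_class == cls, ]
      if (!nrow(ev)) return(NA_integer_)
      ta <- triggered_average(rec, ev$t_peak, c(0.05, 0.05),
                              trigger_kind = "ds_peak")
      cs <- csd(ta$values, spacing = spacing)
      at0 <- cs$values[, which.min(abs(ta$time))]
      cand <- which(cs$channels > hf)
      if (!length(cand)) return(NA_integer_)
      cs$channels[cand[which.min(at0[cand])]]
    }
    s1 <- ds_sink("DS1"); s2 <- ds_sink("DS2")
    if (!is.na(s1)) lm_map["omol"] <- s1
    if (!is.na(s2)) lm_map["mmol"] <- s2
    # gr: strongest DS source strictly below the molecular layers
    below <- suppressWarnings(max(lm_map[c("mmol", "omol")], na.rm = TRUE))
    if (is.finite(below)) {
      ta <- triggered_average(rec, ds_events$t_peak, c(0.05, 0.05))
      cs <- csd(ta$values, spacing = spacing)
      at0 <- cs$values[, which.min(abs(ta$time))]
      cand <- which(cs$channels > below)
      if (length(cand))
        lm_map["gr"] <- cs$channels[cand[which.max(at0[cand])]]
    }
  }

  enforce_layer_order(lm_map)
}

# Dorsoventral ordering pyr < rad < l-m <= hf <= omol < mmol < imol < gr;
# violating landmarks are dropped (with a warning), keeping earlier ones.
enforce_layer_order <- function(lm_map) {
  order_spec <- c("pyr", "rad", "l-m", "hf", "omol", "mmol", "imol", "gr")
  strict <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE)  # pair i, i+1
  repeat {
    present <- order_spec[order_spec %in% names(lm_map)]
    bad <- NULL
    for (i in seq_along(present)[-1]) {
      ia <- match(present[i - 1L], order_spec)
      ib <- match(present[i], order_spec)
      need_strict <- any(strict[ia:(ib - 1L)])
      a <- lm_map[[present[i - 1L]]]; b <- lm_map[[present[i]]]
      if ((need_strict && b <= a) || (!need_strict && b < a)) {
        bad <- present[i]; break
      }
    }
    if (is.null(bad)) break
    warning("layer ordering violated; omitting landmark ", bad)
    lm_map <- lm_map[names(lm_map) != bad]
  }
  present <- order_spec[order_spec %in% names(lm_map)]
  structure(lm_map[present], class = "layer_map")
}
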