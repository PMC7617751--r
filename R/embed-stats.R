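#' Discrete Frechet distance and trajectory similarity
#'
#' Distance by the standard dynamic program over point couplings;
#' similarity is defined as `10 / distance` (a fixed scaling bringing
#' typical embedding-trajectory values near 1). Identical trajectories have
#' distance 0 and similarity `Inf`.
#'
#' @param a,b 2-D polylines (matrices with >= 1 row, 2 columns).
#' @return `frechet_dist`: the distance; `frechet_similarity`: a list with
#'   `similarity` and `distance`.
#' @export
frechet_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!nrow(a) || !nrow(b)) stop("empty trajectory")
  frechet_dist_cpp(a, b)
}

#' @rdname frechet_dist
#' @export
frechet_similarity <- function(a, b) {
  d <- frechet_dist(a, b)
  list(similarity = if (d == 0) Inf else 10 / d, distance = d)
}

#' Fourier phase-shift surrogate of a 2-D trajectory
#'
#' The polyline is encoded as the complex series `x + iy`, its discrete
#' Fourier transform taken, the phase spectrum circularly shifted by a
#' random bin offset (DC untouched), and the trajectory reconstructed by
#' the inverse transform. The amplitude spectrum and the mean position are
#' preserved exactly; only the phase structure is disrupted.
#'
#' @param traj 2-D polyline (>= 4 points).
#' @param shift integer bin offset; `NULL` draws one uniformly (requires a
#'   seeded RNG for reproducibility). `0` returns the input.
#' @return surrogate polyline, same dimensions.
#' @export
fourier_surrogate <- function(traj, shift = NULL) {
  traj <- as.matrix(traj)
  n <- nrow(traj)
  if (n < 4L) stop("need at least 4 points for a Fourier surrogate")
  if (is.null(shift)) shift <- sample.int(n - 1L, 1L)
  z <- complex(real = traj[, 1], imaginary = traj[, 2])
  Z <- fft(z)
  ph <- Arg(Z); am <- Mod(Z)
  idx <- 2:n
  ph[idx] <- ph[((idx - 2L - shift) %% (n - 1L)) + 2L]
  zs <- fft(am * exp(1i * ph), inverse = TRUE) / n
  cbind(Re(zs), Im(zs))
}

# Resample a polyline to n arc-length-equidistant points.
resample_polyline <- function(traj, n = 100) {
  traj <- as.matrix(traj)
  arc <- c(0, cumsum(sqrt(rowSums(diff(traj)^2))))
  if (max(arc) == 0) return(traj[rep(1L, n), , drop = FALSE])
  uu <- seq(0, max(arc), length.out = n)
  cbind(approx(arc, traj[, 1], xout = uu, ties = "ordered")$y,
        approx(arc, traj[, 2], xout = uu, ties = "ordered")$y)
}

#' Surrogate-normalised trajectory consistency
#'
#' Compares the observed similarity of two trajectories to a null built
#' from Fourier phase-shift surrogates: for each of `n_surrogates` draws,
#' both trajectories are independently phase-shifted and their similarity
#' recomputed; the consistency score is
#' `z = (s - mean(surrogates)) / sd(surrogates)`.
#'
#' @param a,b 2-D polylines.
#' @param n_surrogates surrogate draws (default 10000).
#' @param seed integer RNG seed.
#' @param n_points common resampling length before comparison.
#' @return A `similarity_result`: list with `similarity`, `z`,
#'   `surrogate_n`, `surrogate_mean`, `surrogate_sd`.
#' @export
consistency_z <- function(a, b, n_surrogates = 10000, seed = NULL,
                          n_points = 100) {
  if (!is.null(seed)) set.seed(seed)
  ra <- resample_polyline(a, n_points)
  rb <- resample_polyline(b, n_points)
  s_obs <- frechet_similarity(ra, rb)$similarity
  s_sur <- vapply(seq_len(n_surrogates), function(i) {
    frechet_similarity(fourier_surrogate(ra), fourier_surrogate(rb))$similarity
  }, 0)
  mu <- mean(s_sur); sg <- sd(s_sur)
  if (!is.finite(sg) || sg == 0)
    stop("surrogate similarity distribution has zero spread")
  structure(list(similarity = s_obs, z = (s_obs - mu) / sg,
                 surrogate_n = n_surrogates, surrogate_mean = mu,
                 surrogate_sd = sg),
            class = "similarity_result")
}

# Mutual information (bits) between two label vectors.
label_mi <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

#' Leave-one-out k-NN layer classification of embedding coordinates
#'
#' Each point is predicted from all the others with a uniform-weight
#' k-nearest-neighbour classifier (k = 4, matching the smallest per-layer
#' sample size in typical banks). Reports the row-normalised confusion
#' matrix, the mutual information between true and predicted labels, and a
#' label-shuffle null distribution of the mutual information.
#'
#' @param coords n x 2 matrix of embedding coordinates.
#' @param labels true layer labels.
#' @param k neighbours (default 4).
#' @param n_shuffle label permutations for the null (default 1000).
#' @param seed RNG seed for the shuffle null.
#' @return A `layer_classifier_report`: list with `predicted`, `confusion`
#'   (rows sum to 1), `accuracy`, `per_layer_accuracy`, `mutual_info`
#'   (bits), `shuffle_mi`.
#' @export
loo_layer_classifier <- function(coords, labels, k = 4, n_shuffle = 1000,
                                 seed = NULL) {
  labels <- as.character(labels)
  cnt <- table(labels)
  if (any(cnt <= k))
    stop("layers with <= k points: ",
         paste(names(cnt)[cnt <= k], collapse = ", "))
  n <- nrow(coords)
  pred <- character(n)
  for (i in seq_len(n))
    pred[i] <- as.character(class::knn(coords[-i, , drop = FALSE],
                                       coords[i, , drop = FALSE],
                                       cl = factor(labels[-i]), k = k))
  conf <- table(true = labels, pred = factor(pred, levels = sort(unique(labels))))
  conf <- sweep(conf, 1L, pmax(rowSums(conf), 1L), "/")
  if (!is.null(seed)) set.seed(seed)
  shuffle_mi <- vapply(seq_len(n_shuffle), function(s)
    label_mi(sample(labels), pred), 0)
  per_layer <- diag(conf[, rownames(conf), drop = FALSE])
  structure(
    list(predicted = pred, confusion = conf,
         accuracy = mean(pred == labels),
         per_layer_accuracy = setNames(as.numeric(per_layer), rownames(conf)),
         mutual_info = label_mi(labels, pred), shuffle_mi = shuffle_mi),
    class = "layer_classifier_report")
}

#' Projection variability versus event sample size
#'
#' For each requested event count, mean waveforms are recomputed from every
#' window of that many consecutive events (up to `max_draws`), projected
#' onto the fitted embedding, and summarised by the spread
#' `sqrt(det(cov(points)))` and by the probability that the fitted k-NN
#' classifier assigns the correct layer (with `l-m`, `hf` and the outer
#' molecular layer merged, as they are not separable).
#'
#' @param model fitted `embedding_model` with trajectory.
#' @param x channel voltage series.
#' @param fs sampling rate (Hz).
#' @param swr_peaks,theta_dzc full event/trigger time vectors (s).
#' @param sizes event counts to evaluate (applied to SWR events; all theta
#'   triggers are always used).
#' @param true_layer the channel's true layer label (for the classification
#'   curve; `NA` skips it).
#' @param k classifier neighbours.
#' @param max_draws cap on consecutive windows per size.
#' @return data.frame with `size`, `n_draws`, `spread`, `p_correct`.
#' @export
projection_variability <- function(model, x, fs, swr_peaks, theta_dzc,
                                   sizes, true_layer = NA, k = 4,
                                   max_draws = 10000) {
  merge_layers <- function(l) ifelse(l %in% c("l-m", "hf", "omol"), "lm-hf-om", l)
  labelled <- !is.na(model$meta$layer) & model$meta$layer != "NA"
  train_coords <- model$coords[labelled, , drop = FALSE]
  train_lab <- factor(merge_layers(model$meta$layer[labelled]))
  out <- NULL
  n_ev <- length(swr_peaks)
  for (s in sizes) {
    if (s > n_ev) {
      warning("size ", s, " exceeds available events (", n_ev, "); skipped")
      next
    }
    starts <- seq_len(n_ev - s + 1L)
    if (length(starts) > max_draws)
      starts <- starts[seq(1L, length(starts), length.out = max_draws)]
    feats <- lapply(starts, function(st)
      channel_features(x, fs, swr_peaks[st:(st + s - 1L)], theta_dzc))
    proj <- project_features(model, feats)
    pts <- cbind(proj$x, proj$y)
    spread <- if (nrow(pts) > 1L) sqrt(max(det(cov(pts)), 0)) else 0
    p_corr <- NA_real_
    if (!is.na(true_layer)) {
      pred <- class::knn(train_coords, pts, cl = train_lab, k = k)
      p_corr <- mean(as.character(pred) == merge_layers(true_layer))
    }
    out <- rbind(out, data.frame(size = s, n_draws = length(starts),
                                 spread = spread, p_correct = p_corr))
  }
  out
}
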