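zscore <- function(x) {
  s <- sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

#' Waveform features of one channel
#'
#' Mean LFP waveforms on a channel around the two network-event triggers
#' used by the embedding: a 500-ms window centred on ripple-envelope peaks
#' (sharp-wave/ripple deflection) and a 150-ms window centred on the
#' descending zero-crossings of pyramidal-layer theta. Each mean waveform is
#' individually z-scored so the features carry shape, not gain.
#'
#' @param x channel voltage series.
#' @param fs sampling rate (Hz).
#' @param swr_peaks ripple-envelope peak times (s).
#' @param theta_dzc descending zero-crossing times of pyramidal theta (s).
#' @param channel_id,subject_id,layer,depth metadata carried through to the
#'   embedding (layer may be `NA` for unlabelled probes/tetrodes).
#' @return A `channel_features` object: list with `swr_waveform`
#'   (`round(0.5 fs) + 1` samples), `theta_waveform` (`round(0.15 fs) + 1`
#'   samples), `n_swr`, `n_theta`, and the metadata fields.
#' @export
channel_features <- function(x, fs, swr_peaks, theta_dzc,
                             channel_id = NA, subject_id = NA,
                             layer = NA, depth = NA) {
  if (!length(swr_peaks)) stop("no SWR events supplied for channel features")
  if (!length(theta_dzc)) stop("no theta cycles supplied for channel features")
  win <- function(w) {                  # window with round(w * fs) + 1 samples
    n_target <- round(w * fs)
    pre <- n_target %/% 2
    c(pre, n_target - pre) / fs
  }
  swr_ta <- triggered_average(x, swr_peaks, win(0.5), fs = fs,
                              trigger_kind = "ripple_peak")
  th_ta <- triggered_average(x, theta_dzc, win(0.15), fs = fs,
                             trigger_kind = "theta_descending_zero")
  structure(
    list(swr_waveform = zscore(swr_ta$values[1, ]),
         theta_waveform = zscore(th_ta$values[1, ]),
         n_swr = swr_ta$n_events, n_theta = th_ta$n_events,
         channel_id = channel_id, subject_id = subject_id,
         layer = layer, depth = depth),
    class = "channel_features")
}

#' Collect channel features into a feature bank
#'
#' @param feats list of `channel_features`.
#' @return list with `swr` and `theta` matrices (channels x samples) and a
#'   `meta` data.frame (`subject`, `channel`, `layer`, `depth`).
#' @export
collect_features <- function(feats) {
  list(swr = do.call(rbind, lapply(feats, `[[`, "swr_waveform")),
       theta = do.call(rbind, lapply(feats, `[[`, "theta_waveform")),
       meta = data.frame(
         subject = vapply(feats, function(f) as.character(f$subject_id), ""),
         channel = vapply(feats, function(f) as.numeric(f$channel_id), 0),
         layer = vapply(feats, function(f) as.character(f$layer), ""),
         depth = vapply(feats, function(f) as.numeric(f$depth), 0)))
}

# Union k-nearest-neighbour graph with Euclidean edge weights; disconnected
# components are bridged through their shortest connecting edge.
knn_geodesics <- function(X, k) {
  n <- nrow(X)
  if (n < k + 1L)
    stop(sprintf("only %d points for a k=%d neighbourhood graph; reduce k", n, k))
  De <- as.matrix(dist(X))
  edges <- NULL
  for (i in seq_len(n)) {
    nb <- order(De[i, ])[2:(k + 1L)]
    edges <- rbind(edges, cbind(i, nb, De[i, nb]))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], weight = edges[, 3]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  g <- igraph::simplify(g, edge.attr.comb = "min")
  comp <- igraph::components(g)
  while (comp$no > 1L) {
    a <- which(comp$membership == 1L)
    b <- which(comp$membership != 1L)
    sub <- De[a, b, drop = FALSE]
    ij <- arrayInd(which.min(sub), dim(sub))
    g <- igraph::add_edges(g, c(a[ij[1]], b[ij[2]]),
                           attr = list(weight = De[a[ij[1]], b[ij[2]]]))
    comp <- igraph::components(g)
  }
  D <- igraph::distances(g, algorithm = "dijkstra")
  list(D = D[order(as.integer(rownames(D))), order(as.integer(colnames(D)))],
       De = De)
}

#' Fit the laminar waveform embedding
#'
#' PCA is applied separately to the z-scored sharp-wave and theta waveform
#' banks (four components each, balancing the two feature types), and the
#' concatenated 8-D projections are embedded in 2-D with ISOMAP: a
#' k-nearest-neighbour graph (k = 15), geodesic distances by Dijkstra's
#' algorithm, and classical MDS of the geodesic matrix. The training
#' geodesics and eigen-decomposition are retained for Nystrom out-of-sample
#' projection. Channels are resampled to a common 50-um depth step per
#' subject before fitting.
#'
#' @param bank feature bank from [collect_features()].
#' @param n_pc principal components per waveform type (default 4).
#' @param k ISOMAP neighbourhood size (default 15).
#' @param spacing_resample depth step (um) for per-subject channel
#'   resampling; `NULL` disables.
#' @return An `embedding_model`: list with `coords` (n x 2), `meta`,
#'   `layer_coords`, PCA transforms, geodesic matrix and spectral data for
#'   projection, `var_explained_2d`, and `diameter`.
#' @export
fit_embedding <- function(bank, n_pc = 4, k = 15, spacing_resample = 50) {
  meta <- bank$meta
  keep <- seq_len(nrow(meta))
  if (!is.null(spacing_resample)) {
    keep <- unlist(lapply(split(seq_len(nrow(meta)), meta$subject), function(ix) {
      d <- meta$depth[ix]
      targets <- seq(min(d), max(d), by = spacing_resample)
      unique(ix[vapply(targets, function(t) which.min(abs(d - t)), 0L)])
    }), use.names = FALSE)
    keep <- sort(keep)
  }
  swr <- bank$swr[keep, , drop = FALSE]
  theta <- bank$theta[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]

  pca_swr <- prcomp(swr, center = TRUE, scale. = FALSE)
  pca_theta <- prcomp(theta, center = TRUE, scale. = FALSE)
  X <- cbind(pca_swr$x[, seq_len(n_pc), drop = FALSE],
             pca_theta$x[, seq_len(n_pc), drop = FALSE])

  geo <- knn_geodesics(X, k)
  D2 <- geo$D^2
  n <- nrow(D2)
  B <- -0.5 * (D2 - outer(rowMeans(D2), rep(1, n)) -
                 outer(rep(1, n), colMeans(D2)) + mean(D2))
  eig <- eigen(B, symmetric = TRUE)
  coords <- eig$vectors[, 1:2] %*% diag(sqrt(pmax(eig$values[1:2], 0)))
  pos <- pmax(eig$values, 0)

  layer_coords <- NULL
  lab <- meta$layer
  if (any(!is.na(lab) & lab != "NA" & lab != "")) {
    ok <- !is.na(lab) & lab != "NA" & lab != ""
    layer_coords <- do.call(rbind, lapply(split(which(ok), lab[ok]), function(ix)
      colMeans(coords[ix, , drop = FALSE])))
  }

  structure(
    list(coords = coords, meta = meta, layer_coords = layer_coords,
         pca_swr = pca_swr, pca_theta = pca_theta, n_pc = n_pc, k = k,
         X = X, D = geo$D, eig_values = eig$values[1:2],
         eig_vectors = eig$vectors[, 1:2], mean_D2 = colMeans(D2),
         var_explained_2d = sum(pos[1:2]) / sum(pos),
         diameter = max(dist(coords)), trajectory = NULL),
    class = "embedding_model")
}

# Map new 8-D points into the fitted ISOMAP space (Nystrom extension):
# geodesic distances to all training points are estimated through the new
# point's k nearest training neighbours, then plugged into the MDS kernel.
isomap_extend <- function(model, Xnew) {
  n <- nrow(model$X)
  t(apply(Xnew, 1L, function(x) {
    e <- sqrt(colSums((t(model$X) - x)^2))
    nb <- order(e)[seq_len(min(model$k, n))]
    dgeo <- apply(model$D[nb, , drop = FALSE] + e[nb], 2L, min)
    ky <- 0.5 * (model$mean_D2 - dgeo^2)
    as.numeric(crossprod(model$eig_vectors, ky) /
                 (sqrt(pmax(model$eig_values, 1e-12))))
  }))
}

#' Build the cross-animal layer trajectory
#'
#' Connects across-subject mean layer coordinates in anatomical order,
#' adding `round(distance / point_spacing)` intermediate control points
#' between each successive layer pair. Intermediate points are the fitted
#' coordinates of anatomically equidistant channels between the two layers,
#' averaged across subjects. A quadratic interpolating spline through the
#' control points, sampled densely, gives the trajectory polyline and its
#' arc-length parameterisation.
#'
#' @param model a fitted `embedding_model`.
#' @param point_spacing embedding-space distance per intermediate point
#'   (default 20; scale-dependent, see the model's `diameter`).
#' @param n_dense dense polyline sample count.
#' @return the model with a `trajectory` slot: list with `points`
#'   (n_dense x 2), `arc` (cumulative arc length), `control` (control
#'   points), `layer_arc` (arc-length position of each layer centre).
#' @export
build_trajectory <- function(model, point_spacing = 20, n_dense = 400) {
  lc <- model$layer_coords
  if (is.null(lc) || nrow(lc) < 2L)
    stop("need at least two layer coordinates to build a trajectory")
  order_spec <- c("pyr", "rad", "l-m", "hf", "omol", "mmol", "imol", "gr")
  layers <- order_spec[order_spec %in% rownames(lc)]
  lc <- lc[layers, , drop = FALSE]
  meta <- model$meta

  control <- lc[1, , drop = FALSE]
  for (i in seq_len(nrow(lc) - 1L)) {
    d <- sqrt(sum((lc[i + 1L, ] - lc[i, ])^2))
    n_int <- floor(d / point_spacing)
    if (n_int > 0) {
      fr <- seq_len(n_int) / (n_int + 1L)
      inter <- matrix(0, n_int, 2)
      n_sub <- 0L
      for (s in unique(meta$subject)) {
        ix <- which(meta$subject == s)
        d1 <- mean(meta$depth[ix][meta$layer[ix] %in% layers[i]])
        d2 <- mean(meta$depth[ix][meta$layer[ix] %in% layers[i + 1L]])
        if (!is.finite(d1) || !is.finite(d2)) next
        targets <- d1 + fr * (d2 - d1)
        rows <- ix[vapply(targets, function(t)
          which.min(abs(meta$depth[ix] - t)), 0L)]
        inter <- inter + model$coords[rows, , drop = FALSE]
        n_sub <- n_sub + 1L
      }
      if (n_sub > 0) control <- rbind(control, inter / n_sub)
    }
    control <- rbind(control, lc[i + 1L, , drop = FALSE])
  }

  # drop consecutive coincident control points (duplicate spline knots)
  if (nrow(control) > 1L) {
    keep <- c(TRUE, sqrt(rowSums(diff(control)^2)) > 1e-9)
    control <- control[keep, , drop = FALSE]
  }
  u <- c(0, cumsum(sqrt(rowSums(diff(control)^2))))
  uu <- seq(0, max(u), length.out = n_dense)
  pts <- cbind(quad_interp(u, control[, 1], uu),
               quad_interp(u, control[, 2], uu))
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  layer_arc <- vapply(seq_len(nrow(lc)), function(i) {
    arc[which.min(colSums((t(pts) - lc[i, ])^2))]
  }, 0)
  names(layer_arc) <- layers
  model$trajectory <- list(points = pts, arc = arc, control = control,
                           layer_arc = layer_arc)
  model
}

# Interpolating quadratic (order-3) B-spline; linear fallback for < 3 points.
quad_interp <- function(u, y, uout) {
  m <- length(u)
  if (m < 3L) return(approx(u, y, xout = uout, rule = 2)$y)
  mids <- if (m > 3L) (u[2:(m - 2L)] + u[3:(m - 1L)]) / 2 else numeric()
  knots <- c(rep(u[1], 3), mids, rep(u[m], 3))
  Bmat <- splines::splineDesign(knots, u, ord = 3)
  cf <- solve(Bmat, y)
  as.numeric(splines::splineDesign(knots, pmin(pmax(uout, u[1]), u[m]),
                                   ord = 3) %*% cf)
}

#' Project channel features onto the fitted embedding
#'
#' Applies the stored PCA transforms and the Nystrom out-of-sample ISOMAP
#' extension, then linearises against the trajectory: the projection's
#' `linear_pos` is the arc length of the nearest trajectory point, and
#' `nearest_layer` is the layer whose trajectory position is closest.
#'
#' @param model a fitted `embedding_model` (with trajectory for
#'   linearisation).
#' @param features a `channel_features` object, a list of them, or a feature
#'   bank from [collect_features()].
#' @return data.frame with `x`, `y`, `linear_pos`, `distance_to_trajectory`,
#'   `nearest_layer` (the last three `NA` when no trajectory is present).
#' @export
project_features <- function(model, features) {
  if (inherits(features, "channel_features")) features <- list(features)
  bank <- if (is.list(features) && !is.null(features$swr)) features
  else collect_features(features)
  Xs <- predict(model$pca_swr, bank$swr)[, seq_len(model$n_pc), drop = FALSE]
  Xt <- predict(model$pca_theta, bank$theta)[, seq_len(model$n_pc), drop = FALSE]
  Y <- isomap_extend(model, cbind(Xs, Xt))
  out <- data.frame(x = Y[, 1], y = Y[, 2], linear_pos = NA_real_,
                    distance_to_trajectory = NA_real_,
                    nearest_layer = NA_character_)
  tr <- model$trajectory
  if (!is.null(tr)) {
    for (i in seq_len(nrow(Y))) {
      d2 <- colSums((t(tr$points) - as.numeric(Y[i, ]))^2)
      j <- which.min(d2)
      out$linear_pos[i] <- tr$arc[j]
      out$distance_to_trajectory[i] <- sqrt(d2[j])
      out$nearest_layer[i] <-
        names(tr$layer_arc)[which.min(abs(tr$layer_arc - tr$arc[j]))]
    }
  }
  out
}

#' Split linearised positions into deep and superficial groups
#'
#' Fits a two-component Gaussian mixture to linearised embedding positions
#' and thresholds at the interior intersection of the weighted component
#' densities. Positions below the threshold (toward the pyramidal end of the
#' trajectory, i.e. the stratum-oriens side) are labelled `"deep"`, above it
#' `"superficial"`.
#'
#' @param linear_positions numeric vector (n >= 10).
#' @param seed optional integer seed for the mixture fit initialisation.
#' @return list with `labels`, `threshold`, and the mixture `fit`.
#' @export
split_deep_superficial <- function(linear_positions, seed = NULL) {
  if (length(linear_positions) < 10L)
    stop("need at least 10 positions for the deep/superficial split")
  if (!is.null(seed)) set.seed(seed)
  fit <- gmm1d(linear_positions)
  if (!fit$degenerate &&
      abs(diff(fit$mean)) < mean(fit$sd) / 2)
    warning("component means closer than pooled SD/2: distribution may be unimodal")
  thr <- gmm1d_threshold(fit)
  list(labels = ifelse(linear_positions < thr, "deep", "superficial"),
       threshold = thr, fit = fit)
}
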