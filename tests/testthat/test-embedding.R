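fs <- 1250

test_that("channel features are z-scored, gain-invariant, correctly sized", {
  set.seed(40)
  x <- rnorm(60 * fs)
  swr_t <- seq(2, 58, by = 2)
  th_t <- seq(1.5, 58, by = 0.125)
  f <- channel_features(x, fs, swr_t, th_t)
  expect_length(f$swr_waveform, round(0.5 * fs) + 1)
  expect_length(f$theta_waveform, round(0.15 * fs) + 1)
  expect_equal(mean(f$swr_waveform), 0, tolerance = 1e-9)
  expect_equal(sd(f$swr_waveform), 1, tolerance = 1e-9)
  expect_equal(sd(f$theta_waveform), 1, tolerance = 1e-9)
  f2 <- channel_features(7.3 * x, fs, swr_t, th_t)
  expect_equal(f2$swr_waveform, f$swr_waveform, tolerance = 1e-9)
  expect_equal(f2$theta_waveform, f$theta_waveform, tolerance = 1e-9)
  expect_error(channel_features(x, fs, numeric(), th_t), "SWR")
  expect_error(channel_features(x, fs, swr_t, numeric()), "theta")
})

test_that("theta waveforms reverse phase across the fissure", {
  fx <- embedding_fixture()
  b <- fx$bank
  lay <- b$meta$layer
  sub <- b$meta$subject
  s1 <- sub == sub[1]
  pyr_wf <- b$theta[which(s1 & lay == "pyr")[2], ]
  hf_wf <- b$theta[which(s1 & lay == "hf")[1], ]
  rad_wf <- b$theta[which(s1 & lay == "rad")[2], ]
  expect_lt(cor(pyr_wf, hf_wf), 0)        # anti-phase across the fissure
  expect_gt(cor(pyr_wf, rad_wf), 0)       # pre-fissure shift is gradual
})

test_that("the embedding preserves planar geometry (flat-manifold oracle)", {
  set.seed(41)
  n <- 60
  plane <- cbind(runif(n, 0, 10), runif(n, 0, 6))
  basis <- qr.Q(qr(matrix(rnorm(64), 8)))[, 1:2]
  X <- plane %*% t(basis)
  geo <- hipplamina:::knn_geodesics(X, k = 15)
  D2 <- geo$D^2
  B <- -0.5 * (D2 - outer(rowMeans(D2), rep(1, n)) -
                 outer(rep(1, n), colMeans(D2)) + mean(D2))
  eig <- eigen(B, symmetric = TRUE)
  Y <- eig$vectors[, 1:2] %*% diag(sqrt(eig$values[1:2]))
  d_true <- as.numeric(dist(plane))
  d_emb <- as.numeric(dist(Y))
  expect_lt(median(abs(d_emb - d_true) / d_true), 0.05)
})

test_that("embedding agrees with an independent ISOMAP implementation", {
  skip_if_not_installed("vegan")
  fx <- embedding_fixture()
  model <- fx$model
  ref <- vegan::isomap(dist(model$X), ndim = 2, k = model$k)
  pr <- vegan::procrustes(ref$points, model$coords, symmetric = TRUE)
  expect_gt(cor(as.numeric(pr$X), as.numeric(pr$Yrot)), 0.99)
})

test_that("fitted model separates layers and orders them along the trajectory", {
  fx <- embedding_fixture()
  model <- fx$model
  expect_gt(model$var_explained_2d, 0.6)
  lab <- model$meta$layer
  ok <- !is.na(lab) & lab != "NA"
  # mean silhouette of the key layer clusters is positive (individual points
  # spread along the within-layer depth gradient the embedding resolves)
  d <- as.matrix(dist(model$coords[ok, ]))
  labo <- lab[ok]
  for (layer in c("pyr", "rad", "mmol", "gr")) {
    sil <- vapply(which(labo == layer), function(i) {
      mem <- setdiff(which(labo == layer), i)
      a <- mean(d[i, mem])
      b <- min(vapply(setdiff(unique(labo), layer),
                      function(l2) mean(d[i, labo == l2]), 0))
      (b - a) / max(a, b)
    }, 0)
    expect_gt(mean(sil), 0)
  }
  # layer centres are anatomically ordered along the linearised trajectory
  arc <- model$trajectory$layer_arc
  ord <- c("pyr", "rad", "l-m", "hf", "omol", "mmol", "imol", "gr")
  expect_true(all(diff(arc[ord[ord %in% names(arc)]]) > 0))
  expect_error(fit_embedding(collect_features(fx$subs[[1]]$feats[1:8])),
               "reduce k")
})

test_that("out-of-sample projection reproduces training coordinates", {
  fx <- embedding_fixture()
  model <- fx$model
  proj <- project_features(model, fx$bank)
  err <- sqrt(rowSums((cbind(proj$x, proj$y) - model$coords)^2))
  expect_lt(max(err) / model$diameter, 0.01)
  expect_true(all(proj$linear_pos >= 0 &
                    proj$linear_pos <= max(model$trajectory$arc)))
})

test_that("trajectory interpolation follows the distance/20-style point rule", {
  # two layer centres 60 apart -> 3 intermediate points at spacing 20
  depths <- seq(0, 150, by = 37.5)
  coords <- cbind(60 * depths / 150, 0)
  fake <- structure(list(
    coords = coords,
    meta = data.frame(subject = "s", channel = 1:5,
                      layer = c("pyr", NA, NA, NA, "rad"), depth = depths),
    layer_coords = rbind(pyr = c(0, 0), rad = c(60, 0)),
    diameter = 65, trajectory = NULL), class = "embedding_model")
  out <- build_trajectory(fake, point_spacing = 20)
  expect_identical(nrow(out$trajectory$control), 5L)  # 2 layers + 3 intermediates
  # distance below the spacing -> no intermediate points
  fake$layer_coords <- rbind(pyr = c(0, 0), rad = c(15, 0))
  out2 <- build_trajectory(fake, point_spacing = 20)
  expect_identical(nrow(out2$trajectory$control), 2L)
  # collinear control points give a straight trajectory
  expect_lt(max(abs(out$trajectory$points[, 2][1:300])), 1e-6)
  expect_error(build_trajectory(structure(list(layer_coords = coords[1, , drop = FALSE]),
                                          class = "embedding_model")),
               "two layer")
})

test_that("tetrode descent recovers layer-scale depth ordering", {
  fx <- embedding_fixture()
  model <- fx$model
  spec <- session_spec(seed = 77, duration_awake = 180, duration_rest = 180)
  depths <- c(300, 500, 700, 900, 1150)
  desc <- generate_tetrode_descent(spec, depths)
  feats <- lapply(desc, function(d)
    channel_features(d$rec$data[1, ], d$rec$fs, d$truth$swr$t_peak,
                     d$truth$theta_dzc, depth = d$truth$depth))
  proj <- project_features(model, feats)
  expect_true(all(diff(proj$linear_pos) > 0))
  expect_identical(generate_tetrode_descent(spec, numeric()), list())
  expect_error(generate_tetrode_descent(spec, 99999), "range")
})

test_that("deep/superficial split thresholds at the density intersection", {
  set.seed(42)
  v <- c(rnorm(250, 3, 0.5), rnorm(250, 7, 0.5))
  sp <- split_deep_superficial(v, seed = 1)
  expect_equal(sp$threshold, 5, tolerance = 0.3)
  truth <- rep(c("deep", "superficial"), each = 250)
  expect_gte(mean(sp$labels == truth), 0.99)
  # unequal weights shift the threshold toward the lighter component
  v2 <- c(rnorm(400, 3, 0.5), rnorm(100, 7, 0.5))
  expect_gt(split_deep_superficial(v2, seed = 1)$threshold, sp$threshold)
  expect_warning(split_deep_superficial(rep(2, 20), seed = 1), "degenerate|unimodal")
  expect_error(split_deep_superficial(rnorm(5)), "10")
})
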