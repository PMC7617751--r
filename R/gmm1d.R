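# One-dimensional two-component Gaussian mixtures are used in three places:
# dentate-spike class splitting, the trough-to-peak latency threshold, and
# the deep/superficial split of linearised projections. The fit comes from
# mclust; the density-intersection threshold is computed here.

# Fit a 2-component 1-D Gaussian mixture; components ordered by mean.
#' @importFrom mclust Mclust mclustBIC
gmm1d <- function(x) {
  if (sd(x) == 0) {
    warning("degenerate mixture: all values identical")
    return(list(mean = c(x[1], x[1]), sd = c(0, 0), weight = c(0.5, 0.5),
                degenerate = TRUE))
  }
  fit <- mclust::Mclust(x, G = 2, modelNames = c("V", "E"), verbose = FALSE)
  p <- fit$parameters
  sds <- sqrt(if (length(p$variance$sigmasq) == 1L)
    rep(p$variance$sigmasq, 2) else p$variance$sigmasq)
  ord <- order(p$mean)
  list(mean = as.numeric(p$mean[ord]), sd = sds[ord],
       weight = as.numeric(p$pro[ord]), degenerate = FALSE)
}

# Hard assignment by posterior probability (1 = lower-mean component).
gmm1d_classify <- function(fit, x) {
  d1 <- fit$weight[1] * dnorm(x, fit$mean[1], max(fit$sd[1], 1e-12))
  d2 <- fit$weight[2] * dnorm(x, fit$mean[2], max(fit$sd[2], 1e-12))
  ifelse(d1 >= d2, 1L, 2L)
}

# Interior intersection of the two weighted component densities.
gmm1d_threshold <- function(fit) {
  if (fit$degenerate || abs(diff(fit$mean)) < 1e-12) return(mean(fit$mean))
  f <- function(x) fit$weight[1] * dnorm(x, fit$mean[1], fit$sd[1]) -
    fit$weight[2] * dnorm(x, fit$mean[2], fit$sd[2])
  lo <- fit$mean[1]; hi <- fit$mean[2]
  if (f(lo) * f(hi) > 0) return(mean(fit$mean))  # no interior sign change
  uniroot(f, c(lo, hi))$root
}
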