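#' Bootstrap percentile confidence interval
#'
#' Resamples the data with replacement, computes the statistic per
#' resample, and reports the 99% interval as the 0.5th-99.5th percentile
#' range of the bootstrap distribution.
#'
#' @param values numeric vector (>= 2 values).
#' @param statistic function of a numeric vector (default `mean`).
#' @param n resamples (default 100000; below 1000 triggers a warning).
#' @param seed RNG seed.
#' @param probs interval percentiles (default `c(0.005, 0.995)`).
#' @return A `resample_result`: list with `estimate`, `ci_low`, `ci_high`,
#'   `n_resamples`, `seed`.
#' @export
bootstrap_ci <- function(values, statistic = mean, n = 100000, seed = 1,
                         probs = c(0.005, 0.995)) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (n < 1000) warning("fewer than 1000 resamples: interval will be unstable")
  set.seed(seed)
  m <- length(values)
  boot <- if (identical(statistic, mean)) {
    # fast path: resampled means via a single index matrix
    colMeans(matrix(values[sample.int(m, m * n, replace = TRUE)], nrow = m))
  } else {
    vapply(seq_len(n), function(i)
      statistic(values[sample.int(m, m, replace = TRUE)]), 0)
  }
  qs <- quantile(boot, probs, names = FALSE)
  structure(list(estimate = statistic(values), ci_low = qs[1], ci_high = qs[2],
                 n_resamples = n, seed = seed),
            class = "resample_result")
}

#' Permutation test for a difference in group means
#'
#' Null distribution by random reassignment of group labels; the one-tailed
#' p-value is the fraction of permuted mean differences at or above the
#' absolute observed difference, doubled for a two-tailed test.
#'
#' @param group_a,group_b numeric vectors.
#' @param n permutations (default 100000).
#' @param seed RNG seed.
#' @param tails 1 or 2.
#' @return list with `p`, `observed` (mean difference), `n`.
#' @export
permutation_diff_test <- function(group_a, group_b, n = 100000, seed = 1,
                                  tails = 2) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  obs <- mean(group_a) - mean(group_b)
  pool <- c(group_a, group_b)
  na <- length(group_a); m <- length(pool)
  set.seed(seed)
  tot <- sum(pool)
  perm <- vapply(seq_len(n), function(i) {
    sa <- sum(pool[sample.int(m, na)])
    sa / na - (tot - sa) / (m - na)
  }, 0)
  p1 <- mean(perm >= abs(obs))
  p <- if (tails == 2) min(1, 2 * p1) else p1
  list(p = p, observed = obs, n = n)
}

#' Optogenetic laser-response test
#'
#' Compares the firing rate in a short window after each laser pulse to the
#' baseline rate over the second preceding it. The null swaps baseline and
#' response rates with 50% probability per trial; a unit is responsive when
#' the observed mean increase exceeds the 99th percentile of the null AND
#' the mean response rate exceeds the baseline mean by at least two
#' baseline standard deviations.
#'
#' @param spike_times spike times (s).
#' @param pulse_times laser onset times (s), >= 20 pulses, windows
#'   non-overlapping.
#' @param window response window after onset (s, default 0.010).
#' @param baseline baseline window before onset (s, default 1).
#' @param n null permutations (default 100000).
#' @param seed RNG seed.
#' @return list with `responsive`, `p`, `observed` (rate increase, Hz),
#'   `baseline_mean`, `baseline_sd`, `response_mean`.
#' @export
laser_response_test <- function(spike_times, pulse_times, window = 0.010,
                                baseline = 1, n = 100000, seed = 1) {
  if (length(pulse_times) < 20L) stop("need at least 20 laser pulses")
  pt <- sort(pulse_times)
  if (any(diff(pt) < window + baseline))
    stop("overlapping pulse windows: pulses closer than baseline + window")
  st <- sort(spike_times)
  base_rate <- vapply(pt, function(t0)
    sum(st >= t0 - baseline & st < t0) / baseline, 0)
  resp_rate <- vapply(pt, function(t0)
    sum(st >= t0 & st < t0 + window) / window, 0)
  obs <- mean(resp_rate - base_rate)
  k <- length(pt)
  set.seed(seed)
  sgn <- matrix(sample(c(1, -1), k * n, replace = TRUE), nrow = k)
  null <- colMeans(sgn * (resp_rate - base_rate))
  p <- mean(null >= obs)
  responsive <- obs > quantile(null, 0.99) &&
    mean(resp_rate) > mean(base_rate) + 2 * sd(base_rate)
  list(responsive = responsive, p = p, observed = obs,
       baseline_mean = mean(base_rate), baseline_sd = sd(base_rate),
       response_mean = mean(resp_rate))
}
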