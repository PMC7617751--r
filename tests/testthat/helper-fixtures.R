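# Shared fixtures are built once per test run and memoised, since several
# suites exercise the same synthetic study conditions.
.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# The default study-condition session: 10 min, 32 channels.
default_session <- function() {
  get_fixture("sess_default", function() generate_session(session_spec(seed = 42)))
}

# Greedy one-to-one matching of detected vs true event times.
match_events <- function(detected, truth, tol = 0.02) {
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (t0 in detected) {
    j <- which(!used & abs(truth - t0) < tol)
    if (length(j)) { used[j[1]] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fp = length(detected) - tp, fn = sum(!used),
       precision = if (length(detected)) tp / length(detected) else NA_real_,
       recall = if (length(truth)) tp / length(truth) else NA_real_)
}

# Detected events, theta cycles, and per-channel waveform features for one
# synthetic subject (used by the embedding suites).
subject_features <- function(seed, duration = 180) {
  sess <- generate_session(session_spec(seed = seed, duration_awake = duration,
                                        duration_rest = duration))
  rec <- sess$rec
  pyr <- sess$truth$layers[["pyr"]]
  swr <- detect_swr(rec, pyr, ref_ch = 1)
  dec <- masked_emd(rec$data[pyr, seq_len(round(duration * rec$fs))], rec$fs)
  cy <- delineate_cycles(dec$imfs[, 6], dec$residue, rec$fs)
  dzc <- cy$t_zc_desc[cy$valid]
  feats <- lapply(seq_len(n_channels(rec)), function(ch)
    channel_features(rec$data[ch, ], rec$fs, swr$t_peak, dzc,
                     channel_id = ch, subject_id = rec$subject_id,
                     layer = sess$truth$channel_layers[ch],
                     depth = rec$depths[ch]))
  list(sess = sess, swr = swr, dzc = dzc, feats = feats, cycles = cy)
}

# Four-subject embedding model with trajectory (the embedding study
# condition), memoised.
embedding_fixture <- function() {
  get_fixture("embedding", function() {
    subs <- lapply(21:24, subject_features)
    bank <- collect_features(unlist(lapply(subs, `[[`, "feats"),
                                    recursive = FALSE))
    model <- fit_embedding(bank)
    model <- build_trajectory(model, point_spacing = model$diameter / 40)
    list(subs = subs, bank = bank, model = model)
  })
}

# Smooth closed random trajectory with uniformly random Fourier phases;
# phase-shift surrogates of it are exchangeable with it by construction.
random_phase_trajectory <- function(n_pts = 40, decay = 1.2) {
  k <- n_pts %/% 2
  amp <- c(0, (1 / seq_len(k))^decay)
  phs <- runif(k + 1, 0, 2 * pi)
  Z <- complex(modulus = c(amp, rep(0, n_pts - k - 1)),
               argument = c(phs, rep(0, n_pts - k - 1)))
  z <- fft(Z, inverse = TRUE)
  cbind(Re(z), Im(z))
}

# Exhaustive-coupling oracle for the discrete Frechet distance (tiny inputs).
frechet_oracle <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  d <- as.matrix(dist(rbind(a, b)))[seq_len(n), n + seq_len(m), drop = FALSE]
  memo <- matrix(NA_real_, n, m)
  f <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    r <- if (i == 1 && j == 1) d[1, 1]
    else if (i == 1) max(f(1, j - 1), d[i, j])
    else if (j == 1) max(f(i - 1, 1), d[i, j])
    else max(min(f(i - 1, j), f(i - 1, j - 1), f(i, j - 1)), d[i, j])
    memo[i, j] <<- r
    r
  }
  f(n, m)
}
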