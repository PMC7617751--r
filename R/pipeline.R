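#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], with every
#' analysis parameter at its standard value (detection thresholds, band
#' edges, mask frequencies, embedding hyperparameters). Unknown keys in a
#' user-supplied configuration are rejected.
#'
#' @param ... overrides (validated against the default keys).
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    input = NULL,            # recording path; NULL = simulate
    simulate_seed = 1,
    simulate_awake = 360,    # simulated epoch durations (s)
    simulate_rest = 240,
    out_dir = "hipplamina-out",
    seed = 1,
    detect_channel = NULL,   # NULL = automatic reference-channel selection
    ref_channel = 1,
    dg_channels = NULL,      # NULL = skip dentate-spike detection
    top_ref_channel = 1,
    theta_channel = NULL,    # NULL = detect channel
    awake = NULL,            # c(start, end) seconds; NULL = whole recording
    rest = NULL,
    bands = list(ripple = c(80, 250), ripple_control = c(200, 500),
                 slow = c(20, 45), mid = c(50, 100), fast = c(100, 250)),
    mask_freqs = c(350, 200, 70, 40, 30, 7),
    gamma_freqs = exp(seq(log(18), log(310), length.out = 24)),
    n_phase_bins = 36)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown configuration keys: ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (!is.null(cfg$bands)) {
    for (b in cfg$bands) if (b[1] >= b[2]) stop("band edges must satisfy lo < hi")
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @param cfg a `pipeline_config`.
#' @return `read_pipeline_config` returns a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the laminar analysis pipeline
#'
#' Executes the stages in dependency order: ingest (or simulate), ripple
#' reference-channel selection, SWR detection, dentate-spike detection and
#' classification, theta extraction and cycle delineation, layer
#' landmarking, and a theta-gamma profile on the detection channel. Writes
#' event tables (CSV), the layer map (JSON), the theta cycles (CSV), and a
#' run manifest with all parameters and seeds.
#'
#' @param cfg a [pipeline_config()] (or a YAML path).
#' @return invisibly, a list of the produced artifact paths and results.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL
  rec <- stage("ingest", {
    if (is.null(cfg$input)) {
      sess <- generate_session(session_spec(
        seed = cfg$simulate_seed, duration_awake = cfg$simulate_awake,
        duration_rest = cfg$simulate_rest))
      truth <- sess$truth
      sess$rec
    } else read_recording(cfg$input)
  })
  fs <- rec$fs
  detect_ch <- cfg$detect_channel
  if (is.null(detect_ch))
    detect_ch <- stage("reference-channel", select_reference_channel(rec))

  swr <- stage("detect-swr", detect_swr(rec, detect_ch, cfg$ref_channel))
  swr_path <- file.path(cfg$out_dir, "swr_events.csv")
  write.csv(swr, swr_path, row.names = FALSE)

  ds <- NULL
  dg <- cfg$dg_channels
  if (is.null(dg) && !is.null(truth)) dg <- truth$dg_channels
  if (!is.null(dg)) {
    # dentate spikes are a sleep/rest phenomenon: restrict to the rest epoch
    rest <- cfg$rest
    if (is.null(rest) && !is.null(truth))
      rest <- as.numeric(truth$epochs[truth$epochs$kind == "rest",
                                      c("t_start", "t_end")])
    ds <- stage("detect-ds", {
      drec <- if (is.null(rest)) rec else crop_recording(rec, rest[1], rest[2])
      ev <- detect_dentate_spikes(drec, dg, cfg$top_ref_channel)
      ev <- classify_ds(ev, drec, pyr_ch = detect_ch, dg_deep = max(dg))
      if (!is.null(rest)) ev$t_peak <- ev$t_peak + rest[1]
      ev
    })
    write.csv(ds, file.path(cfg$out_dir, "ds_events.csv"), row.names = FALSE)
  }

  th_ch <- cfg$theta_channel %||% detect_ch
  aw <- cfg$awake
  if (is.null(aw) && !is.null(truth))
    aw <- as.numeric(truth$epochs[truth$epochs$kind == "awake",
                                  c("t_start", "t_end")])
  if (is.null(aw)) aw <- c(0, rec_duration(rec))
  seg <- rec$data[th_ch, (round(aw[1] * fs) + 1L):round(aw[2] * fs)]
  cycles <- stage("theta", {
    dec <- masked_emd(seg, fs, mask_freqs = cfg$mask_freqs)
    cy <- delineate_cycles(dec$imfs[, 6], dec$residue, fs)
    cy[, 1:5] <- cy[, 1:5] + aw[1]
    cy
  })
  write.csv(cycles, file.path(cfg$out_dir, "theta_cycles.csv"),
            row.names = FALSE)

  layers <- stage("landmark", landmark_layers(rec, swr, ds))
  jsonlite::write_json(as.list(unclass(layers)),
                       file.path(cfg$out_dir, "layers.json"),
                       auto_unbox = TRUE)

  manifest <- list(package_version = as.character(utils::packageVersion("hipplamina")),
                   r_version = R.version.string,
                   seed = cfg$seed, detect_channel = detect_ch,
                   config = unclass(cfg)[c("simulate_seed", "ref_channel",
                                           "top_ref_channel", "n_phase_bins")],
                   n_swr = nrow(swr), n_ds = if (is.null(ds)) 0L else nrow(ds),
                   n_cycles = sum(cycles$valid))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(out_dir = cfg$out_dir, rec = rec, swr = swr, ds = ds,
                 cycles = cycles, layers = layers, truth = truth))
}
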