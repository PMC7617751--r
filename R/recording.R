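#' Laminar recording container
#'
#' Bundles a channels-by-samples voltage matrix with its sampling rate and
#' per-channel electrode depths. Channel 0 convention: row 1 is the most
#' dorsal contact; depths increase ventrally along the probe.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param depths numeric vector of per-channel depths (micrometers), strictly
#'   increasing, one per row of `data`.
#' @param layer_labels optional character vector of per-channel layer names.
#' @param session_id,subject_id identifier strings.
#' @return An object of class `laminar_recording`.
#' @export
recording <- function(data, fs, depths, layer_labels = NULL,
                      session_id = "session", subject_id = "subject") {
  data <- as.matrix(data)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (nrow(data) != length(depths))
    stop("`data` has ", nrow(data), " rows but `depths` has length ",
         length(depths))
  if (any(diff(depths) <= 0))
    stop("`depths` must be strictly increasing (dorsal to ventral)")
  if (anyNA(data))
    stop("voltage matrix contains NA/NaN")
  if (!is.null(layer_labels) && length(layer_labels) != nrow(data))
    stop("`layer_labels` length must match channel count")
  structure(
    list(data = data, fs = fs, depths = as.numeric(depths),
         layer_labels = layer_labels,
         session_id = session_id, subject_id = subject_id),
    class = "laminar_recording")
}

#' @export
print.laminar_recording <- function(x, ...) {
  cat(sprintf("<laminar_recording> %s / %s\n", x$subject_id, x$session_id))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  depths %g-%g um (spacing %g um)\n",
              min(x$depths), max(x$depths), median(diff(x$depths))))
  invisible(x)
}

#' Number of channels / duration helpers
#' @param rec a `laminar_recording`.
#' @return integer channel count or duration in seconds.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' Median channel spacing of a recording (micrometers)
#' @param rec a `laminar_recording`.
#' @export
rec_spacing <- function(rec) median(diff(rec$depths))

#' Read / write a laminar recording
#'
#' The on-disk layout is a serialized list (`lfp` float matrix, `depths`,
#' `fs`, identifiers, optional `layer_labels`) plus a JSON sidecar
#' (`<path>.json`) mirroring the scalar metadata. The round trip is lossless;
#' schema violations (missing `lfp`/`fs`/`depths`, non-monotonic depths) are
#' errors.
#'
#' @param rec a `laminar_recording`.
#' @param path file path (conventionally `.lamrec`).
#' @return `read_recording` returns a `laminar_recording`; `write_recording`
#'   returns `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "laminar_recording"))
  payload <- list(lfp = rec$data, fs = rec$fs, depths = rec$depths,
                  layer_labels = rec$layer_labels,
                  session_id = rec$session_id, subject_id = rec$subject_id)
  saveRDS(payload, path)
  sidecar <- list(fs = rec$fs, session_id = rec$session_id,
                  subject_id = rec$subject_id,
                  n_channels = nrow(rec$data), n_samples = ncol(rec$data))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  payload <- readRDS(path)
  if (!is.list(payload) || is.null(payload$lfp))
    stop("schema error: file has no `lfp` dataset")
  for (field in c("fs", "depths"))
    if (is.null(payload[[field]]))
      stop("schema error: missing `", field, "`")
  recording(payload$lfp, payload$fs, payload$depths,
            layer_labels = payload$layer_labels,
            session_id = payload$session_id %||% "session",
            subject_id = payload$subject_id %||% "subject")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Crop a recording to a time interval
#'
#' Returns the samples in `[t_start, t_end)`; useful for restricting
#' analyses to behavioural epochs (e.g. dentate-spike detection runs on
#' sleep/rest only). Event times measured on the cropped recording are
#' relative to `t_start`.
#'
#' @param rec a `laminar_recording`.
#' @param t_start,t_end interval bounds in seconds.
#' @return a `laminar_recording` with the same channel metadata.
#' @export
crop_recording <- function(rec, t_start, t_end) {
  i0 <- max(1L, round(t_start * rec$fs) + 1L)
  i1 <- min(ncol(rec$data), round(t_end * rec$fs))
  if (i1 <= i0) stop("empty crop interval")
  recording(rec$data[, i0:i1, drop = FALSE], rec$fs, rec$depths,
            layer_labels = rec$layer_labels,
            session_id = rec$session_id, subject_id = rec$subject_id)
}
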