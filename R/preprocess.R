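# Preprocessing chain: resample -> average re-reference -> epoch -> baseline.

#' Resample a continuous session
#'
#' Anti-aliased polyphase resampling to `target_fs` (downsampling only).
#' The rate ratio must be rational; the signal is zero-stuffed by the
#' upsampling factor, low-pass filtered with a windowed-sinc (Hamming) FIR
#' at the target Nyquist frequency with exact group-delay compensation and
#' reflect padding, then decimated. Event sample indices are rescaled by the
#' rate ratio with round-half-even.
#'
#' @param raw A [raw_session()].
#' @param target_fs Target rate in Hz, `<= raw$fs`.
#' @return A [raw_session()] at `target_fs`. If `target_fs == raw$fs` the
#'   input is returned unchanged.
#' @export
resample <- function(raw, target_fs) {
  stopifnot(inherits(raw, "raw_session"))
  if (target_fs > raw$fs) {
    stopf("upsampling (%g -> %g Hz) is not supported", raw$fs, target_fs)
  }
  if (target_fs == raw$fs) return(raw)
  # rational approximation of the ratio
  ratio <- target_fs / raw$fs
  frac <- .rational(ratio)
  L <- frac[1]; M <- frac[2]
  n <- ncol(raw$data)
  x <- t(raw$data)  # samples x channels
  if (L > 1) {
    up <- matrix(0, n * L, ncol(x))
    up[seq(1, n * L, by = L), ] <- x
    x <- up
  }
  fs_up <- raw$fs * L
  cutoff <- min(raw$fs / 2, target_fs / 2)
  numtaps <- 2 * ceiling(8 * fs_up / cutoff / 2) + 1
  taps <- L * signal::fir1(numtaps - 1, cutoff / (fs_up / 2))
  y <- fir_filtfft(x, taps)
  y <- y[seq(1, nrow(y), by = M), , drop = FALSE]
  events <- raw$events
  if (nrow(events) > 0) {
    events$sample <- as.integer(round((events$sample - 1) * ratio) + 1)
  }
  raw_session(t(y), target_fs, raw$channel_names, events,
              participant_id = raw$participant_id,
              provenance = c(raw$provenance,
                             list(resampled_from = raw$fs)))
}

# Small-denominator rational approximation p/q of x (q <= 1000).
.rational <- function(x, max_den = 1000) {
  for (q in seq_len(max_den)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stopf("rate ratio %g is not rational within denominator %d", x, max_den)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean over all channels from every channel.
#'
#' @param raw A [raw_session()] with at least two channels.
#' @return A [raw_session()] whose channel mean is zero at every sample.
#' @export
rereference_average <- function(raw) {
  stopifnot(inherits(raw, "raw_session"))
  if (nrow(raw$data) < 2) stopf("average re-reference needs >= 2 channels")
  data <- sweep(raw$data, 2, colMeans(raw$data))
  raw_session(data, raw$fs, raw$channel_names, raw$events,
              participant_id = raw$participant_id,
              provenance = c(raw$provenance, list(reference = "average")))
}

#' Extract epochs around imagery onsets
#'
#' Cuts a half-open window `[t_start, t_end)` (seconds, relative to each
#' event) from the recording: samples `onset + round(t_start * fs)` up to
#' but excluding `onset + round(t_end * fs)`. At 250 Hz the default window
#' `[-0.5, 4.0)` yields 1125 samples per epoch. Task labels come from the
#' events; block indices and self-evaluation categories are joined from the
#' session plan and subjective data when supplied.
#'
#' @param raw A [raw_session()].
#' @param window Length-2 numeric, `[t_start, t_end)` in seconds.
#' @param plan Optional [make_session_plan()] for block indices.
#' @param subjective Optional [simulate_subjective()] result for per-trial
#'   self-evaluation categories.
#' @return An object of class `epoch_set`: `data` (trials x channels x
#'   samples array), `fs`, `window`, `labels` (factor), `block`,
#'   `self_eval`, `channel_names`, `participant_id`.
#' @export
extract_epochs <- function(raw, window = c(-0.5, 4.0), plan = NULL,
                           subjective = NULL) {
  stopifnot(inherits(raw, "raw_session"))
  if (window[1] >= window[2]) {
    stopf("epoch window must satisfy t_start < t_end, got [%g, %g)",
          window[1], window[2])
  }
  fs <- raw$fs
  off0 <- round(window[1] * fs)
  off1 <- round(window[2] * fs)
  n_samp <- off1 - off0
  ev <- raw$events
  if (nrow(ev) == 0) stopf("no events to epoch")
  first <- ev$sample + off0
  last <- ev$sample + off1 - 1
  bad <- which(first < 1 | last > ncol(raw$data))
  if (length(bad) > 0) {
    stopf("epoch window out of bounds for trial(s): %s",
          paste(utils::head(bad, 10), collapse = ", "))
  }
  n_tr <- nrow(ev)
  n_ch <- nrow(raw$data)
  data <- array(NA_real_, c(n_tr, n_ch, n_samp))
  for (i in seq_len(n_tr)) {
    data[i, , ] <- raw$data[, first[i]:last[i]]
  }
  labels <- factor(ev$label, levels = unique(ev$label))
  block <- rep(NA_integer_, n_tr)
  if (!is.null(plan)) {
    if (nrow(plan$trials) != n_tr) {
      stopf("plan has %d trials but session has %d events",
            nrow(plan$trials), n_tr)
    }
    if (!all(plan$trials$code == ev$code)) {
      stopf("plan and event marker codes disagree")
    }
    block <- plan$trials$block
    labels <- factor(ev$label, levels = plan$task_names)
  }
  self_eval <- factor(rep(NA_character_, n_tr),
                      levels = c("correct", "not_correct",
                                 "correct_not_well"))
  if (!is.null(subjective)) {
    if (length(subjective$self_eval) != n_tr) {
      stopf("subjective data covers %d trials but session has %d",
            length(subjective$self_eval), n_tr)
    }
    self_eval <- subjective$self_eval
  }
  structure(
    list(data = data, fs = fs, window = as.numeric(window),
         labels = labels, block = block, self_eval = self_eval,
         channel_names = raw$channel_names,
         participant_id = raw$participant_id),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %s: %d trials x %d ch x %d samples @ %g Hz, window [%g, %g)\n",
    x$participant_id, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
    x$fs, x$window[1], x$window[2]))
  print(table(x$labels))
  invisible(x)
}

#' Whole-epoch baseline correction
#'
#' Subtracts, per trial and channel, the mean over the full epoch window.
#' (A conventional pre-stimulus-only baseline is available via
#' `baseline = "prestim"`, which uses only samples before the imagery
#' onset; the whole-epoch rule is the default.)
#'
#' @param epochs An [extract_epochs()] result.
#' @param baseline `"whole"` (default) or `"prestim"`.
#' @return The `epoch_set` with per-(trial, channel) means removed.
#' @export
baseline_correct <- function(epochs, baseline = c("whole", "prestim")) {
  stopifnot(inherits(epochs, "epoch_set"))
  baseline <- match.arg(baseline)
  d <- epochs$data
  idx <- if (baseline == "whole") {
    seq_len(dim(d)[3])
  } else {
    if (epochs$window[1] >= 0) stopf("no pre-onset samples in this window")
    seq_len(round(-epochs$window[1] * epochs$fs))
  }
  m <- apply(d[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- d - as.vector(m)  # recycles over the 3rd dimension
  epochs
}

#' Run the full preprocessing chain
#'
#' Fixed order: resample to the working rate, re-reference to the common
#' average, extract epochs, baseline-correct over the whole epoch.
#'
#' @param raw A [raw_session()].
#' @param analysis Analysis settings ([analysis_defaults()]).
#' @param plan,subjective Passed to [extract_epochs()].
#' @return An `epoch_set`.
#' @export
preprocess <- function(raw, analysis = analysis_defaults(), plan = NULL,
                       subjective = NULL) {
  raw <- resample(raw, analysis$target_fs)
  raw <- rereference_average(raw)
  epochs <- extract_epochs(raw, analysis$epoch_window, plan = plan,
                           subjective = subjective)
  baseline_correct(epochs)
}

#' Serialize an epoch set to a binary array plus TSV sidecar
#'
#' Writes `<basepath>.dat` (float32, trial-major), `<basepath>.json`
#' (dimensions and metadata) and `<basepath>.tsv` (per-trial labels).
#'
#' @param epochs An `epoch_set`.
#' @param basepath Output path without extension.
#' @return Invisibly, the file paths.
#' @export
write_epochs <- function(epochs, basepath) {
  stopifnot(inherits(epochs, "epoch_set"))
  hdr <- list(dim = dim(epochs$data), fs = epochs$fs,
              window = epochs$window, channel_names = epochs$channel_names,
              participant_id = epochs$participant_id)
  jsonlite::write_json(hdr, paste0(basepath, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(basepath, ".dat"), "wb")
  writeBin(as.vector(epochs$data), con, size = 4, endian = "little")
  close(con)
  utils::write.table(
    data.frame(trial = seq_along(epochs$labels),
               label = as.character(epochs$labels),
               block = epochs$block,
               self_eval = as.character(epochs$self_eval)),
    paste0(basepath, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paste0(basepath, c(".dat", ".json", ".tsv")))
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param basepath Path without extension.
#' @return An `epoch_set` (data at float32 precision).
#' @export
read_epochs <- function(basepath) {
  hdr <- jsonlite::read_json(paste0(basepath, ".json"), simplifyVector = TRUE)
  dims <- as.integer(hdr$dim)
  con <- file(paste0(basepath, ".dat"), "rb")
  vals <- readBin(con, "numeric", n = prod(dims), size = 4, endian = "little")
  close(con)
  meta <- utils::read.table(paste0(basepath, ".tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  structure(
    list(data = array(vals, dims), fs = hdr$fs, window = hdr$window,
         labels = factor(meta$label, levels = unique(meta$label)),
         block = meta$block,
         self_eval = factor(meta$self_eval,
                            levels = c("correct", "not_correct",
                                       "correct_not_well")),
         channel_names = hdr$channel_names,
         participant_id = hdr$participant_id),
    class = "epoch_set"
  )
}
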