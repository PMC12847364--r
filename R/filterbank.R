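# Filter-bank decomposition of epoched EEG.

#' Filter-bank specification
#'
#' Defaults to the nine non-overlapping 4 Hz bands covering 4-40 Hz
#' (4-8, 8-12, ..., 36-40 Hz), realized as symmetric linear-phase FIR
#' bandpass filters (windowed-sinc, Hamming window, 251 taps).
#'
#' @param bands List of `c(low, high)` pairs in Hz; must be ascending and
#'   non-overlapping.
#' @param numtaps Odd filter length.
#' @return An object of class `filterbank_spec`.
#' @export
filterbank_spec <- function(bands = analysis_defaults()$bands,
                            numtaps = 251) {
  if (!is_count(numtaps) || numtaps %% 2 == 0) {
    stopf("numtaps must be an odd positive integer")
  }
  prev_high <- 0
  for (b in bands) {
    if (length(b) != 2 || b[1] <= 0 || b[1] >= b[2]) {
      stopf("each band must be c(low, high) with 0 < low < high")
    }
    if (b[1] < prev_high) stopf("bands must be ascending and non-overlapping")
    prev_high <- b[2]
  }
  structure(list(bands = lapply(bands, as.numeric),
                 numtaps = as.integer(numtaps),
                 design = "windowed-sinc (Hamming)"),
            class = "filterbank_spec")
}

#' Design the filter-bank coefficients
#'
#' One symmetric (linear-phase) FIR bandpass per band. Designed responses
#' stay above -6 dB on `[low+1, high-1]` Hz and below -20 dB at `low-2` and
#' `high+2` Hz with the default 251 taps at 250 Hz.
#'
#' @param spec A [filterbank_spec()].
#' @param fs Sampling rate the filters will run at, in Hz.
#' @return An object of class `filter_bank`: list with `taps` (list of
#'   coefficient vectors), `bands`, `fs`, `numtaps`.
#' @export
design_filterbank <- function(spec = filterbank_spec(), fs = 250) {
  stopifnot(inherits(spec, "filterbank_spec"))
  nyq <- fs / 2
  taps <- lapply(spec$bands, function(b) {
    if (b[2] >= nyq) {
      stopf("band [%g, %g] Hz exceeds the Nyquist frequency %g Hz",
            b[1], b[2], nyq)
    }
    signal::fir1(spec$numtaps - 1, b / nyq, type = "pass")
  })
  structure(list(taps = taps, bands = spec$bands, fs = fs,
                 numtaps = spec$numtaps),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %d bands (%g-%g Hz), %d taps @ %g Hz\n",
              length(x$bands), x$bands[[1]][1],
              x$bands[[length(x$bands)]][2], x$numtaps, x$fs))
  invisible(x)
}

#' Apply the filter bank to an epoch set
#'
#' Filters every epoch with each band's FIR via FFT convolution with
#' reflect padding and exact group-delay compensation, then crops the
#' output to the analysis window `[0, crop_s)` seconds after the imagery
#' onset — the pre-onset part of the epoch serves as edge padding rather
#' than entering the analysis. With the defaults (1125-sample epochs at
#' 250 Hz, 4 s analysis window) each band output has 1000 samples.
#'
#' @param epochs An `epoch_set`.
#' @param bank A [design_filterbank()] result at the epochs' rate.
#' @param crop_s Analysis-window length in seconds after onset; defaults to
#'   the epoch's post-onset extent.
#' @return An object of class `band_epochs`: `data` (trials x channels x
#'   samples x bands array), `bands`, `fs`, `labels` and trial metadata
#'   carried over from the epochs.
#' @export
apply_filterbank <- function(epochs, bank, crop_s = NULL) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(bank, "filter_bank"))
  if (abs(bank$fs - epochs$fs) > 1e-9) {
    stopf("filter bank designed for %g Hz but epochs are at %g Hz",
          bank$fs, epochs$fs)
  }
  d <- epochs$data
  n_tr <- dim(d)[1]; n_ch <- dim(d)[2]; n_samp <- dim(d)[3]
  if (n_samp < bank$numtaps) {
    stopf("epoch length %d shorter than filter length %d", n_samp,
          bank$numtaps)
  }
  fs <- epochs$fs
  if (is.null(crop_s)) crop_s <- epochs$window[2]
  onset_idx <- round(-epochs$window[1] * fs) + 1
  n_out <- round(crop_s * fs)
  if (onset_idx + n_out - 1 > n_samp) {
    stopf("analysis window [0, %g) s exceeds the epoch extent", crop_s)
  }
  # samples x (trial*channel) matrix for one-pass FFT filtering; the
  # forward FFT is shared across all bands
  x <- matrix(aperm(d, c(3, 1, 2)), nrow = n_samp)
  out <- array(NA_real_, c(n_tr, n_ch, n_out, length(bank$bands)))
  keep <- onset_idx:(onset_idx + n_out - 1)
  ys <- fir_filtfft_multi(x, bank$taps)
  for (b in seq_along(bank$taps)) {
    y <- ys[[b]][keep, , drop = FALSE]
    out[, , , b] <- aperm(array(y, c(n_out, n_tr, n_ch)), c(2, 3, 1))
  }
  structure(
    list(data = out, bands = bank$bands, fs = fs, labels = epochs$labels,
         block = epochs$block, self_eval = epochs$self_eval,
         channel_names = epochs$channel_names,
         participant_id = epochs$participant_id),
    class = "band_epochs"
  )
}

#' @export
print.band_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<band_epochs> %d trials x %d ch x %d samples x %d bands\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

# Per-trial, per-band sample covariance matrices of band-filtered epochs:
# array [n_ch, n_ch, n_trials, n_bands]. All CSP fitting and log-variance
# feature extraction are quadratic forms in these, so computing them once
# per dataset makes fold-wise refitting cheap without any leakage (the
# covariances are label-free).
band_covariances <- function(band_epochs) {
  stopifnot(inherits(band_epochs, "band_epochs"))
  d <- band_epochs$data
  n_tr <- dim(d)[1]; n_ch <- dim(d)[2]; n_samp <- dim(d)[3]
  n_bands <- dim(d)[4]
  covs <- array(NA_real_, c(n_ch, n_ch, n_tr, n_bands))
  for (b in seq_len(n_bands)) {
    for (i in seq_len(n_tr)) {
      xi <- matrix(d[i, , , b], nrow = n_ch)
      covs[, , i, b] <- tcrossprod(xi) / (n_samp - 1)
    }
  }
  structure(list(covs = covs, bands = band_epochs$bands,
                 labels = band_epochs$labels,
                 block = band_epochs$block,
                 self_eval = band_epochs$self_eval,
                 channel_names = band_epochs$channel_names,
                 participant_id = band_epochs$participant_id),
            class = "band_covs")
}
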