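# Synthetic continuous EEG generation.

# Unit-variance Gaussian noise band-limited to [low, high] Hz by hard
# spectral masking. Returns a length-n vector. Generated at a
# power-of-two FFT length and truncated, for speed.
band_noise <- function(n, fs, band) {
  nfft <- stats::nextn(n, 2)
  x <- stats::rnorm(nfft)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = nfft + 1)[seq_len(nfft)]
  f <- pmin(f, fs - f)  # two-sided frequency axis
  mask <- f >= band[1] & f <= band[2]
  if (!any(mask)) stopf("band [%g, %g] Hz empty at fs=%g, n=%d",
                        band[1], band[2], fs, n)
  X[!mask] <- 0
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / nfft
  (y - mean(y)) / stats::sd(y)
}

# 1/f^exponent background noise, unit variance. Spectrum flattened below
# 1 Hz to avoid a drift-dominated trace.
pink_noise <- function(n, fs, exponent = 1) {
  nfft <- stats::nextn(n, 2)
  x <- stats::rnorm(nfft)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = nfft + 1)[seq_len(nfft)]
  f <- pmin(f, fs - f)
  amp <- pmax(f, 1)^(-exponent / 2)
  amp[1] <- 0  # no DC
  y <- Re(stats::fft(X * amp, inverse = TRUE))[seq_len(n)] / nfft
  (y - mean(y)) / stats::sd(y)
}

#' Construct a continuous-EEG container
#'
#' Validates and wraps a channels x samples matrix with its metadata. Used
#' by the simulator and the BrainVision reader; all preprocessing operations
#' consume and return this class.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one per row of `data`.
#' @param events data.frame with columns `sample` (1-based), `code`
#'   (integer), `label` (character); sorted by `sample`.
#' @param participant_id Identifier string.
#' @param provenance Free-form metadata list.
#' @return An object of class `raw_session`.
#' @export
raw_session <- function(data, fs, channel_names, events,
                        participant_id = "P01", provenance = list()) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stopf("raw data contains NaN/Inf")
  if (length(channel_names) != nrow(data)) {
    stopf("channel_names length (%d) != channel count (%d)",
          length(channel_names), nrow(data))
  }
  if (nrow(events) > 0) {
    if (is.unsorted(events$sample)) stopf("events must be sorted by sample")
    if (any(events$sample < 1) || any(events$sample > ncol(data))) {
      stopf("event sample indices must lie within the recording")
    }
  }
  structure(
    list(data = data, fs = fs, channel_names = as.character(channel_names),
         events = events, participant_id = participant_id,
         provenance = provenance),
    class = "raw_session"
  )
}

#' @export
print.raw_session <- function(x, ...) {
  cat(sprintf("<raw_session> %s: %d ch x %d samples @ %g Hz, %d events\n",
              x$participant_id, nrow(x$data), ncol(x$data), x$fs,
              nrow(x$events)))
  invisible(x)
}

#' Simulate a continuous EEG session
#'
#' Generates multichannel EEG realizing a session plan under the signal
#' model of [sim_config()]: fixed smooth topographies mixing band-limited
#' Gaussian sources whose variance is gated during each trial's imagery
#' window, plus a common posterior alpha rhythm and per-channel 1/f noise.
#' Event markers are embedded at every imagery onset with the task's code.
#'
#' @param plan A [make_session_plan()] result.
#' @param sim A [sim_config()].
#' @param trial_gain Optional per-trial multiplier on the effect size
#'   (length `nrow(plan$trials)`), used to couple self-evaluation flags to
#'   signal quality; defaults to 1 for every trial.
#' @param seed Integer seed (defaults to `sim$seed`); output is a
#'   deterministic function of `(plan, sim, trial_gain, seed)`.
#' @param participant_id Identifier stored in the session.
#' @return A [raw_session()].
#' @export
#' @examples
#' cfg <- protocol_config(task_names = c("L", "R"),
#'                        trials_per_task_per_block = 2, n_blocks = 1,
#'                        fs = 100, n_channels = 4)
#' raw <- simulate_raw(make_session_plan(cfg, 1), sim_config(seed = 1))
simulate_raw <- function(plan, sim, trial_gain = NULL, seed = sim$seed,
                         participant_id = "P01") {
  stopifnot(inherits(plan, "session_plan"), inherits(sim, "sim_config"))
  cfg <- plan$cfg
  trials <- plan$trials
  n <- plan$n_samples
  fs <- plan$fs
  if (is.null(trial_gain)) trial_gain <- rep(1, nrow(trials))
  if (length(trial_gain) != nrow(trials)) {
    stopf("trial_gain must have one entry per trial")
  }
  montage <- montage_1010(cfg$n_channels)
  topo <- .task_topographies(montage, sim)
  active <- setdiff(unique(trials$task), "REST")
  unknown <- setdiff(active, colnames(topo))
  if (length(unknown) > 0) {
    stopf("unknown task label(s) in plan: %s", paste(unknown, collapse = ", "))
  }
  with_seed(seed, {
    n_ch <- cfg$n_channels
    # background: per-channel 1/f noise
    data <- matrix(0, n_ch, n)
    for (ch in seq_len(n_ch)) {
      data[ch, ] <- sim$noise_sd * pink_noise(n, fs, sim$noise_exponent)
    }
    # common posterior alpha source
    alpha_topo <- .topography(montage, c(0, -0.85), sim$kernel_sigma)
    data <- data + outer(alpha_topo, sim$alpha_amp * band_noise(n, fs, c(8, 12)))
    # task-gated band-limited sources
    task_len <- round(cfg$task_s * fs)
    g0 <- sim$effect_size * sim$participant_scale
    for (task in active) {
      depth <- if (task == "SInoKin") sim$sinokin_depth else 1
      sig <- numeric(n)
      rows <- which(trials$task == task)
      for (comp in sim$band_modulation) {
        src <- band_noise(n, fs, comp$band)
        env <- rep(1, n)
        for (i in rows) {
          idx <- trials$onset[i]:min(n, trials$onset[i] + task_len - 1)
          scale2 <- 1 + g0 * trial_gain[i] * depth * comp$m
          env[idx] <- sqrt(pmax(scale2, 0.02))
        }
        sig <- sig + src * env
      }
      data <- data + outer(topo[, task], sim$source_amp * sig)
    }
    events <- data.frame(sample = trials$onset,
                         code = trials$code,
                         label = trials$task,
                         stringsAsFactors = FALSE)
    raw_session(data, fs, montage$label, events,
                participant_id = participant_id,
                provenance = list(generator = "imagerybci::simulate_raw",
                                  seed = as.integer(seed),
                                  effect_size = sim$effect_size,
                                  config_hash = config_hash(list(cfg, sim))))
  })
}
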