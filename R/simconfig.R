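# Configuration of the synthetic EEG signal model.

#' Signal-model configuration for the synthetic session generator
#'
#' The generator follows the standard CSP-friendly generative picture:
#' band-limited Gaussian sources mixed instantaneously through fixed smooth
#' topographies, on top of 1/f background noise and a common posterior alpha
#' rhythm. Each non-rest task owns one source whose band-wise variance is
#' gated during that task's 4-s imagery windows: in band `b` the source
#' variance is scaled by `(1 + g * m_b)`, where `g = effect_size` and `m_b`
#' is the signed band modulation (negative = event-related
#' desynchronization). With `effect_size = 0` every task's data distribution
#' is identical by construction, which makes the generator usable as a
#' leakage detector for the decoding pipeline.
#'
#' Task confusability is controlled by two knobs mirroring the physiological
#' expectation that kinesthetic singing imagery shares articulatory cortex
#' with tongue imagery: `overlap_alpha` mixes the kinesthetic-singing
#' topography toward the tongue topography (1 = identical maps), and
#' `sinokin_depth` scales the modulation depth of non-kinesthetic singing
#' imagery (small values push it toward rest).
#'
#' @param effect_size Dimensionless modulation depth `g >= 0`.
#' @param band_modulation Named list of band components shared by all active
#'   tasks: each element `list(band = c(low, high), m = <signed fraction>)`.
#'   Defaults modulate the mu and beta rhythms downward (ERD).
#' @param overlap_alpha Fraction in `[0, 1]`; topographic overlap between the
#'   tongue and kinesthetic-singing sources.
#' @param sinokin_depth Relative modulation depth (`>= 0`) of the
#'   non-kinesthetic singing task.
#' @param source_amp Source standard deviation at rest, in microvolts.
#' @param noise_sd Per-channel 1/f background standard deviation (microvolts).
#' @param noise_exponent Spectral exponent of the background (power ~
#'   `1/f^exponent`).
#' @param alpha_amp Amplitude of the common posterior ~10 Hz source
#'   (microvolts).
#' @param participant_scale Per-participant multiplier on `effect_size`,
#'   emulating inter-participant variability.
#' @param kernel_sigma Spatial width of the Gaussian topography kernels.
#' @param self_eval_probs Named probabilities of the three self-evaluation
#'   answers (`correct`, `not_correct`, `correct_not_well`); must sum to 1.
#' @param self_eval_mode `"informative"` (flagged trials are generated with
#'   reduced or zero effect size) or `"uninformative"` (flags independent of
#'   the signal).
#' @param weak_gain Effect-size multiplier for `correct_not_well` trials in
#'   informative mode (`not_correct` trials get 0).
#' @param kviq_effect_cor Correlation between simulated questionnaire scores
#'   and the participant's effect-size multiplier.
#' @param seed Default integer seed for the simulation operations.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(effect_size = 1.0,
                       band_modulation = list(
                         mu = list(band = c(8, 12), m = -0.75),
                         beta = list(band = c(18, 26), m = -0.55)),
                       overlap_alpha = 0.6,
                       sinokin_depth = 0.6,
                       source_amp = 5,
                       noise_sd = 8,
                       noise_exponent = 1,
                       alpha_amp = 4,
                       participant_scale = 1,
                       kernel_sigma = 0.35,
                       self_eval_probs = c(correct = 0.8,
                                           not_correct = 0.05,
                                           correct_not_well = 0.15),
                       self_eval_mode = c("uninformative", "informative"),
                       weak_gain = 0.5,
                       kviq_effect_cor = 0,
                       seed = 1L) {
  self_eval_mode <- match.arg(self_eval_mode)
  if (!is.numeric(effect_size) || effect_size < 0) {
    stopf("effect_size must be >= 0")
  }
  if (overlap_alpha < 0 || overlap_alpha > 1) {
    stopf("overlap_alpha must lie in [0, 1]")
  }
  if (sinokin_depth < 0) stopf("sinokin_depth must be >= 0")
  for (comp in band_modulation) {
    if (length(comp$band) != 2 || comp$band[1] >= comp$band[2]) {
      stopf("each band_modulation component needs band = c(low, high)")
    }
    if (comp$m <= -1) stopf("band modulation m must exceed -1")
  }
  need <- c("correct", "not_correct", "correct_not_well")
  if (!setequal(names(self_eval_probs), need)) {
    stopf("self_eval_probs must be named: %s", paste(need, collapse = ", "))
  }
  if (abs(sum(self_eval_probs) - 1) > 1e-8 || any(self_eval_probs < 0)) {
    stopf("self_eval_probs must be non-negative and sum to 1")
  }
  structure(
    list(effect_size = effect_size,
         band_modulation = band_modulation,
         overlap_alpha = overlap_alpha,
         sinokin_depth = sinokin_depth,
         source_amp = source_amp,
         noise_sd = noise_sd,
         noise_exponent = noise_exponent,
         alpha_amp = alpha_amp,
         participant_scale = participant_scale,
         kernel_sigma = kernel_sigma,
         self_eval_probs = self_eval_probs[need],
         self_eval_mode = self_eval_mode,
         weak_gain = weak_gain,
         kviq_effect_cor = kviq_effect_cor,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> g=%g (participant x%g), overlap_alpha=%g, sinokin_depth=%g, %s self-eval\n",
    x$effect_size, x$participant_scale, x$overlap_alpha, x$sinokin_depth,
    x$self_eval_mode))
  invisible(x)
}

# Source centers on the schematic montage plane. Left-hand imagery modulates
# the contralateral (right) motor cortex and vice versa; feet imagery is
# midline-central; tongue imagery is bilateral inferior fronto-temporal;
# the singing-specific source is left-lateralized inferior frontal/temporal.
.task_source_centers <- function() {
  list(
    L = c(0.45, 0.0),
    R = c(-0.45, 0.0),
    F = c(0.0, 0.12),
    T = matrix(c(-0.9, 0.25, 0.9, 0.25), ncol = 2, byrow = TRUE),
    SI = matrix(c(-0.55, 0.55, -1.05, -0.45), ncol = 2, byrow = TRUE)
  )
}

# Per-task topography vectors (n_channels x n_sources), with the
# kinesthetic-singing map mixed toward the tongue map by overlap_alpha.
.task_topographies <- function(montage, sim) {
  ctr <- .task_source_centers()
  topo <- sapply(ctr, function(cc) .topography(montage, cc, sim$kernel_sigma))
  si_kin <- (1 - sim$overlap_alpha) * topo[, "SI"] +
    sim$overlap_alpha * topo[, "T"]
  si_kin <- si_kin / sqrt(sum(si_kin^2))
  cbind(L = topo[, "L"], R = topo[, "R"], F = topo[, "F"], T = topo[, "T"],
        SIkin = si_kin, SInoKin = topo[, "SI"])
}
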