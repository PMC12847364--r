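# Simulated subjective data: self-evaluation, questionnaire, preferences.

#' Simulate per-trial self-evaluation and questionnaire data
#'
#' Draws, for every trial of the plan, one of the three self-evaluation
#' answers ("I performed it correctly" / "I did not perform it correctly" /
#' "I performed it correctly but not very well") with the probabilities in
#' `sim$self_eval_probs`. In `"informative"` mode the answers are causally
#' linked to signal quality: the returned `trial_gain` is 0 for
#' `not_correct` trials and `sim$weak_gain` for `correct_not_well` trials,
#' and feeding it to [simulate_raw()] generates those trials with reduced or
#' absent task modulation. In `"uninformative"` mode `trial_gain` is 1
#' everywhere, so the flags carry no information about the signal.
#'
#' Also simulates a short imagery questionnaire (visual and kinesthetic
#' subscales, five 1-5 items each), per-task difficulty ratings after blocks
#' 1, 4 and 7 (or the nearest existing blocks), and the three preference
#' answers. Questionnaire scores are drawn with correlation
#' `sim$kviq_effect_cor` to the participant's effect-size multiplier.
#'
#' @param plan A [make_session_plan()] result.
#' @param sim A [sim_config()].
#' @param seed Integer seed (defaults to `sim$seed + 1`).
#' @return An object of class `subjective_data` with fields `self_eval`
#'   (factor per trial), `trial_gain`, `kviq_visual`, `kviq_kinesthetic`,
#'   `kviq_total`, `difficulty` (task x rated-block matrix), `preference`
#'   (list) and `mode`.
#' @export
simulate_subjective <- function(plan, sim, seed = sim$seed + 1L) {
  stopifnot(inherits(plan, "session_plan"), inherits(sim, "sim_config"))
  probs <- sim$self_eval_probs
  if (abs(sum(probs) - 1) > 1e-8) stopf("self_eval_probs must sum to 1")
  levels <- c("correct", "not_correct", "correct_not_well")
  n_tr <- nrow(plan$trials)
  with_seed(seed, {
    self_eval <- factor(sample(levels, n_tr, replace = TRUE, prob = probs),
                        levels = levels)
    trial_gain <- if (sim$self_eval_mode == "informative") {
      c(correct = 1, not_correct = 0,
        correct_not_well = sim$weak_gain)[as.character(self_eval)]
    } else {
      rep(1, n_tr)
    }
    # questionnaire: 5 items per subscale, 1..5 each, correlated with the
    # participant's effect-size multiplier through a shared latent
    rho <- sim$kviq_effect_cor
    latent_p <- (sim$participant_scale - 1)  # 0 for an average participant
    draw_scale <- function() {
      z <- rho * latent_p + sqrt(max(0, 1 - rho^2)) * stats::rnorm(1)
      items <- round(3 + z + 0.8 * stats::rnorm(5))
      sum(pmin(pmax(items, 1), 5))
    }
    kviq_visual <- draw_scale()
    kviq_kin <- draw_scale()
    rated <- intersect(c(1, 4, 7), seq_len(max(plan$trials$block)))
    if (length(rated) == 0) rated <- 1
    difficulty <- matrix(
      pmin(pmax(round(2 + stats::rnorm(length(plan$task_names) *
                                         length(rated), sd = 0.9)), 1), 5),
      nrow = length(plan$task_names),
      dimnames = list(plan$task_names, paste0("block", rated)))
    non_rest <- setdiff(plan$task_names, "REST")
    preference <- list(
      top4 = sample(non_rest, min(4, length(non_rest))),
      t_vs_si = sample(c("T", "SI"), 1, prob = c(0.1, 0.9)),
      sikin_vs_sinokin = sample(c("SIkin", "SInoKin"), 1,
                                prob = c(0.6, 0.4))
    )
    structure(
      list(self_eval = self_eval,
           trial_gain = as.numeric(trial_gain),
           kviq_visual = kviq_visual,
           kviq_kinesthetic = kviq_kin,
           kviq_total = kviq_visual + kviq_kin,
           difficulty = difficulty,
           preference = preference,
           mode = sim$self_eval_mode,
           participant_id = NA_character_),
      class = "subjective_data"
    )
  })
}

#' @export
print.subjective_data <- function(x, ...) {
  tab <- table(x$self_eval)
  cat(sprintf(
    "<subjective_data> %d trials (%s); KVIQ v=%d k=%d; mode=%s\n",
    length(x$self_eval),
    paste(names(tab), tab, sep = "=", collapse = ", "),
    x$kviq_visual, x$kviq_kinesthetic, x$mode))
  invisible(x)
}

#' Simulate a full session: plan, subjective data and raw EEG
#'
#' Convenience wrapper wiring [make_session_plan()],
#' [simulate_subjective()] and [simulate_raw()] together with a single seed.
#' In informative self-evaluation mode the subjective trial gains are passed
#' through to the raw-EEG generator.
#'
#' @param cfg A [protocol_config()].
#' @param sim A [sim_config()].
#' @param seed Integer seed; sub-seeds are derived with [derive_seed()].
#' @param participant_id Identifier string.
#' @return List with elements `plan`, `subjective`, `raw`.
#' @export
simulate_session <- function(cfg, sim, seed = sim$seed,
                             participant_id = "P01") {
  plan <- make_session_plan(cfg, derive_seed(seed, "plan"))
  subjective <- simulate_subjective(plan, sim, derive_seed(seed, "subjective"))
  subjective$participant_id <- participant_id
  raw <- simulate_raw(plan, sim, trial_gain = subjective$trial_gain,
                      seed = derive_seed(seed, "raw"),
                      participant_id = participant_id)
  list(plan = plan, subjective = subjective, raw = raw)
}
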