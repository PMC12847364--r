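# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Reduced 7-task protocol: 10 trials/class in one block, 16 channels,
# simulated directly at the 250 Hz working rate.
reduced_protocol <- function(n_channels = 16, trials = 10, blocks = 1,
                             tasks = imagery_tasks()) {
  protocol_config(task_names = tasks, trials_per_task_per_block = trials,
                  n_blocks = blocks, fs = 250, n_channels = n_channels)
}

# One preprocessed session under the given effect size.
make_epochs <- function(effect = 1.3, seed = 1, cfg = reduced_protocol(),
                        sim = NULL) {
  if (is.null(sim)) sim <- sim_config(effect_size = effect, seed = seed)
  sess <- simulate_session(cfg, sim, seed = seed)
  preprocess(sess$raw, plan = sess$plan, subjective = sess$subjective)
}

# Cached strong-effect session shared by several suites.
strong_epochs <- function() {
  cached("strong_epochs", make_epochs(effect = 1.3, seed = 1))
}

# Small two-class Gaussian trials with known class covariances, as a
# band_covs object with a single band (for CSP oracle tests).
gaussian_band_covs <- function(S_list, n_trials, n_samp = 200, seed = 1) {
  set.seed(seed)
  n_ch <- nrow(S_list[[1]])
  k <- length(S_list)
  total <- n_trials * k
  covs <- array(NA_real_, c(n_ch, n_ch, total, 1))
  labels <- factor(rep(paste0("c", seq_len(k)), each = n_trials))
  roots <- lapply(S_list, function(S) {
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), n_ch) %*% t(e$vectors)
  })
  for (i in seq_len(total)) {
    cl <- as.integer(labels[i])
    X <- roots[[cl]] %*% matrix(rnorm(n_ch * n_samp), n_ch)
    covs[, , i, 1] <- tcrossprod(X) / (n_samp - 1)
  }
  structure(list(covs = covs, bands = list(c(8, 12)), labels = labels,
                 block = rep(1L, total),
                 self_eval = factor(rep(NA_character_, total),
                                    levels = c("correct", "not_correct",
                                               "correct_not_well")),
                 channel_names = paste0("ch", seq_len(n_ch)),
                 participant_id = "SIM"),
            class = "band_covs")
}

# Exact (deterministic) band_covs whose per-trial covariances equal the
# class covariance exactly — for closed-form CSP checks.
exact_band_covs <- function(S_list, n_trials = 4) {
  n_ch <- nrow(S_list[[1]])
  k <- length(S_list)
  total <- n_trials * k
  covs <- array(NA_real_, c(n_ch, n_ch, total, 1))
  labels <- factor(rep(paste0("c", seq_len(k)), each = n_trials))
  for (i in seq_len(total)) covs[, , i, 1] <- S_list[[as.integer(labels[i])]]
  structure(list(covs = covs, bands = list(c(8, 12)), labels = labels,
                 block = rep(1L, total),
                 self_eval = factor(rep(NA_character_, total),
                                    levels = c("correct", "not_correct",
                                               "correct_not_well")),
                 channel_names = paste0("ch", seq_len(n_ch)),
                 participant_id = "SIM"),
            class = "band_covs")
}
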