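test_that("simulation is bit-identical given the same configuration and seed", {
  cfg <- reduced_protocol(n_channels = 8, trials = 2)
  sim <- sim_config(seed = 5)
  plan <- make_session_plan(cfg, seed = 5)
  r1 <- simulate_raw(plan, sim)
  r2 <- simulate_raw(plan, sim)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)
  r3 <- simulate_raw(plan, sim, seed = 6)
  expect_false(identical(r1$data, r3$data))
})

test_that("events land at imagery onsets with the task's marker code", {
  cfg <- reduced_protocol(n_channels = 4, trials = 3)
  plan <- make_session_plan(cfg, seed = 2)
  raw <- simulate_raw(plan, sim_config(seed = 2))
  expect_equal(raw$events$sample, plan$trials$onset)
  expect_equal(raw$events$code, match(raw$events$label, cfg$task_names))
  expect_equal(nrow(raw$data), 4)
  expect_true(all(is.finite(raw$data)))
})

test_that("unknown task labels in the plan are rejected", {
  cfg <- protocol_config(task_names = c("L", "XX"),
                         trials_per_task_per_block = 2, n_blocks = 1,
                         fs = 100, n_channels = 4)
  plan <- make_session_plan(cfg, seed = 1)
  expect_error(simulate_raw(plan, sim_config()), "unknown task")
})

test_that("at zero effect size the task conditions are statistically indistinguishable", {
  # two-sample t-tests on log band-power for every channel x band must fail
  # to reject at alpha = 0.01 for >= 95% of cells (null by construction)
  cfg <- reduced_protocol(n_channels = 8, trials = 12,
                          tasks = c("L", "R"))
  ep <- make_epochs(effect = 0, seed = 11, cfg = cfg)
  bank <- design_filterbank(filterbank_spec(), fs = ep$fs)
  be <- apply_filterbank(ep, bank)
  d <- be$data  # trials x ch x samp x band
  lv <- log(apply(d, c(1, 2, 4), stats::var))
  g1 <- be$labels == "L"
  pvals <- c()
  for (ch in seq_len(dim(lv)[2])) {
    for (b in seq_len(dim(lv)[3])) {
      pvals <- c(pvals, stats::t.test(lv[g1, ch, b], lv[!g1, ch, b])$p.value)
    }
  }
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("task modulation scales band power in the task's own windows", {
  # with strong ERD, mu-band log-variance during L trials drops relative to
  # R trials on channels near the left-hand source
  ep <- cached("mod_epochs", {
    cfg <- reduced_protocol(n_channels = 8, trials = 12, tasks = c("L", "R"))
    make_epochs(effect = 1.3, seed = 12, cfg = cfg)
  })
  bank <- design_filterbank(filterbank_spec(list(c(8, 12))), fs = ep$fs)
  be <- apply_filterbank(ep, bank)
  lv <- log(apply(be$data[, , , 1], c(1, 2), stats::var))
  c4 <- which(be$channel_names == "C4")
  mu_L <- mean(lv[be$labels == "L", c4])
  mu_R <- mean(lv[be$labels == "R", c4])
  expect_lt(mu_L, mu_R)  # ERD: power loss during left-hand imagery at C4
})

test_that("subjective data respects probabilities and links gains only in informative mode", {
  cfg <- reduced_protocol(n_channels = 4, trials = 10)
  plan <- make_session_plan(cfg, seed = 3)
  # degenerate probabilities: everything "correct", discard rules are no-ops
  s_all <- simulate_subjective(plan, sim_config(
    self_eval_probs = c(correct = 1, not_correct = 0, correct_not_well = 0)))
  expect_true(all(s_all$self_eval == "correct"))
  expect_true(all(s_all$trial_gain == 1))
  sim_inf <- sim_config(self_eval_mode = "informative",
                        self_eval_probs = c(correct = 0.5, not_correct = 0.3,
                                            correct_not_well = 0.2),
                        weak_gain = 0.5)
  s_inf <- simulate_subjective(plan, sim_inf, seed = 4)
  expect_equal(unname(s_inf$trial_gain[s_inf$self_eval == "not_correct"]),
               rep(0, sum(s_inf$self_eval == "not_correct")))
  expect_equal(unname(s_inf$trial_gain[s_inf$self_eval == "correct_not_well"]),
               rep(0.5, sum(s_inf$self_eval == "correct_not_well")))
  sim_uni <- sim_config(self_eval_mode = "uninformative",
                        self_eval_probs = c(correct = 0.5, not_correct = 0.3,
                                            correct_not_well = 0.2))
  s_uni <- simulate_subjective(plan, sim_uni, seed = 4)
  expect_true(all(s_uni$trial_gain == 1))
  expect_true(all(s_uni$difficulty >= 1 & s_uni$difficulty <= 5))
  expect_equal(s_inf$kviq_total, s_inf$kviq_visual + s_inf$kviq_kinesthetic)
})

test_that("malformed self-evaluation probabilities are rejected", {
  expect_error(sim_config(self_eval_probs = c(correct = 0.5,
                                              not_correct = 0.5,
                                              correct_not_well = 0.5)),
               "sum to 1")
  expect_error(sim_config(self_eval_probs = c(a = 1, b = 0, c = 0)),
               "named")
  expect_error(sim_config(overlap_alpha = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(effect_size = -1), ">= 0")
})
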