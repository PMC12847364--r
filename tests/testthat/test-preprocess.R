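make_tone_session <- function(freqs, fs = 500, dur = 10, events = NULL) {
  t <- (seq_len(fs * dur) - 1) / fs
  data <- do.call(rbind, lapply(freqs, function(f) sin(2 * pi * f * t)))
  if (is.null(events)) {
    events <- data.frame(sample = integer(0), code = integer(0),
                         label = character(0))
  }
  raw_session(data, fs, paste0("ch", seq_along(freqs)), events)
}

test_that("downsampling 500 to 250 Hz halves the sample count and keeps amplitude", {
  raw <- make_tone_session(c(10, 10))
  out <- resample(raw, 250)
  expect_equal(out$fs, 250)
  expect_equal(ncol(out$data), ncol(raw$data) / 2)
  # 10 Hz tone amplitude preserved within 1% away from the edges
  mid <- 200:2300
  expect_lt(abs(max(abs(out$data[1, mid])) - 1), 0.01)
})

test_that("resampling at the original rate is the identity and upsampling refuses", {
  raw <- make_tone_session(c(5, 7))
  expect_identical(resample(raw, 500), raw)
  expect_error(resample(raw, 1000), "upsampling")
})

test_that("event indices rescale with round-half-even and map onto epoch onsets", {
  ev <- data.frame(sample = c(1001, 2000, 2601), code = c(1L, 2L, 1L),
                   label = c("L", "R", "L"))
  raw <- make_tone_session(c(10, 12), events = ev)
  out <- resample(raw, 250)
  expect_equal(out$events$sample, as.integer(round((ev$sample - 1) / 2) + 1))
  # onsets map to the epoch sample round(0.5 * fs) within +-1 after resampling
  ep <- extract_epochs(out, c(-0.5, 4.0))
  onset_idx <- round(0.5 * out$fs) + 1
  expect_equal(dim(ep$data)[3], 1125)
  for (i in seq_len(nrow(out$events))) {
    expect_lt(abs(ep$data[i, 1, onset_idx] - raw$data[1, ev$sample[i]]), 0.15)
  }
})

test_that("average re-reference zeroes the channel mean and matches hand algebra", {
  raw <- make_tone_session(c(10, 20, 30))
  out <- rereference_average(raw)
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
  # 2-channel case: [a, b] -> [(a-b)/2, (b-a)/2]
  a <- rnorm(50); b <- rnorm(50)
  r2 <- raw_session(rbind(a, b), 100, c("c1", "c2"),
                    data.frame(sample = integer(0), code = integer(0),
                               label = character(0)))
  o2 <- rereference_average(r2)
  expect_equal(o2$data[1, ], (a - b) / 2, ignore_attr = TRUE)
  expect_equal(o2$data[2, ], (b - a) / 2, ignore_attr = TRUE)
  # already zero-mean input unchanged
  expect_equal(rereference_average(o2)$data, o2$data)
  expect_error(rereference_average(raw_session(matrix(1, 1, 10), 100, "c1",
                                               o2$events)), ">= 2")
})

test_that("epoching uses half-open windows, validates bounds, joins metadata", {
  cfg <- reduced_protocol(n_channels = 4, trials = 4, tasks = c("L", "R"))
  plan <- make_session_plan(cfg, seed = 7)
  sim <- sim_config(seed = 7)
  subj <- simulate_subjective(plan, sim)
  raw <- simulate_raw(plan, sim)
  ep <- extract_epochs(raw, c(-0.5, 4.0), plan = plan, subjective = subj)
  expect_equal(dim(ep$data)[1], nrow(plan$trials))
  expect_equal(dim(ep$data)[3], round(4.5 * raw$fs))
  expect_equal(as.character(ep$labels), plan$trials$task)
  expect_equal(ep$block, plan$trials$block)
  expect_equal(ep$self_eval, subj$self_eval)
  expect_error(extract_epochs(raw, c(0, 0)), "t_start < t_end")
  expect_error(extract_epochs(raw, c(-0.5, 1e5)), "out of bounds")
})

test_that("a default-protocol session yields one epoch per planned trial", {
  # cheap surrogate recording with the full 490-event plan at 2 channels
  cfg <- protocol_config(fs = 100, n_channels = 2)
  plan <- make_session_plan(cfg, seed = 1)
  n <- plan$n_samples
  raw <- raw_session(matrix(rnorm(2 * n), 2), 100, c("c1", "c2"),
                     data.frame(sample = plan$trials$onset,
                                code = plan$trials$code,
                                label = plan$trials$task))
  ep <- extract_epochs(raw, c(-0.5, 4.0), plan = plan)
  expect_equal(dim(ep$data)[1], 490)
})

test_that("baseline correction removes per-trial, per-channel means", {
  ep <- cached("io_epochs", {
    cfg <- reduced_protocol(n_channels = 4, trials = 3, tasks = c("L", "R"))
    make_epochs(effect = 0.5, seed = 2, cfg = cfg)
  })
  m <- apply(ep$data, c(1, 2), mean)
  expect_lt(max(abs(m)), 1e-9)
  # arithmetic example: epoch [1, 2, 3] -> [-1, 0, 1]
  d <- array(0, c(1, 2, 3))
  d[1, 1, ] <- c(1, 2, 3)
  d[1, 2, ] <- 5
  toy <- structure(list(data = d, fs = 3, window = c(0, 1),
                        labels = factor("L"), block = 1L,
                        self_eval = factor(NA, levels = c(
                          "correct", "not_correct", "correct_not_well")),
                        channel_names = c("a", "b"), participant_id = "P"),
                   class = "epoch_set")
  out <- baseline_correct(toy)
  expect_equal(out$data[1, 1, ], c(-1, 0, 1))
  expect_equal(out$data[1, 2, ], c(0, 0, 0))  # constant channel -> zeros
})
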