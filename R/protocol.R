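# Experimental protocol description and session planning.

#' Default task vocabulary
#'
#' The seven mental tasks of the paradigm: left-hand, right-hand, feet and
#' tongue motor imagery, kinesthetic and non-kinesthetic singing imagery, and
#' rest. Marker codes are the integer positions in this vector.
#'
#' @return Character vector of the seven task labels.
#' @export
imagery_tasks <- function() {
  c("L", "R", "F", "T", "SIkin", "SInoKin", "REST")
}

#' Protocol configuration
#'
#' Describes one recording session: which tasks are cued, how many trials of
#' each per block, how many blocks, the per-trial timing, and the acquisition
#' parameters. Defaults reproduce the full paradigm: 7 tasks x 10 trials per
#' block x 7 blocks = 490 trials, 64 channels at 500 Hz.
#'
#' Trial timing: a blank screen of uniform random duration (`blank_range_s`),
#' a "Ready!" cue (`ready_s`), a "GO!" cue (`go_s`), then the imagery period
#' (`task_s`) whose first sample is the marked trial onset, followed by a
#' self-evaluation pause (`post_s`).
#'
#' @param task_names Ordered task labels; marker code is position in vector.
#' @param trials_per_task_per_block Trials of each task within one block.
#' @param n_blocks Number of blocks; task order reshuffles every block.
#' @param fs Sampling rate in Hz.
#' @param n_channels Electrode count (a 10-10 subset, see [montage_1010()]).
#' @param blank_range_s Length-2 interval for the uniform pre-cue blank (s).
#' @param ready_s,go_s,task_s,post_s Fixed segment durations in seconds.
#' @return An object of class `protocol_config`.
#' @export
#' @examples
#' cfg <- protocol_config()
#' cfg$n_blocks * cfg$trials_per_task_per_block  # trials per task
protocol_config <- function(task_names = imagery_tasks(),
                            trials_per_task_per_block = 10,
                            n_blocks = 7,
                            fs = 500,
                            n_channels = 64,
                            blank_range_s = c(0.5, 1.5),
                            ready_s = 0.5,
                            go_s = 0.5,
                            task_s = 4.0,
                            post_s = 1.0) {
  if (length(task_names) < 1 || anyDuplicated(task_names)) {
    stopf("task_names must be a non-empty vector of unique labels")
  }
  for (nm in c("trials_per_task_per_block", "n_blocks", "fs", "n_channels")) {
    if (!is_count(get(nm))) stopf("%s must be a positive integer", nm)
  }
  if (length(blank_range_s) != 2 || any(blank_range_s <= 0) ||
      blank_range_s[1] > blank_range_s[2]) {
    stopf("blank_range_s must be a positive non-decreasing interval")
  }
  for (nm in c("ready_s", "go_s", "task_s", "post_s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0 ||
        (nm != "post_s" && v <= 0)) {
      stopf("%s must be a positive duration in seconds", nm)
    }
  }
  structure(
    list(task_names = as.character(task_names),
         n_tasks = length(task_names),
         trials_per_task_per_block = as.integer(trials_per_task_per_block),
         n_blocks = as.integer(n_blocks),
         fs = fs,
         n_channels = as.integer(n_channels),
         blank_range_s = as.numeric(blank_range_s),
         ready_s = ready_s, go_s = go_s, task_s = task_s, post_s = post_s),
    class = "protocol_config"
  )
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf(
    "<protocol_config> %d tasks (%s) x %d/block x %d blocks = %d trials; %d ch @ %g Hz\n",
    x$n_tasks, paste(x$task_names, collapse = ","),
    x$trials_per_task_per_block, x$n_blocks,
    x$n_tasks * x$trials_per_task_per_block * x$n_blocks,
    x$n_channels, x$fs))
  invisible(x)
}

#' Build a randomized session plan
#'
#' Lays the trials of a session out in time. Each block contains exactly
#' `trials_per_task_per_block` trials of every task, in a fresh random order
#' per block; inter-trial gaps are drawn uniformly from `blank_range_s` and
#' the fixed ready/go segments precede every imagery onset.
#'
#' @param cfg A [protocol_config()].
#' @param seed Integer seed; the plan is a deterministic function of
#'   `(cfg, seed)`.
#' @return An object of class `session_plan`: a list with `trials` (a
#'   data.frame with columns `block`, `trial_in_block`, `task`, `code`,
#'   `onset` — the 1-based sample index of the first imagery sample),
#'   `n_samples`, `fs`, `task_names`, and the generating `cfg`.
#' @export
#' @examples
#' plan <- make_session_plan(protocol_config(), seed = 1)
#' nrow(plan$trials)        # 490
#' table(plan$trials$task)  # 70 per task
make_session_plan <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "protocol_config"))
  with_seed(seed, {
    fs <- cfg$fs
    rows <- vector("list", cfg$n_blocks)
    cursor <- fs  # 1 s of lead-in before the first trial
    for (b in seq_len(cfg$n_blocks)) {
      tasks <- sample(rep(cfg$task_names, each = cfg$trials_per_task_per_block))
      n <- length(tasks)
      blanks <- stats::runif(n, cfg$blank_range_s[1], cfg$blank_range_s[2])
      onset <- integer(n)
      for (i in seq_len(n)) {
        pre <- round((blanks[i] + cfg$ready_s + cfg$go_s) * fs)
        onset[i] <- cursor + pre + 1
        cursor <- cursor + pre + round((cfg$task_s + cfg$post_s) * fs)
      }
      rows[[b]] <- data.frame(
        block = b,
        trial_in_block = seq_len(n),
        task = tasks,
        code = match(tasks, cfg$task_names),
        onset = onset,
        stringsAsFactors = FALSE
      )
    }
    trials <- do.call(rbind, rows)
    structure(
      list(trials = trials,
           n_samples = cursor + fs,  # 1 s lead-out
           fs = fs,
           task_names = cfg$task_names,
           cfg = cfg),
      class = "session_plan"
    )
  })
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("<session_plan> %d trials over %d blocks, %.1f s @ %g Hz\n",
              nrow(x$trials), max(x$trials$block), x$n_samples / x$fs, x$fs))
  invisible(x)
}
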