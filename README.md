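# imagerybci

Simulation and decoding of multi-class mental-imagery EEG for
brain-computer interfaces (BCIs).

Active BCIs translate intentionally produced brain activity into device
commands. The workhorse control signals are motor imagery (MI) of the left
hand (L), right hand (R), both feet (F) and tongue (T), plus a rest state
(REST) — but four or five commands limit what a system can do. A promising
way to widen the command set is **singing imagery (SI)**: silently singing a
familiar, lyric-bearing song, either attending to the kinesthetic
sensations of jaw/tongue/lip articulation (SI_kin) or not (SI_noKin). This
package provides the full analysis stack needed to study such paradigms:

* a **protocol-faithful synthetic session generator** — 7 tasks × 70
  trials in 7 reshuffled blocks, 64-channel 10-10 montage at 500 Hz,
  per-trial blank/ready/go/imagery timing — with a controllable
  event-related desynchronization (ERD) signal model: band-limited Gaussian
  sources mixed through smooth scalp topographies, whose band-wise variance
  is scaled by `1 + g·m_b` during each trial's 4-s imagery window
  (`g` = effect size, `m_b` < 0 for ERD), on top of 1/f noise and a common
  posterior alpha rhythm. At `g = 0` all task conditions are statistically
  identical, which turns the generator into a leakage detector for the
  decoding pipeline. Simulated per-trial self-evaluation answers and
  imagery-questionnaire (KVIQ-style) scores feed the subjective-data
  analyses;
* **BrainVision I/O** (`.vhdr/.vmrk/.eeg`, multiplexed IEEE float32) with
  bit-exact event round trips;
* the **preprocessing chain**: polyphase resampling to 250 Hz, common
  average reference, epoching −0.5..4.0 s around imagery onset,
  whole-epoch baseline correction;
* **filter-bank common spatial patterns (FBCSP)**: nine 4 Hz bands from 4
  to 40 Hz (251-tap linear-phase FIR), CSP per band — the binary
  generalized eigenproblem `Σ₁ w = λ(Σ₁+Σ₂) w` with 5 filter pairs per
  band, or multiclass CSP by approximate joint diagonalization (Pham's
  algorithm) with information-based filter ranking — giving 90
  log-variance features (10 filters × 9 bands);
* **mRMR feature selection** (mutual-information difference, MID): greedy
  maximization of `I(f; y) − mean_s I(f; s)` over equal-frequency
  discretized features, keeping the top 25;
* a **random-forest decoder** (100 trees, Gini, √p split candidates) under
  **leakage-safe repeated stratified cross-validation** (5 × 10-fold;
  CSP, discretization, selection and classifier all refit inside every
  training fold) across all 2-, 4-, 5- and 6-class task combinations
  (21 / 25 / 11 / 2 scenarios; at most one SI variant beyond the binary
  case);
* **chance-level statistics**: inverse binomial-CDF significance
  thresholds (the smallest `k` with `BinomCDF(k; n, 1/c) ≥ 1−α`, e.g.
  57.1% for 140 trials / 2 classes at α = 0.05), label-permutation null
  distributions with empirical p-values, paired t / Cohen's d comparisons,
  correlation analyses, and the flagged-trial discard analysis with
  class-matched random removal.

## Worked example

Simulate one reduced session (16 channels, 10 trials per task, generated
directly at 250 Hz) with a strong planted effect, preprocess it, and decode
two scenarios:

```r
library(imagerybci)

cfg <- protocol_config(trials_per_task_per_block = 10, n_blocks = 1,
                       fs = 250, n_channels = 16)
sim <- sim_config(effect_size = 1.3, seed = 1)
sess <- simulate_session(cfg, sim, seed = 1)

epochs <- preprocess(sess$raw, plan = sess$plan,
                     subjective = sess$subjective)
epochs
#> <epoch_set> P01: 70 trials x 16 ch x 1125 samples @ 250 Hz, window [-0.5, 4)
#>       L       R       F       T   SIkin SInoKin    REST
#>      10      10      10      10      10      10      10

cv <- cv_config(n_folds = 10, n_repeats = 2, seed = 1)
crossvalidate_scenario(epochs, c("L", "R"), cv)
#> <scenario_result> L+R: 92.5% (sd 18.3) over 20 folds, 20 trials

res6 <- crossvalidate_scenario(
  epochs, c("L", "R", "F", "T", "REST", "SIkin"), cv)
res6
#> <scenario_result> L+R+F+T+REST+SIkin: 59.2% (sd 13.8) over 20 folds, 60 trials
res6$confusion
#>        L  R F T SIkin REST
#> L     18  0 0 0     2    0
#> R      1 19 0 0     0    0
#> F      1  0 9 2     6    2
#> T      1  0 5 7     4    3
#> SIkin  4  1 2 2     7    4
#> REST   2  0 4 1     2   11
```

The left/right-hand pair decodes at 92.5%; the 6-class problem reaches
59.2% mean balanced accuracy, and its pooled confusion matrix shows the
designed confusability of tongue MI with kinesthetic singing imagery
(rows T and SIkin). Both are far above their chance benchmarks:

```r
binomial_threshold(60, 6)
#> <significance_threshold> 25.0% (15/60 correct, 6 classes, alpha=0.05)
chance_band(120, 6)
#> [1] 10.00000 23.33333
```

A full multi-participant study (simulate → preprocess → decode → report)
runs from one seed with `run_study()`, or from the shell via the wrapper
in `inst/scripts/run_study.R`; per-stage execution with staleness-guarded
artifacts is available through `run_stage()`.

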