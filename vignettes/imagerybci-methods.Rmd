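---
title: "Methods: simulating and decoding multi-class imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding multi-class imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `imagerybci`. The package implements a complete offline analysis
stack for multi-class mental-imagery brain-computer interfaces — four
motor-imagery tasks (left hand L, right hand R, feet F, tongue T), two
singing-imagery variants (kinesthetic SIkin, non-kinesthetic SInoKin) and
rest — together with a synthetic-session generator that makes every stage
testable without access to recorded EEG.

## The synthetic signal model

`simulate_raw()` realizes the textbook generative model under which
common spatial patterns (CSP) is optimal: linear instantaneous mixing of
statistically independent band-limited Gaussian sources through fixed
scalp topographies, plus additive noise,

$$x(t) = \sum_s a_s\, s_s(t) + n(t).$$

Concretely:

* **Background.** Each channel receives independent $1/f$ noise
  (spectral exponent `noise_exponent`, default 1, flattened below 1 Hz;
  standard deviation `noise_sd`, default 8 µV), and a common posterior
  ~10 Hz source (amplitude `alpha_amp`, default 4 µV) mimics the resting
  alpha rhythm.
* **Task sources.** Every non-rest task owns one source, mixed through a
  unit-norm topography built from Gaussian kernels (width `kernel_sigma`
  = 0.35 in schematic scalp units) on 2-D projected 10-10 electrode
  coordinates: lateralized central kernels for L/R (contralateral to the
  imagined hand), a midline-central kernel for F, bilateral inferior
  fronto-temporal kernels for T, and a left-lateralized inferior-frontal
  plus posterior-temporal pair for the singing-specific source. These are
  coarse physiological placements only; no source localization is
  claimed.
* **Event-related (de)synchronization.** Each source emits unit-variance
  band-limited components (defaults: mu 8–12 Hz with $m = -0.75$, beta
  18–26 Hz with $m = -0.55$) at amplitude `source_amp` (5 µV) at all
  times. During a trial of the owning task, the variance of component $b$
  is scaled by $1 + g\,m_b$, where $g$ = `effect_size`. Negative $m$
  yields ERD (power loss). With $g = 0$ every task's data distribution is
  identical *by construction* — the basis of the null-calibration and
  leakage tests. The positivity bound $g\,m_b > -1$ caps usable $g$ at
  about 1.33 under the default mu modulation.
* **Task similarity knobs.** `overlap_alpha` mixes the SIkin topography
  toward the tongue topography (1 = identical maps), emulating the shared
  articulatory-motor substrate of tongue MI and kinesthetic singing
  imagery; `sinokin_depth` scales SInoKin's modulation depth, pushing it
  toward rest as it approaches 0. The singing-specific source is placed
  away from the tongue kernels so that `overlap_alpha` is the *only*
  mechanism coupling T and SIkin.
* **Participant and trial heterogeneity.** `participant_scale` multiplies
  $g$ per participant (`run_study()` draws it log-normally, sd 0.25 on
  the log scale); per-trial gains let the subjective simulator couple
  self-evaluation flags to signal quality.

**What the generator does not emulate:** volume-conduction/leadfield
realism, eye-blink or EMG artifacts, nonstationary drifts, learning or
fatigue effects across blocks, and any nonlinear or phase-coupled
dynamics. Passing tests on this generator therefore demonstrate that the
pipeline recovers *variance-structured* class information without
leakage; they do not certify performance on recorded EEG, where artifacts
and nonstationarity dominate the error budget.

**Reference conditions.** The protocol defaults are the full paradigm
(7 tasks × 10 trials/block × 7 blocks = 490 trials, 64 channels at
500 Hz; trial = 0.5–1.5 s uniform blank + 0.5 s ready + 0.5 s go + 4 s
imagery). The default effect size is $g = 1$ (a strong but not extreme
ERD); $g = 1.3$ — near-complete mu suppression, just inside the
positivity bound — is the package's documented *strong-effect* reference
used by the signal-recovery tests. No quantitative effect sizes exist to
import for these tasks, so both values are calibration choices of the
generator, fixed once.

## Subjective data

`simulate_subjective()` draws one of the three per-trial self-evaluation
answers (performed correctly / not correctly / correctly but not very
well) from `self_eval_probs`. In **informative** mode the answer is
causally tied to signal quality (trial gain 0 for "not correctly",
`weak_gain` = 0.5 for "not very well"); in **uninformative** mode the
flags are independent of the signal. The two modes bracket the question
the discard analysis asks: flags can only help trial exclusion if they
actually mark degraded signal. Questionnaire scores (two 5-item, 1–5
subscales) are drawn with correlation `kviq_effect_cor` to the
participant's effect multiplier; difficulty ratings (1–5, after blocks 1,
4 and 7) and the three preference answers complete the record.

## Preprocessing

Fixed order: resample → average re-reference → epoch → baseline.

* **Resampling** (500 → 250 Hz by default) is polyphase: zero-stuffing,
  a Hamming windowed-sinc low-pass at the target Nyquist with exact
  group-delay compensation and reflect padding, then decimation. The
  resampler is implemented in-package because the pipeline's contract
  (pure-tone amplitude preserved within 1%) demands a longer anti-alias
  filter than generic resamplers use. Event indices rescale by the rate
  ratio with round-half-even.
* **Epochs** are half-open windows $[-0.5, 4.0)$ s around imagery onset
  (1125 samples at 250 Hz), 0-based sample convention
  `onset + round(t·fs)`.
* **Baseline** subtracts the whole-epoch mean per trial and channel —
  deliberately *not* a pre-stimulus baseline, matching the convention of
  subtracting each epoch's own mean; a `"prestim"` option is provided and
  labeled as the deviation.

## Filter-bank CSP

Nine non-overlapping 4 Hz bands (4–8 … 36–40 Hz) as symmetric
linear-phase FIR filters (windowed-sinc, Hamming, 251 taps at 250 Hz;
single-pass FFT convolution with exact group-delay shift — a
forward-backward pass would square the magnitude response and is not what
a linear-phase design implies). Responses stay above −6 dB on
`[low+1, high−1]` Hz and below −20 dB two Hz outside the band. Band
outputs are cropped to the **post-onset analysis window** $[0, 4)$ s: the
pre-onset half second serves only as edge padding, since covariance
estimates should describe the imagery period.

Covariances are per-trial sample covariances of the band-filtered
analysis window, trace-normalized before class averaging (so amplitude
scale cannot masquerade as class information). Because log-variance
features are quadratic forms in these matrices, the package computes all
per-trial band covariances once per dataset and refits CSP per fold from
cheap class averages — fold-wise refitting at no leakage risk (the
covariances are label-free).

* **Binary CSP** solves $\Sigma_1 w = \lambda(\Sigma_1+\Sigma_2)w$ by
  whitening with $\Sigma_1+\Sigma_2$; eigenvalues sort descending and 5
  pairs (10 filters) are kept from the spectrum ends, scaled so
  $w'(\Sigma_1+\Sigma_2)w = 1$.
* **Whitening is rank-aware.** Average-referenced EEG has channel rank
  $n-1$ exactly; eigendirections below $10^{-9}$ of the leading
  eigenvalue are dropped rather than amplified. If the remaining rank
  cannot support the requested filters, the fit errors and points to the
  diagonal-loading option (`loading`, default 0 = off; when enabled it
  adds $\varepsilon\,\mathrm{tr}(C)/n \cdot I$).
* **Multiclass CSP** whitens the class-prior-weighted grand-average
  covariance, then approximately jointly diagonalizes the class
  covariances with Pham's iterative pairwise algorithm for
  symmetric-positive-definite sets (per-element criterion tolerance
  $10^{-6}$, sweep cap 100, non-convergence errors with the residual
  off-diagonal energy). Pham's method is the standard AJD for covariance
  sets and converges quadratically where orthogonal Jacobi sweeps creep
  on small-sample covariances. Filters are rescaled to unit
  grand-average variance and ranked by the Gaussian-approximation
  information score
  $-\left(\sum_c p_c \log\sqrt{v_c} + \tfrac{3}{16}\big(\sum_c p_c (v_c^2-1)\big)^2\right)$
  with $v_c = w'\Sigma_c w$; ties break toward the lower filter index.
  Ten filters per band are kept — the same count as the binary
  configuration — so the feature table is 90-dimensional in every
  scenario.
* **Features** are unnormalized $\log(\mathrm{var}(w'x))$ (the
  variance-fraction normalization common elsewhere is available as a
  switch, off by default).

## Feature selection and classification

Features are discretized per column into 5 equal-frequency bins whose
edges are order statistics of the *training* data (rank-based, hence
invariant to monotone transforms; constant columns collapse to one bin
and are flagged). Mutual information uses the plug-in contingency-table
estimator. Greedy MID selection takes the most relevant feature first,
then maximizes relevance minus mean redundancy against the selected set,
keeping 25 of 90; ties break toward the lower index. One caveat worth
knowing: because redundancy is a *mean* over the selected set, selecting
an irrelevant feature dilutes the redundancy penalty of near-duplicates —
exact MID can therefore interleave noise columns between a feature and
its duplicate. The test suite pins the implementation to an exhaustive
greedy evaluation rather than to intuition about specific orders.

The classifier is a 100-tree random forest (Gini impurity, unrestricted
depth, bootstrap resampling, $\lfloor\sqrt{p}\rfloor$ split candidates,
majority vote), via `ranger` with single-thread execution and explicit
seeds for both training and prediction — `predict` tie-breaking is
otherwise seeded from the global RNG, which would break reproducibility.

## Cross-validation and leakage

`crossvalidate_scenario()` runs `n_repeats` × `n_folds` stratified
cross-validation (defaults 5 × 10). Folds are dealt per class round-robin
from a random starting fold; a training fold that loses a class is an
error, while an empty test fold (possible only when trials < folds) is
skipped as missing. **Everything label-dependent — CSP filters,
discretization edges, mRMR selection, the forest — is fitted inside each
training fold.** Where convention sometimes fits the selector once per
dataset, that reading is available as `refit_selector = FALSE` and is off
by default, because fold-fitting everything is the only leakage-safe
interpretation. A `leak_demo` switch fits the whole feature pipeline on
all trials before splitting; on effect-free data it saturates accuracy
(the test suite shows ~100% versus in-band for the shipped default),
which is the diagnostic that motivates the design.

Balanced accuracy (mean per-class recall) is reported everywhere; with
the generator's exactly balanced classes it coincides with plain
accuracy. Scenario enumeration covers all task subsets of size 2, 4, 5, 6
with at most one SI variant beyond the binary case (21/25/11/2
scenarios). Binary scenarios use binary CSP by default; `csp =
"multiclass"` applies the joint-diagonalization fitter to binary problems
too, for consistency studies.

## Statistics

* **Chance thresholds.** `binomial_threshold(n, k, α)` returns
  $100\cdot\min\{j : F_{\mathrm{Bin}(n,1/k)}(j) \ge 1-\alpha\}/n$,
  reported to one decimal. For the full protocol: 57.1% (n=140, k=2),
  29.3% (n=280, k=4), 19.8% (n=420, k=6). For n=350, k=5 the rule gives
  82/350 = **23.4%**; a value of 23.3% sometimes quoted for this
  configuration does not follow from the rule at any nearby rounding, so
  the package reports the computed 23.4 rather than forcing agreement.
* **Permutation tests.** `permutation_null()` re-runs the *entire*
  cross-validated pipeline on label shuffles. The empirical p,
  $(1+\#\{\mathrm{null} \ge \mathrm{obs}\})/(n_{\mathrm{perm}}+1)$, can
  never reach 0 and is floored at $1/(n_{\mathrm{perm}}+1)$. A one-sample
  t of the null distribution against the observed accuracy is also
  reported because that comparison is a common reporting convention —
  with the caveat, stated in the result object, that testing a
  distribution against a scalar is statistically unconventional. Default
  `n_perm` = 100, configurable.
* **Effect sizes and correlations.** Paired t with paired Cohen's d
  ($\bar d / s_d$; zero-variance differences flagged, not propagated),
  and product-moment correlation with a Spearman option.
* **Discard analysis.** Removing self-flagged trials is compared against
  removing an equal number of *class-count-matched* random trials (a
  fully random variant is a switch), both arms re-running the
  cross-validated scenario; the matched counts are audited in the output.
  No multiple-testing correction is applied anywhere (per-comparison
  α = 0.05), and report footers say so.

## Orchestration and reproducibility

`run_study()` chains simulate → preprocess → decode → report for N
participants from one global seed. Seeds fan out through
`derive_seed(seed, tag, …)`, a 32-bit multiply-xor rolling hash over the
tag sequence — every participant, fold shuffle, forest, prediction,
permutation and random removal has its own named stream, so any stage can
be reproduced in isolation. `run_stage()` executes single stages against
on-disk artifacts; each artifact carries the configuration hash and
stages refuse stale inputs. Identical configuration and seed reproduce
all outputs bit-identically on the same platform.

## Problem sizes used by the test suite

The suite exercises the full default protocol where cheap (session
planning, enumeration, thresholds) and reduced conditions where the
decoder loop is involved, chosen once as this package's test conditions:
16-channel montages with 10 trials per class (one block, generated
directly at 250 Hz) for null calibration and signal recovery; 8-channel,
12-trials-per-class sessions for the discard analyses; 2 repeats of
10-fold cross-validation in those checks. Null calibration averages
several independent sessions (10 for 2-class, 4 for 6-class) and compares
the grand mean against the single-run 95% binomial band — a conservative
check, since the band is not narrowed for the averaging. The
strong-effect recovery check requires the 6-class accuracy to exceed its
reduced-n binomial threshold in at least 9 of 10 fixed seeds.

## Known limitations

* The generator's variance-modulation model is the best case for
  CSP-family methods; pipelines that pass here can still underperform on
  artifact-laden recordings.
* Pham's AJD optimizes a likelihood-style criterion, not off-diagonal
  energy directly; for non-commuting class covariances the residual
  off-diagonal energy is a diagnostic, not a guarantee.
* The plug-in MI estimator is biased upward at 5 bins with few trials;
  this affects which features are selected, not the leakage safety of the
  selection.
* Balanced accuracy's equivalence to plain accuracy holds only under
  exact class balance; after discarding flagged trials the two diverge,
  which is why the discard analysis reports balanced accuracy.
* `compare_conditions()` implements the paired t for paired samples; the
  pairing of a scalar observed accuracy with a permutation distribution
  is inherently ambiguous, which is why `permutation_null()` reports the
  empirical p alongside it.
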