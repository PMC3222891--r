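---
title: "Decoding overlapping episodic memories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding overlapping episodic memories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patternsep)
```

# The scientific question

When four episodic memories are built from every combination of two
action events and two spatial contexts, no single element identifies a
memory: A = (event 1, context 1), B = (event 1, context 2),
C = (event 2, context 1), D = (event 2, context 2).  If a classifier
can nevertheless tell the four memories apart from the joint activity
pattern across voxels of a medial-temporal region, the region must
carry *bound*, memory-unique representations — the signature of
pattern separation.  Two further analyses refine the picture:

* **Cross-classification (transfer).**  A classifier trained to
  separate A from B (which differ only in spatial context) is tested
  on C versus D.  Above-chance transfer requires a representation of
  spatial context that generalizes across memories.  The event-content
  analogue trains on A versus C and tests on B versus D.
* **Misclassification decomposition.**  Every four-way decoding error
  falls in exactly one class: *spatial* (the predicted memory shares
  the true memory's context), *content* (shares its event) or
  *orthogonal* (shares neither).  If four-way decoding were driven by
  context information alone, spatial errors would dominate; a flat
  error profile supports genuinely distinct memory traces.

`patternsep` implements this full analysis chain — single-trial GLM
estimation, ROI pattern extraction, one-vs-one linear SVM decoding
with leave-one-trial-out cross-validation, the transfer tests, the
error decomposition, and group inference — together with a synthetic
generator whose signal composition makes each analysis independently
controllable.

# The generative model

For each participant the generator draws eight unit-norm Gaussian
template directions over `n_voxels`: one per memory (`u_A..u_D`), one
per context (`v_1, v_2`), one per event (`w_1, w_2`), multiplied by a
common `template_scale`.  A trial of memory m produces

    pattern = amp_bound * u_m + amp_context * v_ctx(m) +
              amp_event * w_ev(m) + noise,     noise ~ N(0, noise_sd^2 I)

Recall-accuracy flags are Bernoulli(1 − `p_inaccurate`), and flagged
trials are excluded from decoding, mirroring the restriction of the
analyses to accurately recalled trials.

## Calibration of the amplitude scale

Amplitudes are only meaningful relative to the template norm and the
noise level.  Two "natural" normalizations both fail to produce a
usable testbed: with strictly unit-norm templates an amplitude of 0.5
against per-voxel noise 1 is undetectable in principle at 80 trials
and 300 voxels (the best linear read-out achieves an effective
discriminability near 0.1, indistinguishable from chance), while
per-voxel-normalized templates (scale `sqrt(n_voxels)`) make decoding
perfect, leaving no misclassifications to analyse.  We therefore fix
`template_scale = 4` once, which puts the default amplitudes in the
regime actually observed in region-of-interest fMRI decoding:
per-voxel contrast-to-noise ≈ `0.5 * 4 / sqrt(300)` ≈ 0.12,
single-participant four-way accuracy around 0.4–0.5, and several
hundred decoding errors per simulated study for the error
decomposition.  This constant is a property of the simulation testbed,
not a tunable analysis parameter.

Defaults (`n_voxels = 300`, `amp_bound = amp_context = 0.5`,
`amp_event = 0`, `noise_sd = 1`, `p_inaccurate = 0.05`) emulate a
hippocampus-like region: memories and their shared spatial contexts
decodable, event content not — the dissociation the analyses are
designed to detect.  Null regions use zero amplitudes.

## What the generator does and does not emulate

It reproduces the statistical structure the analyses rely on: a 2x2
event-by-context design with balanced, repeat-free pseudo-random trial
orders; additive, linearly separable bound/context/event components;
independent participant topographies (decoding is within-participant);
optional upstream BOLD series so the GLM stage is testable.  It does
*not* model spatial autocorrelation, motion or physiological noise,
scanner drift beyond the polynomial terms, inter-regional signal
leakage, or any nonlinearity in the mapping from memory content to
voxel activity.  Passing tests therefore certify the analysis code and
its statistical calibration, not the biological claim; real data can
fail in ways this generator cannot produce.

# Trial ordering

Orders are balanced (each memory exactly `n_trials_per_condition`
times) with no immediate repeats.  Whole-sequence rejection sampling
is infeasible at 80 trials — the acceptance probability of a uniform
shuffle decays like exp(−n/4), below 10^-6 already at 20 trials per
condition — so orders are drawn sequentially with probability
proportional to each memory's remaining count, excluding the memory
just presented, restarting on the rare dead end.  By symmetry across
conditions this keeps the marginal probability of every memory at
every serial position exactly 1/4 (verified by a chi-square test over
10,000 orders); it is not exactly uniform over the set of admissible
sequences, a difference without consequence for any analysis here,
since decoding never uses serial position.

# Single-trial GLM

Each trial's recall period is a boxcar regressor convolved with the
canonical double-gamma HRF (response gamma peaking near 5 s minus 1/6
of an undershoot gamma near 15 s; kernel sampled at the TR over 32 s
and peak-normalized).  All trials sit in one model together with
polynomial drift terms (default order 1) and a constant; estimates are
ordinary least squares, and each trial's beta is converted to a t
statistic by dividing by its standard error under the full model,
`t_i = beta_i / sqrt(sigma2 * [(X'X)^-1]_ii)`.  The t conversion is a
per-voxel, per-regressor rescaling that downweights noisy voxels and
high-leverage trials before classification.

Numerical choices: the fit uses a QR decomposition; rank deficiency is
reported as an error naming the collinear columns; residual variance
within rounding error of zero (relative threshold 1e-12) marks a voxel
as degenerate, and t-map extraction refuses to proceed, since
noiseless data make t undefined.  Timing defaults — 12 s recall
periods separated by 4 s, TR 2 s — are configurable placeholders in
the realistic range for this paradigm; no temporal autocorrelation
correction is applied, so exact-recovery claims are tested with white
noise (an AR(1) generator is available for robustness checks).

# Decoding

The four-way classifier is a linear SVM in the one-vs-one scheme: one
binary soft-margin classifier (cost default 1.0) per unordered pair of
memories, prediction by majority vote, ties broken by the summed
signed decision values and then by the lexicographically smallest
memory label.  Cross-validation is leave-one-trial-out: each accurate
trial is predicted by classifiers trained on all remaining accurate
trials, and no quantity derived from the held-out trial enters
training.  Chance is 1/4 for the four-way analysis and 1/2 for the
transfer analyses.

The binary solver is dual coordinate descent on the L1-hinge dual (the
LIBLINEAR algorithm), with the intercept as an augmented constant
feature; a tolerance of 1e-4 on the projected gradient is the
cross-validation default, and tests that assert exact geometry (e.g.
the two-point max-margin midpoint) tighten it.  For leave-one-trial-out
the solver works in the kernel (Gram) representation: the trial Gram
matrix is computed once, pairwise sub-Grams are cached, and each fold
warm-starts from the full-pair solution — when the held-out trial is
not a support vector the refit is provably identical and skipped.
Tests verify fold-for-fold equality with independently retrained
classifiers and agreement with an independent SVM implementation
(libsvm via e1071).

Feature normalization defaults to `"none"`: the t-value patterns
entering the classifier are already per-voxel scaled by the beta-to-t
conversion, and on the homoscedastic synthetic data additional
z-scoring changed no result while roughly tripling the cost of
permutation inference.  A leakage-free `"zscore"` mode (per-voxel
statistics from each binary problem's training trials, applied to
held-out data) is available and covered by the same fold-equality
tests.

Transfer scoring maps the predicted training label to the test pair
through the shared factor (context: A→C, B→D; event: A→B, C→D).
Custom train/test pairs are validated: each pair must differ in the
shared factor only, and the pairs must be disjoint.  Class imbalance
after accuracy filtering is tolerated without rebalancing; with the
default 5% inaccurate-trial rate the imbalance is small, and the
leave-one-trial-out estimate remains a per-trial quantity.

# Group inference

All group tests are one-tailed (upper) with df = participants − 1;
this is the convention under which every reported statistic in this
literature is self-consistent (e.g. t = 1.90 with df = 14 gives
P = 0.04, and a negative t gives P near 1).  `t_vs_chance` is the
one-sample t-test of per-participant accuracies against chance;
`compare_misclass` is the paired t-test of spatial versus content (or
orthogonal) error proportions, excluding — with a warning —
participants without errors, whose proportions are undefined.  If all
differences are exactly zero the tests report t = 0, P = 0.5; zero
variance around a nonzero mean is an error rather than an infinite
statistic.

The nonparametric companion permutes the condition-label vector over
trials independently within each participant, reruns the full analysis
(including cross-validation), records the group mean, and reports the
add-one p-value `(1 + #(null ≥ observed)) / (1 + n_perm)`, which can
never reach zero.  Permuting labels rather than resampling preserves
the per-condition trial counts in every null draw.  The scheme and all
derived seeds are recorded in the run manifest.  A known property of
cross-validated accuracy under label permutation is a slight
below-chance bias (folds' training sets are imbalanced against the
held-out class); because the same bias affects the observed statistic
and the null draws equally, the permutation test remains calibrated,
and the type-I error of the whole pipeline is verified by simulation
in the test suite.

# Pipeline and reproducibility

`run_all()` composes the stages per region of interest and returns
tidy tables plus a manifest (package version, master seed, per-stage
derived seeds, generator parameters, permutation scheme, voxel scan
order).  Every random draw flows from the master seed through
`derive_seed(seed, tags...)`, a stable string hash, so adding
participants or regions never shifts existing streams and a
manifest-only rerun reproduces results exactly.  Voxel scan order is
ascending array index; masks must match the data grid exactly —
resampling is out of scope and raises an error.

Simulation sizes used by the test suite were chosen to exercise the
study-scale configuration where the claim depends on it (15
participants, 20 trials per condition, 300 voxels, 500 permutations)
and reduced sizes elsewhere (e.g. 6 participants, 10 trials per
condition, 100 voxels, 200 permutations for the 200-dataset type-I
calibration), keeping the full suite within a few minutes on one core.

# Known limitations

* The SVM intercept is weakly regularized (augmented-feature
  formulation); with symmetric training data this is exact, and
  elsewhere it differs negligibly from libsvm's unregularized
  intercept at these problem sizes, as the agreement tests document.
* Polynomial drift differs from SPM's discrete cosine basis; the GLM
  is not bit-compatible with SPM output.
* The permutation test permutes labels within participant; sign-flip
  and between-participant schemes are not implemented.
* Multiple-comparison correction across regions and analyses is
  deliberately absent: per-region uncorrected tests are reported, as
  in the source literature for this design.
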