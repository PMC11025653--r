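---
title: "Methods: parsing complexity metrics as fMRI encoding predictors"
author: "rnngbold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parsing complexity metrics as fMRI encoding predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnngbold)
```

# Overview

`rnngbold` implements, end to end, a pipeline that links incremental-parsing
complexity metrics to brain signals:

1. **Language models.** A Kneser–Ney 5-gram model and an LSTM as sequential
   baselines, and generative recurrent neural network grammars (RNNGs) under
   two transition strategies, top-down and left-corner.
2. **Complexity metrics.** Word-synchronous beam search over RNNG
   derivations yields *surprisal* (`-log p(segment | context)` from beam
   prefix marginals) and *distance* (parser actions explored in the beam per
   segment), plus corpus perplexity.
3. **Regressors.** Per-segment predictors are convolved with a canonical
   hemodynamic response function, sampled at 0.5 Hz (TR = 2 s), the
   language-model columns orthogonalized against word rate, and everything
   standardized.
4. **ROI statistics.** Random-intercept linear mixed models pooled over
   subjects, compared in nested ladders by likelihood-ratio tests with a
   Bonferroni gate of 0.05/8 across the eight left-hemisphere regions of
   interest.
5. **Whole brain.** A simplified two-level GLM: per-subject voxelwise OLS,
   a one-sample t test mapped to z, FDR (0.05) thresholding and a 100-voxel
   cluster-extent rule, with optional 8 mm FWHM Gaussian smoothing.

Real stimulus corpora, trained full-scale checkpoints, and human fMRI data
are not available at desk scale, so the package ships a first-class
synthetic-data module: a head-final PCFG treebank sampler with an exact
enumerator, stimulus schedules at 1 s stimulus-onset asynchrony, and BOLD
simulators (`design x known coefficients + subject intercepts + AR(1)
noise`) with known ground truth. Every downstream stage is validated by
parameter recovery against that truth.

# The generative parser

An RNNG generates a sentence and its constituency tree jointly through
three actions: `GEN(w)` emits a terminal, `NT(X)` opens a nonterminal
constituent, `REDUCE` closes the innermost open constituent. The partial
derivation lives on a stack encoded by a *stack LSTM*: pushing an element
advances the recurrence from the state beneath it; popping restores the
earlier state exactly. Action logits and word logits are affine functions
of the top-of-stack hidden state; action probabilities are softmaxes
restricted to the legal-action set.

**Composition.** On `REDUCE`, the completed constituent's element vectors
(label embedding followed by the children's vectors) are read by a forward
and a reverse LSTM; the two final states are concatenated and passed
through an affine map plus `tanh` to produce a single vector that replaces
the children on the stack. This single-vector bottleneck is what makes the
model hierarchical rather than merely sequential. The combiner
(affine + tanh over the concatenated final states) is one of several
reasonable readings of "combine the forward and reverse encodings"; it was
chosen for its symmetry between directions and is fixed throughout.

**Strategies.** Top-down announces `NT(X)` before any child of X;
left-corner announces it immediately *after* the first child (the left
corner) completes, popping that child into the new constituent. For
head-final, left-branching input the two strategies schedule structural
work very differently, which is exactly the contrast the complexity
metrics are meant to expose.

**Legality and termination.** Top-down: `GEN` and `REDUCE` require an open
constituent, `REDUCE` additionally a completed child on top (so never
immediately after `NT`); a lone completed constituent is absorbing — the
derivation has ended. Left-corner: `GEN` is legal at the start or inside an
open constituent; `NT` requires a completed item on top; `REDUCE` closes
the innermost open constituent, whose left corner guarantees it is never
empty (unary constituents are therefore permitted, and trees of arbitrary
arity are processed without binarization). Under left-corner a completed
root may still become the left corner of a larger constituent, so stopping
is implicit rather than forced; the model is then generatively deficient
(some probability mass sits on continuations), which is standard for this
model family. All probability statements in the tests are therefore
*subprobability* statements where completion is involved.

Two caps make search spaces finite: an **open-constituent cap** (default:
remaining tokens + 10) and an **NT budget** between consecutive `GEN`s
(default 10), the latter needed because left-corner unary cycles
(`NT`/`REDUCE` around a completed root) are not bounded by the open cap.
Both caps are part of the model definition and are applied identically in
training-time scoring, beam search, and the exact enumerator, so the three
views of the model agree exactly.

# Word-synchronous beam search

Conditioned on a sentence, search proceeds token by token. Between two
word boundaries, structural successors of the current beam are expanded in
score order, at most `k` candidates surviving per round; candidates that
generate the next observed token enter the *word beam* (capacity
`k_w = k/10`), and the `k_ft = k/100` best word-generating successors are
fast-tracked each round so lexical candidates are never starved by
structural ones. Exploration stops once no structural candidate scores
above the `k_w`-th best word item — safe because scores only decrease along
a derivation, so the final word beam is identical to the one obtained by
exhausting the frontier.

The beam marginal \(M_i\) is the summed probability of the word beam after
token \(i\) (\(M_0 = 1\)). Surprisal of token \(i\) is
\(-\log(M_i/M_{i-1})\) (natural log by default; bits by config), so token
surprisals telescope to \(-\log M_n\), and RNNG perplexity is
\(\exp(-\log M_n / n)\) — a prefix-marginal quantity, with no
tree-completion term. Because each \(M_i\) is a subset sum of the exact
prefix marginal, beam marginals are lower bounds, and perplexity at an
exhaustive beam is never worse than at a smaller beam; both properties are
tested.

**Distance.** The study counts "parser actions in the beam" per segment;
the text does not pin down whether that means expansions explored or
actions of surviving derivations. The default here is the number of
candidate state expansions performed between word synchronizations
(`distance = "explored"`), the reading closest to "syntactic work";
`"survivors"` (actions taken by surviving beam entries, per token) and
`"viterbi"` (actions on the best derivation) are available behind the same
switch.

**Exactness check.** On a tiny ambiguous grammar with caps
`open_cap = 2, nt_budget = 2`, every derivation prefix can be enumerated by
plain recursion, independent of the beam code. With an exhaustive beam the
two computations agree to machine precision per token, for both strategies,
with random and with trained parameters — the package's strongest guard
against search bugs.

# Training, on a tape

No neural-network library is assumed: the models run on a small tape-based
reverse-mode automatic-differentiation engine written in R, with fused
LSTM-cell, affine+tanh, and affine+softmax-NLL operations (one tape node
each, hand-derived backward passes, verified against central finite
differences to 1e-5). Training is Adam (defaults lr 1e-3–8e-3 as per
config, one update per sentence/tree), minimizing gold-derivation NLL for
RNNGs (oracle actions under the model's own strategy) and sentence NLL
including the end-of-sentence event for the LSTM. Desk-scale defaults are
width 64 and 1 layer; width 256 / 2 layers — the full-scale architecture —
is a config change, not a code change. Word tokens rarer than 2 become
`<unk>` by default. All training is bit-reproducible under a fixed seed
(pure-R numerics, seeded shuffling, no parallelism).

The Kneser–Ney model is interpolated modified Kneser–Ney with discounts
D1, D2, D3+ from count-of-count statistics, continuation counts below the
top order, a uniform floor closing the backoff chain, and n-grams ending in
`<s>` excluded so that every context's distribution sums to exactly 1 over
the prediction support (verified by brute-force summation). Bit
compatibility with any particular external toolkit is a non-goal.

# From metrics to regressors

Per-segment predictors are: `word_rate` (amplitude 1 at each segment
offset), `word_length` (characters per segment), `word_freq` (log mean
within-corpus relative word frequency), `sentid`, `sentpos`, and the six
language-model metrics (`ngram`, `lstm`, `surp_RNNG_TD`, `surp_RNNG_LC`,
`dis_RNNG_TD`, `dis_RNNG_LC`; "5-gram" is not a valid R name, hence
`ngram`). All value predictors are placed at segment offsets — the study
states the offset convention explicitly only for word rate; adopting it for
the others is an assumption recorded here. `sentid`/`sentpos` are convolved
like the other value predictors (the study's wording is ambiguous between
convolving them and entering them per frame; convolution keeps all
event-locked predictors on the same footing).

The HRF is the canonical double-gamma (peak delay 6 s, undershoot delay
16 s, dispersions 1 s, peak:undershoot 6), peak-normalized; convolution
superposes HRF copies on a grid oversampled 50x relative to TR (1 s
stimulus-onset asynchrony against a 2 s TR demands sub-TR resolution), then
samples at frame times. Columns are built per block, frames in the first
20 s of each block dropped, each LM column orthogonalized independently
against {constant, convolved word rate} (the study orthogonalizes against
word rate only, not mutually), six motion parameters appended unconvolved,
and every column standardized — including motion, where the study's "all
the predictors were standardized" is taken at its word. Outlier frames
(|z| > 3 per ROI; the study does not define "outliers", so a conventional
rule is used) are censored before fitting.

The synthetic design reproduces a known property of such designs: after
HRF convolution the surprisal columns are nearly collinear (pairwise
r ≈ 0.99), matching the study's own predictor-correlation table. Inference
about any single surprisal predictor therefore rides on a thin slice of
unique variance — the reason the recovery experiment needs either a large
pooled sample or a substantial effect (below).

# ROI mixed models and ladders

Per ROI, subjects' censored frames are pooled and modeled as
`y = X beta + u[subject] + eps`, `u ~ N(0, sigma_u^2)`. Fitting is maximum
likelihood — never REML, since every fit feeds a likelihood-ratio test on
fixed effects (a REML-based LRT is rejected as a contract error). With a
single random intercept the covariance inverse has a closed
Sherman–Morrison block form, so beta and the residual variance are profiled
out and a single variance ratio is optimized on the log scale; the zero
boundary is always checked. The profiled fitter reproduces `lme4::lmer`
(the natural general-purpose choice, used here as an independent
cross-check, not as the implementation) to 1e-12 on test problems, at a
small fraction of the cost — the calibration and recovery experiments below
run thousands of fits.

Ladders add one predictor at a time to the baseline
(`word_rate + word_length + word_freq + sentid + sentpos + motion`,
random intercept by subject); each step is a chi-square LRT with df 1, and
significance is flagged at the Bonferroni gate alpha = 0.05/8 = 0.00625
across ROIs. All four study ladders are provided: surprisal adding TD before
LC, the reverse, and both distance orders.

## Calibration and recovery: what is tested, and why this way

* **Type-I calibration** (1,000 null simulations, small balanced design,
  white residual noise, a white-noise added predictor): the LRT rejection
  rate at alpha = 0.05 must lie in [0.035, 0.065]. White noise is used
  because the test targets the LRT's distributional correctness under the
  model's own assumptions.
* **AR(1) caveat.** The mixed model — like the study's own `lmer`
  analysis — assumes white residuals. Under the generator's realistic AR(1)
  default (lag-1 rho 0.3) with a smooth HRF-convolved predictor, the LRT is
  anticonservative (measured here at roughly 0.14 at alpha 0.05). Passing
  calibration under white noise therefore does **not** certify calibrated
  p-values on autocorrelated real data; it certifies the statistic.
* **End-to-end recovery** (200 replicates): a true `surp_RNNG_LC` effect is
  injected into five of the eight ROIs; the four-step surprisal ladder is
  run per replicate with AR(1) noise and subject intercepts at the
  generator defaults (sigma_subject 0.3, sigma_noise 1, rho 0.3, 34
  simulated subjects). The per-replicate rejection rate in every
  effect-bearing ROI must be at least 0.9, and an ROI is *flagged* when the
  final-step comparison is significant in a majority of replicates — the
  flagged set must be exactly the effect set. The majority rule is the
  ROI-level decision: with a 0.00625 gate, single null rejections across
  600 null-ROI tests are expected by chance and do not constitute a
  discovered ROI.
* **Configured effect size.** Because the surprisal columns are ~0.99
  collinear (by design, mirroring the study), a small final-step effect is
  undetectable at desk scale (34 simulated subjects x ~170 frames, versus
  the study's ~28,000 pooled rows). The injected effect is 0.6 sd on the
  standardized LC-surprisal regressor, chosen once so that the implied
  final-step z is ~7.5 and the recovery experiment tests the pipeline
  rather than the sample size. What passing shows is parameter recovery
  and error control of the machinery — not that effects of that size are
  typical of real BOLD data.

# Whole-brain stage

Per subject, voxelwise OLS of the simulated 4-D volumes on the design
(motion excluded, matching the study's first-level convention) produces
beta maps; a one-sample t across subjects is mapped monotonically to z;
two-sided voxelwise p-values are corrected by Benjamini–Hochberg at
q = 0.05 within the mask; surviving voxels are grouped by 6-connectivity
(18/26 by config — the study does not state its connectivity) and clusters
under 100 voxels are removed. Gaussian smoothing (sigma = FWHM/2.355 per
axis in mm, reflecting boundaries so constants are preserved) is applied to
subject beta maps at the second level, where the study mentions it; the
extent-rule checks run unsmoothed, because smoothing deliberately spreads a
blob and would turn an extent-rule test into a smoother test. The mask is
synthetic (all-true grid standing in for a cortical mask); anatomical
labeling and MNI space are out of scope.

Null calibration: across 200 pure-noise maps the mean number of surviving
clusters must be at most 0.05; an injected 150-voxel blob must return as
exactly one cluster of at least 100 voxels, and a 99-voxel blob must be
rejected by the extent rule.

# What the synthetic data does and does not emulate

The PCFG fixture is head-final (postpositional noun phrases, verb-final
clauses, left-branching relative clauses) so that top-down and left-corner
derivation geometry genuinely diverge; sentences are segmented into 1–3
token presentation units (the real segment-length distribution of the
stimulus corpus is not public; this choice is unvalidated against it).
Blocks, a 1 s stimulus-onset asynchrony (500 ms display + 500 ms blank),
a 20 s discarded lead-in, and TR = 2 s reproduce the presentation protocol.
BOLD is linear in the design with subject-constant intercepts and
stationary AR(1) noise initialized from its stationary distribution (no
burn-in). Not emulated: real orthography and segmentation, register
structure of a real corpus, scanner drift and physiological noise,
nonlinearity of the hemodynamic response, spatial noise correlation, or
anatomical variability. Passing the recovery tests shows the pipeline
recovers known truth under these idealizations; it does not validate the
linking hypotheses on real data.

# Numerical choices and problem sizes

Tolerances: convolution linearity 1e-12, orthogonality 1e-8,
standardization 1e-8, beam-vs-enumeration 1e-6 per token, LMM closed-form
identities 1e-4–1e-6, cross-implementation log-likelihood 1e-3. Rejection
sampling caps at 100 attempts per tree; enumeration carries an explicit
node budget; infinite z-values at zero-variance voxels are capped at 40 and
flagged. The test suite runs at deliberately small problem sizes — width
8–16 models, 120-sentence treebanks, 200-replicate recovery loops,
12–14-voxel-wide grids — chosen so the full suite completes in minutes on
one CPU while still exercising every stage at non-trivial scale; all sizes
are config arguments, and the full-scale settings (width 256, 2 layers,
beam 100–1,000) run unchanged.

# Known limitations

* Pure-R training is desk-scale; 67k-sentence treebanks at width 256 are
  configurationally supported but not practical here.
* The left-corner model's implicit stopping makes it deficient; perplexity
  comparisons across strategies inherit the prefix-marginal convention.
* p-values on autocorrelated data are anticonservative (see the AR(1)
  caveat); no prewhitening is implemented.
* Random slopes, crossed random effects, and Satterthwaite/Kenward–Roger
  corrections are out of scope, as are MRI preprocessing, atlas
  parcellation, and peak labeling.
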