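---
title: "Estimating the dimensionality of forearm muscle activation from surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the dimensionality of forearm muscle activation from surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgsynergy)
```

## The problem

Myoelectric prostheses read a user's intent from surface EMG recorded over
the forearm. How many independent control signals a given user can produce —
the dimensionality of their muscle activation space — bounds how many degrees
of freedom a simultaneous and proportional interface can drive. Under the
muscle synergy framework, multichannel EMG is modeled as a small number of
fixed co-activation patterns (synergies) recruited by time-varying
coefficients, and the number of synergies is that dimensionality.

`emgsynergy` implements the full analysis chain for NinaPro-style recording
sessions (12 electrodes at 2 kHz, movement/repetition labels per sample):
envelope preprocessing, non-negative matrix factorization (NMF), a
cross-validated rule for choosing the number of synergies, typing of the
extracted synergies by clustering their movement-activation profiles across
subjects, classification of patient synergies against the control types, and
the group statistics relating synergy counts to clinical covariates. A
synthetic-data generator with known ground truth stands in for real
recordings so every stage is testable offline.

## The model

Let `E` be the nonnegative `n x T` matrix of pooled, normalized EMG
envelopes (`n` electrodes, `T` retained samples). NMF approximates

    E ~ W H,    W >= 0 (n x k),    H >= 0 (k x T)

where the columns of `W` are synergies (electrode weightings) and the rows
of `H` their activation coefficients. Reconstruction quality is the variance
accounted for,

    VAF = 100 * (1 - SSE / SST),

with `SSE` the squared residual and `SST` the sum of squares of the original
data (no mean subtraction — the data are nonnegative envelopes, not centered
signals). VAF is computed globally and per electrode (local VAF); the local
criterion protects against a reconstruction that is excellent on strong
channels while ignoring a weak one.

## Preprocessing choices

- **Envelope**: rectification followed by a zero-lag (forward–backward)
  Butterworth lowpass, design order 4, cutoff 3 Hz. The forward–backward
  pass doubles the effective magnitude order and cancels phase lag; any
  undershoot from filter ringing is clipped to zero so the matrix handed to
  NMF stays nonnegative. Whether to clip or to add a signal-dependent offset
  is an open choice; clipping is the documented one here.
- **Decimation** to 100 Hz by plain sample-keeping. With a 3 Hz envelope
  bandwidth the new Nyquist rate (50 Hz) leaves a wide guard band, so no
  anti-alias stage is needed.
- **Pooling**: rest-labeled samples are dropped, the remainder concatenated
  across trials in temporal order, and each channel divided by its own
  standard deviation computed over the pooled samples. No centering is
  applied, again to preserve nonnegativity. The BB/TB channels (biceps,
  triceps) are never pooled: they record arm muscles not involved in
  hand/wrist movements.
- Stage order is fixed: rectify+filter, decimate, segment/pool, normalize.

## Choosing the number of synergies

For each candidate `k` from 1 to `n`, `estimate_k()` repeats (50 times by
default): split the pooled samples at random into an extraction subset (75%)
and a validation subset (25%); factorize the extraction subset at `k`; hold
`W` fixed and refit `H` on the validation subset; record global and local
VAF of the validation reconstruction. The trial with the maximum validation
global VAF represents that `k`. The chosen count is the minimum `k` whose
representative trial achieves global VAF strictly above 95% *and* every
local VAF strictly above 85%. Both criteria are evaluated on the single
best-global-VAF trial; the criteria are strict inequalities. When no `k`
qualifies, the result reports `k = n` with a `saturated` flag rather than
silently inventing a count.

Numerical choices for the NMF itself (multiplicative updates for the
Frobenius objective): iteration cap 500, stop when the relative error change
between evaluations falls below 1e-6 (error is evaluated every 10 iterations
by default), denominator guard 1e-12, initialization uniform on (0, 1) from
an explicit seed. Doubling the iteration cap changes achieved VAF by less
than 0.01 on the synthetic benchmarks, so the cap is not the binding
constraint. A master seed spawns per-(k, repeat) child seeds
deterministically, so runs are reproducible and parallelizable. The
Euclidean (squared-error) update variant is used rather than KL: the model
selection criterion is itself built on squared error.

`estimate_k(..., early_stop = TRUE)` stops scanning at the first `k` that
meets the dual criterion. Because the chosen count is defined as the minimum
qualifying `k`, early stopping cannot change the answer; it only leaves the
per-`k` curves above the stopping point unevaluated. The benchmarks use it
to keep runtimes modest.

## Typing synergies across subjects

Electrode placement in prosthesis-oriented montages is not anatomically
precise, so synergy weight vectors are not comparable across subjects.
Instead each synergy is summarized by *what movements recruit it*: a
17-element profile of mean activation per simple-movement type (wrist and
finger movements; functional grasps are excluded because inter-personal
grasp strategies make those profiles unstable), z-normalized to zero mean
and unit standard deviation to remove the NMF scale ambiguity. The
population (1/N) standard deviation is used throughout — an arbitrary but
fixed convention for bit-reproducibility.

Profiles pooled across control subjects are clustered by k-means under the
correlation distance `1 - r`. On z-normalized vectors `1 - r` is a monotone
function of squared Euclidean distance, so a Lloyd iteration whose centroid
update is the member mean re-z-normalized converges; an emptied cluster is
reseeded from the sample farthest from its centroid. For each candidate
cluster count (2–15) the best of 50 restarts (minimum total within-cluster
distance) is kept, and the count maximizing the mean silhouette (also under
`1 - r`) wins, ties going to the smaller count.

Each cluster is described by its representative movements: with mean `m`
and standard deviation `s` across the centroid's 17 entries, the strongest
movement is *primary* if it reaches `m + 2s`, and the second strongest is
*secondary* if it reaches `m + 1s`; ties break toward the lower movement
index and a constant centroid has no representatives.

Patient synergies are never pooled into the control clustering (their
heterogeneity degrades it); each is assigned to the nearest control centroid
if its distance does not exceed that cluster's maximum within-cluster
sample-to-centroid distance, and reported as untyped (0) otherwise. The
comparison is inclusive (`<=`) so that any feature used in training
re-assigns to its own cluster.

The per-synergy explained-variance share reported alongside the typing is
the global VAF of the rank-1 reconstruction from that synergy alone. An
incremental (leave-one-out) definition would be a defensible alternative;
because synergies are not orthogonal, rank-1 shares need not be additive,
and the documented choice is the rank-1 one.

## Group statistics

Synergy counts are related to clinical covariates by Spearman rank
correlation (mid-rank ties, two-sided); paired comparisons (for example
8- vs 10-electrode counts in the same subjects) use the Wilcoxon signed-rank
test with zero-difference exclusion, exact p-values for up to 25 untied
nonzero differences and the tie-corrected normal approximation otherwise;
unpaired group comparisons use the Mann–Whitney U test; body-size
comparisons use Welch's t. No multiple-testing correction is applied in the
primary analysis (one test per covariate); `adjust_holm()` is available for
larger screens.

## The synthetic generator

`make_ground_truth()` and `synthesize()` emulate a labeled recording
session: 17 movements, 6 repetitions each, interleaved rest, 2 kHz sampling
(defaults 5 s movement, 3 s rest per block — the session structure of the
acquisition protocol the package targets). Ground truth consists of a
nonnegative weight matrix `W_true` and a per-movement activation matrix.
Each synergy is *anchored* on its own electrode subset (the electrodes are
partitioned among synergies, anchor weights near 1, sparse off-anchor
weights with a small floor on every channel): physiologically, distinct
synergies recruit distinct muscle groups, while volume conduction gives
every surface channel some signal. Columns are rejection-sampled until all
pairwise cosine similarities are at or below 0.7. Each synergy dominates a
disjoint block of movements; repetition-level gains are jittered.

By default the emitted signal is a broadband carrier — zero-mean white noise
amplitude-modulated by the planted envelope, plus additive sensor noise at
0.1 of the mean envelope amplitude — so the rectify/filter/decimate stages
are genuinely exercised: the recovered envelope correlates above 0.95 with
the planted one at default settings. With `carrier = FALSE` the nonnegative
envelope itself is emitted (sensor noise then half-normal), which is the
mode used for rank checks and for fast benchmarks. The anchored structure
and the noise default are calibrated so that the synergy-count benchmark
recovers the planted count reliably at default noise and degrades under
noise an order of magnitude larger — a meaningful dynamic range rather than
a trivially easy or impossible task.

`make_cohort()` adds subject-level clinical covariates through a Gaussian
copula: a latent normal drives the subject's true synergy count, and each
covariate is generated with a configurable Spearman association to that
latent, with marginals spanning the ranges typical of transradial amputee
cohorts (residual forearm percentage, age, years since amputation, ordinal
phantom-sensation score). Configured associations
are therefore recoverable end to end through the pipeline.

What the generator does **not** emulate: motor-unit physiology, volume
conduction between specific muscles and electrodes, power-line interference
(the targeted datasets are distributed already Hampel-filtered),
within-session electrode shift, or movement mislabeling. Passing the
recovery benchmarks therefore shows the *algorithmic* chain is correct under
the stated generative model, not that real recordings satisfy that model.

## Problem sizes used in the tests

The test suite and the acceptance script shorten movement/rest blocks to
0.3 s / 0.2 s (0.25 s / 0.125 s for the cohort-statistics rehearsal) and
reduce split repetitions from 50 to 10 (3 for the cohort rehearsal) — the
package's own choice of desk-scale benchmark sizes. Protocol structure,
noise level, separation bound and all thresholds are the package defaults.
The synergy-count benchmark covers true counts 2–6 at 10 electrodes, 20
generator seeds each; the typing benchmark plants 6 synergy types across a
40-subject cohort; the statistics benchmark uses ten 40-subject cohorts.

## Known limitations

- The MAT-file reader supports level-5 containers (including compressed
  elements) but not v7.3/HDF5; files must be saved as v5/v7.
- The dual-VAF rule evaluates both criteria on the single trial with the
  best validation global VAF, which is one reading of the selection rule;
  requiring some trial to pass both jointly is a plausible alternative.
- k-means under `1 - r` with re-normalized centroids is a local optimizer;
  restarts mitigate but do not eliminate local minima.
- Saturated results (`k = n` with no qualifying k) are flagged, not
  resolved; downstream statistics treat the saturated count like any other.
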