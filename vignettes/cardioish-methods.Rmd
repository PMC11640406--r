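---
title: "Lead-transition feature engineering for 12-lead ECG beats: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lead-transition feature engineering for 12-lead ECG beats: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioish)
```

## The model

`cardioish` classifies and explains fixed-length 12-lead ECG beats through
a rank-based symbolic encoding. The premise is physiological: at any
instant of the cardiac cycle, the relative ordering of the twelve lead
amplitudes reflects the spatial direction of the heart's net electrical
vector, and pathologies that displace or silence part of the myocardium
perturb that ordering in characteristic ways. The pipeline therefore
discards absolute amplitude entirely and works with the *ranking* of leads
at each sample.

**Encoding.** For a beat $B \in \mathbb{R}^{12 \times L}$, each sample
column is replaced by the permutation of lead indexes sorted by descending
amplitude (`rank_block()`), and the $L$ permutations are concatenated into
an integer sequence of length $12L$ (`transform_beat()`). The encoding is
invariant to any positive rescaling of the whole beat and to any
per-sample constant added to all leads, which gives robustness to gain
differences and common-mode baseline wander for free. It is *not*
invariant to per-lead baseline shifts, which genuinely reorder leads.

**Features.** The $12 \times 12$ transition table of that sequence counts
how often lead $a$ is immediately followed by lead $b$; the counts always
total $12L - 1$. Within one sample's permutation no lead repeats, so
diagonal cells can only be hit at the boundary between consecutive
samples — exactly where a *stable* ranking keeps the last-ranked lead in
place. Rows are normalised to empirical transition probabilities and the
table is flattened row-major into 144 features, feature
$u = 12(k-1) + l$ being cell $(k, l)$.

**Selection (INCA).** Features are min–max normalised per column, weighted
by neighbourhood component analysis, and ranked by decreasing weight. NCA
fits one weight $w_f$ per feature by maximising the expected leave-one-out
soft nearest-neighbour accuracy

$$F(w) = \frac{1}{n}\sum_i \sum_{j \neq i,\, y_j = y_i} p_{ij}
  - \lambda \sum_f w_f^2,
\qquad
p_{ij} = \frac{e^{-d_{ij}}}{\sum_{k \neq i} e^{-d_{ik}}},
\qquad
d_{ij} = \sum_f w_f^2\,|x_{if} - x_{jf}|,$$

a weighted cityblock distance with squared weights so that relevance is
sign-free. Growing prefixes of the ranking (sizes `start`..`stop`) are
then scored by stratified cross-validated 1-NN misclassification, all
prefixes under the *same* fold partition so the loss curve is comparable
across sizes, and the smallest prefix attaining the minimum loss is kept
(greedy minimum, fewest features on ties).

**Classification.** 1-nearest neighbour under the L1 metric with
stratified 10-fold cross-validation. With $k = 1$ vote ties cannot occur;
distance ties resolve to the lowest training-row index, so the whole
pipeline is deterministic given its seeds. Reported metrics are overall
accuracy and the geometric mean of per-class recalls, which collapses to
zero if any class is never recovered.

**Symbolic decoding.** Selected feature indexes decode to (from-lead,
to-lead) pairs in the fixed 12-symbol alphabet
`Ld1 Ld2 Ld3 AVR AVL AVF V1S V2S V3A V4A V5L V6L`. The decoding is
*defined* as the exact inverse of the row-major flattening,
$u \mapsto (\lceil u/12 \rceil,\ ((u-1) \bmod 12) + 1)$, and the package
verifies this inversion exhaustively over all 144 indexes in its tests;
any decoding not satisfying it would silently attribute transitions to the
wrong leads. Pairs concatenate, in selection-ranking order, into the
Cardioish sentence; its symbol counts give a frequency distribution whose
base-2 Shannon entropy is bounded by $\log_2 12 \approx 3.5850$ bits, and
its consecutive-symbol transition table defines the connectome graph.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `epsilon` (row / min–max normalisation) | `1e-10` | – | Large enough to guard empty rows and constant columns against division by zero, small enough to be invisible next to counts of order $12L$ at realistic beat lengths. |
| `lambda` (NCA ridge) | `1/n` | – | Shrinks with sample size like the data term; keeps weights finite on separable toy data without biasing rankings at realistic $n$. |
| `max_iter`, `tol` (NCA optimiser) | 60, `1e-6` | – | Full-batch adaptive-step gradient ascent converges on all tested problems well before the cap; the tolerance is a relative objective change. |
| `start`, `stop` (prefix range) | 1, 144 | features | The full range; narrow it to cap the sentence length. |
| `folds` | 10 | – | Standard for beat-level evaluation; automatically reduced (with a warning) when a class has fewer members than folds. |
| `k` (neighbours) | 1 | – | The pipeline's point is that one neighbour suffices once the features are right; `k = 1` also removes vote ties. |
| `noise_sd` (generator) | 0.016 | mV | Calibrated so that ~10% of samples have their full 12-lead ranking perturbed under the default template and gain ladder (measured 0.006 at 0.010, 0.053 at 0.014, 0.104 at 0.016, 0.256 at 0.020 mV). |
| `baseline` (generator) | 0.5 | mV per unit gain | Keeps every lead's waveform strictly positive so the noise-free ranking is constant within a beat. |

## The synthetic generator: what it does and does not emulate

`generate_beatset()` renders beats as a gain- and offset-scaled sum of
five Gaussian waves standing in for P, Q, R, S and T, at 651 samples by
default, with i.i.d. Gaussian amplitude noise. Class structure enters
only through the per-lead gains: each class assigns a strictly decreasing
gain ladder to the leads along its own permutation, so each class's
noise-free rank encoding is a single constant permutation.

One subtlety drove the design: a constant ranking contributes its
transition cells as a *cycle*, and two rotations of the same cycle hit
identical cells, so classes whose gain orderings merely rotate one another
are indistinguishable to the transition features despite having different
rankings. `separable_profiles()` therefore walks the leads with strides 1,
5, 7 and 11 for the first four classes — all coprime to 12, so their
transition-cell sets are pairwise disjoint — and screens further seeded
permutations to share no adjacency set with any earlier class.
`planted_cells()` exposes each class's cycle cells so tests can verify
analytically that selection lands on a genuinely class-discriminative
transition.

What the generator does **not** emulate: physiological waveform morphology
beyond five Gaussians (no QRS notching, no ST-segment dynamics), rhythm
and rate variability, correlated or coloured noise, electrode artefacts,
or inter-beat alignment error — beats arrive pre-segmented and aligned by
construction. Passing tests on this generator therefore demonstrate that
the *pipeline machinery* is correct and recovers planted rank structure at
calibrated noise; they do not certify classification performance on real
recordings, where class differences are subtler than a global lead
reordering.

## Numerical and design choices

* **Ties in ranking.** Equal amplitudes sort stably with the lower lead
  index first, so an all-zero sample maps to `1:12`. A deterministic rule
  is required for reproducibility; raw signed amplitudes are ranked (not
  absolute values).
* **Flattening order.** Row-major, chosen jointly with the symbol
  decoding so that the pair (from-lead = row, to-lead = column) inverts it
  exactly.
* **Fold construction.** Within each class, members are shuffled by seed
  and dealt cyclically; every class appears in every fold whenever counts
  allow, and the fold count drops to the minimum class size otherwise.
* **Degenerate inputs.** Empty transition rows normalise to zero rows;
  constant feature columns normalise to zero; empty selections produce a
  valid zero-length sentence with a warning; single-class label sets are
  rejected.
* **Selection bias, reproduced deliberately.** The selection phase sees
  the labels of all beats before the final cross-validation, so the
  headline accuracy is optimistic. This mirrors the procedure the package
  implements; `run_pipeline(nested = TRUE)` provides an honest variant
  that reruns selection inside every training fold, off by default.
* **Entropy.** Base-2 Shannon entropy of the sentence's symbol counts;
  the package pins the count-to-entropy computation in its tests (the
  bundled example frequency rows evaluate to 3.5752 and 3.5637 bits at
  4 dp).
* **Seeding.** One master seed fans out to per-beat noise seeds and to
  the selection and evaluation fold seeds through a fixed linear
  congruential mix, so every artifact is regenerable from the run
  manifest alone.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
structural invariants on 200 random beats of 5–25 samples; brute-force
cross-checks of transition counting and 1-NN on 50 small random
instances; and end-to-end planted-signature recovery with 2 classes at
the full 651-sample beat length — 10 beats per class noise-free, 100 per
class at the calibrated noise. These sizes were chosen to exercise every
code path at full beat length while keeping the whole suite fast enough
to run habitually during development.

## Known limitations

* NCA weighting is a deterministic full-batch reimplementation; other NCA
  implementations (different optimisers, penalties or initialisation) can
  produce different rankings on weakly-informative features, so selected
  sets should be compared across settings before clinical interpretation.
* The geometric mean is defined over class-wise recalls; with many small
  classes a single hard class dominates it.
* Beat sets are read as pre-segmented, pre-aligned matrices; no QRS
  detection, filtering or resampling is provided.
* The connectome graph is a visualisation of transition counts, not a
  causal or anatomical claim.
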