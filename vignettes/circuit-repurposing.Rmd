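---
title: "Explainable drug-target prioritization on signaling circuit maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable drug-target prioritization on signaling circuit maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitshap)
```

## The model

circuitshap estimates how strongly each *known drug target* (KDT) — a gene
targeted by at least one drug with an annotated pharmacological action —
regulates each *signaling circuit* of a disease map. A circuit (effector
subpathway) is a minimal directed signaling unit ending at an effector gene,
named `"Pathway Name: effector gene"`; a disease map is the collection of
circuits whose genes are associated with the disease. The inputs are two
sample-aligned matrices over a reference cohort of healthy samples: `X`
(samples × KDT expression, normalized upstream) and `Y` (samples × inferred
circuit activities, produced upstream by a signal-propagation method and
consumed here as given).

The map `X -> Y` is learned with a **multi-output random forest** (MORF):
an ensemble of regression trees whose leaves hold one value per circuit and
whose splits minimise the mean squared error summed over all circuits. The
aggregated criterion regularises the splits — every split must be justified
across the whole output space — at the cost of some per-circuit resolution
(see *Limitations*). The forest prediction is the arithmetic mean of the
per-tree leaf vectors, a fact the attribution step exploits.

The fitted map is then explained with **interventional Shapley values**. The
samples are split into a *background* set (used to fit the forest and to
integrate expectations) and a *validation* set (the samples being explained).
For validation sample `x`, feature `i` and circuit `k`, the attribution is
the Shapley value of the game whose value function is

```
v(S) = mean over background rows b of  f_k( hybrid(x, S, b) )
```

with `hybrid(x, S, b)` taking the features in coalition `S` from `x` and the
rest from `b`, and the standard coalition weights `|S|! (p - |S| - 1)! / p!`
over the `p` features. Attributions are computed exactly per tree: along the
joint path of `x` and `b` through a tree, only the features on which the two
points diverge are players, and each reachable leaf contributes its value with
a closed-form factorial weight determined by how many x-committed and
b-committed features lie on its path. Per-tree attributions are averaged over
trees and background rows. Two checkable properties pin the implementation
down: *local accuracy* (the attributions of a sample sum to its prediction
minus the background-mean prediction, enforced to 1e-6 in the tests) and
agreement with a brute-force coalition-enumeration oracle to 1e-8 on small
forests. The oracle traverses the tree lists in pure R and enumerates all
`2^p` coalitions, so it shares no code with the fast path.

The attribution tensor is reduced to a **signed relevance matrix**: the
magnitude of pair `(i, k)` is the mean absolute attribution over validation
samples; its sign is the sign of the Pearson correlation between the KDT's
expression and its attributions across those samples. The correlation rule was
chosen over the sign of the mean attribution because the latter vanishes for
symmetric effects (a KDT whose high and low expression both matter); the
correlation captures the *direction* of influence. With a single validation
sample the sign is undefined and set to 0 with a warning.

Selection then limits the dimensionality: a circuit whose held-out R² falls
below `r2_th` (default 0.5) selects no KDT at all — poorly modeled circuits
contribute nothing — and an adequately modeled circuit selects the KDTs whose
magnitude reaches the `q_th` quantile (default 0.95) of that circuit's
magnitudes. Quantiles use linear interpolation between order statistics
(R type 7) and ties at the threshold are included. The element-wise product of
the signed relevance and the binary selection matrix is the final
**repurposing profile** `S'`.

## Quality measures

Two data-driven measures validate a run, reported per circuit and as a
map-wise average, each with a 95% confidence interval:

* **R²** of the held-out predictions (1 = perfect, 0 = no better than the
  per-circuit mean, unbounded below), with percentile intervals over
  resampling runs.
* **Nogueira selection stability**: for `M` runs over `d` KDTs,
  `s = 1 - mean_f(s_f^2) / ((k/d)(1 - k/d))` where `s_f^2` is the unbiased
  variance of feature `f`'s selection indicator across runs and `k` the mean
  number selected per run. It is 1 iff every run selects the same
  (non-degenerate) set, 0 in expectation under independent random selection,
  and negative for anti-consistent selection; the interval uses the
  estimator's asymptotic normal variance. Stability effect sizes are banded
  poor (`s <= 0.4`), mid (`0.4 < s < 0.75`) and excellent (`s >= 0.75`), and
  these bands color the stability summary figure.

The resampling protocol (`bootstrap_evaluate()`) draws, per run, a fresh
seeded 75/25 train/test split, fits the forest on the training set, scores R²
on the test set, and runs the attribution + selection pipeline with the
training set as background and the test set as validation. We re-split the
background/validation partition inside every run rather than reusing one
split, because the stability estimate is only meaningful when each run sees
an independent perturbation of the data. The default is 100 runs; the final
reported `S'` comes from one additional fit on a fresh split, not from
averaging runs. Stability is computed per circuit (and averaged map-wise)
rather than on the concatenated map-level selection, so that an unstable
circuit cannot hide behind a stable one.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_trees` | 200 | trees in the forest |
| `max_depth` | 8 | maximum tree depth |
| `max_features` | `ceiling(sqrt(p) + 20)`, capped at `p` | candidate features per split |
| `q_th` | 0.95 | relevance quantile for selection (unitless, per circuit) |
| `r2_th` | 0.5 | held-out R² gate for a circuit to select anything |
| `background_subsample` | 1000 | background rows integrated per attribution |
| `fraction` | 0.75 | background (or training) share of each split |
| `k` (imputation) | 5 | neighbours for kNN imputation |
| `n_splits` | 100 | resampling runs of the evaluation |

The `max_features` rule deserves a note: a feature budget a little above
`sqrt(p)` stabilises split selection when many KDTs are irrelevant to most
circuits, while the `+ 20` floor keeps small maps from degenerating to nearly
random splits. `tune_successive_halving()` can replace the depth/feature
defaults by a data-driven choice: candidates start with 10 trees, each round
keeps the top third by validation R² and triples the budget (rate η = 3), and
the winner is refit with the standard 200 trees. Tuning is off by default
(`n_iters = 0`).

Missing expression values are imputed by k-nearest neighbours before fitting:
distances are Euclidean over mutually observed features, rescaled by the
fraction observed, and each missing cell takes the mean of its column over
the `k` nearest rows. Observed cells are never altered, and imputed values
always lie within the column's observed range.

## Numerical choices and degenerate inputs

* Splits scan midpoints between consecutive distinct feature values; ties in
  feature values cannot be split apart. Bootstrap resampling is with
  replacement at full sample size.
* All randomness is governed by integer seeds. User-facing seeds are hashed
  (Knuth multiplicative) before seeding R's RNG because consecutive
  Mersenne-Twister seeds produce correlated first draws, which would couple
  the resampling runs of the evaluation protocol. Fits are bit-reproducible:
  the compiled core uses its own splitmix64 stream rather than
  implementation-defined C++ distributions.
* Zero-variance circuits in a test split make R² undefined; the run is
  skipped with a warning, and more than 20% skipped runs abort the
  evaluation. Degenerate selections (no KDT, or every KDT, in every run) make
  the stability estimator's null variance zero; the estimate is reported as
  `NA` with a warning.
* A circuit failing the R² gate keeps its row in the score table but
  contributes an all-zero column to `S'`.
* In the clustermap, each displayed circuit row of `S'` is scaled by its
  maximum absolute entry (symmetric max-abs scaling into `[-1, 1]`), rather
  than min/max scaled, so that the sign structure and the zero point are
  preserved. Circuits whose stability lower confidence bound falls below 0.4
  are excluded, as are all-zero rows and columns. The hierarchical ordering
  (correlation distance, average linkage) is cosmetic.
* Drug-level aggregation sums (not averages) the `S'` rows of a drug's
  targets, preserving additivity with the ℓ1 ranking; "stable circuits" for
  the per-pathway aggregation are those with stability lower bound at least
  0.4, the same rule the clustermap uses.
* When several disease-map sources are configured at once, the priority is
  explicit `circuits`, then `disease_id`, then `seed_genes`, with a warning;
  the sources are arbitrated, not merged. The gene–disease association score
  threshold defaults to 0 (all curated associations) and is exposed as a
  parameter.

## What the synthetic generator emulates — and what it does not

`generate_synthetic_dataset()` plants a known ground truth: independent
standard-normal KDT expression, and each circuit's activity a linear (or
thresholded) combination of 3 driver KDTs with weight magnitudes in
`[0.5, 1.5]`, random signs, and Gaussian noise (default sd 0.3, a high
signal-to-noise regime). Driver sets may overlap across circuits, mimicking
pleiotropic targets. This exercises every contract in the pipeline — shapes,
alignment, determinism, attribution correctness, selection semantics,
stability — without any download.

It does **not** emulate real expression covariance (GTEx-like samples are
strongly correlated across genes), count-derived noise, or the dimensions of
a real run (thousands of KDTs, tens to hundreds of circuits). Passing tests
on this fixture therefore demonstrate the machinery is correct, not that the
method's biological conclusions transfer; and recovery metrics measured at
the fixture's small scale are conservative in a specific way discussed next.

## Known limitations

The aggregated split criterion makes trees serve all circuits at once. At
realistic scale this is the method's regularisation; at small fixture scale
(tens of KDTs, a handful of circuits with disjoint drivers) it produces a
measurable *dilution*: depth-8 forests cap well below the noiseless R²
ceiling for circuits with several moderate-weight additive drivers, and
strong drivers of one circuit accumulate small spurious attributions on the
others. In our measurements on a 500-sample, 50-KDT, 5-circuit planted
fixture, weakly-driven circuits can fall below the 0.5 R² gate and the
top-quantile selection can mix pleiotropic drivers of other circuits into a
circuit's selected set — behavior we verified is reproduced exactly by an
independent reference learner fit with identical hyperparameters on identical
data. The acceptance script reports these recovery numbers as measured; they
are a property of the procedure at this scale, not an implementation
artifact. Interpreting real runs, the same effect argues for reading `S'`
jointly with the stability bands rather than as isolated per-circuit truth.

Computation is single-threaded; the attribution cost grows as
`n_validation × n_background × n_trees` and the background subsample
(default 1000 rows) is the main runtime lever. The problem sizes used in the
test suite and acceptance script (500 samples, 50 KDTs, 5 circuits, 25
resampling runs for the recovery study; smaller fixtures elsewhere) were
chosen so a complete validation runs in minutes on one CPU while still
exercising the full protocol.
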