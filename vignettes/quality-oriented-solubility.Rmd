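---
title: "Quality-oriented selection and consensus modelling of aqueous solubility data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-oriented selection and consensus modelling of aqueous solubility data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soluq)
```

## The problem

Public aqueous-solubility collections merge measurements from many
sources of very different reliability. The regression target is LogS,
the base-10 logarithm of molar solubility; typical public sources carry
internal errors anywhere between ~0.2 and ~0.7 LogS. Two consequences
drive everything in this package:

* **Observed vs actual performance.** A model scored against test
  labels that themselves carry error $\varepsilon$ can never show an
  observed RMSE below $\varepsilon$: a perfect predictor scores
  $\varepsilon$, and a model with actual (noise-free) RMSE $a$ scores
  $\sqrt{a^2 + \varepsilon^2}$ when the test noise is independent.
  Test-set quality therefore caps what any benchmark can reveal.
* **Training-data quality vs quantity.** Merging everything available
  maximizes size but imports the noisiest sources' errors; selecting by
  quality shrinks the data. The trade-off is empirical and depends on
  both the noise levels and how disagreements are resolved.

`soluq` implements the full pipeline: per-source quality estimation
from multi-lab measurements, duplicate and outlier handling,
quality-driven test/train selection, descriptor computation and
selection, a three-member consensus regressor with per-compound
uncertainty, and chemical-space diagnostics — plus a synthetic
multi-source generator so every stage is testable without downloads.

## Quality estimation from multi-lab measurements

Compounds are identified by InChIKey only; SMILES is payload. All
records sharing a key form a compound group. Within a group, values
within 0.01 LogS of each other are duplicates — copies of one
measurement that wandered between databases — and are merged by
single-linkage (any chain of sub-tolerance gaps merges; no pair inside
tolerance is ever split, which is the only partition rule with that
guarantee). Each cluster is represented by its member mean. A group
with at least two surviving distinct values is *multi-lab*: the same
compound measured with genuinely different outcomes.

A dataset's quality is the pooled SD of its multi-lab measurements.
For source $s$, every multi-lab group containing at least one record
from $s$ contributes the distinct values that originate from $s$,
deviations taken about the *group consensus mean* $\bar v_g$ over all
$n_g$ distinct values:

$$\mathrm{SD}_s=\sqrt{\frac{\sum_g\sum_{v\in s,g}(v-\bar v_g)^2}
{\sum_g m_{s,g}\,(n_g-1)/n_g}},\qquad N(\mathrm{SD})_s=\sum_g m_{s,g},$$

with $m_{s,g}$ the count of $s$'s distinct values in group $g$. The
denominator is the degrees of freedom carried by deviations about a
mean estimated from $n_g$ values, so for a scope covering whole groups
the formula reduces to the classical pooled form
$\sqrt{\sum SS_g/\sum(n_g-1)}$, and for two equal-noise sources at
full overlap it is an unbiased estimate of the common noise SD.
Attributing each value to its origin source (rather than crediting
every participating source with the whole group) keeps the per-source
counts additive — disjoint sources' $N(\mathrm{SD})$ sum to the total
number of multi-lab values — and, just as importantly, keeps the
estimator *sensitive*: pooling every group value into every
participating source would drag all *per-source* SDs toward a common
mixture and erase the quality differences the method exists to detect.

**Outlier flags.** Within a group, each distinct value is compared to
the median of the *other*, not-yet-flagged values, peeling the most
deviant value while the deviation reaches the `gap` threshold (default
1.0 LogS). Peeling matters: a gross outlier would otherwise
contaminate its neighbours' reference medians and make every value in
the group look deviant. A deviation within 0.05 of a whole decade is
additionally labelled `decade-shift` (unit-conversion misprint); a
value whose negation lands within 0.05 of the reference median is
labelled `sign-flip`. Values tied at the maximal deviation are flagged
together — a decade-apart pair is symmetric evidence and names no
culprit. Flags are advisory and never auto-removed. Note a structural
limit: a $\pm 1$-decade misprint produces a deviation distributed
around 1.0, so at the default gap of 1.0 roughly half of all such
misprints are undetectable in principle regardless of noise level;
reliable recovery (we observe recall above 0.8 with a false-flag rate
under 2% per clean group) needs replicate-grade sources
($\sigma\lesssim 0.15$) and a gap below the misprint magnitude (we use
0.6 in the tests).

## Test/train selection

The test set should be the *highest-quality* source that is still
large enough: among sources whose filtered size meets `size_floor`
(default 500), `select_test_set()` picks the minimal-SD source, ties
broken by larger $N(\mathrm{SD})$, then id. Sources with SD above
`sd_cutoff` (default 0.50 LogS) are excluded from training. On the
published nine-source reference table shipped with the package these
defaults reproduce the published decisions: source E (SD 0.274, the
Huuskonen benchmark) becomes the test set and the two high-SD sources
A (0.717) and F (0.582) are dropped.

`build_training_table()` then merges the retained sources into one row
per compound: test-set InChIKeys are removed *first* (so duplicate
collapsing can never move a test compound into training — the leakage
check is asserted on every build), duplicates collapse at the same
0.01 tolerance, and surviving disagreements resolve to the value from
the lowest-SD source (`resolve = "best-source"`; `"mean"` is
available). Output ordering is by InChIKey, making builds
byte-reproducible.

## Descriptors and feature selection

123 two-dimensional descriptors in six groups (atom-based 19,
ring-based 6, bond-based 9, computed LogP 1, topological 18, E-state
70) are defined by a versioned JSON manifest and computed by a
pluggable engine; the default engine drives RDKit through a bundled
Python helper, and a table-backed engine serves precomputed matrices.
The E-state group comprises 68 organic-element atom-type E-state sums
plus the max/min atomic E-state; the exact composition is a documented
approximation chosen once from a single pinned engine. Engine failures
on parseable structures are imputed with training-set medians, never
zero — E-state columns are legitimately zero-heavy, and zero-filling
would conflate failure with absence.

Two selection methods are provided. `lasso_select()` standardizes
internally, fits the L1 path over 100 log-spaced penalties spanning
four decades, and keeps the nonzero coefficients at the CV-minimal
penalty; on the sparse synthetic design used in the tests
($y = 3x_1 - 2x_3 + \epsilon$, $n = 500$, $p = 20$) it recovers
exactly the active set in 20/20 seeded runs. `pcc_select()` ranks by
absolute Pearson correlation (threshold 0.1 by default) and greedily
drops features correlating above 0.95 with an already-kept one. Inside
`cross_validate()` selection is refit per training fold by default, so
held-out rows never influence the chosen descriptors.

## The consensus model

`train_consensus(x, y)` fits three members on identically standardized
data — a single-hidden-layer neural network (100 units, early stopping
on a 10% validation split implemented by warm-started training
chunks), a 500-tree random forest (mtry = p/3, the regression
convention), and 500 rounds of gradient boosting (learning rate 0.05,
early stopping on a 10% split) — and returns a classed model with
`predict`, `print`, `summary`, `residuals` and `plot` methods. The
prediction is the unweighted member mean; its uncertainty is the
members' sample SD, which in the tests cleanly separates high-error
from low-error compounds (top-uncertainty-decile absolute errors
exceed bottom-decile errors in every seeded run). All member
randomness derives from one pipeline seed through fixed offsets, so
identical calls reproduce identical models. Member configurations live
in `consensus_config()`; `consensus_config_light()` (16 units, 300
trees, 300 rounds at rate 0.1) is the package's desk-scale choice for
experiments that retrain the consensus tens of times, and is what the
simulation experiments below use.

On the default synthetic generator with label noise 0.3, ten-fold CV
RMSE sits near 0.52 (members: network and boosting ≈ 0.47, forest
≈ 0.73 — forests are structurally weak on smooth additive truths, and
averaging in a weak member costs accuracy even as it stabilizes the
uncertainty estimate). The tests assert the band [0.3, 0.65]: bounded
below by the generative noise floor and above by this pilot behaviour.

## Chemical-space diagnostics

`coverage_score()` is the assertable statistic: standardize both
matrices by training statistics, calibrate a radius $r^\ast$ as the
0.95 quantile of train-to-train $k$-NN distances, and report the
fraction of test points whose $k$-th training neighbour is within
$r^\ast$. By exchangeability, same-distribution test sets score ≈ the
calibration quantile (0.9515 over 20 seeds in the acceptance run).
`embed_2d()` provides the familiar t-SNE picture (an exact $O(n^2)$
implementation with seeded, deterministic output and an $n/12$
learning rate, suitable for the desk-scale inputs this package
targets) — for *visualization only*, since embeddings distort
distances. `distribution_compat()` checks train/test LogS
compatibility with a two-sample KS statistic (pass at $D \le 0.15$ by
default; the threshold is a package convention, exposed as a flag).

## The synthetic generator

`synth_config()` describes a multi-source study: `n_compounds` (2000),
four sources with noise SDs (0.7, 0.4, 0.3, 0.25) spanning the range
reported for public solubility sources, per-source coverage
probability 0.5 (so multi-lab groups are plentiful), optional verbatim
cross-source duplicates, and optional misprints (±1 decade, sign
flip), every corruption recorded in a hidden ground-truth ledger. True
LogS is a sparse linear function of 20 standard-normal descriptors
plus a mild quadratic term, intercept −3 — giving a target with mean
≈ −3 and SD ≈ 2.1, the scale of real solubility tables.
`corrupt_test_labels()` adds the internal test error $\varepsilon$ for
observed-performance experiments.

What the generator does *not* emulate — real descriptor correlation
structure, chemistry-dependent (e.g. low-solubility) noise, inter-lab
bias, and source-specific chemical subspaces — bounds what passing
tests show about real data. Most notably, under zero-bias Gaussian
noise in an iid descriptor space, a noisy source's records are still
informative (noise 0.7 against a target SD of 2.1) and the
reliability-ranked curation already sidelines its values wherever a
better source measured the same compound; excluding such a source
therefore does **not** reliably improve test RMSE here (the package
reports the paired delta honestly, and the corresponding test is
expected to fail under these conditions). The selection benefit
reported for real data rides on exactly the features the minimal noise
model omits. An optional solubility-dependent noise ramp is available
behind a flag, default off, to keep the default model analyzable.

## Numerical choices and degenerate inputs

* Duplicate tolerance is inclusive (≤ 0.01); cluster representative is
  the member mean (unbiased under symmetric noise).
* `dataset_sd()` returns NA (flagged, never 0) when no multi-lab group
  contributes.
* Zero-variance feature columns standardize with scale 1; zero-variance
  targets are an error for training and an empty selection (with a
  warning) for the lasso.
* Training requires n ≥ 20; leave-one-out CV therefore needs n ≥ 21,
  and a blocked LOO (`loo_block`) trades exactness for speed in smoke
  runs, clearly labelled as an approximation.
* Ties in test-set selection and value resolution break
  deterministically (evidence, then lexicographic id), making every
  curation artifact reproducible byte-for-byte.
* t-SNE on degenerate inputs (identical points) converges to
  near-coincident coordinates; the affinity calibration falls back to
  uniform rows when all pairwise distances vanish.

## Problem sizes in the shipped checks

The test-suite and acceptance script run entirely on synthetic data at
desk scale: oracle comparisons at 1000 (tests) / 200 (script)
randomized group sets; SD recovery and selection experiments at 2000
compounds; the observed-performance floor at 10000; cross-validation
bands at 1200; coverage calibration over 20 seeds. These sizes were
chosen so each property's Monte-Carlo error is well below the effect
it checks.

## Limitations

* Per-source SD conflates measurement noise, inter-lab bias and
  misprints into one number; no explicit bias model is fitted.
* The descriptor manifest approximates a published 123-descriptor set
  whose exact composition is not public; swapping the manifest JSON
  re-pins the feature space.
* Consensus uncertainty is a spread across three members, not a
  calibrated predictive interval.
* Full-scale reproduction of published benchmark numbers requires the
  AqSolDB accession and the original (non-public) member
  hyperparameters; the README describes the recipe.
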