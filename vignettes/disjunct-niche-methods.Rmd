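---
title: "Methods: niche differentiation and range dynamics for disjunct populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: niche differentiation and range dynamics for disjunct populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and procedures `disjunctSDM` implements,
the assumptions behind them, the parameters that matter, and the design
choices we made where the methodology left the design open. It states no
empirical result; numbers come from running the package (see the README and
`scripts/acceptance.R`).

## The analysis in one paragraph

A species with two geographically separated population groups — "core"
(the larger) and "disjunct" (the smaller) — is analysed twice over. In
*environmental space*, the two groups' occurrence densities are compared by
Schoener's D and a background-randomization similarity test, answering
whether the groups occupy climates more or less similar than their
surroundings would suggest. In *geographic space*, presence–background
suitability models fitted to the whole species, to each group, and to their
union ("aggregate") are projected onto future climate scenarios and
summarized by a range-change index, answering whether acknowledging the
subdivision changes the projected fate of the species.

## Shared environmental space

All climate stacks — current and every GCM × RCP future — are pooled
(row-stacked cells × layers), standardized, and decomposed by one principal
component analysis (`pooled_pca()`). Every scenario is then projected with
the *same* loadings and the first two axes are retained. Fitting the
reduction once on pooled climates means a future cell's scores are directly
comparable to the training scores; the alternative (one PCA per scenario)
would entangle climate change with rotation of the axes.

Assumption to be aware of: two axes must capture the environmental
directions the species responds to. Real bioclimatic variable sets are
strongly collinear, which is what makes two axes workable in practice. The
synthetic landscapes mirror this: `generate_climate_stack()` accepts a full
inter-layer correlation matrix, and the packaged study uses two
within-block correlations of 0.85 (a temperature-like and a
precipitation-like block) with the virtual niche loading on the block
means. A niche loading on the *idiosyncratic* part of a single variable is
nearly invisible to a two-axis reduction — models then discriminate poorly
and transfer erratically. That is a faithful property of the method, not of
the implementation, and we exploit it in reverse: known-truth recovery
checks use landscapes whose truth is representable (two layers, or niches
on block means).

## Niche densities, Schoener's D, similarity test

Occupancy surfaces follow the kernel-density occurrence framework: on an
R × R grid (default R = 100) spanning the pooled background scores ±5 %,
both the occurrences and the group's available environment (cells within a
buffer of the group's occurrences) are smoothed with a Gaussian product
kernel. Occupancy is occurrence density divided by background density where
the background density exceeds 1e−12 of its maximum, zero outside that
support, then normalized to sum one. The availability correction removes
the imprint of what climates *exist* near each group, which is the entire
point when the two groups sit in different regions; the uncorrected variant
is available (`correct = FALSE`) for sensitivity analysis.

Defaults and why:

* **Bandwidth** `"auto"`: Silverman's rule per axis on the background
  scores — scale-aware and reproducible; the framework's literature does
  not fix one.
* **Buffers** 5, 10, 15 km: running every analysis at three radii shows
  whether conclusions depend on the background choice.
* **Grid bounds from the pooled backgrounds of both groups**: both
  surfaces live on one grid, so D is a cell-by-cell comparison.

Schoener's D = 1 − ½Σ|z₁ − z₂| is computed on these surfaces; it is exactly
symmetric and lies in [0, 1] by construction (a guard clips float
round-off at the boundaries).

The similarity test fixes the focal group's surface and, 100 times,
replaces the other group's occurrences by an equal number of cells drawn
uniformly *without replacement* from the other group's background
(replacement is not specified in the framework; without replacement avoids
degenerate stacked duplicates when backgrounds are small). One-sided
p-values use the (count + 1)/(reps + 1) convention, so p is never exactly
zero and at 19 replicates the smallest attainable p is 0.05. The test runs
in both directions at α = 0.05. Under its own null the p-values are uniform
on the lattice by exchangeability; the acceptance suite verifies the
realized type-I rate and uniformity empirically.

Whether D should be computed on corrected or raw densities is a genuine
open choice; corrected is the default here because the availability
correction is what makes the two groups comparable at all, and the flag
exposes the other reading.

## The suitability model

The presence–background model is a maximum-entropy estimator in penalized
GLM form: logistic regression of presences against pseudo-absences on
linear, quadratic and product features of (PC1, PC2), with an L1 penalty on
the non-intercept coefficients. Six coefficients suffice for a smooth
unimodal niche in two dimensions; hinge/threshold feature sets add nothing
for the smooth virtual truths used in validation and are out of scope.

Numerical choices:

* **Case weights** normalize each class to total weight one. This makes
  the fit invariant to duplicating background points and gives the penalty
  a per-presence interpretation.
* **Penalty default 0.05/√(n presences)** — the maximum-entropy default
  regularization scale for quadratic features. It vanishes with data and
  keeps small-sample fits finite. We originally considered the heavier
  1/√n, but measured that it shrinks the fitted quadratic's vertex (the
  implied niche optimum) toward the background centroid by ~0.2 PC units
  at n = 500, breaking known-truth optimum recovery; the lighter default
  restores recovery to ~0.03–0.05 PC units without affecting
  discrimination.
* **Optimizer**: monotone accelerated proximal gradient (MFISTA) with a
  fixed Lipschitz step (‖X'WX‖/4), objective trace recorded (and asserted
  non-increasing in tests), convergence at subgradient max-norm < 1e−6,
  iteration cap 5000 flagged — never silent — in `training_meta`.
* **Output link**: logistic. All binarization thresholds are rank-based
  functionals of the scores, so any strictly monotone link yields the same
  binary maps; tests assert the rank invariance.
* **Pseudo-absences**: 10 000 cells drawn uniformly from the whole
  modelling extent, for *every* model type. The niche-analysis buffers are
  deliberately not reused here: one background rule for all SDMs keeps the
  species/core/disjunct comparison clean, and the buffers exist to answer
  a different (environmental-space) question.

Cross-validation repeats a random 70/30 presence split 10 times (background
split alongside); each run's AUC is rank-based on the held-out data, and
TSS/sensitivity/specificity are reported at the held-out `MaxSensSpec`
cutoff, i.e. the maximum achievable TSS on evaluation data — the convention
of ensemble SDM platforms. A `n_pa_sets` knob (default 1) repeats the whole
CV for several independent pseudo-absence draws, for designs that read
"runs" as pseudo-absence sets × CV repetitions.

## Thresholds, consensus, aggregate, range change

Three cutoff rules are scanned over every candidate threshold (unique score
values plus ±∞ sentinels): minimize |sens − spec|; maximize sens + spec;
minimize the distance to the ROC corner √((1−sens)² + (1−spec)²). Ties
break toward the lower cutoff (higher sensitivity — missing a presence is
the costlier error in conservation use). A sentinel winner is reported as
its equivalent finite cutoff so map binarization always receives a finite
threshold. Tests compare all three rules against an exhaustive scan oracle,
exactly.

Binary maps feed majority-consensus ensembles (cell suitable if ≥ 50 % of
members agree). Membership is the maximal reading: all CV runs × all
threshold rules, and for a future RCP additionally all its GCMs. Current
maps are consensus maps over runs × rules too — using a single full-data
model instead is possible via the building blocks, but projecting consensus
against consensus compares like with like. The aggregate model is the
cellwise union of the core and disjunct consensus maps, computed per
scenario; its AUC/TSS are the arithmetic means of the component models'
scores (it has no scores of its own), and its sensitivity is evaluated like
any other map, against *all* occurrences.

Range change RC = 100(RG − RL)/CPR is counted on cells valid in both
scenarios; CPR = 0 raises an explicit error rather than returning NaN.
RC ≥ −100 always; RL ≤ CPR always.

## The synthetic-data module

`generate_climate_stack()` builds layers as Gaussian-filtered white noise
(autocorrelation scale in km = kernel sd), mixed by the Cholesky factor of
the requested inter-layer correlation, then scaled per layer. Edge effects
are renormalized so a constant field is preserved. `generate_future_stack()`
applies per-layer affine shifts plus smooth noise emulating inter-GCM
spread. `virtual_truth()` defines suitability as a product of per-layer
Gaussian terms (so 1 at the optimum), splits the grid into a western core
and an eastern disjunct region separated by ≥ 30 km (the lower end of
real disjunctions), and fixes the true range at 50 % of maximum
suitability — arbitrary, but recorded in the object so all oracles are
self-consistent. `sample_occurrences()` draws cells without replacement
with probability proportional to suitability. `shift_for_area_ratio()`
searches the offset (applied to one or several layers coherently) whose
induced true range is a chosen fraction of the current one — this is how
"the future halves the suitable area" scenarios are constructed with known
truth.

What the generator emulates: smooth, collinear climate surfaces; two
unequal, geographically disjoint sample groups; futures that are coherent
shifts plus noise. What it does not emulate: sampling bias along roads and
borders, spatial clustering of records beyond cell duplication, interannual
variability, non-Gaussian niches, dispersal limits, land-use masks. Passing
the known-truth tests therefore demonstrates correctness of the machinery,
not that any real species' projection is right.

## Problem sizes used in validation

Module tests run on 80 × 80 to 120 × 240 cell landscapes with 1 000–5 000
background points and 3–10 CV repetitions; the known-truth range-change
check uses ten replicate 120 × 120 landscapes with two layers (truth fully
representable), 400/80 occurrences, 3 000 pseudo-absences and the full 10
CV repetitions; the packaged end-to-end study in `scripts/acceptance.R`
uses a 150 × 150 landscape, six layers in two blocks, 300/60 occurrences,
10 000 pseudo-absences, 100 similarity randomizations and 2 GCMs × 2 RCPs.
These sizes were chosen so a desk machine reproduces everything quickly
while keeping every statistical component at its standard setting.

## Known limitations

* Planar geometry only: buffers and distances are Euclidean km on a
  regular grid. Real-CRS rasters must be supplied in a projected CRS.
* Two retained PCA axes are a modelling commitment, not a fitted choice;
  niches orthogonal to them are invisible (see above).
* The similarity test randomizes occurrences at cell resolution; extremely
  small backgrounds (< the group's occurrence count) are refused rather
  than approximated.
* The aggregate model is a union of binaries; it has no calibrated
  suitability surface of its own.
* RC assumes unlimited dispersal: a gained cell counts regardless of
  whether the species could reach it.
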