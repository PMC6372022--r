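---
title: "Voxel-scale connectome inference with kernelconn: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-scale connectome inference with kernelconn: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernelconn)
```

## The inference problem

Anterograde viral tracing labels the axonal projections of neurons around
an injection site, so the fluorescence observed across the brain reflects
the *outgoing* connectivity of the injected location. Given a set of $m$
such experiments on a lattice of $n$ cubic voxels (100 µm side length in
the motivating data), each providing an injection-density vector
$X_{:,e}$ and a projection-density vector $Y_{:,e}$, we want a
nonnegative weighted adjacency matrix $W \in \mathbb{R}^{n \times n}_{\ge 0}$
such that $Y \approx W X$: entry $W_{ij}$ is the expected projection
density at target voxel $i$ per unit of virus injected into source voxel
$j$.

Because there are vastly fewer experiments than source voxels, the
problem is only solvable under a structural assumption: **projections
vary smoothly as the source voxel moves within a major brain division**,
while they may change sharply across division boundaries. No smoothness
is assumed in the *target* direction; target-side regularity emerges only
to the extent the data themselves are smooth.

### Data model

Each experiment is reduced to

* the normalized projection density
  $\bar{Y}_{:,e} = (Y_{:,e} + X_{:,e}) / \sum_v X_{ve}$, the per-unit-virus
  projection pattern. The injection pattern is folded back into the
  response, so the injected voxels carry their own unit mass;
* the injection centroid $c_e$, the $X$-weighted center of mass of the
  injected voxels. The estimator treats the whole injection as if it were
  delivered to this single point, which removes the credit-assignment
  problem of distributing projections over the injection site.

The continuous centroid and its nearest lattice voxel (ties to the lowest
index) are both stored: kernel distances use the continuous position,
while in-sample and held-out predictions are read off at the snapped
voxel. Experiments whose injection density touches more than one division
are dropped at construction time (mirroring the curation applied to real
datasets), unless `allow_spanning = TRUE`.

## The kernel estimator

The package uses a Nadaraya–Watson estimator with a Gaussian radial
kernel $K_\sigma(d) = \exp(-d^2 / 2\sigma^2)$, restricted to the major
division $\mathcal{S}_k$ containing the source voxel:

$$W_{ij} \;=\; \sum_{e :\, c_e \in \mathcal{S}_k} \bar{Y}_{ie}\,\alpha_{ej},
\qquad
\alpha_{ej} \;=\;
\frac{K_\sigma(\lVert v_j - c_e \rVert)}
     {\sum_{f :\, c_f \in \mathcal{S}_k} K_\sigma(\lVert v_j - c_f \rVert)}.$$

Every predicted column is therefore a convex combination of the observed
$\bar{Y}$ patterns of its division — the estimate is nonnegative by
construction, needs no fitting beyond the bandwidth, and is stored as the
rank-$m$ factorization $W = \bar{Y} A$ ($\bar{Y}$ is $n \times m$, $A$ is
$m \times n$). The dense $W$ is never formed; `predict_projection()`,
`virtual_injection()` and `regionalize_connectome()` all work through the
factors, and `materialize_submatrix()` extracts dense blocks under an
explicit memory budget.

Numerical details:

* distances are Euclidean in lattice units; $\sigma$ is in the same
  units;
* if every kernel weight at a voxel underflows to zero (a distant voxel
  under a tiny bandwidth), the full weight is assigned to the nearest
  experiment. This preserves the column-sum-one invariant and makes the
  $\sigma \to 0$ limit the nearest-injection predictor rather than 0/0;
* a division containing voxels but no experiments yields all-zero
  coefficient columns and a warning; predictions there raise an error.

## Error metric and cross-validation

Prediction quality is measured by the symmetric bounded relative error

$$\mathrm{MSE}_{\mathrm{rel}} \;=\;
\frac{2\,\lVert Y^{\mathrm{pred}} - Y^{\mathrm{true}} \rVert_F^2}
     {\lVert Y^{\mathrm{pred}} \rVert_F^2 + \lVert Y^{\mathrm{true}} \rVert_F^2},$$

reported in percent. It agrees with the classical ratio
$\lVert\Delta\rVert^2/\lVert Y\rVert^2$ when errors are small relative to
the signal, but is bounded by 200% (attained exactly when one argument is
zero and the other is not), so experiments with weak signal cannot
dominate an aggregate. For example a scalar prediction of 1 against a
truth of 0.25 scores ≈106% where the classical ratio reports 900%.

Because the estimator is a linear smoother, leave-one-out
cross-validation has a closed form. With $A_c$ the $m \times m$
coefficient matrix evaluated at the injection centers, zeroing the
diagonal and renormalizing each column,

$$(A_c^{\mathrm{CV}})_{ij} = \frac{(A_c)_{ij}}{1 - (A_c)_{jj}} \ (i \ne j),
\qquad (A_c^{\mathrm{CV}})_{jj} = 0,$$

makes $\bar{Y} A_c^{\mathrm{CV}}$ the matrix of held-out predictions —
identical to refitting $m$ times, at the cost of one pass. The test suite
verifies the identity against brute-force refits to $10^{-10}$.

`nested_cv()` wraps this in a nested protocol: for each outer held-out
experiment, an inner closed-form LOO over the remaining experiments
selects $\sigma$ from a grid (default: 11 log-spaced values on $[4, 50]$
lattice units), ties broken toward the larger, smoother bandwidth (the
lower-variance choice; the selection rule is otherwise symmetric, so some
tie-break is needed and smoother is the conservative one). Per-division
errors aggregate all held-out columns in a single stacked Frobenius
ratio, weighting experiments by signal size. Training errors use the
in-sample centroid predictions $\bar{Y} A_c$ at the bandwidth selected
most often across the outer folds (again ties to larger) — the nested
protocol produces one bandwidth per fold, and the modal value is the
single representative refit bandwidth recorded in the report.

The **power to predict** (PTP) restricts the same regional error to
held-out experiments whose source region received at least
`min_replicates` injections (default 2, i.e. at least one other). Without
a replicate, the only information about a region comes from smoothness
interpolation, so this subset isolates predictions backed by direct
evidence.

## Regionalization and the homogeneous baseline

The aggregation operator $\Pi$ ($r \times n$; row $i$ indicates region
$i$'s voxels) and its Moore–Penrose pseudoinverse $\Pi^\dagger$
($n \times r$, entries $1/\lvert\mathcal{R}_j\rvert$) convert voxel
objects to regional ones; $\Pi \Pi^\dagger = I_r$. Three regional weight
conventions are provided:

| mode | formula | meaning |
|---|---|---|
| `strength` | $\Pi W \Pi^\top$ | total weight; conserves $\sum_{ij} W_{ij}$ |
| `norm_density` | $\Pi^{\dagger\top} W \Pi^\dagger$ | per source and target voxel |
| `norm_strength` | $\Pi W \Pi^\dagger$ | per source voxel (comparable with the homogeneous model) |

The **homogeneous baseline** assumes all voxels of a region share one
connectivity profile and is fit on regionalized raw data
($X^R = \Pi X$, $Y^R = \Pi Y$) by nonnegative least squares,
$\min_{W' \ge 0} \lVert W' X^R - Y^R \rVert_F^2$, which separates over
target rows into independent Lawson–Hanson NNLS problems. Exact zeros in
the solution are expected and meaningful — NNLS promotes sparsity, and
falsely zeroed strong connections are this model's characteristic
failure.

`compare_models()` evaluates both models on identical leave-one-out
folds: closed form for the voxel model, brute-force refits for NNLS (no
closed form applies). The two models predict deliberately different
objects — the voxel model predicts $\bar{Y}$ from a unit injection at
the centroid and is scored against $\Pi \bar{Y}$, while the homogeneous
model predicts $Y^R$ from the full injection vector and is scored
against $\Pi Y$ — so each is scored against its own fitting target, in
the shared regional space.

## Weight-distribution analyses

`fit_weight_distributions()` fits lognormal, inverse-gamma, exponential
and normal families to positive weights by maximum likelihood and ranks
them by $\mathrm{BIC} = -2\ell + p\ln N$. Zeros are excluded as absent
connections (the extant-weight threshold is the caller's concern). The
BIC-best family is checked by a Kolmogorov–Smirnov test against its
fitted CDF; note the p-value treats the fitted parameters as known, which
makes non-rejection weaker evidence than the nominal level suggests — the
plain test is reported as such rather than replaced by a parametric
bootstrap. A Shapiro–Wilk test is run on $\log_{10}$ weights (thinned to
5000 evenly spaced order statistics above the test's size limit, and
flagged in the report).

`fit_log_weight_gmm()` selects the number of Gaussian components on
$\log_{10}$ weights by the same BIC convention; the EM fits are
initialized by deterministic model-based hierarchical clustering, so
selection is reproducible without seed juggling.

`fit_distance_dependence()` quantifies weight decay with inter-region
distance (Euclidean distance between region voxel centroids — the
standard choice, recorded in the report) three ways: linear least squares
on $\log_{10} w$ vs $\log_{10} d$; a Levenberg–Marquardt power-law fit
$w = a d^\beta$ on the weight scale; and a Levenberg–Marquardt
exponential $w = a e^{-d/\lambda}$. The two nonlinear RMSEs are
comparable with each other; the log-scale RMSE is labelled separately
because a log-scale fit weights small weights very differently from a
linear-scale fit.

## The synthetic-data generator

`make_lattice()`, `make_ground_truth()` and `simulate_experiments()`
produce a complete, seeded emulation of the data the method assumes: a
box lattice cut into contiguous division slabs with nested region bands,
a nonnegative ground-truth connectome whose columns vary smoothly within
divisions (Gaussian-kernel interpolation of random anchor patterns with
disjoint per-division anchor sets, so columns change sharply at
boundaries), and simulated injections with spherical profiles, lognormal
multiplicative noise, and a detection floor.

Default study conditions and their rationale:

* **injection radius 3 voxels** (0.3 mm at 100 µm voxels): the typical
  injection extent in mesoscale tracing;
* **~20 experiments per 30×10×10-voxel division**: a mean
  centroid-to-nearest-injection spacing of ~5 voxels (0.5 mm), the
  sampling density regime the method is designed for;
* **ground-truth smoothness `sigma_true` ≈ 11 voxels**: a mid-grid value
  of the default bandwidth search range;
* **noise_sd 0.3** (lognormal, mean-preserving, per voxel): moderate
  segmentation noise for general-purpose tests;
* **unit self-projection** (`add_identity = TRUE`): the normalized
  projection density folds the injected unit mass back into the
  response, so the generative regime exactly consistent with that
  construction carries an identity component on the diagonal.

One identifiability fact shapes both the generator and the tests: the
segmentation splits signal into injection and projection channels and
discards projection signal *at* the injection site, so a column's
self-entry is not recoverable from data — the normalized-density
convention fixes it at the injected unit mass. End-to-end recovery is
therefore assessed off-site: with point injections, zero noise and a
vanishing bandwidth, the fitted model reproduces ground-truth columns
exactly away from the injected voxel.

### Design of the bandwidth-recovery study

The generating scale `sigma_true` is *not* automatically the bandwidth
that cross-validation should select: with weak noise, the CV-optimal
bandwidth of a kernel smoother tracks the sampling density (nearest
centroid spacing), not the field's smoothness scale, because
interpolation pays no variance penalty. Bandwidth recovery is a
well-posed question only in the regime where averaging at the generating
scale is actually optimal. The recovery study shipped in the tests was
designed accordingly: per-voxel noise was raised (`noise_sd = 0.8`) to
the level at which a brute-force oracle — minimizing true held-out error
against the noiseless field over the default grid — identifies
`sigma_true` as the optimal bandwidth under the default sampling density,
and the anchor density was doubled (16 per division) so the realized
field's roughness concentrates around its ensemble value, making the
selection stable across realizations. Under those conditions `nested_cv`
selects a grid value within one log-step of `sigma_true` in every fold
across the seeds we examined.

### What the generator does not emulate

Real atlas geometry (curved cortical sheets, irregular region shapes),
registration error, within-injection density structure, manually curated
segmentation errors, and the specific layout of any real experiment
collection. Passing tests demonstrate the estimator's internal
correctness and its statistical behavior under the stated assumptions —
not performance on any particular real dataset.

## Problem sizes and runtime

The shipped tests and the acceptance script run on lattices between
$6^3$ and $24 \times 12 \times 12$ voxels with 5–160 experiments; the
full suite completes in well under a minute on one core. All operations
scale as $O(mn)$ memory through the factored representation except the
deliberately budget-guarded dense extraction, so the same code runs at
atlas scale ($n \sim 10^5$) by chunking.

## Known limitations

* The estimator inherits the Nadaraya–Watson boundary bias: predictions
  near division boundaries are pulled toward interior experiments.
* Cross-validation is leave-one-out only; no spatially blocked variant is
  provided, so error estimates are optimistic where centroids cluster.
* The homogeneous model's LOO is brute-force and scales as $m$ NNLS
  refits; acceptable at hundreds of experiments, slow beyond.
* Nearby source columns of the fitted connectome are correlated by
  construction; graph-theoretic statistics computed on it must account
  for that induced spatial correlation.
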