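---
title: "Neighborhood collaborative filtering for drug-response imputation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighborhood collaborative filtering for drug-response imputation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncfger)
```

This vignette is the package's account of its model: what is assumed,
what each parameter does, how the synthetic generator relates to real
panel data, and where genuinely open design choices were settled.

## The model and its assumptions

The predictor treats a cell-line × drug response matrix as a
recommender-system problem and decomposes each response into three
layers:

1. **Additive global effects** — an overall mean, a per-cell-line
   offset (some lines are broadly resistant or sensitive), and a
   per-drug offset (potency differences dominate the raw values).
   These typically absorb most of the variance in log IC50 panels.
2. **A local interaction signal** — whatever structure remains after
   the additive layer, assumed to be shared among similar cell lines
   and similar drugs, and therefore predictable from neighbors.
3. **Noise** — unstructured measurement error.

The method's central assumptions are (i) that neighborhoods are
meaningful on the *residual* scale, which is why effects are removed
before any similarity or weight computation and restored afterwards,
and (ii) that estimates supported by few observations should be pulled
toward a common value rather than trusted — shrinkage appears in all
three stages (effect estimates, similarities, and the normal equations
for interpolation weights), each governed by its own constant.

### Effect estimation

Effects are estimated sequentially, each on the residuals of the
previous step. Per entity, the least-squares estimate is multiplied by
`n/(n + alpha1)`, where `n` counts that entity's observed responses.
`alpha1 = 3` (dimensionless) is the default for both the cell-line and
drug offsets; the overall mean is left unshrunk, since a single scalar
estimated from every observed entry needs no stabilizing. The two
offsets take separate values of `alpha1` if supplied, because nothing
forces the cell-line and drug axes to need equal stabilization. An
entity with no data (or a degenerate explanatory vector) contributes a
zero effect rather than a `NaN`. The chain is configurable; `effects =
"none"` runs the neighborhood stage on raw values, which matters for
the exact-recovery analysis below.

### Similarity

Three variants are available per axis:

* `COEF` — molecular: Pearson correlation of expression profiles for
  cell lines, Jaccard coefficient of fingerprint bits for drugs.
* `RPCC` — empirical: pairwise-complete Pearson correlation of the
  response residuals, computed per pair over the commonly observed
  entries only.
* `MRPCC` — their elementwise product (default).

`RPCC` is computed on residuals after effect removal, and during
cross-validation on the training fold only: neighbor relations are
estimated on the same scale the predictor operates on, and test values
never reach the similarity computation. Correlating raw responses
instead is available (`rpcc_on = "raw"`) but it mostly re-measures the
drug main effects.

Two numerical conventions keep the neighbor ranking total: undefined
correlations (constant profiles, zero-variance overlaps) become 0, and
pairs with response overlap below `min_overlap` (default 3) are zeroed
— a correlation over two points is ±1 regardless of the data, and the
support shrinkage alone cannot suppress it.

Support shrinkage multiplies each off-diagonal similarity by
`|U|/(|U| + alpha2)` with `alpha2 = 1`. It is applied to the *final*
variant used for ranking (i.e. after the `MRPCC` product, and also to
`COEF`, using the response-overlap counts): the purpose of the factor
is to discount rankings that rest on thin shared response data,
whichever formula produced the score. The product formula keeps signs
as stated — a negative×negative pair ranks positive. This presumes the
molecular correlations are positive-dominated, which holds for real
expression data (see the generator section).

### Neighborhood interpolation

For a target entry, the `K = 10` candidates with the largest shrunk
similarity — restricted to entities actually observed at the target's
counterpart index — are ranked descending, ties broken by ascending
index so that predictions are deterministic. The interpolation weights
solve normal equations built from mean co-products of residuals over
each pair's common support, with the target cell line excluded from
every sum (during cross-validation this is what prevents the target
row from leaking into its own weight system). Because supports vary by
orders of magnitude, each entry is shrunk toward `avg`, the mean of the
supported co-product entries: `beta` (default 500) sets how many
supporting observations an entry needs before its own value dominates.
The value 500 follows the convention of the neighborhood-interpolation
recommender literature this formulation descends from; it is a free
parameter of the method — no value for it is fixed by the model — and
at panel sizes much smaller than commercial recommender data a smaller
`beta` may be appropriate. `avg` is scoped to the K × K neighbor-pair
entries (diagonal included) rather than the whole matrix, keeping each
weight system local and cheap; zero-support pairs shrink fully to `avg`
instead of being dropped, so the system stays K × K.

The non-negative solve `min_{w>=0} w'Aw - 2b'w` uses an active-set
iteration of Lawson–Hanson type on the normal-equations form,
terminating at a KKT residual below `1e-8` (relative to the system's
scale). If the active-set submatrix is singular — guaranteed, for
instance, when two neighbors are exact duplicates — a ridge of
`1e-8 × trace/K` is added and a message emitted. Non-negativity is the
model's interpretability constraint: a neighbor either contributes a
scaled copy of its response or is dropped, never subtracted.

The hybrid predictor averages the drug-oriented and cell-line-oriented
predictions. Orientation is named by the entity *supplying neighbors*:
`orientation = "drug"` interpolates over similar drugs within the
target cell line's row, `"cell_line"` is the strict transpose. The
average is taken on the residual scale; since both orientations share
one effects model, averaging after restoration would give the same
number, which the test suite asserts rather than assumes. If one
orientation has no candidates the other is used alone; if neither has
any, the prediction falls back to the global-effects value and is
flagged.

## Cross-validation design

Observed entries (not rows or columns) are partitioned into 10 random
folds of near-equal size; each fold is masked in turn, the entire
pipeline is refit on the remainder, and the masked entries are
predicted. Metrics are pooled across folds within a repetition — each
drug then has one well-supported estimate per repetition — and the four
drug-averaged metrics are reported with two spreads, across drugs and
across repetitions, since either can be meant by a "±" on such a
number. Sensitive/resistant labels are the first and fourth quartiles
of each drug's observed response distribution (linear-interpolation
quantiles, the R default; boundary ties join the extreme groups; drugs
with fewer than four observations, or all-equal values, are excluded
from the S/R metrics). The default of 5 repetitions keeps a full run at
desk scale — about 15 s at 100 × 30 with 30% missing on one core — and
the `repeats` argument scales to the 100 repetitions used for
publication-grade error bars.

One cross-validation run records the hybrid, both single orientations,
and the global-effects-only baseline for every test entry
(`cv_rmse_by_fold()` summarizes them per fold), so predictor
comparisons use paired per-fold differences on identical test sets —
the appropriate uncertainty for "method A vs method B on the same
folds".

## The synthetic generator

`simulate_response_data()` produces the structure the model assumes:
additive effects plus a rank-`rank` interaction `P Q'` (scaled by
`sigma_int/sqrt(rank)` so the per-entry interaction variance does not
grow with rank) plus Gaussian noise, masked missing-at-random, with
molecular features derived from the same latent factors:

* **Expression** is `gene baseline + loadings × P + noise`. The
  per-gene baseline (`sigma_gene = 2`) is essential realism: in real
  data, expression varies far more between genes than between samples,
  so the Pearson correlation between any two cell lines' profiles is
  positive — which is exactly what makes a *product* similarity
  sign-safe. Without the baseline term, profile correlations are
  symmetric around zero and strongly anti-similar pairs would rank as
  top neighbors. The expression noise (`sigma_expr = 5`) is set so
  that expression similarity rank-correlates with the true latent
  cosine similarity at Spearman ≈ 0.7: informative but imperfect, the
  regime in which a similarity-based method is actually interesting.
* **Fingerprints** are Bernoulli bits whose log-odds are linear in the
  drug factors `Q`, so similar drugs share bits above chance.
* **Masking** is i.i.d.; rows or columns left empty are re-masked (and
  the guard logged), since a fully unobserved entity is meaningless to
  every stage.

What the generator does *not* emulate — and what passing tests
therefore cannot show about real data: structured missingness (real
panels miss entries by screening batch, not at random), tissue-type
block structure, heavy-tailed responses, and — most consequentially —
molecular features that are weak or partial surrogates of the
response-determining biology. Here expression and fingerprints measure
the very factors that generate the interaction, so the molecular
similarity `COEF` is itself a near-ideal estimate of the relevant
similarity, and multiplying it by a response correlation estimated from
~15-entry overlaps mostly adds estimation noise: on this generator
`MRPCC` performs on par with or very slightly worse than `COEF`
(while clearly beating response-only `RPCC`). On real panels, where
features miss response-relevant structure (transport, epigenetics,
mutation status), the response-derived factor carries independent
information — that regime is the method's motivation but is not
reproduced by a generator whose features are direct factor
measurements.

## Degenerate inputs and numerical conventions

* 0/0 effect estimates (no data, zero explanatory sum) → 0.
* Undefined correlations → 0; Jaccard of two empty fingerprints → 0.
* Zero-support similarity pairs → 0 after shrinkage regardless of the
  raw value.
* Neighbor ties → ascending-index order; the predictor contains no
  randomness at all, so fixed inputs give bit-identical outputs.
* Weight systems with all-zero support collapse to `avg = 0` and yield
  a zero residual prediction, i.e. the global-effects fallback.
* Fold assignment is the only consumer of the run seed, drawn under a
  saved-and-restored RNG state so library calls do not perturb user
  code.

### Exact recovery as a solver diagnostic

A rank-1 response matrix containing duplicated drug columns is an
analytic fixture for the interpolation stage: with the effect chain
disabled and `beta = 0`, a zero-objective non-negative solution exists
(put weight 1 on the duplicate), every zero-objective solution
reproduces the held-out entry exactly (all columns are proportional),
and convexity guarantees the active-set solver finds one. The effect
chain must be off for this argument: estimated per-drug offsets differ
between a masked column and its unmasked duplicate by O(1/m), which is
far above solver precision. The test suite holds entries out one at a
time so that all pair supports stay equal and the shrunk system is an
exact least-squares problem.

## Problem sizes

The test suite and the acceptance script run at 100 cell lines × 30
drugs (rank 3, noise s.d. 0.3, 30% missing, 10-fold × 5 repeats) for
end-to-end comparisons, 20–60 entities for unit-level properties, and
K = 3 systems for exhaustive solver enumeration; these sizes were
chosen as the smallest at which the compared quantities have stable
sampling error.

## Known limitations

* Cell lines are characterized by expression only and drugs by
  fingerprint bits only; no mutation, copy-number or pathway features.
* The effect chain implements the three named effects; covariate-based
  effects (the "etc." of the recommender literature) are expressible
  through the spec list but none are provided.
* `beta = 500` is a literature convention, not a fitted value; panels
  much smaller than the screens this default comes from may warrant
  tuning it (exposed in the configuration, not learned internally).
* The evaluation reports point metrics per drug; no significance
  testing between methods is built in.
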