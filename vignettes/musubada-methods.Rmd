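---
title: "Barycentric discriminant analysis for multi-subject tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barycentric discriminant analysis for multi-subject tables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musubada)
```

## The problem

Multi-voxel pattern analysis asks whether the category of a stimulus can be
predicted from a brain scan. Standard discriminant analysis does not fit
this data regime: there are usually far more voxels than scans, scans come
in temporally correlated blocks, and — when brains are not warped into a
common template — every participant contributes a *different* set and
number of voxels. `musubada` implements barycentric discriminant analysis
(BADA) and its multi-table extension for exactly this regime: each
participant (or ROI) is a *subtable* of columns, subtables may have any
width, and the participant-level structure is recovered after the fact by
partial projections.

## The model

Let $\mathbf X$ be the $N \times J$ observations-by-variables matrix, with
rows partitioned into $I$ categories and columns into $K$ subtables of
widths $J_k$. Rows carry masses $\mathbf m$ (default $1/N$), columns carry
weights $\mathbf W$ (default $1/J$; any positive-definite metric is
accepted). The analysis is:

1. **Barycenters.** Each category is represented by the mass-weighted mean
   of its (preprocessed) rows,
   $\mathbf R = \mathrm{diag}(\mathbf Y^\top \mathbf M \mathbf 1)^{-1}
   \mathbf Y^\top \mathbf M \mathbf X$,
   where $\mathbf Y$ is the category indicator matrix.
2. **Generalized PCA.** $\mathbf R$ is decomposed under the category-mass
   metric $\mathbf B$ and column-weight metric $\mathbf W$:
   $\mathbf R = \mathbf P \boldsymbol\Delta \mathbf Q^\top$ with
   $\mathbf P^\top \mathbf B \mathbf P = \mathbf Q^\top \mathbf W \mathbf Q
   = \mathbf I$. Category factor scores are
   $\mathbf F = \mathbf P \boldsymbol\Delta = \mathbf R \mathbf W \mathbf Q$,
   variable factor scores $\mathbf G = \mathbf Q \boldsymbol\Delta$, and
   the per-dimension mass-weighted variance of $\mathbf F$ equals the
   eigenvalue $\lambda_\ell = \delta_\ell^2$.
3. **Supplementary projection.** Observations are projected as
   $\mathbf H = \mathbf X \mathbf W \mathbf Q$. These projections are
   *barycentric*: the mass-weighted category means of $\mathbf H$ equal
   $\mathbf F$ exactly. Each observation is assigned to the nearest
   category in factor space (ordinary Euclidean distance on the factor
   scores, which encodes the generalized $\mathbf W$-distance of the
   original space).
4. **Partial projections.** Subtable $k$ sees the configuration through
   its own columns: $\mathbf F_k = K\,\mathbf R_k \mathbf W_k \mathbf Q_k$.
   The average of the $K$ partial projections recovers $\mathbf F$, and the
   weighted squared variable scores of subtable $k$ sum, over subtables, to
   the eigenvalue: $\lambda_\ell = \sum_k \mathcal I_{\ell,k}$. The
   normalized $\mathcal I_{\ell,k}/\lambda_\ell$ are the contributions used
   to find which participant or ROI carries the discrimination.

The choice of masses and weights selects the family member:

| variant | preprocessing of rows | masses $\mathbf b$ | weights $\mathbf w$ |
|---|---|---|---|
| `plain` | user-chosen steps (default centering) | aggregated row masses | table weights |
| `dica` | relative-frequency profiles, centroid removed | row totals / grand total | inverse column frequencies (chi-square metric) |
| `hellinger` | square roots of profiles, centered | uniform | uniform |
| `classical` | user-chosen steps | aggregated row masses | inverse within-category covariance |

With the chi-square choices, the category factor scores of `dica` equal the
row scores of a correspondence analysis of the aggregated
category-by-variable table; the test suite verifies this against an
independently coded CA oracle at machine precision.

Two conventions worth stating. The barycenter-level transforms described
for count data (profiles, square roots of profiles) are applied here to the
*observation rows before aggregation*: this is what makes the barycentric
identity $\bar{\mathbf H}=\mathbf F$ exact for every variant (for `dica`
the two readings coincide because the row masses are proportional to the
row totals; for `hellinger` they differ by a within-category dispersion
term that vanishes as profiles concentrate). Likewise the grand barycenter
used in the inertia decomposition is the *category-mass-weighted* mean of
$\mathbf F$; with an unweighted mean the additive decomposition below would
fail for non-uniform masses.

## Preprocessing and the leakage contract

Every data-dependent transform (`center`, `zscore`, `mfa`, `statis`, the
profile/centroid steps of the count variants) estimates parameters on
training rows and stores them; held-out rows are always transformed with
stored parameters. The z-score uses the population denominator $N$,
consistent with uniform masses $1/N$ in the inertia algebra. The
multi-subject imaging pipeline is `center` (remove the average scan), `mfa`
(divide each subtable by its first singular value, so no participant
dominates through sheer variance), then `row_ss` (unit sum of squares per
scan), in that order. The MFA and STATIS normalizations can be combined
(`c("center", "mfa", "statis")`); the STATIS weights are then recomputed on
the MFA-normalized subtables, which is the reading we adopt of "first MFA,
then STATIS" — recomputation on the raw scale is available by reordering
the step list. STATIS weights are the first eigenvector of the
RV-coefficient matrix between the subtables' row cross-products, rescaled
to sum to one; each subtable is multiplied by the square root of its
weight.

Interacting combinations (e.g. z-scoring then row normalization) are
allowed; the execution order is always the user's list, and the fitted
parameter list records it.

## Inference

**Inertia and $R^2$.** Total inertia of the observation scores about the
grand barycenter decomposes exactly into within-category plus
between-category parts; $R^2 = \mathcal I_{\text{between}} /
\mathcal I_{\text{total}}$ plays the role of the ANOVA variance ratio. With
many more variables than observations the *in-sample* $R^2$ is optimistic
(the axes are chosen to maximize it — on null data with hundreds of columns
it can exceed 0.4), which is why its significance is assessed by
permutation, never by its face value.

**Permutation test.** Category labels are permuted at the exchangeable-unit
level — whole blocks when blocks exist, since consecutive scans are
temporally correlated — and the model is refitted per permutation. The
p-value uses the add-one estimator $(1 + \#\{R^{*2} \ge R^2\})/(1 + n)$,
which cannot report zero. Under block permutation the preprocessing and
weights do not depend on the labels (except for the `classical` variant,
which is fully refitted), so permutation replicates reuse the preprocessed
matrix for speed.

**Cross-validation.** `loo` leaves one scan out, `block` one whole block.
Each fold re-estimates preprocessing and model on the retained rows only.
Leave-one-out *overestimates* accuracy when scans within a block are
correlated, because the held-out scan's blockmates remain in the training
set; the test suite demonstrates the inflation at lag-one correlation 0.9
and its disappearance at 0. Block-out is therefore the default
recommendation for block designs. For prediction displays, held-out scans
are reconstructed from their fold factor scores and re-projected into the
full solution ($\hat{\mathbf h} = \mathbf x \mathbf W_{-} \mathbf Q_{-}
\mathbf Q_{-}^\top \mathbf W \mathbf Q$).

**Bootstrap and ellipses.** Category positions are bootstrapped by
resampling observations with replacement within each category — within
each category-by-block stratum when the block structure is declared fixed —
and projecting the replicate barycenters onto the *original* axes. All
three ellipse kinds share one construction: center at the cloud mean,
shape from the sample covariance, radius at the empirical Mahalanobis
quantile so the stated fraction of points is inside or on the boundary
(100 points at level 0.95 give exactly 95). Tolerance ellipses summarize
training projections, prediction ellipses the held-out clouds (their
center offset from the barycenter is the estimation bias), confidence
ellipses the bootstrapped barycenters. Non-overlap of two confidence
ellipses in *any* dimension pair implies separation in the whole space;
overlap in a given pair is inconclusive for that projection. The overlap
test samples the center segment and each boundary against the other
ellipse — approximate, but ample for a reporting flag. With more than two
categories the per-pair level should be corrected; Bonferroni
($1 - 2\alpha/(I(I-1))$) and Šidák ($(1-\alpha)^{1/m}$ with $m = I(I-1)/2$
pairs) are provided.

### Known finite-sample behavior of the confidence ellipses

The fixed-axes percentile bootstrap undercovers at small samples, for
three quantifiable reasons we measured during development:

1. the empirical-quantile ellipse over $B$ bootstrap points covers an
   independent draw at about 93.3% for $B = 100$ (94.8% at $B = 1000$)
   even in the exact Gaussian case;
2. within-stratum resampling shrinks the variance by $(n_b - 1)/n_b$,
   where $n_b$ is the *block* length — 16-scan blocks give a 6.7% variance
   deficit regardless of how many blocks there are;
3. the discriminant axes absorb part of the barycenter noise, so the true
   projected means scatter slightly more than the bootstrap cloud.

In the regime the method targets — strong discrimination ($R^2 \approx
0.7$), a few hundred scans per category, blocks of a few dozen scans,
$B \ge 500$ — measured coverage of the true projected category means is
within Monte-Carlo error of nominal (0.943 at the acceptance-test
conditions). With short blocks, weak effects, or few scans per category,
expect a few percentage points of undercoverage; the cross-validated
confusion matrix and the permutation test do not share this issue.

## The synthetic-data generator

`sim_spec()`/`simulate_scans()` emulate the data regime: $I$ categories
presented in $n_{\text{blocks}}$ blocks of consecutive scans, $K$
subtables of unequal widths, category mean shifts of norm `effect_size`
confined to chosen carrier subtables, and stationary AR(1) noise within
blocks (lag-one correlation `intra_block_rho`, independent across blocks
and columns). Defaults mirror a seven-category recognition experiment: 7
categories × 8 blocks × 16 scans = 896 rows and 10 subtables of unequal
width; the subtable widths are tens of columns rather than thousands of
voxels, because the statistical structure (unequal widths, block
correlation, carrier confinement) is what needs emulating, not the voxel
count. `intra_block_rho` defaults to 0.5 as a realistic within-block
temporal correlation for consecutive functional scans. AR(1) is the
minimal mechanism that makes leave-one-out and leave-one-block-out
distinguishable; the generator deliberately omits hemodynamic convolution,
spatial smoothness and scanner drift, so passing tests speak to the
statistical machinery, not to those acquisition artifacts.
`simulate_counts()` produces multinomial rows from category-specific
profiles (log-scale perturbations of a common baseline) for the count
variants. Ground truth (true category means or profiles) is returned with
the data so recovery tests never re-derive it.

## Numerical choices

* GSVD route: ordinary SVD of $\mathbf B^{1/2}\mathbf R\mathbf W^{1/2}$
  (symmetric square root for a full $\mathbf W$), back-transformed; no
  cross-product matrices are formed. Rank cut at
  $\max(I,J)\,\varepsilon\,\delta_{\max}$.
* Sign convention: each right singular vector is flipped so its largest
  absolute entry is positive (ties at the lowest index), making output
  reproducible across BLAS implementations.
* Classification ties (distances equal within $10^{-12}$ relative) go to
  the lowest category index and are flagged with a warning.
* All nonzero dimensions are used for distances by default;
  `n_components` truncates.
* The `classical` within-covariance is inverted exactly when well
  conditioned; otherwise a relative ridge ($10^{-8}$ by default, user
  settable) is added and the pseudo-inverse used; the condition number is
  reported on the model.
* Degenerate inputs: a rank-zero fit yields zero-width factor scores,
  $R^2 = 0$ and a permutation p-value of 1; collinear ellipse clouds are
  flagged degenerate with a zero minor axis; zero-mass categories, zero
  rows, zero-variance columns and zero column frequencies are named
  errors.
* One master seed drives every resampling function; identical seeds give
  bit-identical outputs.

## Problem sizes used by the shipped checks

The test-suite simulations run at desk scale, chosen as the smallest sizes
at which the properties under test are expected to hold: calibration of
the permutation test over 200 replicate null studies of 36 scans each
(199 permutations per study); ellipse coverage over 200 replicate studies
of 768 scans in 32-scan blocks with 1000 bootstrap replicates each;
leakage and recovery over 8–20 replicates of 48-scan studies. The
acceptance script reproduces the pipeline at the full row design (896
scans, 10 subtables).

## Limitations

* The confidence-ellipse coverage caveats above.
* `classical` requires (near-)full-rank within-covariance and is not
  meant for the voxels-exceed-scans regime; use the default weights or
  the count metrics there.
* Partial projections with a full (non-diagonal) $\mathbf W$ use the
  corresponding rows of $\mathbf W$, which preserves the averaging
  identity, but the per-subtable inertia contributions are then no longer
  guaranteed nonnegative term by term.
* Subtable weights $\mathbf c$ are stored and exposed but enter no
  equation unless the user folds them into the column weights; the
  partial-projection multiplier is the uniform $K$.
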