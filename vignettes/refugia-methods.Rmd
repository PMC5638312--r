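---
title: "Methods: population genetics and niche-model hindcasting for refugia inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genetics and niche-model hindcasting for refugia inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

Locating Pleistocene refugia of a long-lived tree combines two independent
lines of evidence. First, regions that stayed habitable through glacial cycles
accumulate genetic diversity: more alleles, more private alleles, higher gene
diversity than recently recolonized regions. Second, a niche model fitted to
the species' current occurrences and climate can be projected onto past
climate reconstructions (Last Glacial Maximum, Last Interglacial) to ask where
suitable habitat persisted. `refugia` implements both tracks against diploid
multilocus microsatellite genotypes grouped into geographic regions and
georeferenced occurrences with gridded bioclimatic covariates.

## Genetics track

**Diversity.** Expected heterozygosity uses the plain gene-diversity form
`He = 1 - sum(p^2)`; the small-sample `N/(N-1)` correction is available behind
the `unbiased` flag but off by default, because the fixation-index identity
`F = 1 - Ho/He` printed in the field's summary tables is defined on the plain
form. A monomorphic locus reports `He = 0` and `F = NA`, never `F = 0`. Table
means are unweighted over loci; because published mean fixation indices are
sometimes recomputed from mean heterozygosities instead, `locus_diversity`
returns both conventions (`F` and `F_from_means`).

**Rarefaction.** Allelic richness at `g` gene copies is the exact
hypergeometric expectation `Ar = sum_a [1 - C(N - N_a, g)/C(N, g)]`, computed
with log-gamma binomial coefficients — no resampling, so results are exact and
deterministic. Private allelic richness multiplies the focal group's retention
probability by the probability that every other group's subsample misses the
allele. The default `g` is the smallest gene-copy count over all group × locus
cells (the analogue of "minimum sample size" standardization); both functions
refuse `g < 2` or `g` exceeding any cell, naming the offending cell.

**Nei decomposition.** Group frequencies are averaged with equal weights
(Nei-1973 convention): `H_T` from the mean frequency vector, `H_G` as the mean
within-group diversity, `G_GT = (H_T - H_G)/H_T`. Loci untyped in any group
are dropped with a warning; `H_T = 0` yields a missing `G_GT`.

**AMOVA.** The analysis runs on gene copies, not individuals: each diploid
contributes two allele copies, and the squared distance between two copies is
the number of loci (typed in both carriers) where they differ. Two reasons,
recorded as a deliberate design decision: (i) the degrees of freedom printed
by the standard software for this analysis correspond to `2N` gene-copy units;
(ii) under a Balding–Nichols island model with parameter `F`, the gene-copy
estimator recovers `F` essentially unbiasedly (measured `F_hat ≈ 0.149` for
`F = 0.15`), while an individual-level mismatch-count distance overestimates
by ~40%. `df_among` is reported as `groups - 1`; a well-known printed table
in this literature shows `groups` instead, which the print method flags rather
than imitates. Negative among-group variance estimates are reported as-is with
a warning and `F_ST` left untruncated. Permutations shuffle whole individuals
(keeping the two copies together) and use the add-one rule, so `p` can never
be 0 and the observed configuration counts once in both numerator and
denominator. Pairwise `F_ST` is a two-group AMOVA per pair. Because
cross-group pairs between duplicated groups contain zero-distance twins, a
duplicated group yields a slightly *negative* estimate, not an exact zero —
tests bound it by estimator noise.

**Clustering.** The shared-allele distance counts multiset-intersection sizes
of allele pairs over jointly typed loci; the Nei–Li distance is one minus the
Dice coefficient on the binary presence matrix. Neither is guaranteed a metric
(Dice violates the triangle inequality); violations are logged, not fatal.
Neighbor joining and Newick serialization are delegated to `ape`, which
recovers additive trees exactly. Bootstrap support resamples *loci* (the
exchangeable units for multilocus genotypes) and reports the percentage of
replicate trees containing each reference bipartition; the interior-branch
z-test of some desktop packages is deliberately not reproduced. PCA runs on
the column-mean-imputed dosage matrix, centered and unscaled, so duplicated
accessions coincide exactly and imputed cells sit at the column center.

**Admixture model.** A Gibbs sampler for the admixture model with independent
allele frequencies: cluster-of-origin indicators for each allele copy, a
symmetric Dirichlet(λ = 1) prior on cluster allele frequencies, Dirichlet(α)
on membership vectors, and a single α updated by random-walk Metropolis on
log α (step sd 0.05, uniform prior on (0, 10]). The correlated-frequency
("F-model") prior of the original software is intentionally out of scope; the
validation target is recovery of synthetic structure and the ΔK peak, not
posterior-for-posterior agreement. The reported `lnPD = mean(lnL) -
var(lnL)/2` is the conventional approximation to the marginal likelihood; on
a toy where the marginal is available in closed form it shows a stable offset
of a few log units (its known bias). ΔK is unaffected because a near-constant
offset cancels in the second differences `|L''(K)|/sd(K)`. ΔK is undefined at
the endpoints and wherever replicate scatter is exactly zero.

## Niche-modeling track

**Features and regularization.** Covariates are min–max scaled to [0, 1] on
the training range (occurrences plus background); classes are linear,
quadratic, pairwise products, forward/reverse hinges and step indicators at
`n_knots` evenly spaced knots (default 50). Penalties follow the published
default schedules per class, interpolated in the occurrence count `m`, as
`beta_j = RM * beta_class(m) * s_j / sqrt(m)` with `s_j` the feature sd over
occurrences floored at 0.05 (features live in [0, 1]). The `1/sqrt(m)` factor
is part of the published defaults; a paraphrase that drops it makes default
penalties an order of magnitude too strong at realistic sample sizes.

**Fitting.** The ℓ1-penalized objective is minimized by cyclic coordinate
descent in compiled code: per coordinate a proximal Newton step with
soft-thresholding, step cap, and backtracking on the *exact* objective, so
descent is monotone and runs are bit-reproducible (fixed feature order, no
randomness). Convergence is a full-cycle objective decrease below `tol`
(default 1e-7); every returned fit carries the smooth-part gradient so the
KKT certificate (`|grad_j| <= beta_j` at zeros, `grad_j = -beta_j sign(l_j)`
at active features) can be asserted. Presences join the fitting background by
default (`add_samples = TRUE`, mirroring the reference implementation): if
occurrences are separable from the background in feature space the optimum is
otherwise unbounded and weights diverge. Coefficient-recovery experiments
against a known log-linear truth use `add_samples = FALSE` with the full grid
as background, because the truth is defined against the uniform grid measure.

**Evaluation.** The block partition splits occurrences at their median
latitude, then each half at its median longitude (ties by record index), and
assigns background by the same boundary lines, boundary points to the lower
bin. AUC is the rank (Mann–Whitney) statistic with ties counted ½. Omission
rates use strict-below thresholds (a pixel at the threshold counts suitable):
minimum training presence, and the `ceiling(0.1 n)`-th smallest training
score for the 10% rate. AICc standardizes raw predictions over the *study
grid's* valid cells (not the background sample), counts nonzero weights as
`k`, and is undefined for `n <= k + 1`. The tuning grid (default six
feature-class sets × RM 1–5 by 0.5) reports fold-averaged AUC/omission
metrics from 4-fold block cross-validation and full-data AICc; the selected
model is the `ΔAICc = 0` record with ties broken by smaller `k`, then smaller
RM. Schoener's D normalizes both rasters to unit mass over jointly valid
cells, `D = 1 - 0.5 * sum|p1 - p2|`, symmetric and invariant to positive
rescaling.

**Spatial utilities.** Distances are haversine on a 6371-km sphere. Spatial
rarefying removes exact duplicates, then greedily deletes the record with the
most neighbors inside the radius (ties: lowest record index) until the
retained set is independent; rerunning is a no-op. The sampling-bias grid
sums Gaussian kernels at cell centers and linearly rescales to [1, max_bias]
with the minimum exactly 1 ("1 = no bias"); the default bandwidth is the mean
nearest-neighbor distance of the occurrences (a standard plug-in choice — the
source analyses do not state one) and default `max_bias = 10`. Rasters use
cell-center coordinates, half-open [west, east) × [south, north) cell
assignment, and ESRI ASCII-grid text I/O only: no GeoTIFF reader exists in
the supported dependency set, so that interface was dropped.

## Synthetic data: the stated world

`simulate_genotypes` draws ancestral frequencies from a Dirichlet and group
frequencies from Dirichlet(`p_anc (1-F)/F`) — the Balding–Nichols
parameterization, chosen because its expected Wright F_ST *is* the stated
simulation parameter, giving closed-form recovery targets. Defaults (three groups of 60,
19 loci, 8 alleles, F = 0.15) mirror a microsatellite germplasm panel;
recovery tests use five groups of 100 where the target prescribes it. Missing
calls are masked uniformly; private alleles are injected as novel codes above
the ancestral pool. `simulate_landscape` builds covariates as Gaussian-smoothed
white noise (kernel sd 5 cells, standardized) and the true suitability as the
normalized exponential of a stated coefficient vector (default 1.5, -1, 0.5,
0 — one strong, one negative, one weak, one null effect). Occurrences are
sampled per cell with probability proportional to suitability times an
optional multiplicative bias, then placed uniformly inside the cell.

What the generators do **not** emulate: linkage disequilibrium, null alleles
and genotyping error, isolation-by-distance within groups, admixed
individuals, realistic climate covariance structure or shared physical
geography between "current" and "paleo" stacks (paleo stands are affine
shifts). A green recovery test therefore establishes estimator correctness
under the island-model / log-linear world, not robustness to those realities.

## Numerical choices and degenerate inputs

Half-missing genotype calls are promoted to fully missing. Allele codes are
opaque integers; no fragment-size binning. Constant covariates and constant
raster layers are dropped with warnings (correlation with them is undefined).
The optimizer floors per-coordinate curvature at 1e-9 and caps single steps at
10 to survive near-degenerate features. The greedy layer-pruning tie-break is
largest mean |r|, then earliest position — for exact duplicates either copy
may be the survivor, and tests assert only that one is. Test suites run at
reduced sizes relative to the criteria's nominal scales (smaller grids, 2000
background cells, hundreds of MCMC sweeps instead of 100 000) purely for run
time; thresholds are never scaled.

## Known limitations

The admixture sampler implements the independent-frequency model only, single
α, no linkage or location priors. AMOVA is one-level (no within-individual or
hierarchical components) and offers no stepwise-mutation (R_ST) statistics.
Maxent features exclude categorical covariates; output stays in raw relative
occurrence rate (logistic/cloglog transforms are display-only conveniences
left to the user). The 25-km/10-km thinning counts of any particular study
depend on its heuristic's tie order; this implementation's greedy rule is
deterministic but need not reproduce another tool's exact retained set.
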