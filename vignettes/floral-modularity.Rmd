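---
title: "Floral modularity and shape evolution with floramod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Floral modularity and shape evolution with floramod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floramod)
```

## The scientific problem

Flowers are built from developmental units (organ whorls), but pollinators
select on *functional* units that can cut across them: an attraction module
that draws the animal in, and an efficiency module that mediates the physical
fit of pollen transfer. Given 3D landmark configurations digitized on many
flowers across a clade with repeated pollinator shifts, one can ask: is the
flower modular at all; which partition of landmarks into modules fits best;
does the strength of modularity differ between pollination syndromes; and do
the modules evolve at different rates, toward syndrome-specific optima?

`floramod` implements that full analysis chain for landmark data of the kind
produced by micro-CT studies of flowers: Procrustes alignment, missing-
landmark estimation, covariance-ratio (CR) modularity tests with permutation
nulls and effect sizes, likelihood model selection over modularity
hypotheses, multivariate phylogenetic signal, per-module Brownian rates,
continuous trait-model comparison, regime-shift search, and
rarefaction/down-sampling robustness harnesses. A synthetic-data generator
with known ground truth makes every stage testable.

The landmark container is a long tibble (`specimen_id`, `species_id`,
`group`, `landmark`, `x`, `y`, `z`); a landmark whose three coordinates are
`NA` is missing. The built-in 37-landmark scheme numbers stamen appendage
tips 1-10, appendage bases 11-20, anther pores 21-30, the style base 31, the
stigma 32 and petal tips 33-37, and `merianieae_hypotheses()` returns the
five standard partitions of it: developmental whorls (H1, 4 modules),
attraction/reproduction (H2), two attraction/efficiency variants (H3, H4)
and the three-module corolla/appendage/efficiency partition (H5). Which
stamens belong to which whorl in H1 is morphological information the
landmark scheme cannot encode, so it is an argument (`whorl1`), not a
constant.

## Generalized Procrustes alignment

`gpa()` centers each configuration, scales it to unit centroid size, and
iteratively rotates each onto the running consensus using proper rotations
only (no reflections -- homologous biological configurations must not be
mirrored). Scaling is retained after rotation (partial Procrustes), so
centroid size is the size variable. The iteration stops when the summed
squared change of the consensus drops below `1e-10` (cap: 100 iterations) --
far beyond practical convergence for real data.

After convergence the consensus is rotated onto its principal axes with
deterministic signs, and all aligned specimens with it. This standardizes the
arbitrary global orientation, so rotating every raw specimen by a common
rotation leaves the aligned output bit-for-bit stable (up to roundoff). Note
one numerical consequence: orientation standardization is only stable when
the consensus has well-separated principal moments; a perfectly spherical
configuration has no preferred axes. Real flowers (and the generator's
ellipsoidal archetype) are safely anisotropic.

PCA of shape space (`shape_pca()`) is an eigendecomposition of the covariance
of the flattened aligned coordinates. No tangent-space projection is applied:
at the shape variation scales of within-clade floral data the difference is
negligible, and this keeps scores, loadings and reconstruction exactly
self-consistent (the tests verify reconstruction to 1e-10).

`protest_scores()` implements the Procrustean concordance test used to
compare two ordinations: both score matrices are centered and scaled to unit
total sum of squares, the statistic is `t = sum of singular values` of their
cross-product (equivalently `sqrt(1 - m2)`), reflections are allowed (the
conventional choice for ordination comparison, unlike GPA), and the p-value
comes from row permutations with the observed configuration included.

## Missing landmarks

Damaged specimens (broken petal tips, chewed stamens) are common; most
geometric-morphometric machinery requires complete configurations.
`estimate_missing()` offers three estimators, all anchored on a reference
set of complete specimens (by default the complete conspecifics when at
least two exist, else all complete specimens -- a per-specimen "most similar
subset" can be supplied explicitly):

* **TPS** -- the reference Procrustes mean is similarity-aligned to the
  damaged specimen on the shared landmarks, a 3D thin-plate spline (kernel
  `U(r) = r`, full affine term) is fitted mapping reference shared landmarks
  to the specimen's, and the missing positions are pushed through the warp.
  The interpolant is exact at the anchors.
* **MS** -- mean substitution: the aligned reference mean positions.
* **REG** -- per missing landmark, least-squares regression of its three
  coordinates on the shared-landmark coordinates across reference specimens.
  With fewer reference specimens than 3p predictors plain least squares is
  singular, so predictors are reduced to the first `min(n_ref - 1, 10)`
  principal components.

`validate_estimation()` is the remove-and-re-estimate harness: it removes
1..kmax random landmarks from a random intact specimen, re-estimates,
re-aligns, and compares the first two PC axes of the estimated and intact
datasets with PROTEST; per landmark it accumulates the recovery error
(relative to centroid size) and Welch T / variance F tests comparing aligned
dispersion around the consensus between estimated and intact data. Welch
tests are used throughout because replicate and damaged sets have different
dispersions by construction. `observer_error()` applies the same distance
machinery to replicate landmarkings versus independent specimens; a sound
protocol shows replicate error at least an order of magnitude below
biological variation.

A generator caveat that matters here: the synthetic species means evolve
each coordinate independently, so species differ by spatially *incoherent*
displacement fields, which no smooth warp can predict -- on such data TPS
has no advantage over mean substitution. Real organisms differ by smooth
deformations; the test suite therefore exercises the TPS-beats-MS direction
on affine-warped archetypes, and the exactness guarantees (anchors, noise-
free recovery) on the generator.

## The covariance-ratio modularity test

For modules A and B with covariance blocks of the 3p-dimensional specimen
covariance S,

    CR(A,B) = sqrt( tr(S_AB S_AB') / sqrt( tr(S_AA* S_AA*') tr(S_BB* S_BB*') ) )

where `*` zeroes the matrix diagonal of the within blocks. CR below 1
indicates modularity; for more than two modules the statistic is the mean
over module pairs. Internally everything reduces to the landmark-level
matrix `Tz[k,l]` of squared 3x3 block norms, so a permutation -- reassigning
whole landmarks (each carrying its x,y,z) to modules of the observed sizes --
costs one small matrix product. The observed value counts as one permutation
(`p >= 1/nperm`; at the default `nperm = 1000` the floor is 0.001), ties with
the observed CR are counted as "as extreme" up to a 1e-9 relative tolerance,
and the effect size is `z = (mean(perm) - CR_obs)/sd(perm)`, positive =
more modular.

`phylo_modularity()` substitutes the evolutionary covariance
`S_evol = (Y - 1a)' C^-1 (Y - 1a)/(n-1)` (GLS root `a`, phylogenetic
covariance `C` from the tree, inverted via Cholesky with a `1e-8 *
mean(diag)` jitter-and-warn fallback when the condition number exceeds 1e12)
and applies the same statistic and null. On a star tree it reduces exactly to
the ordinary test on species means.

Two properties discovered by the test suite are worth knowing. First, CR is
*not* invariant to a global rotation of raw coordinates (the diagonal-zeroing
is orientation-dependent); invariance in practice comes from GPA's
orientation standardization, which is why the package standardizes it.
Second, Procrustes superimposition redistributes rigid module-coherent
variation: if within-module correlation is dominated by whole-module
displacement, registration converts part of it into between-module
covariance and attenuates the CR signal. The statistical acceptance
simulations therefore evaluate the test on common-frame deviations, which is
the covariance structure the test is defined on.

### Comparing modularity strength between groups

Group effect sizes are compared with
`z_12 = (z_1 - z_2)/sqrt(se_1^2 + se_2^2)` and a two-tailed normal p-value.
The standard error of a standardized permutation effect size has two parts:
its sampling variance across datasets, which is 1 under exchangeability
(the z is itself a standard deviate), and the Monte-Carlo error of
estimating it from `nperm` permutations, estimated by splitting the
permutation sample into 10 blocks and taking `var(z_blocks)/10`. Hence
`se^2 = 1 + var(z_blocks)/10`. A block estimate alone (of order `0.1` at
`nperm = 1000`) captures only the Monte-Carlo part and would be wildly
anti-conservative. With the combined estimator the comparison is exactly
calibrated for exchangeable covariance structure (verified by simulation in
the acceptance suite) and conservative for strongly modular shared
structure -- it will not manufacture spurious group differences.

## Model selection over modularity hypotheses

`congruence_matrix()` computes the p x p matrix of congruence coefficients:
cosine-type correlations of landmark deviation fields (aligned position
minus consensus) across specimens; the specimen count N travels with the
matrix so the likelihood cannot desynchronize from its sample size.

`build_model_set()` expands each hypothesis by the grammar {within-module
rho: single | per module} x {between-module rho: single | per pair},
deduplicates models that induce the same partition of the p(p-1)/2
upper-triangle cells (for two modules the between variants coincide), and
appends a single-rho null. The five floral hypotheses (4, 2, 2, 2, 3
modules) plus the null give exactly 15 distinct models.

`emmli_fit()` Fisher-transforms each cell (correlations clamped to
`1 - 1e-9` in magnitude so degenerate duplicated landmarks cannot produce
infinities), takes the class mean as each class's MLE, scores cells with a
normal likelihood of fixed variance `1/(N-3)`, and compares models by AICc
with `n_r = p(p-1)/2` observations and `K` = number of correlation classes.
`K` counts only correlation parameters -- the z-variance is fixed, not
estimated -- which is a deliberate, documented deviation risk relative to
implementations that add a variance parameter; it shifts all models' AICc by
a constant and cannot change their ranking here. Negative congruence
coefficients are legitimate and allowed throughout.

## Phylogenetic comparative layer

* **`kmult()`** -- the multivariate extension of Blomberg's K: observed
  versus Brownian-expected dispersion ratio, about 1 under Brownian motion
  (the acceptance suite checks the mean over 200 simulations lands in
  [0.9, 1.1]), invariant to rescaling branch lengths. The permutation null
  shuffles species across tips, observed included. For a single trait it
  reproduces univariate Blomberg's K (cross-checked against an independent
  implementation in the tests).
* **`module_rates()`** -- per-dimension Brownian rates from phylogenetically
  whitened deviations `Z = L^-1 (Y - 1a)`, averaged within modules
  (`sigma2_j = sum Z^2 / n`, the ML convention; the 1/n bias is below the
  5% level the tests allow at n >= 30). The max/min ratio is tested by
  parametric simulation under a common pooled rate, performed directly in
  whitened space (mathematically identical to simulating on the tree and
  whitening, and much cheaper).
* **`asr_discrete()`** -- Mk ancestral states via `ape::ace` (ER or ARD) with
  AIC reported; marginal probabilities per node. The two-tip equal-rates
  likelihood is verified in the tests against the closed form from the
  2-state transition matrix, summing conditional likelihoods over root
  states (the `ace` convention).
* **`fit_trait_models()`** -- BM, Pagel's lambda, OU and early-burst fits to
  a scalar trait (typically a PC score). The rate and root state are
  profiled out by GLS; the remaining parameter is optimized on bounded
  intervals chosen to be numerically safe and biologically inclusive:
  lambda in [0, 1], alpha in [1e-6, 50/T] (phylogenetic half-lives down to
  ~1.4% of tree depth), EB exponent in [-10/T, 0]. OU uses the fixed-root
  Hansen covariance on an ultrametric tree; non-ultrametric input is an
  error rather than a silent stationarity assumption. Fits flagged
  `at_bound` are reported, not discarded. Fitting univariate models to PC
  scores, rather than penalized fits to the full landmark block, is a
  deliberate scope decision: the regime-level questions (which model class,
  where are the shifts) are asked of the dominant shape axes.

### Regime-shift search

`detect_shifts()` fits a multi-optimum OU model with global alpha and rate.
Every branch subtending at least `min_clade` tips is a candidate shift;
shifts are added by greedy forward selection (candidates scanned by GLS at
the current alpha, the winner refitted with alpha re-optimized) and accepted
when they lower the score

    BIC = -2 logL + (2 + #optima) log(n) + 1.75 * #shifts * log(#branches).

The last term charges each shift *location* for the implicit multiple
testing over all candidate branches, in the spirit of modified information
criteria for changepoint selection; with the plain BIC the maximum of ~2n
correlated single-branch improvements exceeds `log n` so often that
Brownian-motion data yield spurious shifts half the time. The penalty
constant and the default `min_clade = 2` (a single-tip "shift" is
indistinguishable from a species outlier) were fixed by simulation to give
at most ~5% spurious-shift datasets under Brownian nulls while retaining
high localization power for shifts of five stationary standard deviations on
mid-sized clades; both operating characteristics are re-verified by the
acceptance suite on every run. After selection, pairs of regime optima are
greedily merged whenever equating them lowers the score; merged regimes
reached by distinct shifts are reported as convergent. Design columns are
norm-standardized before the GLS solve so that small-alpha regimes (whose
columns scale with alpha) are never dropped as rank-deficient.

## The synthetic-data generator

`sim_spec()` defaults describe the study design this package targets: 37
landmarks, 30 species in three phylogenetically clustered groups of 16/8/6,
about 137 specimens with a right-skewed 1-29 specimens per species
(zero-truncated geometric, mean ~4.6), a pure-birth tree rescaled to unit
depth, Brownian species means with per-module rates (default 3e-4 per unit
depth, the magnitude scale of reported floral net rates), specimen deviations
with landmark-block correlation (defaults rho_w = 0.7, rho_b = 0.1, the
canonical strong-modularity setting of the power analyses; within-coordinate
sd 0.02 on a unit-scale archetype), nuisance similarity transforms
(rotation uniform over SO(3), translation in a unit box, scale log-uniform
in [0.5, 2]), and missing landmarks injected into ~47% of specimens (1-10
per damaged specimen). Block correlation is defined on *landmarks* -- a
landmark's three coordinates share its module -- because the landmark is the
permutation unit of the CR test, so ground truth must be landmark-
structured. The archetype configuration is an anisotropic Fibonacci
ellipsoid with small per-module radial offsets: never collinear, stable
principal axes.

What the generator does *not* emulate: spatially smooth deformation
differences between specimens (coordinates evolve independently), biological
within-species covariance magnitudes (the defaults are chosen for test
power; no published estimates exist to match), allometry, semilandmark
sliding, or digitization error structure. Passing tests on this generator
therefore demonstrate the statistical machinery's operating characteristics,
not biological realism of any particular dataset.

Reproducibility is strict: the same `sim_spec` and seed give bitwise
identical outputs; the resampling harnesses draw all replicate subsets
first and then analyse each with a fixed test seed, so identical draws give
identical results (and a dataset that is already one-specimen-per-species
yields literally constant replicates).

## Problem sizes and budgets in the test suite

The statistical checks run at the sizes the questions demand while staying
desk-scale: 500 null datasets for the CR type-I check, 200 for power and for
the effect-size calibration (KS at the 1% level), 100 EMMLi recoveries at
N = 30, 200 Brownian K_mult replicates on 30-tip trees, 100 rate-ratio
recoveries on 100-tip trees, and 100 each of OU-alpha recovery, shift
localization, and Brownian null specificity on a 100-tip tree. The complete
suite runs in a few minutes on one core.

## Known limitations

* The CR test's permutation null assumes landmarks are exchangeable units;
  highly unequal per-landmark variances weaken that null's realism.
* GPA-registered coordinates are not an unbiased image of the generating
  covariance (superimposition redistributes variation); comparisons of CR
  values across differently registered datasets should go through effect
  sizes, which is exactly what `compare_modularity()` provides.
* The shift search shares the usual limits of greedy selection: shifts that
  are individually below the acceptance threshold but jointly strong can be
  missed, and very recent shifts are attenuated by the OU pull toward the
  old optimum.
* `run_pipeline()` is a convenience orchestrator for the common path; bespoke
  analyses should compose the exported functions directly.
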