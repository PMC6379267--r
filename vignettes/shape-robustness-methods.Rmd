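---
title: "Methods: mapping the genetics of shape robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping the genetics of shape robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shaperobust)
```

## The problem

A landmark-based shape has three layers of variation worth separate genetic
dissection: the *mean shape* (where landmarks sit on average), *canalization*
(how tightly individuals cluster around their genotype's mean shape), and
*developmental stability* (how precisely the two body sides repeat the same
developmental program, read out as fluctuating asymmetry, FA). shaperobust
implements the full pipeline for the latter two on 3D configurations with
object symmetry — structures, like a skull, whose left and right halves
belong to a single object — together with the covariance-matrix machinery
(P, G, E, FA estimation and comparison) that asks whether these buffering
processes shape phenotypic variation in similar directions.

## Morphometric model

Each configuration of `P` bilateral landmark pairs and `U` midline landmarks
is superimposed together with its reflected-relabeled copy (generalized
Procrustes: translation removed, unit centroid size, iterated optimal
rotations against a consensus that is re-symmetrised every sweep). The
symmetric component of an individual is the average of its two aligned
copies, the FA component half their difference. Because reflection-relabeling
acts on vectorised configurations as an orthogonal involution, the two
components live in exactly orthogonal subspaces of dimension
`3P + 2U - 4` and `3P + U - 3`; for the classic 17-pair + 10-midline skull
layout that is 67 and 58. A centred PCA removes the superimposition's null
directions; the retained scores carry the complete symmetric variation
(back-projection reproduces the data to numerical precision), so all
downstream model fitting happens in the reduced basis.

Numerical choices: convergence is declared when the root-mean-square
consensus displacement falls below `1e-9` (default cap 100 iterations; the
fit typically converges in 3–5); rotations are solved by SVD with a proper-
rotation sign correction; tangent projection is orthogonal projection at the
consensus (the raw-residual path is exposed via `tangent = "none"`, since
at the small shape variances this machinery targets the two differ only at
second order). The consensus orientation is determined by the data order, so
only rotation-invariant quantities (distances, norms, eigenvalues) are
comparable across runs that permute or re-orient the input.

## Distance statistics

Canalization is quantified per individual as the distance between its
symmetric shape and the mean shape *conditional on its genotype at a focal
marker*: `m_i = mu + a_i alpha` fitted by least squares, then
`d_i = sqrt((y_i - m_i)' D^{-1} (y_i - m_i))`. Conditioning matters: with an
unbalanced marker, the population mean sits closer to the majority
genotype's mean, and unconditioned distances would fake a variance signal.
`D = I` gives Euclidean distances; `D = S` (the residual covariance,
divisor `n - 1`) gives Mahalanobis distances that up-weight deviations along
directions of low population variance. The printed quadratic form is
returned under `squared = TRUE`; the default takes the square root so the
statistic is a metric. When `S` is singular the default inverse is a
PC-truncated pseudo-inverse (components above `1e-8` of the leading
eigenvalue); a ridge inverse is available. FA distances apply the same
machinery to the asymmetric component around the mean (directional)
asymmetry.

## Genome scans

*Additive variance-QTL scan.* Per chromosome, a leave-one-chromosome-out
GRM (`Z Z' / M` over centred, unit-variance dosage columns — the dominant
GWAS convention) feeds a one-component REML fit (`V = sigma_g^2 K +
sigma_e^2 I`, profiled exactly on the GRM eigenbasis after projecting out
the intercept); phenotype and dosages are whitened by `V^{-1/2}` and each
marker is tested by simple regression (two-sided t). Genome-wide thresholds
come from permuting the whitened distances (1000 by default), recording each
permutation's maximum `-log10 p`, and taking interpolation-free empirical
quantiles at the 5% and 10% levels.

*Marginal-epistasis scan.* For canalization the screening phenotype is the
Mahalanobis distance from the overall mean shape (intercept-only model),
since a per-marker conditional model is not available before markers are
chosen. Each marker gets a variance-component score test with kernel
`K_j = (x_j x_j') o K_{-j}` (elementwise product with the GRM of all other
markers, computed by an exact rank-one downdate): with null OLS residuals
`r` and error variance `s2`, `q = r' K_j r / (2 s2^2)`, and the null is the
weighted sum of chi-square(1) variables with weights
`eig(P0 K_j P0) / (2 s2)`. No population-structure correction is applied at
this stage. Tail probabilities: a Ruben series (mixture of central
chi-squares; exact to `1e-10` and used whenever all weights are positive
with spread below 1e3) with Imhof characteristic-function inversion as the
general path and a Kuonen saddlepoint for deep tails, so p-values never
collapse to zero. Markers below `1e-6` proceed to the pairwise stage: for
each candidate pair the multivariate mean model with `a_j + a_k + a_j a_k`
is fitted to the scores, residuals are internally studentized (dividing by
`sqrt(1 - h_ii)`; without this, high-leverage genotype combinations get
systematically shrunken distances and the interaction test over-flags —
measurably so at 67 shape dimensions), pair-specific Mahalanobis distances
are formed, and the interaction term of `d ~ a_j + a_k + a_j:a_k` is tested
at `alpha = 0.001`. Near-collinear pairs (`r^2 > 0.99`) are skipped and
flagged. Only first-order interactions are considered: higher orders explode
combinatorially and leave too few individuals per genotype combination.

## Covariance estimation and comparison

P and FA are sample covariances of the symmetric and asymmetric components.
G and E come from a block REML of the PC scores on the GRM: the leading
block (default 10 PCs) is fitted with unstructured genetic and residual
covariance by an EM algorithm on the exact restricted likelihood (data
projected on intercept-orthogonal contrasts, rotated to the GRM eigenbasis;
the E-step is grouped by distinct eigenvalues, so structured relatedness is
cheap); remaining PCs are independent univariate REML fits with genetic
covariances fixed at zero. EM convergence is a relative parameter change
below `1e-5` (cap 5000 sweeps); negative-definite parts of the assembled
matrices are clamped at zero with a warning. The multivariate heritability
spectrum `h^2 = G P^{-1}` is computed through the symmetric generalized
eigenproblem `G v = h P v`, which guarantees real eigenvalues; a
pseudo-inverse drops null phenotypic directions.

The comparison suite: Krzanowski common subspace `H = sum A_i A_i'` with the
constraint `k <= q/2` (beyond half the space, sharing is forced) and the
angle `delta_i = acos(sqrt(b' A_i A_i' b))`; because no single `k` is
privileged, `krzanowski_profile()` sweeps `k = 1..q/2`. Euclidean distance
uses the square root of the upper-triangle sum of squares (the quadratic
form itself is exposed by squaring; a distance should be a metric);
element-wise correlations are tested by permuting whole landmarks (xyz
triplets move together) with the add-one convention; eccentricity is
`lambda_1 / lambda_2`; first-eigenvector angles are folded into [0, 90] and
referred to Gaussian-normalized (uniform-on-sphere) random vector pairs.
Comparisons run on half configurations: one body side's paired landmarks,
plus the midline except when FA is involved (FA variation there is confined
to out-of-plane movement, orthogonal to the symmetric space).

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code that defines the study
conditions for every power and calibration experiment. A seeded template
shape (exactly symmetric; pairs mirrored, midline in-plane) receives, per
individual: additive QTL displacements `a_i alpha` in the free symmetric
coordinates; symmetric Gaussian noise with standard deviation
`0.02 sqrt(v_i)` (coordinate units, template span ~2 — about 1% of size,
typical of landmarking studies); and a purely antisymmetric perturbation
with standard deviation `0.01 sqrt(w_i)` generating FA. The multipliers are
`v_i = exp(sum lambda_jk I_jk)` over the configured epistatic pairs.
Genotypes are binomial(2, p) dosages with p uniform on [0.02, 0.5] (the
customary 2% MAF filter), markers round-robin over chromosomes at 250 kb
spacing, no linkage disequilibrium or family structure (the target
population is outbred with negligible structure); the analysis side
nevertheless accepts continuous dosages in [0, 2]. Each configuration is
optionally pushed through a random similarity transform to emulate
arbitrary digitizer coordinates. Full ground truth (template, effects,
multipliers) is recorded for recovery tests.

Two interaction codings are provided. `"and"` (default) fires when both
markers carry dosage >= 1 — the simplest pattern, but it has a marginal
component: carriers of one interacting marker have elevated average
distance, which an additive scan legitimately detects. `"balanced"` uses
the +/-1 product of carrier indicators (an XOR pattern) and has no marginal
mean or variance effect when the carrier frequency is 1/2; it is the right
generator for the headline architectural contrast — an epistatic variance
signal that the additive scan cannot see but the marginal-epistasis test
finds. Power benchmarks plant causal pairs at allele frequency 0.2–0.3
(carrier fraction near 1/2): the threshold coding is uninformative at
frequency extremes, where no method could detect the pair, so a power
statement there would measure the generator, not the test.

What the generator does not emulate — and hence what passing tests do not
establish about real data: linkage disequilibrium (marker merging into
regions is exercised only via shared annotation), relatedness structure
beyond what the user injects through K, measurement error with landmark-
specific covariance, allometry, and mean–variance coupling other than
through the modeled QTL.

## Problem sizes and test design

Simulation-based checks run at desk scale, chosen so the full suite
completes in minutes while each check retains its resolving power:
calibration pools 500 score tests across five independent cohorts of
n = 600 with 100 markers each (pooling matters: p-values within one cohort
share its phenotype and are not exchangeable for a KS test); the additive
scan's null calibration uses two cohorts of 250 markers; pairwise null
rates pool ~5400 pairs over nine cohorts; the planted-pair power check uses
20 cohorts at the stated lambda = 1.5, n = 600; G-matrix recovery uses 20
replicates of a 3-PC, n = 400 sibship design; permutation thresholds in the
negative control use 200 permutations. The 67-dimension layout is used
wherever the distance's distributional shape matters, because the distance
over few dimensions is markedly non-Gaussian and mildly conservative in the
score test.

## Known limitations

The score test treats the distance as an ordinary phenotype; residual
non-normality leaves it slightly conservative in small shape spaces. The EM
REML estimates block-1 covariances jointly but assumes PC-block
independence across the boundary, like any blocked fit. The Krzanowski
statistics compare estimated eigenvector sets and inherit their sampling
noise; with near-isotropic matrices the retained subspace is ill-defined
and the angles are uninformative. Permutation thresholds assume
exchangeability of whitened distances, which holds only as well as the
fitted V. The generator's codings are two idealized epistatic patterns;
real interaction architectures will sit between them.
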