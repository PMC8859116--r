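---
title: "Genomic prediction in polysomic tetraploids: codings, kernels and G x E models"
author: "tetraGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction in polysomic tetraploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetraGP)
```

## The problem

Cultivated potato is a polysomic tetraploid: each biallelic SNP locus has
five genotype classes, AAAA, AAAB, AABB, ABBB and BBBB, i.e. allele
dosages 0-4. Genomic selection in such a crop has to decide how dosage
enters the model. tetraGP implements the three standard choices and the
Bayesian kernel regression machinery around them, so a breeder can rank
selection candidates by genomic-estimated breeding value (GEBV) from
multi-site trial data.

## Marker codings

Three codings of the dosage matrix `X` (N genotypes x M markers):

* **A, pseudo-diploid** - 0 for AAAA, 2 for BBBB, 1 for any heterozygote.
  All heterozygotes are assumed equal, at the midpoint of the
  homozygotes.
* **B, additive tetrasomic** - the dosage itself, 0..4; columns are
  standardized to mean 0 and unit *population* variance (divide by N).
  That convention makes the cross-product matrix `XX'/M` have average
  diagonal exactly 1, the usual GBLUP scaling.
* **C, full tetraploid** - five indicator columns per marker, one per
  genotype class, in the fixed order AAAA..BBBB, so every class can carry
  its own (non-additive) effect.

```{r coding}
fx <- workedFixture()   # the five classes at one marker
cbind(A = codedValues(codePseudoDiploid(fx$dosage))[, 1],
      B = codedValues(codeAdditiveTetrasomic(fx$dosage, FALSE))[, 1])
```

The tetraploid allele frequency per marker is
`p = (4 n_bbbb + 3 n_abbb + 2 n_aabb + n_aaab) / 4N`, identical to the
mean dosage divided by 4. Markers with minor-allele frequency below
`minMAF` (default 0.01) must be filtered before kernel construction
because every relationship formula divides by `p(1 - p)`; for coding C
the genotype-class columns with observed frequency 0 or 1 are dropped and
the effective column count adjusted. Missing dosage calls are imputed
with the rounded expected dosage `round(4p)`; genotypes missing more than
10% of calls are dropped. The imputation rule is this package's own
choice - dosage data sets typically carry a fraction of a percent of
missing calls, for which any reasonable rule is equivalent.

## Kernels

For each coding, two N x N similarity matrices:

* **GB (GBLUP)** - for coding B simply `XX'/M` on the standardized
  matrix. For codings A and C the frequency-weighted forms with
  off-diagonals `(x_j - cp)(x_k - cp) / (c' p(1-p))` and a separate
  *expected-value* diagonal (`1 + ...`), averaged over columns.
* **GK (Gaussian)** - `exp(-h d^2 / q)` with `d^2` the squared Euclidean
  distance between coded rows and `q` the median of the off-diagonal
  squared distances. `q` is computed over off-diagonal entries only;
  including the zero diagonal would bias the median downward. Distances
  use the coded matrices as coded (standardized for B, raw for A/C);
  `makeKernel(..., standardizeGK = )` exposes the switch.

The bandwidth `h` is scale-free thanks to the `q` normalization. When a
phenotype is available, `estimateBandwidth()` picks `h` from a log-spaced
grid (default 13 points on [0.01, 10]) by maximizing the marginal
likelihood of the single-kernel Gaussian-process model with the intercept
and variance ratio profiled out; ties go to the smaller `h`, and `h = 1`
is the no-phenotype default.

A numerical caveat worth stating: the pseudo-diploid GB with the
expected-value diagonal is *not* guaranteed positive semi-definite on
heterozygote-rich tetraploid data (a heterozygote at `p = 0.25` gets
diagonal 0 while its cross-products with other lines need not vanish).
This is a property of the formulas, not a bug. Kernels therefore only
assert symmetry at construction; positive semi-definiteness is imposed
where it matters, at model assembly, by eigendecomposing each covariance
component and dropping eigenvalues below `1e-8` of the largest
(including any negative ones). For GB on codings B/C and for GK the
clipped part is numerically zero.

## The four Bayesian models

With `Z1`, `Z2` the incidence matrices of environments and genotypes:

1. `y = mu 1 + Z2 g + e` - single environment, one kernel,
   `g ~ N(0, s2_g K)`.
2. `y = mu 1 + Z2 g1 + Z2 g2 + e` - single environment, two kernels
   (additive B + non-additive C).
3. `y = mu 1 + Z1 env + Z2 g + ge + e` - multi-environment; environments
   are random with covariance `E` (identity by default), and the G x E
   term has covariance `s2_ge (Z1 E Z1') * (Z2 K Z2')` - the Hadamard
   product. With `E = I` and balanced data this equals the Kronecker
   form `K (x) I` after row ordering (a unit test checks exactly this).
4. Model 3 with two kernels, each with its own interaction term - five
   random components plus the residual.

Environmental-covariable `E` matrices are accepted but not constructed;
reaction-norm covariates are out of scope.

### Gibbs sampler

Each component covariance (over all cells of the trait, observed and
to-predict) is restricted to the observed cells and eigendecomposed
once. Effects are sampled in the eigenbasis, where every full
conditional is diagonal; this is the standard efficiency device of
kernel-regression MCMC software and what makes 30,000-iteration chains
run in seconds at hundreds of observations. The inner loop is compiled
(RcppArmadillo) and draws from R's RNG, so `set.seed()` pins every
posterior summary bit-for-bit.

Priors: flat on the intercept; scaled-inverse-chi-square with
`priorDf = 5` on every variance. The prior modes split `priorR2 = 0.5`
of `var(y)` equally among the random components (each divided by its
mean covariance diagonal, so differently scaled kernels get comparable
shrinkage), with the remainder on the residual. These are weakly
informative defaults in the tradition of Bayesian genomic-regression
software; both knobs are arguments of `fitGibbs()`. Defaults for chain
length follow the standard protocol: 30,000 iterations, 5,000 burn-in,
thinning 2.

Missing phenotype cells - including cross-validation-masked ones - are
excluded from the likelihood rather than data-augmented. Their
predictions are the conditional mean of each random effect given the
sampled training-cell effects, `Sigma[test,obs] pinv(Sigma[obs,obs])
u_obs`, computed through the stored eigenbasis and averaged over retained
samples. The posterior predictive *mean* is identical to what
data augmentation would give, with a simpler sampler.

`mcmcDiagnostics()` reports effective sample sizes (initial positive
sequence estimator) and Geweke-style z-scores, flagging `ESS < 100` or
`|z| > 2`; constant traces are flagged as degenerate rather than raising.

## Cross-validation and selection

* `singleEnvPartitions()` - repeated random splits within one
  environment; defaults 30 replicates of 70% training / 30% testing.
* `cv2Folds()` - the multi-environment CV2 scheme: a line is predicted
  at one site while its records at other sites stay in training.
  Defaults: 10 replicates of a random 4-fold partition. The underlying
  protocol phrase ("four random folds, ten samples") is ambiguous between
  that reading and four folds of ten cells; we adopt the former because
  it yields the replicate-level mean +/- SD that accuracy tables report,
  and both counts are arguments. Masks are constrained so a fold never
  removes all environments of a line; single-environment lines are never
  masked.
* `accuracy()` - Pearson correlation of predicted vs observed test
  values, within environment for multi-environment fits (per-site
  accuracies from the joint fit). Groups with fewer than 3 points or
  zero variance yield `NA` with a warning instead of aborting a
  replicate.
* `selectionIntensity()` / `selectTop()` - truncation-selection
  utilities: `i = dnorm(qnorm(1 - a)) / a` (2.268 at a 3% threshold) and
  the top `ceiling(a N)` genotypes by GEBV, ties broken by id.

Predictive correlations are computed on the phenotype values as
provided; no spatial or design adjustment happens here.

## The synthetic generator

`simulateDosages()` draws per-marker allele frequencies uniformly from a
range (default [0.05, 0.95]) and dosages as Binomial(4, p) - tetrasomic
Hardy-Weinberg sampling. Double reduction, linkage, genotyping error and
pedigree structure are deliberately not modeled; the generator's job is
to produce data with exactly the covariance structure the models assume,
so that parameter recovery and model-ordering checks are interpretable.
Passing tests on this generator therefore demonstrates correctness of
the machinery, not performance on real potato data, where those ignored
features (and non-Gaussian trait distributions) matter.

`simulatePhenotypes()` composes a unit-variance trait from additive
values (standardized B coding x iid marker effects), non-additive values
(one-hot C coding x iid class effects), random site main effects, G x E
deviations with genetic covariance proportional to the additive kernel
and a compound-symmetry correlation across sites, and iid residuals.
Each component is rescaled to its exact target fraction. Defaults
emulate the motivating study's scale: 250 genotypes x 2,000 SNPs x 3
sites, with one site holding ~169/256 of the lines; variance fractions
default to 0.3/0.1/0.1/0.2/0.3 (additive/non-additive/site/G x E/
residual), a mid-heritability tuber trait - real heritabilities were not
published numerically, so these are free parameters chosen once.

## Problem sizes used in the checks

The test suite runs everything at desk scale, chosen so the whole suite
stays in the low minutes: kernel oracles on 6 x 20 toys against
brute-force double loops (agreement to 1e-12); BLUP equivalence on 20
genotypes with 2,000 retained samples; variance-component recovery at
N = 300, M = 1,000, 3 sites with 6,000-iteration chains over 10 seeds;
model-ordering comparisons at N = 120, M = 300 with 1,500-iteration
chains over 10 replicates. Chain lengths for the comparative runs are
shorter than the 30,000-iteration default because the compared fits share
seeds and the orderings of interest are stable well before full
convergence of the variance components.

## Known limitations

* The pseudo-diploid GB indefiniteness described above means model fits
  under coding A operate on the clipped PSD part of that kernel.
* The bandwidth selector implements a marginal-likelihood grid search;
  the original empirical-Bayes procedure it stands in for was specified
  only by citation, so agreement is methodological, not numerical.
* Environments are exchangeable random effects (`E = I`); with 3 sites
  the environment variance is weakly identified and mostly absorbed by
  the prior.
* The Kronecker-product G x E variant is not implemented; for balanced
  data it coincides with the Hadamard form used here.
* CV1 (predicting lines never seen in any environment) is not a
  first-class scheme; compose `singleEnvPartitions()` at the line level
  over all cells of a line to obtain it.
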