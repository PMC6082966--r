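---
title: "Principal-component genomic prediction: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Principal-component genomic prediction: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Genomic prediction regresses phenotypes of a reference population on
thousands of SNP genotypes and uses the estimated marker effects to predict
the genetic merit (GEBV) of selection candidates. Two statistical problems
dominate: far more markers than records, and strong multicollinearity
because linkage disequilibrium (LD) correlates nearby markers. Principal
component analysis addresses both at once — the marker correlation matrix is
rotated into orthogonal components and only the leading ones are kept — but
the standard PC regressions treat the per-component variances as *fixed*
(either all equal, or proportional to the eigenvalues). This package
implements the alternative evaluated here: treat PC-effect variances as
*unknowns* with shrinkage priors (normal, scaled-t, double exponential) and
learn them by Gibbs sampling, alongside the routine SNP-based genomic
prediction models, inside one simulation experiment that measures
cross-validated accuracy, prediction bias, and the persistency of accuracy
across generations.

# Models

All models share the linear mixed model

    y = X s + Z b + e

where `y` are phenotypes, `X` carries the fixed effects (overall mean and
sex), `Z` is the predictor design and `e ~ N(0, I sigma2_e)`. For SNP-based
models `Z` holds genotypes coded −1/0/1; for PC-based models `Z` holds the
scores of the retained principal components. The eight estimators differ
only in the prior on `b`:

| model | design | prior on effects |
|---|---|---|
| `ridge` (Ridge-R) | SNPs | fixed common variance `sigma2_a / m`, solved deterministically |
| `brr` (Bayes-Ridge) | SNPs | normal, common variance with scaled-inv-chi-square prior |
| `bayesa` | SNPs | normal with locus-specific variances (scaled-t marginal) |
| `bayesb` | SNPs | point mass at zero + scaled-t slab, zero-proportion `pi` learned |
| `pcr-eigen` | PC scores | fixed variances proportional to eigenvalues, deterministic |
| `pcr-normal` | PC scores | as `brr`, on scores |
| `pcr-t` | PC scores | as `bayesa`, on scores |
| `pcr-lasso` | PC scores | double exponential (normal scale mixture, Bayesian Lasso) |

Both deterministic models solve the mixed-model equations by Cholesky
factorisation with the simulation-true variances plugged in
(`sigma2_a = 0.25`, `sigma2_e = 0.75`); no REML step is involved. The six
Bayesian models run through one design-matrix-agnostic single-site Gibbs
sampler (C++): fixed effects under a flat prior, each predictor updated
against the current residual, then the variance layer for the chosen prior,
then the residual variance.

## Hyperparameters

Scales follow a weakly informative rule: with a prior "predictor share"
`R2 = 0.5`, the prior *mode* of the total effect variance is
`R2 * var(y) / sum_j var(z_j)` and the prior mode of the residual variance
is `(1 - R2) * var(y)`, each with 5 degrees of freedom. The BayesB zero
proportion gets a Beta(5, 5) prior (mean 0.5, effective weight 10); the
Lasso global rate `gamma^2` gets Gamma(shape 1, rate 1e-4). All of these
are arguments of `fit_bayes()`; the defaults are a declared policy, not a
fitted quantity. MCMC defaults are 12,000 iterations, 2,000 burn-in,
thinning 5; `sigma2_e_chain` is stored so convergence can be checked by
split-chain comparison. Chains are fully reproducible from `set.seed()` /
the `seed` argument.

## PCR-Eigen eigenvalue scaling

When only `k < m` components are retained their eigenvalues no longer sum
to the full trace, so assigning `sigma2_a * lambda_j` directly changes the
implied total genetic variance. By default the retained eigenvalues are
renormalised to sum to one before scaling (`normalize = TRUE` in
`fit_pcr_eigen()`); `normalize = FALSE` keeps the raw eigenvalues for
comparison. Which convention the original analysis used is not stated in
its description; normalisation is the default here because it preserves
`sigma2_a` as the total prior genetic variance.

# PCA

`fit_pca()` computes the Pearson correlation matrix of the training
genotypes and its symmetric eigendecomposition. Numerical choices:

* eigenvalues are clipped at zero (tiny negatives are round-off);
* eigenvector signs are fixed by making the largest-magnitude element of
  each column positive, so runs are byte-reproducible;
* eigenvalue ties keep their original (stable) order;
* retention keeps the smallest `k` whose cumulative eigenvalue fraction
  reaches the threshold (default 0.999).

Projection standardises new genotypes with the *training* means and
standard deviations before multiplying by the eigenvectors, which is the
projection consistent with a correlation-matrix eigensystem. Because the
literal score definition in the source material multiplies the raw
genotype matrix by the eigenvectors, `project(..., scores = "raw")`
reproduces that behaviour; both are provided because the description is
ambiguous on this point.

# The simulator

The generator emulates a QMSim-style two-phase design. Its defaults *are*
the study conditions and are not tuning knobs.

**Genome.** 3 chromosomes of 1 Morgan; 3,000 biallelic SNPs and 15, 60 or
105 multi-allelic QTL (4 alleles at initialisation, configurable) at
uniform random, mutually disjoint positions. Recombination follows the
Haldane map (Poisson crossovers, mean = map length, no interference).
Mutation is recurrent at 1e-3 per marker and 1e-5 per QTL per meiosis; a
marker mutation flips the allele, a QTL mutation creates a new allele.

**Historical phase.** 400 female and 20 male founders; random mating with
linear growth to 1,000 animals over 100 generations, then 400 generations
at constant size, ending with 70 males. Male counts are interpolated
linearly from 20 to 70 across the 500 generations, mirroring how QMSim
interpolates parameters specified at the first and last historical
generations; the alternative reading (20 males throughout, 70 only at the
end) halves the effective population size and pushes far more SNPs below
the MAF threshold than the published counts for this design allow.

**Recent phase.** Generation 0 samples 35 males and 455 females from the
final historical generation. Each later generation selects the top 35
males and top 455 females of the previous generation, pairs each dam with
a random selected sire, and produces 2 offspring per dam (910 per
generation). Generations 8–9 (n = 1,820) form the reference population,
generations 10–15 the candidate sets.

Two design points deserve justification:

* *Selection criterion.* Parents are ranked by **own phenotype** — the
  estimated breeding value available without a pedigree BLUP, with
  selection accuracy `h = 0.5`. Ranking directly on the true breeding value
  (also available, `criterion = "tbv"`) selects with accuracy 1 and, in
  this design, collapses the additive variance to roughly a third of its
  nominal value by generation 8 through the Bulmer effect and rapid
  fixation of large QTL, so the reference population no longer has the
  intended heritability of 0.25. Phenotype ranking keeps the realized
  heritability near the design value (roughly 0.1–0.3 across replicates)
  while still producing a strong genetic trend.
* *Sex assignment.* Offspring sexes are an exact random half split rather
  than independent Bernoulli(0.5) draws: each generation needs exactly 455
  dams out of 910 offspring, and independent draws would leave fewer than
  455 females in about half of all runs.

**Trait.** Each QTL allele gets an additive effect drawn from
gamma(shape 0.4) with a random sign, centred within locus; all effects are
then rescaled by one common factor so that var(TBV) in the final
historical generation equals `sigma2_a = 0.25` exactly. The calibration is
one-time: alleles created later by mutation reuse the stored scale factor.
Phenotype = TBV + N(0, 0.75); no sex effect is simulated.

## What the generator does and does not emulate

It reproduces drift, recurrent mutation, recombination-driven LD decay,
family structure under truncation selection, and a trait with known TBVs.
It does **not** emulate genotyping errors or missing calls, dominance or
epistasis, overlapping generations, designed matings, crossover
interference, or ascertainment bias in SNP discovery. Passing tests
therefore demonstrate internal consistency of the methods under an
idealised additive architecture, not performance on real livestock data.

# Evaluation

*Accuracy* is the Pearson correlation between GEBV and TBV (TBV is known in
simulation). *Bias* is the OLS regression of TBV on GEBV; slope near 1
means neither inflated nor deflated predictions; the reported R² is the
squared correlation. `five_fold_cv()` partitions the reference animals
uniformly at random (no stratification; seed recorded), fits on 4/5 and
evaluates on the held-out fifth; summaries are fold-weighted means with
SE = sd/sqrt(folds). `persistency()` applies one fit, trained on the full
reference population, to each candidate generation in turn; accuracy is
expected to decline with generation as recombination erodes the
marker–QTL LD the fit exploits.

# Numerical details

* Variances and `|b_j|` in the inverse-Gaussian update are floored at
  1e-10; a non-finite draw aborts with the iteration index.
* Update order is fixed (fixed effects, predictors in index order,
  variance layer, residual variance) for reproducibility.
* The mixed-model equations are solved by one Cholesky factorisation; a
  singular fixed-effect block (confounded mean/sex) is reduced to an
  estimable subset with a warning.
* A fold whose held-out TBVs have zero variance yields `NA` accuracy and is
  excluded from fold means with a warning.

# Problem sizes used by the test suite

The shipped tests keep the default run short by scaling the study down:
most unit tests use a 2-chromosome genome with 120 SNPs and a population of
about 80; the method-ordering comparison uses 800 SNPs, 15 QTL, 400
animals per generation and 3,000-iteration chains; one full-scale 105-QTL
replicate (3,000 SNPs, 500 + 15 generations, n = 1,820 training animals)
is built once and shared by the calibration and table checks. The full
3-scenario × 8-model × 10-replicate grid is run with
`run_scenario(scenario_config())` and takes on the order of hours on one
CPU; it is resumable per replicate.

# Known limitations

* Under this neutral mutation–drift emulation the eigen-spectrum of the
  marker correlation matrix is markedly less concentrated than published
  descriptions of comparable data report (first 100 PCs carry ~60–65% of
  the variance here). The SNP retention rate after MAF filtering pins the
  historical effective population size near 150–250, while a spectrum with
  90% of the variance in 100 components would require a much smaller
  effective size; both cannot hold at once in this model class, so the two
  spectrum-concentration checks fail honestly. An uncentred (cosine)
  genotype inner-product matrix concentrates far more strongly, but the
  Pearson correlation matrix is the documented contract and is what
  `fit_pca()` computes.
* Realized heritability in the reference population is a random outcome of
  selection and drift (roughly 0.1–0.3 across replicates), not a
  controlled input; single-replicate checks against its design value can
  miss narrowly.
* The deterministic BLUP solvers plug in the simulation-true variance
  components; no variance-component estimation is provided.
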