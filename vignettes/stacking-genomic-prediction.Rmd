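---
title: "Stacked ensemble genomic prediction: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked ensemble genomic prediction: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stackgs)
```

## The problem

Genomic selection ranks breeding candidates by genomic estimated breeding
values (GEBVs) predicted from genome-wide SNP genotypes. `stackgs`
implements a stacked ensemble for this task: three heterogeneous base
learners — support vector regression (SVR), kernel ridge regression (KRR)
and the elastic net (ENET) — are fitted on rows of a genomic relationship
matrix, and an ordinary least-squares (OLS) meta-learner combines their
predictions. GBLUP and BayesB, the two standard references in animal and
plant breeding, are provided as from-scratch comparators, and a trait
simulator makes the whole pipeline testable without any real dataset.

## Input representation: the genomic relationship matrix

All learners consume rows of the VanRaden genomic relationship matrix

$$G = \frac{M M'}{\sum_j 2 p_j q_j},$$

where $M$ is the $n \times m$ genotype matrix with $2p_j$ subtracted from
column $j$ ($p_j$ the in-sample alternate-allele frequency,
$q_j = 1 - p_j$). Using $G$ rows instead of raw genotypes reduces the
feature dimension from $m$ (tens of thousands) to $n$ and with it the
overfitting pressure on the level-0 models. Two consequences worth
noting:

* Columns of $M$ are mean-zero, so every row of `vanraden_grm()` output
  sums to zero and $G$ is positive semi-definite up to round-off; both
  are asserted in the test suite.
* $G$ is built **once from all individuals** (training and test
  together) and then sliced: `grm_features()` gives training rows over
  training columns for fitting and test rows over the same columns for
  prediction. Allele-frequency sharing between training and test
  individuals is deliberate — it mirrors the whole-population protocol
  under which the method was designed — and shares no phenotype
  information.

## The stacking flow

`self_fit_predict()` runs the two-step flow:

1. **Metadata.** A balanced `k_meta = 5`-fold plan partitions the
   training set. Each base learner is fitted on four folds and predicts
   the fifth; row $i$ of the resulting `train_meta` matrix is therefore
   produced by a model that never saw $y_i$. This leakage contract is
   tested with a mean-predictor mock whose out-of-fold prediction must
   equal the complement-fold mean, never the global mean.
2. **Meta-learner.** Exact OLS (with intercept) of the training
   phenotypes on `train_meta`, solved by SVD. OLS is intentionally the
   simplest possible combiner: the metadata columns are highly
   correlated, and a regularized or nonlinear level-1 model would invite
   the very overfitting stacking is meant to avoid. Rank-deficient
   metadata (e.g. duplicated learners) yields the minimum-norm solution
   with a warning.

Test-set metadata comes from base learners **refit on the full training
set** (default). The alternative — averaging the five fold models — is
available via `test_mode = "average"`; refitting was chosen as default
because it uses all training data in the deployed models. The
meta-learner intercept can be disabled (`intercept = FALSE`); with it,
the single-learner stack is an exact affine transform of its base
learner, so Pearson accuracy is reproduced to machine precision — a
useful sanity property asserted in the tests.

Hyperparameter search (`grid_search()`) runs inside every metadata fold
on its own training portion with an inner 5-fold split, so tuning never
touches the held-out fold. Fixed parameters (a singleton grid) skip the
search entirely; that is the configuration used for the package's large
simulation checks, with defaults SVR $(C=1, \epsilon=0.1,
\gamma=1/n_\text{features})$, linear-kernel KRR $(\lambda=1)$ and ENET
$(\alpha=0.01, \rho=0.5)$ — sensible mid-grid values for standardized
phenotypes on GRM features.

## Base learners

* **SVR** minimizes $\tfrac12\|w\|^2 + C\sum_i L_\epsilon(f(x_i)-y_i)$
  with the $\epsilon$-insensitive loss and a Gaussian kernel
  $k(x,x') = \exp(-\gamma\|x-x'\|^2)$; solved by libsvm (e1071). The
  test suite verifies the returned dual solution against the KKT
  optimality certificate of the dual program rather than against a
  second solver.
* **KRR** uses the closed form $f(x) = k'(K+\lambda I)^{-1}y$, computed
  by Cholesky factorization of the symmetrized, jittered-if-needed
  system. $\lambda = 0$ with a singular kernel is an explicit error.
* **ENET** solves $\tfrac1{2n}\|y - b - Xw\|^2 +
  \alpha(\rho\|w\|_1 + \tfrac{1-\rho}2\|w\|_2^2)$ by coordinate descent
  (glmnet). glmnet internally standardizes the response, which rescales
  its penalty by $1/\mathrm{sd}(y)$; `fit_enet()` compensates so the
  objective above holds exactly — verified against closed-form ridge
  and soft-threshold solutions in the tests.

## GBLUP and REML

The mixed model $y = 1\mu + g + e$, $g \sim N(0, G\sigma_g^2)$,
$e \sim N(0, I\sigma_e^2)$ is estimated by REML profiled over the
variance ratio $\delta = \sigma_e^2/\sigma_g^2$. After the spectral
decomposition $G = UDU'$ the restricted likelihood is a cheap 1-D
function of $\delta$, optimized by Brent search on $\log\delta \in
[-12, 12]$; this is exact for a single random effect and requires one
$O(n^3)$ eigendecomposition. Predictions follow
$\hat g_\text{test} = G_{ts}(G_{tt} + \delta I)^{-1}(y - \hat\mu 1)$
with $\hat\mu$ the GLS mean.

A structural identity ties the modules together: GBLUP equals KRR with a
linear kernel whose Gram matrix is $G$ itself at $\lambda = \delta$,
fitted on $y - \hat\mu$. The test constructs features $X = UD^{1/2}$ (so
$XX' = G$ exactly) and checks agreement to $10^{-6}$. Note this is
*not* the same as using rows of $G$ as linear features (that Gram is
$G^2$).

## BayesB

The marker-effect model $y = 1\mu + \sum_j m_j \alpha_j \delta_j + e$
places a point mass at zero on each marker (prior exclusion probability
$\pi$, default 0.95) and a scaled-inverse-$\chi^2$ prior
($\nu = 4.2$) on each included marker's effect variance. The sampler is
a marginalized ("collapsed") Gibbs scheme: the inclusion indicator is
drawn with the effect integrated out via a likelihood ratio, the effect
from its normal full conditional when included, the per-marker variances
and residual variance from scaled-inverse-$\chi^2$ full conditionals and
the intercept from its normal full conditional. Marginalization of the
effect in the indicator step was chosen over Metropolis-within-Gibbs for
mixing. The chain is written in C++ (Rcpp) and uses R's RNG, so it is
exactly reproducible under `set.seed()`.

The default effect-variance scale is calibrated so the included markers
jointly explain a prior heritability of 0.5:
$S = \mathrm{var}(y)\,h^2_\text{prior}\,(\nu-2) /
(\nu\,(1-\pi)\sum_j 2p_jq_j)$. Every prior constant is exposed in
`bayesb_config()`. Setting `pi = 0` with a single fixed effect variance
collapses the model onto ridge regression of marker effects; the tests
confirm the resulting GEBVs correlate above 0.98 with GBLUP on polygenic
simulations, as theory demands. Default chains are 10,000 iterations
with 2,000 burn-in, thinning 5; the reproducibility test requires
posterior-mean GEBV correlation above 0.95 between independent chains.

## The simulator

`simulate_genotypes()` draws per-marker allele frequencies uniformly on
`maf_range` (default 0.05–0.5) and genotypes i.i.d. Binomial(2, $p_j$):
Hardy–Weinberg proportions, **no linkage disequilibrium**, no
missingness. Unlinked sites keep every analytic check clean (e.g. the
VanRaden diagonal concentrates at 1). `simulate_phenotypes()` builds
$g = M_c\beta$ over the causal loci and adds
$e \sim N(0, \mathrm{var}(g)(1-h^2)/h^2)$, so realized heritability
targets $h^2$ and $\mathrm{corr}(g, y) = \sqrt{h^2}$ — both verified by
simulation. Phenotypes are standardized to mean 0 / sd 1 by default,
matching the convention of pre-standardized dairy datasets.

Three architectures mirror the classic dairy-trait trichotomy: a major
gene carrying 50% of genetic variance plus 100 small loci; 10 moderate
loci (jointly 50% of genetic variance) plus 490 small loci; and 500
i.i.d. small effects. The qualitative labels "major", "moderate" and
"small" have no published quantitative definition; the shares and counts
here are this package's parameterization, chosen so that variable-
selection methods (BayesB) and homogeneous-shrinkage methods (GBLUP)
become distinguishable. Effects are Normal rather than gamma for
simplicity; the architecture-specific scaling is the only structure
imposed.

What the simulator does **not** emulate: linkage disequilibrium,
population/family structure, dominance or epistasis, genotyping error,
and fixed-effect contamination (phenotypes are assumed pre-corrected).
Passing tests therefore demonstrate internal correctness and behavior
under idealized sampling, not performance on structured livestock data.

## Evaluation protocol

`cross_validate()` implements K-fold (default 20) cross-validation with
balanced random folds; each fold is predicted by a pipeline fitted
entirely on the remaining folds (REML, tuning and metadata included).
Accuracy is the Pearson correlation $r = \mathrm{cov}(y, \hat y) /
\sqrt{\mathrm{var}(y)\mathrm{var}(\hat y)}$ between corrected phenotypes
and predicted GEBVs; reported as mean ± sd across folds (a standard
error can be derived from the per-fold vector). Folds whose accuracy is
undefined (constant predictions) are excluded with a warning rather than
zero-filled, to avoid biasing means. `compare_methods()` draws one fold
plan per comparison so all methods see byte-identical splits. Plans with
folds smaller than 3 are rejected (Pearson r is undefined there), which
rules out leave-one-out.

A note on expected accuracy under the simulator: with $m$ unlinked
markers, GBLUP accuracy behaves like
$\sqrt{h^2\,nh^2/(nh^2+M_e)}$ with $M_e \approx m$, i.e. about 0.25–0.33
at the simulation sizes used here ($n = 600$–1000, $m = 2000$,
$h^2 = 0.5$) — far below the $\sqrt{h^2} \approx 0.71$ ceiling. Real
chip data with strong LD (small $M_e$) sit much closer to the ceiling;
the simulator's accuracies are not comparable to published livestock
values and are not meant to be.

## Problem sizes and numerical choices

The shipped checks use simulation sizes chosen to exercise the methods
at meaningful scale while staying desk-fast: GRM diagnostics at
500×2000; REML recovery at n = 1000, m = 2000 over 10 seeds; BayesB
planted-QTL recovery at n = 500, m = 1000 with 10,000-iteration chains
over 10 replicates; the ensemble-vs-base comparison on five 600×2000
datasets (one per architecture plus two extra polygenic seeds) under
20-fold CV with fixed hyperparameters.

Other numerics: Cholesky with a relative jitter of $10^{-10}$ on
near-singular kernel systems; GBLUP retries once with a $10^{-8}$
relative jitter before failing; grid-search ties break to the first
lattice point (documented, deterministic); failed lattice points score
$-\infty$ and the search continues; all stochastic stages derive their
streams from a single integer seed, so every result in this package is
reproducible from one number.

## Known limitations

No LD-aware simulation (an AR(1)-haplotype extension would be the
natural next step); no dominance or epistasis anywhere; no multi-trait
models; BayesB offers no BayesA/C/R variants; binary PLINK (.bed) is not
read — convert to .raw/VCF/CSV first; and the stacking layer is
deliberately single-level with exactly one meta-learner (OLS), multi-
layer stacks being out of scope.
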