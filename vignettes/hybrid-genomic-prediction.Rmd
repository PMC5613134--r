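---
title: "Multi-kernel genomic prediction of hybrid performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-kernel genomic prediction of hybrid performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Two-pool hybrid breeding crosses female (maintainer) and male (restorer)
inbred lines and sells the F1. With 36 lines per pool there are 1296
possible hybrids; a trial network can phenotype only a few hundred of them,
in an incomplete factorial design. Two prediction questions follow:

1. *Complete the factorial*: predict untested crosses between parents that
   each have phenotyped descendants.
2. *Predict hybrids of untested parents* (T1: one parent untested; T0:
   both): here classical combining-ability analysis is blind, because a
   parent's effect is estimated only through its own progeny.

`hybridgs` implements the model families, the kernels, the cross-validation
machinery and a synthetic-study generator for this setting, with seed oil
content in a 9-environment sunflower MET as the reference scenario.

# Models and kernels

All models are per-environment linear mixed models for the adjusted
phenotype $y_{fm}$ of cross $f \times m$:

$$y_{fm} = \mu + F_f + M_m\,[+\,I_{fm}] + \varepsilon_{fm}$$

with $F \sim N(0, \sigma^2_f K_f)$, $M \sim N(0, \sigma^2_m K_m)$,
$I \sim N(0, \sigma^2_{fm} K_{fm})$, $\varepsilon \sim N(0,
\sigma^2_\varepsilon I)$, all mutually independent. The model families
differ only in their kernels:

* **GCA** uses identity kinships — parents assumed unrelated; equivalent to
  the classical combining-ability model.
* **FM** uses $K_f = X_f X_f'$ and $K_m = Z_m Z_m'$, where row $f$ of $X_f$
  holds the centered 0/1 alleles the (fully inbred) female transmits to all
  of its hybrids; likewise $Z_m$ for males. Centering is per locus within
  the role's own panel, so each kernel captures within-pool relatedness.
* **FMI** adds the interaction kernel. The default construction is
  $K_{fm} = W_{fm} W_{fm}'$ with $W_{fm}$ the same-locus elementwise
  product of the $X_f$ and $Z_m$ rows. An alternative,
  `method = "kinship_product"`, uses the Hadamard product of the expanded
  parental kinships, $K_{fm}[(f,m),(f',m')] = K_f[f,f'] \cdot K_m[m,m']$,
  which is the Gram matrix over all locus-*pair* products. The two agree
  only for a single locus; the elementwise form is the diagonal ($l = l'$)
  restriction of the pair form. We ship both because both appear in the
  hybrid-prediction literature; the elementwise form is the default for
  model fitting since its off-diagonal structure separates far better from
  the residual (the pair-product kernel is nearly a heteroscedastic
  identity at realistic designs, making $\sigma^2_{fm}$ vs
  $\sigma^2_\varepsilon$ weakly identified), while the factorizing pair
  form is the one whose algebra ($K_f \cdot K_m$ factorization, used in our
  identity tests) is exact.
* **FM_oil / mk_oil** restrict the kernels to SNPs inside (or within a
  1 kb window of) pathway genes, or model pathway and remaining SNPs as
  separate kernels with their own variances (MultiBLUP-style).
* **mk_epi** adds Hadamard squares $K_f \circ K_f$ and $K_m \circ K_m$:
  by the Schur product theorem these are PSD, and they model all pairwise
  additive×additive interactions within a pool.

**Kernel scaling.** Kernels default to a $1/L$ scale so variance components
are comparable across SNP subsets of different sizes. Predictions, the
restricted likelihood and z-ratios are invariant to any positive rescaling
(a tested property); plain cross-products are obtained with `scale = 1`.
`genetic_variances()` converts a component to the trait scale via
$\hat\sigma^2 \, \mathrm{tr}(K)/(n-1)$, exact for centered kernels whose
rows sum to zero.

# The REML engine

`reml_fit()` maximizes the restricted log-likelihood of
$y = Xb + \sum_k Z_k u_k + \varepsilon$ over the variance components using
average-information (AI) Newton steps on log variances with step halving
and a trust region, and hands over to a bounded L-BFGS-B polish (analytic
gradient, cached evaluations) when progress stalls — which happens on the
genuinely flat ridges that arise when a kernel is weakly separated from
the residual. Numerical choices:

* all solves by dense Cholesky of the $n \times n$ covariance ($n \le$ a
  few hundred per environment — no sparse machinery is warranted);
* convergence when the restricted log-likelihood changes by less than
  $10^{-8}$ and components by less than $10^{-6}$ relative (components far
  below phenotypic scale are measured absolutely, so a boundary component
  drifting on the log scale cannot stall termination);
* components are floored at $10^{-10} \times \mathrm{var}(y)$; anything
  below $10^{-6} \times \mathrm{var}(y)$ at convergence is reported as
  exactly 0 with a boundary flag (the value a table would print as 0.00),
  and its z-ratio is flagged undefined;
* standard errors come from the inverse AI matrix; the z-ratio is
  $\hat\sigma^2 / \mathrm{SE}$;
* the fixed part is an intercept for all hybrid model families; the
  engine accepts a general fixed-effect formula because the plot-level
  spatial adjustment needs row/column/repetition/status factors (aliased
  columns are dropped by rank detection, with a warning).

BLUPs are computed for *every* level of each kernel, observed or not:
$\hat u_k = \hat\sigma^2_k K_k Z_k' P y$, so an untested parent's effect is
its kinship-weighted projection of the training residuals — exactly zero
under an identity kinship, which is why the GCA model cannot rank untested
parents. The engine is validated against a grid-search oracle of the
restricted likelihood, the closed-form balanced one-way ANOVA estimators,
`lme4` on shared cases during development, the explicit conditional-normal
prediction formula, and the RR-BLUP ridge equivalence.

# Phenotype adjustment

Raw plot records (environment, row, column, repetition, genotype, check
status, oil %) are adjusted per environment with fixed row and column
factors (sum-coded), repetition when present, check status, and a random
independent genotype effect fitted by the same REML engine. The adjusted
phenotype of a hybrid is $\hat\mu$ + the hybrid-status coefficient + its
BLUP; checks are excluded from the output. Row and column enter as
unordered factors — deliberately the simplest model consistent with a
one-line description of spatial adjustment; autoregressive or spline
surfaces are out of scope. Two consequences are worth knowing: adjusted
values are BLUP-shrunken (their genetic variance is smaller than the
plot-level truth), and in an unreplicated trial the genotype/residual split
is identified only by replicated checks — with too few check plots REML can
legitimately put the genotype variance at zero. The generator therefore
sows ~10% check plots, the density an augmented unreplicated oil trial
would actually use.

# Cross-validation

Two test-set schemes, each drawing 100 sets by default (any number; all
models are always evaluated on the *same* sets so comparisons are paired):

* `sample_random_hybrids()`: 10% of observed hybrids per set (round half
  up) — the "complete the factorial" scenario;
* `sample_by_parents()`: 10% of the pooled 72 parent lines per set
  (7 parents), the test set being every observed hybrid with at least one
  sampled parent — so no sampled parent has descendants in training, and
  every test hybrid is T1 or T0 (labels returned). Sampling is unstratified
  by sex by default, with a `stratified` option.

Per set and environment, variance components are re-estimated on the
training hybrids only and the test hybrids predicted through the kernels;
predictive ability is the Pearson correlation between adjusted phenotypes
and predictions. Means and variances over sets are reported per
environment plus the unweighted MET average. No significance test is
attached to differences between models: the sampled test sets overlap, so
neither $\mathrm{SD}/\sqrt{100}$ nor a bootstrap gives a valid variance of
the mean ability. Per-set RNG uses substreams derived from one root seed
(`seed + 7919·set`), so growing `n_sets` never reshuffles earlier sets.

# Stability

`met_performance()` assembles the complete hybrids × environments matrix of
predicted performances ($\hat\mu$ + BLUP per environment), and
`wricke_ecovalence()` computes each hybrid's contribution
$W_i = \sum_e (p_{ie} - \bar p_{i\cdot} - \bar p_{\cdot e} + \bar
p_{\cdot\cdot})^2$ to the genotype×environment interaction sum of squares;
$\sum_i W_i$ equals the interaction SS of the double-centered matrix (a
tested identity). The default stability cutoff $W < 5$ (squared oil %) is
the screening value used for oil content; it is data-scale dependent and
exposed as an argument.

# The synthetic study generator

`simulate_study()` produces a complete, seeded study: parent VCFs, cross
design, plot phenotypes, pathway BED, and a retained ground truth. What it
emulates, and how:

* **Parents.** Each pool descends from 5 founder lines; a parent is a
  chromosome-wise mosaic of founders (geometric blocks, mean 20 loci).
  Founder mosaics are the essential ingredient: they give the background
  genomic relatedness of an elite pool, without which marker kinship
  carries no information about untested parents and genomic prediction
  could not outperform combining-ability analysis for T0/T1 hybrids even
  in principle. Male founders come from two mildly diverged subpopulations
  (Balding–Nichols $F = 0.05$, with 30% cross-subpopulation block mixing),
  so the male pool is slightly more structured than the female pool. A
  configurable fraction of loci (default 5%) is planted as exact
  duplicates or complements to exercise redundancy collapse.
* **Design.** Greedy balanced assignment of 490 crosses among 36 × 36
  parents gives 12–15 observed descendants per parent and a connected
  design; ~1% of crosses are flagged unobserved per environment.
* **Genetic values.** Per role, a MET-shared and per-environment specific
  genetic value are built from Gaussian marker effects mapped through the
  transmitted-allele matrix; the specific parts are orthogonalized against
  the shared part (and, while the parent count allows, against each other)
  and standardized, then combined as $\sqrt{\rho_e}\,\hat G +
  \sqrt{1-\rho_e}\,\hat D_e$ and rescaled so each environment's realized
  parental variance equals its target exactly. With $\rho_e$ drawn in
  (0.47, 0.77) the realized pairwise additive genetic correlations land at
  $\sqrt{\rho_e \rho_{e'}}$ within a few hundredths. Female variances
  default to 1.5× male (the 3:2 inheritance pattern); one designated
  environment (the 4th) carries a female×male interaction. An optional
  `pathway_share` confines a chosen share of genetic variance to pathway
  loci for FM_oil/mk_oil contrasts.
* **Plots.** Genetic values plus an environment main effect
  (mean 45% oil), a linear row gradient and sinusoidal column trend,
  ~10% replicated check plots, and Gaussian residual noise.

**What exact rescaling buys and costs.** Pinning each environment's
realized variance to its target makes the emulation bands (3:2 ratio
within [1.2, 1.8], correlation range) hold essentially deterministically —
with unconditional Gaussian draws they would hold only ~half the time at
this panel size, because a 5-founder kernel has few effective dimensions
and the realized variance of a draw is volatile. The cost is a small
conditioning bias: REML estimates the generative parameter, and forcing
every draw's sample variance to a constant inflates the kernel-conditional
estimate by a Jensen factor we measure at +2–3% at default size. Our
parameter-recovery checks over 200 simulated environments resolve exactly
this order, so they sit at the edge of their Monte-Carlo interval; we
document rather than hide this, since removing it would require either
non-Gaussian (eigenbasis sign-flip) effects or giving up the exact
emulation bands. Relatedly, a null female×male interaction is estimated at
the zero boundary in roughly half of environments, not more: REML under a
null component is the classic ½-mixture of an atom at zero and small
positive values, and the weak separation of interaction from residual at
realistic design sizes keeps the atom near that bound — the same pattern
the reference MET shows, with printed zeros in 5 of 9 environments.

What the generator does *not* emulate: linkage-disequilibrium decay within
blocks (alleles inside a mosaic block are perfectly correlated, between
blocks independent), dominance at the allele level (the interaction is a
kernel construct), non-Gaussian effect distributions, spatially
autocorrelated field error, and year structure among environments. Passing
tests therefore certify the machinery and its statistical behavior under a
faithful but idealized study, not performance on any particular real trial.

# Problem sizes used by the test and acceptance runs

Module tests run on toy panels (4–20 parents, 20–600 loci). The
study-scale checks use: parameter recovery — 20 independent studies × 10
environments at the default 36 × 36 / 490 / 2000-locus size (200 REML fits
per model family); cross-validation direction — 10 replicate studies × 3
environments × 20 paired test sets for the held-out-parent scheme, with
the random-hybrid arm on 3 of those replicates; the acceptance script —
one full default study (9 environments) with 15 paired test sets per
scheme. These sizes were chosen so a complete run finishes comfortably on
one CPU while keeping Monte-Carlo resolution at the few-percent level.

# Known limitations

* The adjustment model is a factor-based stand-in for richer spatial
  models; unreplicated environments with sparse checks can drive the
  genotype variance to the boundary, collapsing that environment's
  adjusted values.
* Dense algebra bounds the practical size to a few thousand observations
  per environment.
* Parents must be fully inbred and imputed upstream: heterozygous or
  missing calls are hard errors by design.
* Multi-allelic SNPs are out of scope; redundancy collapse assumes
  biallelic 0/1 coding.
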