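# hybridgs

Genomic prediction of hybrid performance from incomplete factorial mating
designs, built for two-pool hybrid breeding programs such as sunflower
maintainer (B-line) × restorer (R-line) crosses. The motivating application
is seed oil content observed in a multi-environment trial (MET): a breeder
crosses 36 female with 36 male inbred lines, phenotypes ~490 of the 1296
possible hybrids across 9 environments, and wants to predict the hybrids
never made — including crosses whose parents have *no* phenotyped
descendants at all (the so-called T1/T0 hybrids).

## The models

Within each environment the adjusted phenotype *y<sub>fm</sub>* of the
hybrid between female *f* and male *m* is modeled with a multi-kernel
linear mixed model fitted by REML:

- **GCA** — `y_fm = μ + GCA_f + GCA_m + ε`, with independent parental
  effects (identity kinships). The classical general-combining-ability
  model: a parent's effect is estimable only through its own descendants.
- **FM** — the same two effects, but `F ~ N(0, σ²_f K_f)` and
  `M ~ N(0, σ²_m K_m)` with genomic kinships `K_f = X_f X_f′`,
  `K_m = Z_m Z_m′` built from the centered alleles each inbred parent
  transmits to its hybrids. Untested parents are predicted through their
  marker relatedness to tested ones (GBLUP; equivalent to ridge-regression
  BLUP on marker effects).
- **FMI** — FM plus a female×male interaction (SCA) term with kernel
  `K_fm = W_fm W_fm′`, `W_fm` the Hadamard product of the transmitted-allele
  rows.
- **FM_oil / mk_oil** — kinships restricted to SNPs in (or within 1 kb of)
  genes of the oil-metabolism pathway, or a MultiBLUP-style four-kernel
  model giving pathway and remaining SNPs their own variances.
- **mk_epi** — FM plus Hadamard-square epistasis kernels `K_f∘K_f`,
  `K_m∘K_m` (all pairwise additive×additive interactions).

Around the engine the package provides: VCF/BED/CSV readers and writers for
parental genotypes, cross designs and pathway annotations; SNP filtering
and complete-LD redundancy collapse; per-environment spatial adjustment of
raw plot data (row/column/repetition/check-status fixed effects + random
genotype); the two test-set schemes of hybrid cross-validation (random
hybrids vs. held-out parents, T0/T1 tiers); Wricke-ecovalence stability
screening of MET predictions; and a fully seeded synthetic-study generator
with retained ground truth.

## Worked example

```r
library(hybridgs)
library(dplyr)

study <- simulate_study(sim_config(n_envs = 2, n_loci = 800, seed = 42))

# genotypes: polymorphism filter, redundancy collapse
mask <- filter_polymorphic(study$females, study$males)
fem  <- subset_loci(study$females, mask)
mal  <- subset_loci(study$males, mask)
red  <- collapse_redundant(fem, mal)
fem  <- subset_loci(fem, red$referent); mal <- subset_loci(mal, red$referent)

# plot phenotypes -> per-environment adjusted values
adjusted <- adjust_phenotypes(study$plots)

# kernels and an FM fit for one environment
kf <- additive_kinship(center_transmitted(fem))
km <- additive_kinship(center_transmitted(mal))
crosses <- as_tibble(study$design)[, c("hybrid_id", "female_id", "male_id")]
d <- inner_join(filter(adjusted, environment == "E1"), crosses,
                by = "hybrid_id")
fit <- reml_fit(d, assemble_model("FM", list(kf = kf, km = km)))
tidy(fit)
#> # A tibble: 3 × 6
#>   term     variance std_error z_ratio share boundary
#>   <chr>       <dbl>     <dbl>   <dbl> <dbl> <lgl>
#> 1 female      2.60     0.719     3.61 0.429 FALSE
#> 2 male        2.64     0.733     3.60 0.436 FALSE
#> 3 residual    0.814    0.0563   14.4  0.135 FALSE
```

The `variance` column is on the kernel scale (kernels default to a `1/L`
scaling); `genetic_variances(fit)` converts to the trait scale. `share` is
the part of variance: both parental pools carry strong genetic signal here,
with a small residual after spatial adjustment (the female and male shares
of any one simulated environment scatter around the generator's 3:2
target). Predict every cross of the factorial — including unobserved ones
— and screen stability:

```r
pred <- predict_hybrids(fit, crosses)           # mu + BLUP_f + BLUP_m
plan <- sample_by_parents(study$design, 0.10, n_sets = 20, seed = 1)
cv   <- run_cv(adjusted, study$design, c("GCA", "FM"), plan,
               kernels = list(kf = kf, km = km))
glance(cv)                                      # MET mean ability per model
#> # A tibble: 2 × 3
#>   model mean_ability n_environments
#>   <chr>        <dbl>          <int>
#> 1 FM           0.611              2
#> 2 GCA          0.547              2
```

Every test hybrid here has at least one parent with no phenotyped
descendants in training, and the genomic FM model beats the GCA model by
~12% in predictive ability — marker kinship carries information about
untested parents that combining-ability analysis cannot access. Under
random-hybrid sampling the two models are nearly tied. `wricke_ecovalence(met_performance(fits, crosses))` ranks
hybrids by mean MET performance and flags those with a small contribution
to the genotype×environment interaction sum of squares as stable.

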