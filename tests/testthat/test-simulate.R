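# mid-size config keeps the checks meaningful without full-study cost
mid_cfg <- function(...) {
  sim_config(n_females = 20, n_males = 20, n_loci = 600, n_crosses = 120,
             n_envs = 4, ...)
}

test_that("simulated parents are reproducible, structured and carry planted duplicates", {
  cfg <- mid_cfg(seed = 5, dup_fraction = 0.1)
  a <- simulate_parents(cfg)
  b <- simulate_parents(cfg)
  expect_identical(a$females$alleles, b$females$alleles)
  expect_identical(a$males$alleles, b$males$alleles)
  expect_length(a$duplicate_of, 60)
  # planted duplicates are recovered by redundancy collapse
  mask <- filter_polymorphic(a$females, a$males)
  red <- collapse_redundant(subset_loci(a$females, mask),
                            subset_loci(a$males, mask))
  expect_gte(sum(!red$referent), 0.9 * 0.1 * 600)
  expect_lte(sum(!red$referent), 1.2 * 0.1 * 600)
  # male pool is the more structured one: within-subpopulation kinship
  # exceeds between-subpopulation kinship
  km <- vanraden_kinship(a$males)
  grps <- rep(1:2, each = 10)
  within <- mean(km[outer(grps, grps, "==") & upper.tri(km)])
  between <- mean(km[outer(grps, grps, "!=") & upper.tri(km)])
  expect_gt(within, between)
  # no divergence: male and female mean off-diagonal kinship are comparable
  flat <- simulate_parents(mid_cfg(seed = 5, male_divergence = 0))
  km0 <- vanraden_kinship(flat$males)
  kf0 <- vanraden_kinship(flat$females)
  expect_lt(abs(mean(km0[upper.tri(km0)]) - mean(kf0[upper.tri(kf0)])), 0.05)
})

test_that("simulated designs are near-balanced, connected, and complete when asked", {
  cfg <- mid_cfg(seed = 7)
  des <- simulate_design(cfg, simulate_parents(cfg))
  expect_s3_class(des, "factorial_design")  # constructor enforces connectivity
  cf <- table(des$female_id); cm <- table(des$male_id)
  expect_lte(max(cf) - min(cf), 2)
  expect_lte(max(cm) - min(cm), 2)
  # full grid
  small <- sim_config(n_females = 4, n_males = 4, n_loci = 20,
                      n_crosses = 16, n_envs = 1, seed = 1)
  full <- simulate_design(small, simulate_parents(small))
  expect_equal(nrow(full), 16)
  # full-size default: descendant counts honor the 12-15 window
  dcfg <- sim_config(seed = 2, n_loci = 50)
  ddes <- simulate_design(dcfg, simulate_parents(dcfg))
  cnt <- c(table(ddes$female_id), table(ddes$male_id))
  expect_true(all(cnt >= 12 & cnt <= 15))
})

test_that("phenotype truth hits the configured variance targets and correlation range", {
  cfg <- mid_cfg(seed = 11, sigma2_f = 2.25, sigma2_m = 1.5, sigma2_e = 1.5,
                 interaction_envs = 2, sigma2_fm = 0.8)
  parents <- simulate_parents(cfg)
  des <- simulate_design(cfg, parents)
  ph <- simulate_phenotypes(cfg, parents, des)
  tg <- ph$truth$genetic_values
  # per-parent genetic variances are rescaled to the targets exactly
  e1 <- tg[tg$environment == "E1", ]
  fvals <- tapply(e1$g_female, des$female_id[match(e1$hybrid_id, des$hybrid_id)],
                  unique)
  expect_equal(var(unlist(fvals)), 2.25, tolerance = 1e-6)
  # interaction present only in the designated environment
  expect_equal(ph$truth$components$sigma2_fm, c(0, 0.8, 0, 0))
  expect_true(all(tg$g_inter[tg$environment != "E2"] == 0))
  expect_gt(var(tg$g_inter[tg$environment == "E2"]), 0)
  # female:male variance ratio near 3:2 over hybrids
  rat <- with(tg[tg$environment == "E3", ], var(g_female) / var(g_male))
  expect_gte(rat, 1.2); expect_lte(rat, 1.8)
  # realized additive genetic correlations near their targets
  tg$add <- tg$g_female + tg$g_male
  wide <- tidyr::pivot_wider(tg[, c("environment", "hybrid_id", "add")],
                             names_from = "environment", values_from = "add")
  cm <- cor(as.matrix(wide[, -1]))
  tgt <- sqrt(outer(ph$truth$components$rho, ph$truth$components$rho))
  expect_lt(max(abs(cm[upper.tri(cm)] - tgt[upper.tri(cm)])), 0.1)
  # near-unit rho: environments collapse onto the shared effect
  hi <- mid_cfg(seed = 11, cor_range = c(0.995, 0.999))
  ph2 <- simulate_phenotypes(hi, parents, des)
  t2 <- ph2$truth$genetic_values
  t2$add <- t2$g_female + t2$g_male
  w2 <- tidyr::pivot_wider(t2[, c("environment", "hybrid_id", "add")],
                           names_from = "environment", values_from = "add")
  expect_gt(min(cor(as.matrix(w2[, -1]))), 0.98)
})

test_that("plot records are well-formed and oil stays in a plausible span", {
  cfg <- mid_cfg(seed = 13)
  st <- simulate_study(cfg)
  expect_false(any(duplicated(
    st$plots[c("environment", "row", "col", "rep")])))
  expect_true(all(st$plots$oil > 25 & st$plots$oil < 65))
  expect_true(all(c("check", "hybrid") %in% st$plots$status))
  # every observed cross has exactly one hybrid plot per environment
  for (e in design_environments(st$design)[1:2]) {
    obs <- observed_crosses(st$design, e)
    hp <- st$plots[st$plots$environment == e & st$plots$status == "hybrid", ]
    expect_setequal(hp$genotype, obs$hybrid_id)
  }
})

test_that("a written study round-trips through the package readers", {
  cfg <- sim_config(n_females = 6, n_males = 6, n_loci = 80, n_crosses = 18,
                    n_envs = 2, seed = 17, n_pathway_genes = 5)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  fem <- read_parents_vcf(file.path(dir, "females.vcf"), "female")
  expect_equal(fem$alleles, st$females$alleles)
  des <- read_design_csv(file.path(dir, "design.csv"))
  expect_equal(tibble::as_tibble(des), tibble::as_tibble(st$design))
  ann <- read_pathway_bed(file.path(dir, "pathway.bed"), window = cfg$window)
  expect_equal(ann$genes$start, st$pathway$genes$start)
  expect_equal(ann$genes$end, st$pathway$genes$end)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$components$sigma2_f, st$truth$components$sigma2_f)
})

test_that("end-to-end: adjusted phenotypes and FM fits recover the planted components", {
  # a well-conditioned panel for this plumbing check: enough founders that
  # a single study's kernel-conditional REML deviation stays small
  cfg <- sim_config(n_females = 16, n_males = 16, n_loci = 500,
                    n_crosses = 96, n_envs = 3, seed = 23,
                    sigma2_f = 2.25, sigma2_m = 1.5, sigma2_e = 1.2,
                    n_founders = 12, block_loci = 15,
                    interaction_envs = integer(0), dup_fraction = 0)
  st <- simulate_study(cfg)
  adj <- adjust_phenotypes(st$plots)
  kf <- additive_kinship(center_transmitted(st$females))
  km <- additive_kinship(center_transmitted(st$males))
  crosses <- tibble::as_tibble(st$design)[, c("hybrid_id", "female_id", "male_id")]
  est <- sapply(design_environments(st$design), function(e) {
    d <- dplyr::inner_join(adj[adj$environment == e, ], crosses,
                           by = "hybrid_id")
    fit <- reml_fit(d, assemble_model("FM", list(kf = kf, km = km)))
    # prediction of true genetic ranking should be strong
    pr <- predict_hybrids(fit, crosses)
    tg <- st$truth$genetic_values
    tge <- tg[tg$environment == e, ]
    expect_gt(cor(pr$predicted, tge$genetic[match(pr$hybrid_id, tge$hybrid_id)]),
              0.5)
    gv <- genetic_variances(fit)
    setNames(gv$genetic_variance, gv$term)
  })
  # adjusted phenotypes are BLUP-shrunken and a single study's estimates are
  # conditional on one founder draw, so the absolute scale is loose here
  # (tight Monte-Carlo recovery lives in the acceptance suite); direction
  # and positivity must hold: both parental components present, female
  # larger on average (the planted 3:2 ratio)
  expect_true(all(est["female", ] > 0))
  expect_true(all(est["male", ] > 0))
  expect_gt(mean(est["female", ]), mean(est["male", ]))
  expect_gt(mean(est["residual", ]), 0)
})
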