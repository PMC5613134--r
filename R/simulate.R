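#' Configuration of a synthetic factorial study
#'
#' Defaults emulate a sunflower-style hybrid oil-content program: 36
#' maintainer (female) x 36 restorer (male) inbred lines, ~490 crosses with
#' each parent contributing 12-15 observed descendants, 9 environments whose
#' pairwise genetic correlations fall in 0.47-0.77, a female:male genetic
#' variance ratio of 3:2, near-zero female x male interaction except in one
#' designated environment, and oil content spanning roughly 32-59%.
#'
#' @param n_females,n_males numbers of parental lines per pool.
#' @param n_loci SNP loci (default 2000).
#' @param n_chromosomes chromosomes loci are spread over.
#' @param n_crosses crosses in the incomplete factorial (default 490).
#' @param n_envs environments of the MET (default 9).
#' @param sigma2_f,sigma2_m,sigma2_e per-environment female, male and
#'   residual variances (recycled); `NULL` draws them per environment from
#'   ranges typical of oil content (male 0.7-2.0, female = ratio x male,
#'   residual 1.0-2.0, in squared oil %).
#' @param female_male_ratio target female:male genetic variance ratio
#'   (default 1.5).
#' @param interaction_envs indices of environments carrying a female x male
#'   interaction (default: environment 4 only).
#' @param sigma2_fm interaction variance in those environments (default 0.7).
#' @param cor_range range the pairwise inter-environment genetic
#'   correlations are drawn to land in (default c(0.47, 0.77)).
#' @param dup_fraction fraction of loci planted as duplicates/complements of
#'   other loci, exercising redundancy collapse (default 0.05).
#' @param male_divergence Fst-like divergence of the two male subpopulations
#'   (default 0.05); females are a single population, so males come out
#'   slightly more structured.
#' @param male_founder_mixing probability a male mosaic block copies a
#'   founder of the other subpopulation (default 0.3); keeps the male
#'   structure mild rather than two disjoint pools.
#' @param n_founders founder lines per pool (default 5). Parents are
#'   chromosome mosaics of their pool's founders, giving the background
#'   genomic relatedness of an elite breeding pool — without it, marker
#'   kinship carries no information about parents never seen in training.
#' @param block_loci mean mosaic block length in loci (default 20).
#' @param n_pathway_genes genes in the focal metabolic pathway (default 40).
#' @param window pathway flanking window in bases (default 1000).
#' @param pathway_share share of genetic variance confined to pathway loci;
#'   `NULL` (default) spreads effects uniformly over loci.
#' @param missing_rate per-environment probability a cross is unobserved
#'   (default 0.01).
#' @param mean_oil grand mean oil content in % (default 45).
#' @param env_effect_sd SD of environment main effects in % (default 2.5).
#' @param spatial_amplitude amplitude of the planted field row/column
#'   gradients in % oil (default 1; 0 disables field effects).
#' @param n_checks check varieties per environment (default 5, each sown in
#'   10 plots spread over the field, i.e. roughly 10% check plots as in an
#'   augmented unreplicated trial); 0 disables checks.
#' @param seed root seed; every output is bitwise reproducible given the
#'   config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_females = 36, n_males = 36, n_loci = 2000,
                       n_chromosomes = 17, n_crosses = 490, n_envs = 9,
                       sigma2_f = NULL, sigma2_m = NULL, sigma2_e = NULL,
                       female_male_ratio = 1.5, interaction_envs = 4,
                       sigma2_fm = 0.7, cor_range = c(0.47, 0.77),
                       dup_fraction = 0.05, male_divergence = 0.05,
                       male_founder_mixing = 0.3,
                       n_founders = 5, block_loci = 20,
                       n_pathway_genes = 40, window = 1000,
                       pathway_share = NULL, missing_rate = 0.01,
                       mean_oil = 45, env_effect_sd = 2.5,
                       spatial_amplitude = 1, n_checks = 5, seed = 1) {
  cfg <- as.list(environment())
  assert_that(n_females >= 2 && n_males >= 2 && n_loci >= 2 && n_envs >= 1,
              "counts must be >= 2 (>= 1 environment)")
  assert_that(n_crosses <= n_females * n_males, "too many crosses requested")
  assert_that(all(cor_range > 0 & cor_range < 1) && diff(cor_range) >= 0,
              "cor_range must be inside (0, 1)")
  structure(cfg, class = "sim_config")
}

#' Simulate the two parental panels
#'
#' Per-locus allele frequencies are uniform on (0.1, 0.9). Each pool
#' descends from a small set of founder lines: a parent is a chromosome-wise
#' mosaic of its pool's founders (geometric block lengths), which gives the
#' background genomic relatedness typical of an elite breeding pool and is
#' what lets marker kinship say anything about parents with no phenotyped
#' descendants. Females form a single population; the male founders are
#' split into two subpopulations whose allele frequencies diverge by a
#' Balding-Nichols style parameter, so the male pool is more structured. A
#' configured fraction of loci is planted as exact duplicates or complements
#' of other loci (redundant markers in complete LD across the combined
#' panel).
#'
#' @param cfg a [sim_config()].
#' @return list with `females` and `males` ([parent_panel()]s) and
#'   `duplicate_of` (named map of planted redundant loci).
#' @export
simulate_parents <- function(cfg) {
  set.seed(substream_seed(cfg$seed, 1))
  L <- cfg$n_loci
  chrom <- sort(rep_len(seq_len(cfg$n_chromosomes), L))
  pos <- stats::ave(seq_len(L), chrom, FUN = function(i)
    sort(sample.int(5e6, length(i))))
  loci <- tibble::tibble(chrom = sprintf("chr%02d", chrom), pos = as.integer(pos),
                         id = sprintf("snp%05d", seq_len(L)))
  p <- stats::runif(L, 0.1, 0.9)
  draw <- function(n, freq) {
    matrix(stats::rbinom(n * length(freq), 1, rep(freq, each = n)), n)
  }
  # chromosome-wise founder mosaic: block boundaries ~ geometric; a block
  # copies a founder from `own`, or from `other` with probability `mix`
  mosaic <- function(n_parents, founders, own = NULL, other = NULL, mix = 0) {
    own <- own %||% seq_len(nrow(founders))
    out <- matrix(0L, n_parents, L)
    for (i in seq_len(n_parents)) {
      pick <- integer(L)
      for (ch in unique(chrom)) {
        ii <- which(chrom == ch)
        at <- 1L
        while (at <= length(ii)) {
          len <- 1L + stats::rgeom(1, 1 / cfg$block_loci)
          idx <- ii[at:min(at + len - 1L, length(ii))]
          pool <- if (length(other) && stats::runif(1) < mix) other else own
          pick[idx] <- pool[sample.int(length(pool), 1)]
          at <- at + len
        }
      }
      out[i, ] <- founders[cbind(pick, seq_len(L))]
    }
    out
  }
  founders_f <- draw(cfg$n_founders, p)
  fem <- mosaic(cfg$n_females, founders_f)
  d <- cfg$male_divergence
  if (d > 0) {
    a <- p * (1 - d) / d
    b <- (1 - p) * (1 - d) / d
    p1 <- stats::rbeta(L, a, b); p2 <- stats::rbeta(L, a, b)
  } else p1 <- p2 <- p
  nf1 <- ceiling(cfg$n_founders / 2)
  founders_m <- rbind(draw(nf1, p1), draw(cfg$n_founders - nf1, p2))
  pop1 <- seq_len(nf1); pop2 <- setdiff(seq_len(cfg$n_founders), pop1)
  n1 <- ceiling(cfg$n_males / 2)
  mal <- rbind(
    mosaic(n1, founders_m, pop1, pop2, cfg$male_founder_mixing),
    mosaic(cfg$n_males - n1, founders_m, pop2, pop1, cfg$male_founder_mixing))

  n_dup <- floor(cfg$dup_fraction * L)
  duplicate_of <- character(0)
  if (n_dup > 0) {
    tgt <- sample(seq_len(L), n_dup)
    src <- sample(setdiff(seq_len(L), tgt), n_dup, replace = TRUE)
    flip <- stats::runif(n_dup) < 0.5
    for (i in seq_len(n_dup)) {
      colf <- fem[, src[i]]; colm <- mal[, src[i]]
      if (flip[i]) { colf <- 1 - colf; colm <- 1 - colm }
      fem[, tgt[i]] <- colf; mal[, tgt[i]] <- colm
    }
    duplicate_of <- stats::setNames(loci$id[src], loci$id[tgt])
  }
  rownames(fem) <- sprintf("F%02d", seq_len(cfg$n_females))
  rownames(mal) <- sprintf("M%02d", seq_len(cfg$n_males))
  list(females = parent_panel(fem, loci, "female"),
       males = parent_panel(mal, loci, "male"),
       duplicate_of = duplicate_of)
}

#' Simulate pathway gene annotations
#'
#' Places genes (2-5 kb) at random positions of the simulated genome so a
#' subset of SNPs falls inside the genes or their flanking windows.
#'
#' @param cfg a [sim_config()].
#' @param loci locus tibble of the simulated panels.
#' @return a [pathway_annotation()].
#' @export
simulate_pathway <- function(cfg, loci) {
  set.seed(substream_seed(cfg$seed, 2))
  # anchor genes near existing SNPs so the pathway subset is non-trivial
  anchor <- loci[sample.int(nrow(loci), cfg$n_pathway_genes), ]
  len <- sample(2000:5000, cfg$n_pathway_genes, replace = TRUE)
  start <- pmax(1L, anchor$pos - sample(0:1500, cfg$n_pathway_genes, TRUE))
  pathway_annotation(
    tibble::tibble(chrom = anchor$chrom, start = start,
                   end = start + len,
                   id = sprintf("gene%03d", seq_len(cfg$n_pathway_genes))),
    window = cfg$window)
}

#' Simulate the incomplete factorial design
#'
#' Greedy balanced assignment: each new cross pairs a least-used female with
#' a least-used compatible male, producing per-parent descendant counts
#' within a narrow window (12-15 at the default full size) and a connected
#' design. About `missing_rate` of the crosses are flagged unobserved per
#' environment.
#'
#' @param cfg a [sim_config()].
#' @param parents result of [simulate_parents()].
#' @return a [factorial_design()] with environments `E1..En`.
#' @export
simulate_design <- function(cfg, parents) {
  set.seed(substream_seed(cfg$seed, 3))
  fid <- parent_ids(parents$females)
  mid <- parent_ids(parents$males)
  nf <- length(fid); nm <- length(mid)
  cnt_f <- stats::setNames(integer(nf), fid)
  cnt_m <- stats::setNames(integer(nm), mid)
  used <- matrix(FALSE, nf, nm, dimnames = list(fid, mid))
  pairs <- vector("list", cfg$n_crosses)
  for (i in seq_len(cfg$n_crosses)) {
    f_cand <- fid[cnt_f == min(cnt_f[rowSums(!used) > 0])]
    f_cand <- f_cand[rowSums(!used[f_cand, , drop = FALSE]) > 0]
    f <- sample(f_cand, 1)
    open <- mid[!used[f, ]]
    m_cand <- open[cnt_m[open] == min(cnt_m[open])]
    m <- sample(m_cand, 1)
    used[f, m] <- TRUE
    cnt_f[f] <- cnt_f[f] + 1L
    cnt_m[m] <- cnt_m[m] + 1L
    pairs[[i]] <- c(f, m)
  }
  pairs <- do.call(rbind, pairs)
  crosses <- tibble::tibble(
    hybrid_id = paste0(pairs[, 1], "x", pairs[, 2]),
    female_id = pairs[, 1], male_id = pairs[, 2])
  for (e in seq_len(cfg$n_envs))
    crosses[[sprintf("E%d", e)]] <- stats::runif(nrow(crosses)) > cfg$missing_rate
  factorial_design(crosses)
}

#' Simulate plot phenotypes and retain ground truth
#'
#' Additive marker effects are split into a MET-shared and an
#' environment-specific part (`effect = sqrt(rho) * shared +
#' sqrt(1 - rho) * specific`, rho drawn per environment inside `cor_range`),
#' which places pairwise inter-environment genetic correlations in the
#' configured range. Female and male contributions are rescaled to the
#' target per-environment variances (3:2 female:male by default); designated
#' environments add a female x male interaction built from the Hadamard
#' transmitted-allele product. Genetic values are laid onto field plots with
#' row/column gradients, check plots and residual noise.
#'
#' @param cfg a [sim_config()].
#' @param parents result of [simulate_parents()].
#' @param design a [factorial_design()] from [simulate_design()].
#' @param pathway optional [pathway_annotation()]; required when
#'   `cfg$pathway_share` is set.
#' @return list with `plots` (plot-record tibble) and `truth` (per-env
#'   variance components, genetic values, marker-effect correlation targets,
#'   pathway mask).
#' @export
simulate_phenotypes <- function(cfg, parents, design, pathway = NULL) {
  set.seed(substream_seed(cfg$seed, 4))
  xf <- center_transmitted(parents$females)
  zm <- center_transmitted(parents$males)
  L <- ncol(xf$values)
  envs <- design_environments(design)
  nE <- length(envs)

  s2m <- rep_len(cfg$sigma2_m %||% stats::runif(nE, 0.7, 2.0), nE)
  s2f <- rep_len(cfg$sigma2_f %||% (cfg$female_male_ratio * s2m), nE)
  s2e <- rep_len(cfg$sigma2_e %||% stats::runif(nE, 1.0, 2.0), nE)
  s2fm <- numeric(nE)
  s2fm[intersect(cfg$interaction_envs, seq_len(nE))] <- cfg$sigma2_fm

  w_loci <- rep(1, L)
  path_mask <- rep(FALSE, L)
  if (!is.null(pathway)) path_mask <- select_pathway_snps(xf$loci, pathway)
  if (!is.null(cfg$pathway_share)) {
    assert_that(any(path_mask), "pathway_share set but no pathway SNPs")
    w_loci[path_mask] <- cfg$pathway_share / sum(path_mask)
    w_loci[!path_mask] <- (1 - cfg$pathway_share) / sum(!path_mask)
    w_loci <- sqrt(w_loci * L)
  }

  rho <- stats::runif(nE, cfg$cor_range[1], cfg$cor_range[2])
  # shared and env-specific genetic values per role; the specific part is
  # orthogonalized against the shared part and both are standardized, so the
  # realized variance is exactly the target and pairwise genetic
  # correlations land at sqrt(rho_e * rho_e') up to small cross terms
  standardize <- function(g) {
    g <- g - mean(g)
    g / stats::sd(g)
  }
  # orthogonalize a raw specific part against the shared part and, while the
  # parent count allows it, against the previous environments' specific
  # parts, so pairwise genetic correlations are sqrt(rho_e rho_e') exactly
  # at the parent level
  ortho_specific <- function(g, basis) {
    g <- g - mean(g)
    for (b in basis) g <- g - b * drop(crossprod(b, g) / crossprod(b))
    standardize(g)
  }
  shared_f <- standardize(drop(xf$values %*% (stats::rnorm(L) * w_loci)))
  shared_m <- standardize(drop(zm$values %*% (stats::rnorm(L) * w_loci)))
  truth_g <- list(); alpha <- list()
  env_main <- stats::rnorm(nE, 0, cfg$env_effect_sd)
  rescale <- function(g, target) {
    v <- stats::var(g)
    if (v <= 0) return(g)
    g * sqrt(target / v)
  }
  basis_f <- list(shared_f); basis_m <- list(shared_m)
  for (e in seq_len(nE)) {
    af <- stats::rnorm(L) * w_loci
    am <- stats::rnorm(L) * w_loci
    spec_f <- ortho_specific(drop(xf$values %*% af), basis_f)
    spec_m <- ortho_specific(drop(zm$values %*% am), basis_m)
    if (length(basis_f) < nrow(xf$values) - 2) {
      basis_f <- c(basis_f, list(spec_f))
      basis_m <- c(basis_m, list(spec_m))
    }
    gf <- sqrt(s2f[e]) * (sqrt(rho[e]) * shared_f + sqrt(1 - rho[e]) * spec_f)
    gm <- sqrt(s2m[e]) * (sqrt(rho[e]) * shared_m + sqrt(1 - rho[e]) * spec_m)
    names(gf) <- rownames(xf$values)
    names(gm) <- rownames(zm$values)
    gi <- stats::setNames(numeric(nrow(design)), design$hybrid_id)
    if (s2fm[e] > 0) {
      w <- xf$values[design$female_id, , drop = FALSE] *
        zm$values[design$male_id, , drop = FALSE]
      gi <- rescale(drop(w %*% (stats::rnorm(L) * w_loci)), s2fm[e])
      names(gi) <- design$hybrid_id
    }
    truth_g[[e]] <- tibble::tibble(
      environment = envs[e],
      hybrid_id = design$hybrid_id,
      g_female = unname(gf[design$female_id]),
      g_male = unname(gm[design$male_id]),
      g_inter = unname(gi[design$hybrid_id]))
    truth_g[[e]]$genetic <- truth_g[[e]]$g_female + truth_g[[e]]$g_male +
      truth_g[[e]]$g_inter
    truth_g[[e]]$expected <- cfg$mean_oil + env_main[e] + truth_g[[e]]$genetic
    alpha[[e]] <- list(female = af, male = am)
  }
  genetic_values <- dplyr::bind_rows(truth_g)

  plots <- list()
  for (e in seq_len(nE)) {
    obs <- observed_crosses(design, envs[e])
    g <- truth_g[[e]][match(obs$hybrid_id, truth_g[[e]]$hybrid_id), ]
    n_check_plots <- if (cfg$n_checks > 0) cfg$n_checks * 10L else 0L
    n_plot <- nrow(obs) + n_check_plots
    ncol_f <- ceiling(sqrt(n_plot))
    nrow_f <- ceiling(n_plot / ncol_f)
    cells <- sample.int(nrow_f * ncol_f, n_plot)
    rr <- (cells - 1L) %/% ncol_f + 1L
    cc <- (cells - 1L) %% ncol_f + 1L
    row_eff <- cfg$spatial_amplitude * scale(seq_len(nrow_f))[, 1]
    col_eff <- cfg$spatial_amplitude *
      sin(2 * pi * seq_len(ncol_f) / ncol_f) / 2
    geno <- c(obs$hybrid_id,
              if (n_check_plots) rep(sprintf("check%d", seq_len(cfg$n_checks)),
                                     each = 10L))
    status <- c(rep("hybrid", nrow(obs)), rep("check", n_check_plots))
    base <- c(g$expected,
              if (n_check_plots) rep(cfg$mean_oil + env_main[e] - 1 +
                                       seq_len(cfg$n_checks) * 0.5, each = 10L))
    plots[[e]] <- tibble::tibble(
      environment = envs[e], row = rr, col = cc, rep = 1L,
      genotype = geno, status = status,
      oil = base + row_eff[rr] + col_eff[cc] + stats::rnorm(n_plot, 0, sqrt(s2e[e])))
  }
  plots <- dplyr::bind_rows(plots)
  assert_that(all(plots$oil > 0 & plots$oil < 100),
              "simulated oil left (0,100); check config scales")

  truth <- list(
    components = tibble::tibble(environment = envs, sigma2_f = s2f,
                                sigma2_m = s2m, sigma2_fm = s2fm,
                                sigma2_e = s2e, rho = rho,
                                env_main = env_main),
    genetic_values = genetic_values,
    pathway_mask = path_mask,
    marker_effects = alpha)
  list(plots = plots, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Orchestrates [simulate_parents()], [simulate_pathway()],
#' [simulate_design()] and [simulate_phenotypes()] from one seeded config.
#'
#' @param cfg a [sim_config()].
#' @return list with `config`, `females`, `males`, `duplicate_of`, `design`,
#'   `pathway`, `plots`, `truth`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  parents <- simulate_parents(cfg)
  pathway <- simulate_pathway(cfg, parents$females$loci)
  design <- simulate_design(cfg, parents)
  ph <- simulate_phenotypes(cfg, parents, design, pathway)
  list(config = cfg, females = parents$females, males = parents$males,
       duplicate_of = parents$duplicate_of, design = design,
       pathway = pathway, plots = ph$plots, truth = ph$truth)
}

#' Write a simulated study to disk
#'
#' Emits the parent VCFs, design CSV, plot CSV, pathway BED and a ground
#' truth JSON under a directory, the same formats the reading functions of
#' the package accept.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_parents_vcf(study$females, file.path(dir, "females.vcf"))
  write_parents_vcf(study$males, file.path(dir, "males.vcf"))
  write_design_csv(study$design, file.path(dir, "design.csv"))
  readr::write_csv(study$plots, file.path(dir, "plots.csv"))
  write_pathway_bed(study$pathway, file.path(dir, "pathway.bed"))
  jsonlite::write_json(
    list(components = study$truth$components,
         genetic_values = study$truth$genetic_values,
         pathway_mask = study$truth$pathway_mask,
         duplicate_of = as.list(study$duplicate_of)),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
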