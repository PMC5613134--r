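# fixtures built in code + independent oracles used across test files

# two tiny panels sharing a locus list
tiny_panels <- function() {
  loci <- tibble::tibble(chrom = "chr01", pos = c(100L, 200L, 300L, 400L),
                         id = paste0("s", 1:4))
  fem <- rbind(F1 = c(0, 0, 1, 0), F2 = c(1, 0, 0, 0), F3 = c(1, 1, 1, 0))
  mal <- rbind(M1 = c(0, 1, 1, 1), M2 = c(1, 1, 0, 0), M3 = c(0, 0, 1, 1))
  list(females = parent_panel(fem, loci, "female"),
       males = parent_panel(mal, loci, "male"))
}

tiny_design <- function() {
  factorial_design(tibble::tibble(
    hybrid_id = c("F1xM1", "F1xM2", "F2xM1", "F2xM2", "F3xM1", "F3xM3"),
    female_id = c("F1", "F1", "F2", "F2", "F3", "F3"),
    male_id   = c("M1", "M2", "M1", "M2", "M1", "M3"),
    E1 = TRUE))
}

random_panels <- function(n_f = 8, n_m = 8, L = 50, seed = 1) {
  set.seed(seed)
  loci <- tibble::tibble(chrom = "chr01", pos = seq_len(L) * 100L,
                         id = sprintf("s%03d", seq_len(L)))
  repeat {
    fem <- matrix(rbinom(n_f * L, 1, runif(L, 0.2, 0.8)[rep(1:L, each = n_f)]),
                  n_f, dimnames = list(paste0("F", 1:n_f), NULL))
    mal <- matrix(rbinom(n_m * L, 1, runif(L, 0.2, 0.8)[rep(1:L, each = n_m)]),
                  n_m, dimnames = list(paste0("M", 1:n_m), NULL))
    ok <- all(colSums(rbind(fem, mal)) %in% seq_len(n_f + n_m - 1))
    if (ok) break
  }
  list(females = parent_panel(fem, loci, "female"),
       males = parent_panel(mal, loci, "male"))
}

# independent restricted log-likelihood: straight matrix formula via
# determinant() and solve(), no Cholesky/chol2inv path shared with the engine
reml_loglik_oracle <- function(y, G_list, sigma2) {
  n <- length(y)
  X <- matrix(1, n, 1)
  V <- diag(sigma2[length(sigma2)], n)
  for (k in seq_along(G_list)) V <- V + sigma2[k] * G_list[[k]]
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       t(y) %*% P %*% y + (n - 1) * log(2 * pi)))
}

# observation-level covariance structure of a random term, for oracles
term_G <- function(term, data) {
  K <- unclass(term$kinship)
  pos <- match(as.character(data[[term$column]]), rownames(K))
  K[pos, pos, drop = FALSE]
}

# a small connected design over the random panels, optionally holding a
# parent out of all crosses
tiny_grid_design <- function(p, n = 15, seed = 1, hold_out_female = NULL) {
  set.seed(seed)
  grid <- tidyr::expand_grid(female_id = parent_ids(p$females),
                             male_id = parent_ids(p$males))
  if (!is.null(hold_out_female))
    grid <- grid[grid$female_id != hold_out_female, ]
  repeat {
    pick <- grid[sample(nrow(grid), n), ]
    ok <- tryCatch({
      factorial_design(dplyr::mutate(
        pick, hybrid_id = paste0(female_id, "x", male_id), E1 = TRUE,
        .before = 1))
    }, error = function(e) NULL)
    if (!is.null(ok)) return(ok)
  }
}
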