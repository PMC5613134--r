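#' Assemble the random terms of a hybrid prediction model family
#'
#' Model families, per environment, for the adjusted phenotype of hybrid
#' f x m:
#' \describe{
#'   \item{GCA}{`y = mu + GCA_f + GCA_m + e`, identity kinships: parental
#'     lines assumed unrelated.}
#'   \item{FM}{female and male effects with genomic kinships
#'     `K_f = X_f X_f'`, `K_m = Z_m Z_m'`.}
#'   \item{FMI}{FM plus the female-by-male interaction with
#'     `K_fm = W_fm W_fm'`.}
#'   \item{FM_oil}{FM with kinships restricted to pathway SNPs.}
#'   \item{mk_oil}{multi-kernel FM: female/male x pathway/remaining SNP
#'     groups, four genetic terms each with its own variance.}
#'   \item{mk_epi}{FM plus Hadamard-square epistasis kernels
#'     `K_f*K_f` and `K_m*K_m`.}
#' }
#'
#' @param kind one of `"GCA"`, `"FM"`, `"FMI"`, `"FM_oil"`, `"mk_oil"`,
#'   `"mk_epi"`.
#' @param kernels named list of `kinship_matrix` objects; required entries by
#'   kind: FM/FMI/mk_epi need `kf`, `km` (FMI also `kfm`); FM_oil needs
#'   `kf_pathway`, `km_pathway`; mk_oil needs those plus `kf_rest`,
#'   `km_rest`. GCA needs none.
#' @param female_ids,male_ids all parent ids (for the GCA identity kinships).
#' @return list of [random_term()]s.
#' @export
assemble_model <- function(kind, kernels = list(), female_ids = NULL,
                           male_ids = NULL) {
  need <- function(nm) {
    for (x in nm)
      if (is.null(kernels[[x]]))
        stop(sprintf("model '%s' needs kernel '%s'", kind, x), call. = FALSE)
    lapply(kernels[nm], identity)
  }
  switch(kind,
    GCA = {
      assert_that(!is.null(female_ids) && !is.null(male_ids),
                  "GCA model needs female_ids and male_ids")
      list(random_term("female", "female_id", levels = female_ids),
           random_term("male", "male_id", levels = male_ids))
    },
    FM = {
      k <- need(c("kf", "km"))
      list(random_term("female", "female_id", k$kf),
           random_term("male", "male_id", k$km))
    },
    FMI = {
      k <- need(c("kf", "km", "kfm"))
      list(random_term("female", "female_id", k$kf),
           random_term("male", "male_id", k$km),
           random_term("interaction", "hybrid_id", k$kfm))
    },
    FM_oil = {
      k <- need(c("kf_pathway", "km_pathway"))
      list(random_term("female", "female_id", k$kf_pathway),
           random_term("male", "male_id", k$km_pathway))
    },
    mk_oil = {
      k <- need(c("kf_pathway", "km_pathway", "kf_rest", "km_rest"))
      list(random_term("female_pathway", "female_id", k$kf_pathway),
           random_term("female_rest", "female_id", k$kf_rest),
           random_term("male_pathway", "male_id", k$km_pathway),
           random_term("male_rest", "male_id", k$km_rest))
    },
    mk_epi = {
      k <- need(c("kf", "km"))
      list(random_term("female", "female_id", k$kf),
           random_term("male", "male_id", k$km),
           random_term("female_epistasis", "female_id",
                       epistasis_kinship(k$kf)),
           random_term("male_epistasis", "male_id",
                       epistasis_kinship(k$km)))
    },
    stop("unknown model kind: ", kind, call. = FALSE)
  )
}

#' Parts of variance of a fitted model
#'
#' Each component's proportion of the total variance (residual included),
#' the standard table alongside raw REML components.
#'
#' @param fit a `hybridgs_fit`, or a named numeric vector of variance
#'   components (residual included).
#' @param digits rounding for display-style output; `NULL` for full
#'   precision.
#' @return tibble with `term`, `variance`, `share`.
#' @export
parts_of_variance <- function(fit, digits = NULL) {
  s2 <- if (inherits(fit, "hybridgs_fit")) fit$sigma2 else fit
  assert_that(is.numeric(s2) && all(s2 >= 0), "components must be >= 0")
  tot <- sum(s2)
  if (tot <= 0) stop("total variance is zero", call. = FALSE)
  share <- s2 / tot
  if (!is.null(digits)) share <- round(share, digits)
  tibble::tibble(term = names(s2) %||% paste0("comp", seq_along(s2)),
                 variance = unname(s2), share = unname(share))
}

#' z-ratio of a variance component
#'
#' The REML estimate divided by its average-information standard error, a
#' quick screen for whether a component (e.g. the female x male interaction)
#' is supported by the data. Undefined for components estimated at the zero
#' boundary.
#'
#' @param fit a `hybridgs_fit`.
#' @param term term name (including `"residual"`).
#' @return scalar z-ratio, or `NA` with a warning for a boundary component.
#' @export
zratio <- function(fit, term) {
  assert_that(term %in% names(fit$sigma2), paste("unknown term", term))
  if (fit$boundary[[term]]) {
    warning(sprintf("component '%s' is at the zero boundary; z-ratio undefined",
                    term))
    return(NA_real_)
  }
  unname(fit$sigma2[[term]] / fit$se[[term]])
}

#' Predict hybrid genetic values
#'
#' Genetic value of cross f x m is `mu + u_F[f] + u_M[m]` plus the
#' interaction BLUP when the model carries one; multi-kernel models sum the
#' BLUPs of every female-attached and male-attached term. Parents (or
#' crosses, for interaction terms) never observed in training are predicted
#' through their kinship covariance with observed levels; a parent absent
#' from the kinship altogether is an error.
#'
#' @param fit a `hybridgs_fit`.
#' @param crosses data frame with `hybrid_id`, `female_id`, `male_id`.
#' @return tibble `hybrid_id`, `female_id`, `male_id`, `predicted`.
#' @export
predict_hybrids <- function(fit, crosses) {
  crosses <- tibble::as_tibble(crosses)[, c("hybrid_id", "female_id", "male_id")]
  pred <- rep(fit$mu, nrow(crosses))
  for (k in seq_along(fit$terms)) {
    tk <- fit$terms[[k]]
    u <- fit$blup[[k]]
    lev <- as.character(crosses[[tk$column]])
    pos <- match(lev, names(u))
    if (anyNA(pos))
      stop(sprintf("term '%s': level '%s' absent from kinship",
                   tk$name, lev[which(is.na(pos))[1]]), call. = FALSE)
    pred <- pred + u[pos]
  }
  dplyr::mutate(crosses, predicted = unname(pred))
}

#' Trait-scale genetic variances of a fitted model
#'
#' A variance component is defined relative to its kernel: `u ~ N(0,
#' sigma2 K)`. For centered cross-product kernels (whose rows sum to zero)
#' the expected sample variance of the effects over the kernel's n levels is
#' `sigma2 * tr(K) / (n - 1)`, which puts every component on the trait
#' scale regardless of the kernel scaling convention — the number to compare
#' against a simulation's planted variances or across SNP subsets.
#'
#' @param fit a `hybridgs_fit`.
#' @return tibble with `term`, `variance` (kernel scale) and
#'   `genetic_variance` (trait scale; residual passes through unchanged).
#' @export
genetic_variances <- function(fit) {
  fac <- vapply(fit$terms, function(tk) {
    K <- unclass(tk$kinship)
    sum(diag(K)) / (nrow(K) - 1)
  }, 0)
  tibble::tibble(
    term = names(fit$sigma2),
    variance = unname(fit$sigma2),
    genetic_variance = unname(fit$sigma2 * c(fac, 1)))
}
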