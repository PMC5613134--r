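#' Centered transmitted-allele matrix
#'
#' The building block of every genomic kernel: for each parent of one role,
#' the 0/1 allele it transmits to its hybrids, centered per locus. Centering
#' uses the allele frequency of the role's own panel, so the resulting
#' kinship captures within-role relatedness.
#'
#' @param panel a [parent_panel()].
#' @param mask logical or integer locus selection (default: all loci).
#' @param center optional numeric vector of per-locus centering constants to
#'   reuse (e.g. frequencies from another locus set); default: column means.
#' @return object of class `transmitted_alleles`: list with `values`
#'   (parents x loci centered matrix), `role`, `center`, `loci`.
#' @export
center_transmitted <- function(panel, mask = NULL, center = NULL) {
  mask <- mask %||% rep(TRUE, ncol(panel$alleles))
  x <- panel$alleles[, mask, drop = FALSE]
  if (ncol(x) == 0L) stop("locus mask selects no loci", call. = FALSE)
  ctr <- center %||% colMeans(x)
  assert_that(length(ctr) == ncol(x), "one centering constant per locus")
  structure(
    list(values = sweep(x, 2, ctr), role = panel$role, center = ctr,
         loci = panel$loci[mask, , drop = FALSE]),
    class = "transmitted_alleles")
}

#' @export
print.transmitted_alleles <- function(x, ...) {
  cat(sprintf("<transmitted_alleles> %s: %d parents x %d loci\n",
              x$role, nrow(x$values), ncol(x$values)))
  invisible(x)
}

new_kinship <- function(values, provenance, locus_set = "all", scale = 1) {
  values <- (values + t(values)) / 2  # enforce exact symmetry
  structure(values,
            class = c("kinship_matrix", "matrix", "array"),
            provenance = provenance, locus_set = locus_set,
            kin_scale = scale)
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %s (%s loci, scale %s): %d x %d\n",
              attr(x, "provenance"), attr(x, "locus_set"),
              format(attr(x, "kin_scale")), nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(4, nrow(x))), seq_len(min(4, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Tidy a kinship matrix into long format
#' @param x a kinship matrix.
#' @param ... unused.
#' @return tibble with columns `entity_1`, `entity_2`, `kinship`.
#' @method tidy kinship_matrix
#' @export
tidy.kinship_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    entity_1 = rep(rownames(m), times = ncol(m)),
    entity_2 = rep(colnames(m), each = nrow(m)),
    kinship = as.vector(m))
}

#' Additive kinship from transmitted alleles
#'
#' The cross-product kernel `K = scale * X X'` over the centered transmitted
#' alleles of one parental role. The default `scale = 1/L` makes variance
#' components comparable across SNP subsets of different sizes; `scale = 1`
#' gives the plain cross-product (predictions are invariant to the choice,
#' variance components rescale by `1/scale`).
#'
#' @param x a [center_transmitted()] result.
#' @param scale positive kernel scale, or `NULL` for `1/L`.
#' @param locus_set label recorded in provenance (e.g. `"pathway"`).
#' @return a `kinship_matrix` over the role's parents.
#' @export
additive_kinship <- function(x, scale = NULL, locus_set = "all") {
  assert_that(ncol(x$values) >= 1, "no loci in transmitted-allele matrix")
  scale <- scale %||% (1 / ncol(x$values))
  assert_that(scale > 0, "scale must be positive")
  new_kinship(scale * tcrossprod(x$values), "additive", locus_set, scale)
}

#' Female-by-male interaction kinship over hybrid crosses
#'
#' Covariance kernel of the specific-combining-ability (female x male
#' interaction) effect. The default (`"transmitted_product"`) builds the row
#' of cross (f, m) as the same-locus element-wise (Hadamard) product of
#' female row f and male row m of the centered transmitted-allele matrices
#' and takes its cross-product `K_fm = W_fm W_fm'`; this is the kernel the
#' hybrid model families fit, and it is well separated from the residual
#' even at moderate design sizes. `method = "kinship_product"` instead takes
#' the Hadamard product of the two parental cross-product kinships expanded
#' to crosses, `K_fm[(f,m),(f',m')] = K_f[f,f'] * K_m[m,m']` (exactly, when
#' all three use scale 1) — the Gram matrix of all locus-pair products
#' `x_fl * z_ml'`, i.e. the full pairwise-interaction generalization of
#' which the default is the diagonal (l = l') restriction. Entities are the
#' supplied crosses (observed or to-predict), not the full female x male
#' grid.
#'
#' @param xf,zm [center_transmitted()] results for females and males on the
#'   same locus set.
#' @param crosses data frame with `hybrid_id`, `female_id`, `male_id`.
#' @param scale positive kernel scale, or `NULL` for `1/L`
#'   (`"transmitted_product"`) / `1/L^2` (`"kinship_product"`), matching the
#'   additive default `1/L`; `scale = 1` gives the plain construction.
#' @param method kernel construction, see above.
#' @param locus_set provenance label.
#' @return a `kinship_matrix` over hybrid ids.
#' @export
interaction_kinship <- function(xf, zm, crosses, scale = NULL,
                                method = c("transmitted_product",
                                            "kinship_product"),
                                locus_set = "all") {
  method <- match.arg(method)
  assert_that(ncol(xf$values) == ncol(zm$values) &&
                all(xf$loci$id == zm$loci$id),
              "female and male matrices must share the locus set")
  L <- ncol(xf$values)
  if (method == "kinship_product") {
    scale <- scale %||% (1 / L^2)
    kf <- tcrossprod(xf$values)[crosses$female_id, crosses$female_id,
                                drop = FALSE]
    km <- tcrossprod(zm$values)[crosses$male_id, crosses$male_id,
                                drop = FALSE]
    v <- scale * kf * km
  } else {
    scale <- scale %||% (1 / L)
    w <- xf$values[crosses$female_id, , drop = FALSE] *
      zm$values[crosses$male_id, , drop = FALSE]
    v <- scale * tcrossprod(w)
  }
  dimnames(v) <- list(crosses$hybrid_id, crosses$hybrid_id)
  new_kinship(v, paste0("interaction-", method), locus_set, scale)
}

#' Additive-by-additive epistasis kinship
#'
#' Element-wise square (Hadamard self-product) of an additive kinship. By the
#' Schur product theorem the result is again positive semi-definite; it
#' models the covariance of all pairwise additive-by-additive SNP
#' interactions within a parental role.
#'
#' @param k an additive `kinship_matrix`.
#' @return a `kinship_matrix` with provenance `"epistasis"`.
#' @export
epistasis_kinship <- function(k) {
  new_kinship(unclass(k) * unclass(k), "epistasis",
              attr(k, "locus_set"), attr(k, "kin_scale")^2)
}

#' VanRaden method-1 genomic relationship matrix
#'
#' `G = M M' / (2 sum p_l (1 - p_l))` with M the per-locus mean-centered
#' genotype matrix and p_l the allele frequency estimated from the supplied
#' parents. For inbred 0/1 panels the transmitted-allele dosage is used
#' directly. Used for ordering parents in design heat maps / dendrograms.
#'
#' @param panel a [parent_panel()], or a combined allele matrix.
#' @return a `kinship_matrix` with provenance `"vanraden"`.
#' @export
vanraden_kinship <- function(panel) {
  al <- if (inherits(panel, "parent_panel")) panel$alleles else as.matrix(panel)
  p <- colMeans(al)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all loci monomorphic: VanRaden kinship undefined", call. = FALSE)
  m <- sweep(al, 2, p)
  new_kinship(tcrossprod(m) / denom, "vanraden", "all", 1 / denom)
}

#' Check kinship symmetry and positive semi-definiteness
#'
#' @param k a `kinship_matrix`.
#' @param tol relative eigenvalue tolerance.
#' @return TRUE invisibly; error when the kernel is not (numerically) PSD.
#' @export
validate_kinship <- function(k, tol = 1e-8) {
  m <- unclass(k)
  assert_that(max(abs(m - t(m))) < 1e-10, "kinship not symmetric")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  assert_that(min(ev) >= -tol * max(abs(ev), 1e-300),
              "kinship not positive semi-definite")
  invisible(TRUE)
}
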