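#' Parental genotype panel
#'
#' A `parent_panel` holds the homozygous allele calls of the inbred parents of
#' one role of a two-pool hybrid program: the females (maintainer / B-lines)
#' or the males (restorer / R-lines). Parents are fully inbred, so each locus
#' carries a single transmitted allele coded 0 (reference) or 1 (alternate).
#'
#' @param alleles integer/numeric matrix, parents x loci, entries in \{0, 1\}.
#'   Row names are parent ids (generated when absent).
#' @param loci data frame with columns `chrom`, `pos` (1-based) and `id`,
#'   one row per column of `alleles`.
#' @param role `"female"` or `"male"`.
#'
#' @return An object of class `parent_panel`: list with elements `alleles`
#'   (matrix), `loci` (tibble, sorted by chromosome then position) and `role`.
#' @export
#' @examples
#' al <- rbind(f1 = c(0, 1, 0), f2 = c(1, 1, 0))
#' loci <- data.frame(chrom = "1", pos = c(10, 20, 30), id = paste0("s", 1:3))
#' parent_panel(al, loci, role = "female")
parent_panel <- function(alleles, loci, role = c("female", "male")) {
  role <- match.arg(role)
  alleles <- as.matrix(alleles)
  loci <- tibble::as_tibble(loci)
  assert_that(all(c("chrom", "pos", "id") %in% names(loci)),
              "loci must have columns chrom, pos, id")
  assert_that(ncol(alleles) == nrow(loci),
              "alleles has a column per locus row")
  if (anyNA(alleles))
    stop("missing genotype calls; impute upstream before loading", call. = FALSE)
  assert_that(all(alleles %in% c(0, 1)),
              "alleles must be homozygous-inbred coded 0/1")
  if (is.null(rownames(alleles)))
    rownames(alleles) <- paste0(substr(role, 1, 1), seq_len(nrow(alleles)))
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  alleles <- alleles[, ord, drop = FALSE]
  colnames(alleles) <- loci$id
  structure(
    list(alleles = alleles, loci = loci, role = role),
    class = "parent_panel"
  )
}

#' @export
print.parent_panel <- function(x, ...) {
  cat(sprintf("<parent_panel> %s: %d parents x %d loci on %d chromosome(s)\n",
              x$role, nrow(x$alleles), ncol(x$alleles),
              dplyr::n_distinct(x$loci$chrom)))
  invisible(x)
}

#' @export
dim.parent_panel <- function(x) dim(x$alleles)

#' Parent ids of a panel
#' @param panel a [parent_panel()].
#' @return character vector of parent ids.
#' @export
parent_ids <- function(panel) rownames(panel$alleles)

#' Tidy a parent panel into long format
#'
#' @param x a [parent_panel()].
#' @param ... unused.
#' @return tibble with columns `parent_id`, `chrom`, `pos`, `locus_id`,
#'   `allele`.
#' @method tidy parent_panel
#' @export
tidy.parent_panel <- function(x, ...) {
  tibble::tibble(
    parent_id = rep(rownames(x$alleles), times = ncol(x$alleles)),
    chrom     = rep(x$loci$chrom, each = nrow(x$alleles)),
    pos       = rep(x$loci$pos, each = nrow(x$alleles)),
    locus_id  = rep(x$loci$id, each = nrow(x$alleles)),
    allele    = as.vector(x$alleles)
  )
}

#' Subset the loci of a panel
#'
#' @param panel a [parent_panel()].
#' @param mask logical vector over loci, or integer indices.
#' @return a [parent_panel()] restricted to the selected loci.
#' @export
subset_loci <- function(panel, mask) {
  parent_panel(panel$alleles[, mask, drop = FALSE],
               panel$loci[mask, , drop = FALSE], role = panel$role)
}

#' Read an inbred parent panel from a VCF file
#'
#' Accepts homozygous diploid calls (`0/0`, `1/1`, phased or not) and haploid
#' calls (`0`, `1`). Heterozygous or missing calls are an error: panels are
#' expected to be fully inbred and imputed upstream.
#'
#' @param path VCF file (plain or bgzipped).
#' @param role `"female"` or `"male"`.
#' @return a [parent_panel()].
#' @export
read_parents_vcf <- function(path, role = c("female", "male")) {
  role <- match.arg(role)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  code <- function(g) {
    g <- sub("\\|", "/", g)
    out <- rep(NA_real_, length(g))
    out[g %in% c("0/0", "0")] <- 0
    out[g %in% c("1/1", "1")] <- 1
    out
  }
  al <- apply(gt, 2, code)
  if (anyNA(al)) {
    bad <- which(is.na(al), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-homozygous or missing call at locus %s for sample %s",
      rownames(gt)[bad[1]], colnames(gt)[bad[2]]), call. = FALSE)
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  loci <- tibble::tibble(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         id = ids)
  parent_panel(t(al), loci, role = role)
}

#' Write a parent panel as a minimal VCF
#'
#' Emits haploid GT calls (parents are inbred) with placeholder REF/ALT
#' alleles, readable back by [read_parents_vcf()].
#'
#' @param panel a [parent_panel()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_parents_vcf <- function(panel, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=hybridgs",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", parent_ids(panel)), collapse = "\t")
  )
  gt <- t(panel$alleles)  # loci x parents, entries 0/1 are valid haploid GT
  body <- paste(panel$loci$chrom, panel$loci$pos, panel$loci$id,
                "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
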