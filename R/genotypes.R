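#' Flag loci polymorphic in at least one parental panel
#'
#' Markers carrying no variation in either heterotic pool are uninformative
#' for hybrid prediction and are discarded. Two readings of "not polymorphic
#' in either panel" are supported: the default keeps a locus polymorphic in
#' at least one panel; `rule = "both"` keeps only loci polymorphic in both.
#'
#' @param females,males [parent_panel()]s sharing the same locus list.
#' @param rule `"any"` (default: drop only loci monomorphic in both panels)
#'   or `"both"` (drop loci monomorphic in at least one panel).
#' @return logical mask over loci (TRUE = keep).
#' @export
filter_polymorphic <- function(females, males, rule = c("any", "both")) {
  rule <- match.arg(rule)
  check_shared_loci(females, males)
  poly <- function(p) {
    cs <- colSums(p$alleles)
    cs > 0 & cs < nrow(p$alleles)
  }
  pf <- poly(females); pm <- poly(males)
  if (rule == "any") pf | pm else pf & pm
}

check_shared_loci <- function(females, males) {
  key_f <- paste(females$loci$chrom, females$loci$pos)
  key_m <- paste(males$loci$chrom, males$loci$pos)
  if (length(key_f) != length(key_m) || any(key_f != key_m)) {
    bad <- if (length(key_f) != length(key_m)) 1L else which(key_f != key_m)[1]
    stop(sprintf("panels disagree on locus %d (%s vs %s)", bad,
                 key_f[min(bad, length(key_f))] %||% "<none>",
                 key_m[min(bad, length(key_m))] %||% "<none>"),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Collapse redundant SNPs to one referent per complete-LD group
#'
#' Over the combined female + male panel, two loci are redundant when their
#' allele columns are identical or exact complements (both give |r| = 1, i.e.
#' complete linkage disequilibrium). Each redundancy group keeps a single
#' referent: the locus with the smallest (chromosome, position), ties broken
#' by lexicographic id.
#'
#' @param females,males [parent_panel()]s sharing the same locus list.
#' @return list with `referent` (logical mask over loci, TRUE = kept) and
#'   `groups` (tibble `locus_id`, `referent_id`).
#' @export
collapse_redundant <- function(females, males) {
  check_shared_loci(females, males)
  comb <- rbind(females$alleles, males$alleles)
  if (ncol(comb) == 0L) stop("empty locus set", call. = FALSE)
  # canonical key: a column and its complement hash identically
  keys <- apply(comb, 2, function(col) {
    a <- paste(col, collapse = "")
    b <- paste(1 - col, collapse = "")
    if (a <= b) a else b
  })
  loci <- females$loci
  ord <- order(loci$chrom, loci$pos, loci$id)
  referent_idx <- ord[!duplicated(keys[ord])]
  referent <- rep(FALSE, ncol(comb))
  referent[referent_idx] <- TRUE
  groups <- tibble::tibble(
    locus_id = loci$id,
    referent_id = loci$id[referent_idx][match(keys, keys[referent_idx])]
  )
  list(referent = referent, groups = groups)
}

#' Infer hybrid genotypes from inbred parents
#'
#' With fully homozygous parents, Mendelian transmission fixes the hybrid:
#' cross f x m carries the female allele and the male allele at every locus,
#' heterozygous exactly where the parents differ.
#'
#' @param design a [factorial_design()].
#' @param females,males [parent_panel()]s sharing the same locus list.
#' @return list with matrices `female_allele` and `male_allele`
#'   (hybrids x loci, rownames = hybrid ids) and the `loci` tibble.
#' @export
infer_hybrid_genotypes <- function(design, females, males) {
  check_shared_loci(females, males)
  check_design_parents(design, females, males)
  fa <- females$alleles[design$female_id, , drop = FALSE]
  ma <- males$alleles[design$male_id, , drop = FALSE]
  rownames(fa) <- rownames(ma) <- design$hybrid_id
  list(female_allele = fa, male_allele = ma, loci = females$loci)
}

#' Pathway gene annotation
#'
#' Genes of a metabolic pathway of interest (e.g. oil metabolism), with a
#' flanking window so regulatory variants near the gene are captured.
#'
#' @param genes data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `id`.
#' @param window bases added on each side of every gene (default 1000).
#' @return object of class `pathway_annotation`.
#' @export
pathway_annotation <- function(genes, window = 1000) {
  genes <- tibble::as_tibble(genes)
  assert_that(all(c("chrom", "start", "end", "id") %in% names(genes)),
              "genes needs chrom, start, end, id columns")
  assert_that(window >= 0, "window must be >= 0")
  structure(list(genes = genes, window = window),
            class = "pathway_annotation")
}

#' Read pathway genes from a BED file
#'
#' BED half-open 0-based coordinates are converted to 1-based inclusive on
#' read.
#'
#' @param path BED file (chrom, start, end, gene id).
#' @param window flanking bases on each side (default 1000).
#' @return a [pathway_annotation()].
#' @export
read_pathway_bed <- function(path, window = 1000) {
  gr <- rtracklayer::import(path, format = "BED")
  pathway_annotation(
    tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),   # rtracklayer converts to 1-based
      end   = GenomicRanges::end(gr),
      id    = gr$name %||% paste0("gene", seq_along(gr))
    ),
    window = window
  )
}

#' Write pathway genes to a BED file
#' @param annotation a [pathway_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pathway_bed <- function(annotation, path) {
  g <- annotation$genes
  readr::write_tsv(
    tibble::tibble(chrom = g$chrom, start = g$start - 1L, end = g$end,
                   name = g$id),
    path, col_names = FALSE)
  invisible(path)
}

#' Select SNPs inside or near pathway genes
#'
#' A locus is kept when its position falls within `[start - window,
#' end + window]` (1-based inclusive) of at least one annotated gene.
#'
#' @param loci tibble with `chrom`, `pos`, `id`.
#' @param annotation a [pathway_annotation()].
#' @return logical mask over loci.
#' @export
select_pathway_snps <- function(loci, annotation) {
  g <- annotation$genes
  w <- annotation$window
  genes_gr <- GenomicRanges::GRanges(
    g$chrom,
    IRanges::IRanges(pmax(1L, g$start - w), g$end + w))
  loci_gr <- GenomicRanges::GRanges(loci$chrom,
                                    IRanges::IRanges(loci$pos, loci$pos))
  # annotation may cover chromosomes absent from the panel (and vice versa)
  mask <- suppressWarnings(IRanges::overlapsAny(loci_gr, genes_gr))
  if (!any(mask))
    message("no SNPs fall inside the pathway windows")
  mask
}
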