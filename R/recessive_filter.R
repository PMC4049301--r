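# The rare-recessive filtering cascade: bait-region restriction, population
# frequency filter, zygosity partition, functional-class filter, gene-level
# recessive candidate model and candidate-list intersection, with a stepwise
# per-sample count report.

# consequence classes that count as "non-synonymous or splice-site
# substitutions and indels" for the functional filter
.FUNCTIONAL_CLASSES <- c("missense", "stop_gained", "stop_lost", "start_lost",
                         "canonical_splice", "frameshift", "inframe_indel")

#' Restrict variants to bait regions plus a window
#'
#' Keeps variants whose position falls within any region expanded by `window`
#' nucleotides on both sides. Variants on contigs absent from the region set
#' are dropped with a message.
#'
#' @param variants `data.frame` with `chrom` and `pos` columns.
#' @param regions A `GRanges` of bait/panel regions (e.g. from
#'   `rtracklayer::import(..., format = "BED")`).
#' @param window Expansion in nucleotides on each side (default 100).
#' @return The subset of `variants` within the expanded regions.
#' @export
restrict_to_regions <- function(variants, regions, window = 100L) {
  if (!nrow(variants)) return(variants)
  off_contig <- !variants$chrom %in%
    unique(as.character(GenomicRanges::seqnames(regions)))
  if (any(off_contig)) {
    message(sum(off_contig), " variant(s) on contigs absent from the region ",
            "set were dropped")
  }
  expanded <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(regions),
    ranges = IRanges::IRanges(
      start = pmax(GenomicRanges::start(regions) - window, 1L),
      end = GenomicRanges::end(regions) + window
    )
  )
  vr <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, end = variants$pos)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(vr, expanded))
  variants[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
}

#' Population frequency filter
#'
#' Keeps variants that are novel (absent from every resource) or whose maximum
#' minor allele frequency across reporting resources is below the threshold --
#' the strictest reading of "novel or estimated frequency < 0.01".
#'
#' @param variants `data.frame` with `chrom, pos, ref, alt`.
#' @param freqs Long frequency table (`chrom, pos, ref, alt, resource, maf`),
#'   e.g. from [read_freq_table()].
#' @param threshold Frequency cutoff in (0, 0.5]; keep if max MAF `< threshold`.
#' @return The surviving subset of `variants`.
#' @export
frequency_filter <- function(variants, freqs, threshold = 0.01) {
  stopifnot(threshold > 0, threshold <= 0.5)
  if (!nrow(variants)) return(variants)
  vkey <- .variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  fkey <- .variant_key(freqs$chrom, freqs$pos, freqs$ref, freqs$alt)
  max_maf <- tapply(freqs$maf, fkey, max)
  m <- max_maf[vkey]
  keep <- is.na(m) | m < threshold
  variants[keep, , drop = FALSE]
}

#' Partition a sample's carried variants by zygosity
#'
#' Homozygous-reference and missing genotypes belong to neither set; the het
#' and hom sets are disjoint and together are exactly the carried variants.
#'
#' @param variants `data.frame` with an `id` column matching `gt` rownames.
#' @param gt Integer genotype matrix (variants x samples; alt allele count,
#'   `NA` missing).
#' @param sample Sample name (column of `gt`).
#' @return List with elements `het` and `hom` (subsets of `variants`).
#' @export
zygosity_partition <- function(variants, gt, sample) {
  g <- gt[match(variants$id, rownames(gt)), sample]
  list(
    het = variants[!is.na(g) & g == 1L, , drop = FALSE],
    hom = variants[!is.na(g) & g == 2L, , drop = FALSE]
  )
}

#' Functional consequence-class filter
#'
#' Keeps variants whose consequence class is non-synonymous (missense,
#' stop gained/lost, start lost), canonical splice, or an indel class;
#' synonymous, UTR, deep intronic and (by default) splice-region variants are
#' dropped. Splice-region changes can be retained with
#' `keep_splice_region = TRUE`.
#'
#' @param annotated `data.frame` with a non-missing `class` column (from
#'   [annotate_variants()]).
#' @param keep_splice_region Also keep `splice_region` calls.
#' @return The surviving subset of `annotated`.
#' @export
functional_class_filter <- function(annotated, keep_splice_region = FALSE) {
  if (is.null(annotated$class) || anyNA(annotated$class)) {
    stop("unannotated variant(s): run annotate_variants() before the ",
         "functional class filter")
  }
  keep_classes <- .FUNCTIONAL_CLASSES
  if (keep_splice_region) keep_classes <- c(keep_classes, "splice_region")
  annotated[annotated$class %in% keep_classes, , drop = FALSE]
}

#' Gene-level recessive candidate model
#'
#' A gene is a candidate for one sample when that sample carries at least one
#' homozygous variant in it, or at least two distinct heterozygous variants
#' (a putative compound heterozygote; phase unknown at this stage). Inputs are
#' assumed already frequency- and class-filtered.
#'
#' @param het,hom Annotated variant tables for one sample (each row one
#'   variant x gene assignment, with `key` and `gene` columns).
#' @return `data.frame` with `gene`, `n_het`, `n_hom` and `support`
#'   (`"hom"`, `"compound_het"` or `"both"`), one row per candidate gene.
#' @export
recessive_gene_candidates <- function(het, hom) {
  n_het <- if (nrow(het)) tapply(het$key, het$gene, function(k) length(unique(k)))
           else integer(0)
  n_hom <- if (nrow(hom)) tapply(hom$key, hom$gene, function(k) length(unique(k)))
           else integer(0)
  genes <- union(names(n_het), names(n_hom))
  if (!length(genes)) {
    return(data.frame(gene = character(0), n_het = integer(0),
                      n_hom = integer(0), support = character(0)))
  }
  nh <- as.integer(n_het[genes])
  nh[is.na(nh)] <- 0L
  nm <- as.integer(n_hom[genes])
  nm[is.na(nm)] <- 0L
  cand <- nm >= 1L | nh >= 2L
  support <- ifelse(nm >= 1L & nh >= 2L, "both",
                    ifelse(nm >= 1L, "hom", "compound_het"))
  out <- data.frame(gene = genes, n_het = as.integer(nh),
                    n_hom = as.integer(nm), support = support,
                    stringsAsFactors = FALSE)[cand, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Intersect candidate genes with the motile-cilia panel list
#'
#' Case-insensitive symbol intersection.
#'
#' @param genes Character vector of candidate gene symbols.
#' @param panel_list Character vector of panel (cilia) gene symbols.
#' @return The subset of `genes` present in `panel_list` (original casing).
#' @export
candidate_list_intersection <- function(genes, panel_list) {
  if (!length(panel_list)) {
    stop("empty candidate gene panel list (configuration error)")
  }
  genes[toupper(genes) %in% toupper(panel_list)]
}
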