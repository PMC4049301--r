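# The stepwise cascade report: ordered per-sample counts mirroring the shape
# of a panel-filtering summary table (total variants; MAF < threshold; the
# heterozygous branch down to compound-het candidate genes on the cilia list;
# the homozygous branch down to homozygous candidate genes on the list).

.CASCADE_STEPS <- c(
  "total", "maf_filtered",
  "het", "het_functional", "genes_compound_het", "genes_compound_het_cilia",
  "hom", "hom_functional", "genes_hom_cilia"
)

#' Construct (and validate) a cascade report
#'
#' Accepts the nine ordered step counts for one sample and checks the report
#' identities: counts are non-increasing along each branch, and the zygosity
#' partition identity `het + hom = maf_filtered` holds.
#'
#' @param sample Sample name.
#' @param counts Named numeric vector with entries `total, maf_filtered, het,
#'   het_functional, genes_compound_het, genes_compound_het_cilia, hom,
#'   hom_functional, genes_hom_cilia`.
#' @param genes Optional list of surviving gene sets per gene-level step.
#' @param variants Optional list of surviving variant keys per step.
#' @return An object of class `cascade_report`.
#' @export
cascade_report <- function(sample, counts, genes = list(), variants = list()) {
  if (!all(.CASCADE_STEPS %in% names(counts))) {
    stop("counts must contain: ", paste(.CASCADE_STEPS, collapse = ", "))
  }
  x <- structure(
    list(sample = sample,
         counts = as.integer(counts[.CASCADE_STEPS]) |>
           stats::setNames(.CASCADE_STEPS),
         genes = genes, variants = variants),
    class = "cascade_report"
  )
  validate_cascade_report(x)
  x
}

#' Validate cascade report identities
#'
#' Checks branch monotonicity (each step's count is at most its parent's) and
#' the partition identity `het + hom = maf_filtered`. Errors on violation.
#'
#' @param x A `cascade_report`.
#' @return `x`, invisibly, if valid.
#' @export
validate_cascade_report <- function(x) {
  ct <- x$counts
  chain <- function(a, b) {
    if (ct[[b]] > ct[[a]]) {
      stop("cascade count for '", b, "' (", ct[[b]], ") exceeds '", a, "' (",
           ct[[a]], ") in sample ", x$sample)
    }
  }
  chain("total", "maf_filtered")
  chain("maf_filtered", "het")
  chain("het", "het_functional")
  chain("het_functional", "genes_compound_het")
  chain("genes_compound_het", "genes_compound_het_cilia")
  chain("maf_filtered", "hom")
  chain("hom", "hom_functional")
  chain("hom_functional", "genes_hom_cilia")
  if (ct[["het"]] + ct[["hom"]] != ct[["maf_filtered"]]) {
    stop("zygosity partition identity violated in sample ", x$sample, ": ",
         ct[["het"]], " het + ", ct[["hom"]], " hom != ",
         ct[["maf_filtered"]], " frequency-filtered variants")
  }
  invisible(x)
}

#' @export
print.cascade_report <- function(x, ...) {
  labels <- c(
    total = "Total variants",
    maf_filtered = "Variants with MAF < threshold",
    het = "Heterozygous",
    het_functional = "Heterozygous non-synonymous/splice/indel",
    genes_compound_het = "Genes with compound heterozygous variants",
    genes_compound_het_cilia = "  ...with motile cilia functions",
    hom = "Homozygous",
    hom_functional = "Homozygous non-synonymous/splice/indel",
    genes_hom_cilia = "  ...with motile cilia functions"
  )
  cat("cascade_report for", x$sample, "\n")
  for (s in .CASCADE_STEPS) {
    cat(sprintf("  %-45s %6d\n", labels[[s]], x$counts[[s]]))
  }
  invisible(x)
}

#' @export
as.data.frame.cascade_report <- function(x, ...) {
  data.frame(step = .CASCADE_STEPS, sample = x$sample,
             count = unname(x$counts[.CASCADE_STEPS]),
             stringsAsFactors = FALSE)
}

#' Run the full rare-recessive cascade for one sample
#'
#' Fixed stage order: bait-region restriction, frequency filter, zygosity
#' split, functional-class filter, gene-level recessive model, candidate-list
#' intersection. A variant passes the class filter if any of its transcript
#' annotations carries a kept class; gene-level steps count a variant in every
#' gene whose transcript it hits.
#'
#' @param sample Sample name (column of `gt`).
#' @param variants Variant table (`chrom, pos, ref, alt, id`).
#' @param annotation Output of [annotate_variants()] for these variants.
#' @param gt Integer genotype matrix (variants x samples).
#' @param freq Long frequency table.
#' @param regions Bait regions (`GRanges`).
#' @param gene_list Motile-cilia candidate gene symbols.
#' @param maf Frequency threshold (default 0.01).
#' @param window Bait-region expansion in nt (default 100).
#' @param keep_splice_region Retain `splice_region` consequences in the
#'   functional filter.
#' @return A [cascade_report()] whose `genes` element carries the surviving
#'   gene sets and supporting genotype tables, and whose `variants` element
#'   carries surviving variant keys per step.
#' @export
run_cascade <- function(sample, variants, annotation, gt, freq, regions,
                        gene_list, maf = 0.01, window = 100L,
                        keep_splice_region = FALSE) {
  stopifnot("id" %in% names(variants))
  variants$key <- .variant_key(variants$chrom, variants$pos, variants$ref,
                               variants$alt)

  in_panel <- restrict_to_regions(variants, regions, window = window)
  g <- gt[match(in_panel$id, rownames(gt)), sample]
  carried <- in_panel[!is.na(g) & g >= 1L, , drop = FALSE]

  rare <- frequency_filter(carried, freq, threshold = maf)
  zp <- zygosity_partition(rare, gt, sample)

  ann_rows <- function(vv) {
    a <- annotation[annotation$key %in% vv$key, , drop = FALSE]
    a
  }
  het_ann <- functional_class_filter(ann_rows(zp$het), keep_splice_region)
  hom_ann <- functional_class_filter(ann_rows(zp$hom), keep_splice_region)

  cand <- recessive_gene_candidates(het_ann, hom_ann)
  genes_ch <- cand$gene[cand$n_het >= 2L]
  genes_hom <- cand$gene[cand$n_hom >= 1L]
  genes_ch_cilia <- candidate_list_intersection(genes_ch, gene_list)
  genes_hom_cilia <- candidate_list_intersection(genes_hom, gene_list)

  counts <- c(
    total = nrow(carried),
    maf_filtered = nrow(rare),
    het = nrow(zp$het),
    het_functional = length(unique(het_ann$key)),
    genes_compound_het = length(genes_ch),
    genes_compound_het_cilia = length(genes_ch_cilia),
    hom = nrow(zp$hom),
    hom_functional = length(unique(hom_ann$key)),
    genes_hom_cilia = length(genes_hom_cilia)
  )
  cascade_report(
    sample, counts,
    genes = list(
      compound_het = genes_ch, compound_het_cilia = genes_ch_cilia,
      hom = genes_hom, hom_cilia = genes_hom_cilia,
      candidates = cand,
      het_ann = het_ann, hom_ann = hom_ann
    ),
    variants = list(
      total = carried$key, maf_filtered = rare$key,
      het = zp$het$key, hom = zp$hom$key,
      het_functional = unique(het_ann$key),
      hom_functional = unique(hom_ann$key)
    )
  )
}

#' Final candidate genes of a cascade report
#'
#' Union of the compound-heterozygous and homozygous candidate genes that
#' survive the cilia-list intersection.
#'
#' @param report A [run_cascade()] result.
#' @return Character vector of gene symbols.
#' @export
candidate_genes <- function(report) {
  sort(union(report$genes$compound_het_cilia, report$genes$hom_cilia))
}

#' Run the cascade for every affected sample of a cohort input set
#'
#' @param inputs List as returned by [read_cohort_inputs()] (or a
#'   [simulate_cohort()] object), plus an `annotation` table; samples with
#'   phenotype 2 in the pedigree (and present in the genotype matrix) are
#'   processed.
#' @param annotation Output of [annotate_variants()].
#' @param ... Passed to [run_cascade()].
#' @return Named list of [cascade_report()]s, one per affected sample.
#' @export
run_cascade_all <- function(inputs, annotation, ...) {
  affected <- inputs$ped$iid[inputs$ped$pheno == 2L]
  affected <- intersect(affected, colnames(inputs$gt))
  reports <- lapply(affected, function(s) {
    run_cascade(s, inputs$variants, annotation, inputs$gt, inputs$freq,
                inputs$regions, inputs$gene_list, ...)
  })
  stats::setNames(reports, affected)
}
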