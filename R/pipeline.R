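# End-to-end run: read inputs, annotate, run the cascade per affected sample,
# test co-segregation of surviving candidate genes in each family, map
# truncating candidate alleles onto the protein domain annotation, and write
# a combined report (TSV + markdown) plus a candidates VCF.

# attach variant ids to an annotation table by matching the variant table
.annotation_with_ids <- function(annotation, variants) {
  key_v <- .variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  annotation$id <- variants$id[match(annotation$key, key_v)]
  annotation
}

#' Run the full prioritization pipeline on a cohort input directory
#'
#' @param input_dir Directory written by [write_inputs()] (or laid out the
#'   same way).
#' @param output_dir Directory for `report.tsv`, `report.md`,
#'   `candidates.vcf` and `segregation.tsv`.
#' @param maf Frequency threshold (default 0.01).
#' @param window Bait-region window in nt (default 100).
#' @param keep_splice_region Retain splice-region consequences in the
#'   functional filter.
#' @param domain_annotation Optional [load_domains()] result applied to
#'   candidate genes matching its `protein_id` (default: the bundled RSPH1
#'   annotation).
#' @return (Invisibly) a list with `reports` (per-sample cascade reports),
#'   `segregation` (verdict table), `domain_hits`, and `candidates`
#'   (surviving variant annotation rows).
#' @export
run_pipeline <- function(input_dir, output_dir, maf = 0.01, window = 100L,
                         keep_splice_region = FALSE,
                         domain_annotation = load_domains()) {
  inputs <- read_cohort_inputs(input_dir)
  annotation <- annotate_variants(inputs$variants, inputs$tx_set,
                                  check_ref = FALSE)
  annotation <- .annotation_with_ids(annotation, inputs$variants)

  reports <- run_cascade_all(inputs, annotation, maf = maf, window = window,
                             keep_splice_region = keep_splice_region)

  # candidate genes per family (from each affected sample's final step)
  fam_of <- stats::setNames(inputs$ped$fid, inputs$ped$iid)
  genes_by_family <- list()
  for (s in names(reports)) {
    fam <- fam_of[[s]]
    genes_by_family[[fam]] <- sort(union(
      genes_by_family[[fam]], candidate_genes(reports[[s]])
    ))
  }
  seg <- segregation_table(inputs$ped, inputs$gt, annotation, genes_by_family)

  # domain mapping of truncating/splice candidate variants in annotated genes
  domain_hits <- .map_candidate_domains(reports, annotation, inputs$tx_set,
                                        domain_annotation)

  cand_keys <- unique(unlist(lapply(reports, function(r) {
    c(r$genes$het_ann$key[r$genes$het_ann$gene %in% candidate_genes(r)],
      r$genes$hom_ann$key[r$genes$hom_ann$gene %in% candidate_genes(r)])
  })))
  candidates <- annotation[annotation$key %in% cand_keys, , drop = FALSE]

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  .write_report_tsv(reports, file.path(output_dir, "report.tsv"))
  utils::write.table(seg, file.path(output_dir, "segregation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .write_report_md(reports, seg, domain_hits,
                   file.path(output_dir, "report.md"))
  .write_candidates_vcf(candidates, inputs, file.path(output_dir,
                                                      "candidates.vcf"))
  invisible(list(reports = reports, segregation = seg,
                 domain_hits = domain_hits, candidates = candidates))
}

.map_candidate_domains <- function(reports, annotation, tx_set,
                                   domain_annotation) {
  if (is.null(domain_annotation)) return(NULL)
  genes <- unique(unlist(lapply(reports, candidate_genes)))
  tx_genes <- vapply(tx_set, `[[`, character(1), "gene")
  rows <- list()
  for (gene in genes) {
    # the annotation describes one protein; apply it only to that gene
    if (!identical(domain_annotation$protein_id, gene)) next
    hit_tx <- which(tx_genes == gene)
    if (!length(hit_tx)) next
    tx <- tx_set[[hit_tx[1]]]
    ann <- annotation[annotation$gene == gene &
                      annotation$class %in%
                        c("stop_gained", "canonical_splice"), , drop = FALSE]
    ann <- ann[!duplicated(ann$key), , drop = FALSE]
    for (i in seq_len(nrow(ann))) {
      if (ann$class[i] == "stop_gained") {
        res <- ann$codon_ordinal[i]
        inferred <- FALSE
      } else {
        # acceptor variant: codon of the first coding base of the next exon
        anchor <- ann$c_pos[i]
        if (is.na(anchor) || anchor < 1L) next
        sv <- splice_variant_residue(tx, anchor)
        res <- sv$residue
        inferred <- TRUE
      }
      if (res > domain_annotation$protein_length) next
      hits <- locate_residue(domain_annotation, res)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, c_hgvs = ann$c_hgvs[i], class = ann$class[i],
        residue = res, inferred = inferred,
        domain = if (nrow(hits)) paste0(hits$label, "#", hits$ordinal,
                                        collapse = ",") else "none",
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

.write_report_tsv <- function(reports, path) {
  df <- do.call(rbind, lapply(reports, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_report_md <- function(reports, seg, domain_hits, path) {
  lines <- c("# Rare-recessive panel filtering report", "")
  labels <- c(
    total = "Total variants",
    maf_filtered = "Variants with MAF < threshold",
    het = "Heterozygous, MAF < threshold",
    het_functional = "Heterozygous non-synonymous, splice-site or indel",
    genes_compound_het = "Genes with compound heterozygous variants",
    genes_compound_het_cilia = "Genes with motile cilia functions (compound het)",
    hom = "Homozygous, MAF < threshold",
    hom_functional = "Homozygous non-synonymous, splice-site or indel",
    genes_hom_cilia = "Genes with motile cilia functions (homozygous)"
  )
  samples <- names(reports)
  lines <- c(lines,
             paste0("| Step | ", paste(samples, collapse = " | "), " |"),
             paste0("|---|", paste(rep("---|", length(samples)), collapse = "")))
  for (s in .CASCADE_STEPS) {
    vals <- vapply(reports, function(r) r$counts[[s]], integer(1))
    lines <- c(lines, paste0("| ", labels[[s]], " | ",
                             paste(vals, collapse = " | "), " |"))
  }
  lines <- c(lines, "", "## Final candidate genes", "")
  for (s in samples) {
    cg <- candidate_genes(reports[[s]])
    lines <- c(lines, paste0("- ", s, ": ",
                             if (length(cg)) paste(cg, collapse = ", ")
                             else "(none)"))
  }
  if (nrow(seg)) {
    lines <- c(lines, "", "## Co-segregation (autosomal recessive)", "",
               "| Family | Gene | Status | Phase verified |", "|---|---|---|---|")
    for (i in seq_len(nrow(seg))) {
      lines <- c(lines, paste0("| ", seg$family[i], " | ", seg$gene[i], " | ",
                               seg$status[i], " | ", seg$phase_verified[i],
                               " |"))
    }
  }
  if (!is.null(domain_hits)) {
    lines <- c(lines, "", "## Domain mapping of truncating candidates", "",
               "| Gene | Variant | Residue | Domain | Inferred |",
               "|---|---|---|---|---|")
    for (i in seq_len(nrow(domain_hits))) {
      lines <- c(lines, paste0(
        "| ", domain_hits$gene[i], " | ", domain_hits$c_hgvs[i], " | ",
        domain_hits$residue[i], " | ", domain_hits$domain[i], " | ",
        domain_hits$inferred[i], " |"
      ))
    }
  }
  writeLines(lines, path)
}

.write_candidates_vcf <- function(candidates, inputs, path) {
  v <- inputs$variants
  key_v <- .variant_key(v$chrom, v$pos, v$ref, v$alt)
  keep <- v[key_v %in% candidates$key, , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=ciliaseek_report",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=CHGVS,Number=1,Type=String,Description=\"HGVS c. name\">",
    "##INFO=<ID=PHGVS,Number=1,Type=String,Description=\"HGVS p. name\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  )
  kk <- .variant_key(keep$chrom, keep$pos, keep$ref, keep$alt)
  ann1 <- candidates[match(kk, candidates$key), , drop = FALSE]
  info <- paste0("GENE=", ann1$gene, ";CSQ=", ann1$class,
                 ";CHGVS=", ann1$c_hgvs,
                 ifelse(is.na(ann1$p_hgvs), "",
                        paste0(";PHGVS=", ann1$p_hgvs)))
  body <- paste(keep$chrom, keep$pos, keep$id, keep$ref, keep$alt, ".",
                "PASS", info, sep = "\t")
  writeLines(c(hdr, body), path)
}
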