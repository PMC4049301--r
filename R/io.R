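# On-disk interchange: VCF v4.2 (multi-sample, GT only), BED (0-based
# half-open, via rtracklayer), 6-column PED, the long frequency table TSV,
# the candidate gene list, and transcript-model JSON. Writing is plain
# deterministic text (no timestamps) so identical cohorts yield identical
# bytes; reading goes through vcfR / rtracklayer.

.gt_to_string <- function(code) {
  out <- rep("./.", length(code))
  out[!is.na(code) & code == 0L] <- "0/0"
  out[!is.na(code) & code == 1L] <- "0/1"
  out[!is.na(code) & code == 2L] <- "1/1"
  out
}

.gt_from_string <- function(gt) {
  g <- sub(":.*$", "", gt)
  g <- gsub("|", "/", g, fixed = TRUE)
  out <- rep(NA_integer_, length(g))
  out[g %in% "0/0"] <- 0L
  out[g %in% c("0/1", "1/0")] <- 1L
  out[g %in% "1/1"] <- 2L
  out
}

#' Write all pipeline inputs for a simulated cohort to a directory
#'
#' Emits `cohort.vcf` (VCF v4.2, GT fields), `panel.bed` (bait regions,
#' 0-based half-open), `cohort.ped` (FID IID PAT MAT SEX PHENO; phenotype
#' 2 = affected), `frequencies.tsv` (chrom, pos, ref, alt, resource, maf),
#' `gene_list.txt` (motile-cilia candidate symbols), `transcripts.json` and
#' `cohort_truth.tsv` (the simulator's planted genotypes, for recovery
#' checks only -- not a pipeline input).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_inputs <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pcd_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- cohort$variants

  # --- VCF ------------------------------------------------------------------
  contigs <- unique(v$chrom)
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=ciliaseek_simulate_seed_", cohort$spec$seed),
    paste0("##contig=<ID=", contigs, ",length=",
           vapply(contigs, function(ct) nchar(cohort$genomes[[ct]]), numeric(1)),
           ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(cohort$gt)), collapse = "\t")
  )
  gt_str <- apply(cohort$gt, 2L, .gt_to_string)
  body <- paste(
    v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
    apply(gt_str, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), file.path(dir, "cohort.vcf"))

  # --- BED ------------------------------------------------------------------
  rtracklayer::export(cohort$regions, file.path(dir, "panel.bed"),
                      format = "BED")

  # --- PED ------------------------------------------------------------------
  utils::write.table(cohort$ped, file.path(dir, "cohort.ped"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  # --- frequency table, gene list, transcripts, truth -----------------------
  utils::write.table(cohort$freq, file.path(dir, "frequencies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(cohort$gene_list, file.path(dir, "gene_list.txt"))
  write_transcript_json(cohort$tx_set, file.path(dir, "transcripts.json"))
  utils::write.table(cohort$truth, file.path(dir, "cohort_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a multi-sample VCF into a variant table and genotype matrix
#'
#' Parsing is delegated to [vcfR::read.vcfR()]; genotypes are recoded as alt
#' allele counts (0/1/2, `NA` for missing or half calls).
#'
#' @param path VCF file.
#' @return List with `variants` (`chrom, pos, ref, alt, id`) and `gt`
#'   (integer matrix, variants x samples).
#' @export
read_vcf_cohort <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  variants <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], id = fix[, "ID"],
    stringsAsFactors = FALSE
  )
  gts <- vcfR::extract.gt(vcf, element = "GT")
  gt <- apply(gts, 2L, .gt_from_string)
  dimnames(gt) <- list(variants$id, colnames(gts))
  list(variants = variants, gt = gt)
}

#' Read a PLINK-style 6-column pedigree file
#'
#' Columns: family id, individual id, father, mother, sex (1 = male,
#' 2 = female), phenotype (2 = affected, 1 = unaffected). `0` marks a missing
#' parent (founder).
#'
#' @param path PED file (whitespace-separated, no header).
#' @return `data.frame` with columns `fid, iid, pat, mat, sex, pheno`.
#' @export
read_ped <- function(path) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c(rep("character", 4L),
                                          rep("integer", 2L)))
  names(ped) <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  ped
}

#' Read the long population allele-frequency table
#'
#' Malformed rows (unparseable or out-of-range frequencies) are skipped with a
#' warning and so behave as absent from that resource. Frequencies above 0.5
#' are folded onto the minor allele.
#'
#' @param path TSV with header `chrom pos ref alt resource maf`.
#' @return `data.frame` with a folded `maf` column.
#' @export
read_freq_table <- function(path) {
  f <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  f$maf <- suppressWarnings(as.numeric(f$maf))
  bad <- is.na(f$maf) | f$maf < 0 | f$maf > 1
  if (any(bad)) {
    warning(sum(bad), " malformed frequency row(s) skipped (treated as absent)")
    f <- f[!bad, , drop = FALSE]
  }
  f$maf <- pmin(f$maf, 1 - f$maf)
  f
}

#' Read every pipeline input from a directory written by [write_inputs()]
#'
#' @param dir Directory containing `cohort.vcf`, `panel.bed`, `cohort.ped`,
#'   `frequencies.tsv`, `gene_list.txt`, `transcripts.json`.
#' @return List with `variants`, `gt`, `ped`, `freq`, `gene_list`, `regions`
#'   (a `GRanges`), and `tx_set`.
#' @export
read_cohort_inputs <- function(dir) {
  need <- c("cohort.vcf", "panel.bed", "cohort.ped", "frequencies.tsv",
            "gene_list.txt", "transcripts.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("missing input file(s) in ", dir, ": ", paste(missing, collapse = ", "))
  }
  vcf <- read_vcf_cohort(file.path(dir, "cohort.vcf"))
  list(
    variants = vcf$variants,
    gt = vcf$gt,
    ped = read_ped(file.path(dir, "cohort.ped")),
    freq = read_freq_table(file.path(dir, "frequencies.tsv")),
    gene_list = readLines(file.path(dir, "gene_list.txt")),
    regions = rtracklayer::import(file.path(dir, "panel.bed"), format = "BED"),
    tx_set = read_transcript_json(file.path(dir, "transcripts.json"))
  )
}
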