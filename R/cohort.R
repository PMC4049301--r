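#' Specification for a synthetic gene-panel cohort
#'
#' Defaults emulate the study design the pipeline targets: 70 unrelated
#' probands sequenced on a targeted ciliopathy panel (each with two genotyped
#' unaffected parents), an unrelated control set, a shared pool of background
#' variants with a rare-skewed allele-frequency spectrum, and one causal gene
#' in which every case carries a planted biallelic loss-of-function genotype.
#'
#' @param n_cases Number of affected, unrelated probands.
#' @param n_controls Number of unrelated unaffected controls.
#' @param n_genes Number of background panel genes (the causal gene is extra).
#' @param n_background_variants Size of the shared background variant pool.
#' @param maf_shape1,maf_shape2 Shape parameters of the background allele
#'   frequency spectrum: a beta distribution scaled onto (0, 0.5], rare-skewed
#'   by default so the MAF < 0.01 filter is exercised in both directions.
#' @param causal_gene Symbol of the causal gene (must be in the transcript set).
#' @param causal_mode `"compound_het"` (two heterozygous loss-of-function
#'   alleles per case, one inherited from each parent) or `"homozygous"`.
#' @param missing_rate Fraction of background genotype calls masked to `./.`.
#' @param cilia_gene_fraction Fraction of background genes included on the
#'   motile-cilia candidate list alongside the causal gene.
#' @param seed Integer seed; fully determines every generated byte.
#'
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 70L, n_controls = 100L, n_genes = 60L,
                        n_background_variants = 3000L,
                        maf_shape1 = 0.2, maf_shape2 = 1.8,
                        causal_gene = "RSPH1",
                        causal_mode = c("compound_het", "homozygous"),
                        missing_rate = 0, cilia_gene_fraction = 0.2,
                        seed = 1L) {
  causal_mode <- match.arg(causal_mode)
  stopifnot(
    n_cases >= 1L, n_controls >= 0L, n_genes >= 1L,
    missing_rate >= 0, missing_rate <= 1,
    cilia_gene_fraction >= 0, cilia_gene_fraction <= 1,
    maf_shape1 > 0, maf_shape2 > 0
  )
  structure(
    list(
      n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
      n_genes = as.integer(n_genes),
      n_background_variants = as.integer(n_background_variants),
      maf_shape1 = maf_shape1, maf_shape2 = maf_shape2,
      causal_gene = causal_gene, causal_mode = causal_mode,
      missing_rate = missing_rate,
      cilia_gene_fraction = cilia_gene_fraction,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# spliced-transcript position -> genomic position
.t2g <- function(tx, tx_pos) {
  ex <- .tx_exons(tx)
  k <- findInterval(tx_pos, ex$tx_start)
  if (tx$strand == "+") ex$start[k] + (tx_pos - ex$tx_start[k])
  else ex$end[k] - (tx_pos - ex$tx_start[k])
}

# default transcript set: the causal fixture plus background genes on their
# own contigs, strands alternating
.default_tx_set <- function(spec) {
  fx <- make_rsph1_fixture(fixture_spec(gene = spec$causal_gene,
                                        seed = spec$seed))
  tx_set <- list(fx$tx)
  genomes <- as.list(fx$genome)
  for (i in seq_len(spec$n_genes)) {
    gene <- sprintf("PNL%03d", i)
    b <- make_background_transcript(
      gene, seed = (spec$seed + 7919L * i) %% 2147483647L,
      strand = if (i %% 2L == 0L) "-" else "+"
    )
    tx_set[[i + 1L]] <- b$tx
    genomes[[b$tx$contig]] <- unname(b$genome)
  }
  names(tx_set) <- vapply(tx_set, `[[`, character(1), "gene")
  list(tx_set = tx_set, genomes = genomes)
}

# the planted loss-of-function alleles, in genomic coordinates, for a mode
.planted_variants <- function(tx, genome, mode) {
  mk <- function(c_pos, offset, alt_t, c_hgvs, maf) {
    g <- coding_to_genomic(tx, c_pos, offset)
    ref <- substring(genome, g, g)
    alt <- if (tx$strand == "-") .complement(alt_t) else alt_t
    data.frame(chrom = tx$contig, pos = g, ref = ref, alt = alt,
               gene = tx$gene, c_hgvs = c_hgvs, true_maf = maf,
               stringsAsFactors = FALSE)
  }
  if (mode == "compound_het") {
    rbind(
      mk(281L, 0L, "A", "c.281G>A", 0),          # nonsense, novel
      mk(275L, -2L, "C", "c.275-2A>C", 9 / 13000) # splice acceptor
    )
  } else {
    mk(85L, 0L, "T", "c.85G>T", 5 / 13000)        # early nonsense
  }
}

#' Simulate a gene-panel cohort with planted causal genotypes
#'
#' Draws a shared pool of background variants across the background genes
#' (positions exonic plus a small near-splice intronic fraction; allele
#' frequencies from the spec's beta spectrum), genotypes every sample under
#' Hardy-Weinberg with Mendelian gene-dropping inside trios, and plants the
#' causal biallelic configuration in every case: compound-het cases carry the
#' nonsense + splice-acceptor pair (one allele from each parent), homozygous
#' cases carry the early nonsense allele from both carrier parents. Controls
#' carry no planted allele. Background variants are never placed in the causal
#' gene, so a case's causal-gene genotype is exactly its plant.
#'
#' @param spec A [cohort_spec()].
#' @param tx_set Optional named list of [transcript_model()]s (must contain
#'   the causal gene); when omitted a default panel is generated from the spec
#'   seed. When supplied, `genomes` must be supplied too.
#' @param genomes Named list of contig sequences matching `tx_set`.
#' @return An object of class `pcd_cohort`: transcript models, contig
#'   sequences, the variant table (`chrom, pos, ref, alt, id, gene, true_maf,
#'   planted`), an integer genotype matrix (variants x samples; 0/1/2 alt
#'   allele count, `NA` missing), sample and pedigree tables, the population
#'   frequency table, the candidate (cilia) gene list, bait regions as a
#'   `GRanges`, and the `truth` table of planted genotypes.
#' @export
simulate_cohort <- function(spec, tx_set = NULL, genomes = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(tx_set)) {
    d <- .default_tx_set(spec)
    tx_set <- d$tx_set
    genomes <- d$genomes
  }
  if (!spec$causal_gene %in% names(tx_set)) {
    stop("causal gene ", spec$causal_gene, " absent from transcript set")
  }
  causal_tx <- tx_set[[spec$causal_gene]]
  bg_genes <- setdiff(names(tx_set), spec$causal_gene)
  if (spec$n_background_variants < length(bg_genes)) {
    warning("n_background_variants (", spec$n_background_variants,
            ") too small to populate all ", length(bg_genes), " genes")
  }

  set.seed(spec$seed)

  # ---- samples and pedigrees ----------------------------------------------
  cases <- sprintf("CASE%02d", seq_len(spec$n_cases))
  fathers <- sprintf("FA%02d", seq_len(spec$n_cases))
  mothers <- sprintf("MO%02d", seq_len(spec$n_cases))
  controls <- if (spec$n_controls > 0L)
    sprintf("CTRL%03d", seq_len(spec$n_controls)) else character(0)
  samples <- data.frame(
    sample = c(cases, fathers, mothers, controls),
    family = c(rep(sprintf("FAM%02d", seq_len(spec$n_cases)), 3L),
               sprintf("CF%03d", seq_len(spec$n_controls))),
    role = c(rep("case", spec$n_cases), rep("father", spec$n_cases),
             rep("mother", spec$n_cases), rep("control", spec$n_controls)),
    affected = c(rep(TRUE, spec$n_cases),
                 rep(FALSE, 2L * spec$n_cases + spec$n_controls)),
    stringsAsFactors = FALSE
  )
  ped <- .build_pedigrees(spec, samples)

  # ---- background variant pool --------------------------------------------
  n_bg <- spec$n_background_variants
  alloc <- rep(n_bg %/% length(bg_genes), length(bg_genes))
  extra <- n_bg - sum(alloc)
  if (extra > 0L) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1L
  bg <- list()
  for (gi in seq_along(bg_genes)) {
    tx <- tx_set[[bg_genes[gi]]]
    k <- alloc[gi]
    if (k == 0L) next
    L <- nchar(tx$seq)
    n_intronic <- rbinom(1L, k, 0.05)
    n_exonic <- k - n_intronic
    tpos <- sample.int(L, min(n_exonic, L))
    gpos <- .t2g(tx, tpos)
    if (n_intronic > 0L && nrow(tx$exons) > 1L) {
      ex <- .tx_exons(tx)
      donors <- ex$tx_end[-nrow(ex)] # transcript-internal boundaries
      b <- donors[sample.int(length(donors), n_intronic, replace = TRUE)]
      off <- sample(1:8, n_intronic, replace = TRUE) *
        sample(c(1L, -1L), n_intronic, replace = TRUE)
      # negative offsets anchor on the next exon's first base
      anchor <- ifelse(off > 0L, b, b + 1L)
      gi_pos <- vapply(seq_len(n_intronic), function(j) {
        ga <- .t2g(tx, anchor[j])
        if (tx$strand == "+") ga + off[j] else ga - off[j]
      }, numeric(1))
      gpos <- c(gpos, gi_pos)
    }
    gpos <- unique(as.integer(gpos))
    gseq <- genomes[[tx$contig]]
    ref <- substring(gseq, gpos, gpos)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                  character(1), USE.NAMES = FALSE)
    bg[[length(bg) + 1L]] <- data.frame(
      chrom = tx$contig, pos = gpos, ref = ref, alt = alt, gene = tx$gene,
      stringsAsFactors = FALSE
    )
  }
  bg <- do.call(rbind, bg)
  bg$true_maf <- pmax(0.5 * rbeta(nrow(bg), spec$maf_shape1, spec$maf_shape2),
                      5e-5)
  bg$planted <- FALSE

  planted <- .planted_variants(causal_tx, genomes[[causal_tx$contig]],
                               spec$causal_mode)
  pl <- data.frame(chrom = planted$chrom, pos = planted$pos, ref = planted$ref,
                   alt = planted$alt, gene = planted$gene,
                   true_maf = planted$true_maf, planted = TRUE,
                   stringsAsFactors = FALSE)
  variants <- rbind(bg, pl)
  variants <- variants[order(variants$chrom, variants$pos, variants$alt), ,
                       drop = FALSE]
  variants$id <- sprintf("var%05d", seq_len(nrow(variants)))
  rownames(variants) <- NULL

  # ---- genotypes -----------------------------------------------------------
  nv <- nrow(variants)
  ns <- nrow(samples)
  q <- ifelse(variants$planted, 0, variants$true_maf)
  gt <- matrix(0L, nrow = nv, ncol = ns,
               dimnames = list(variants$id, samples$sample))
  # founders (parents + controls) under HWE
  founder_cols <- which(samples$role != "case")
  for (j in founder_cols) gt[, j] <- rbinom(nv, 2L, q)
  # cases inherit one allele from each parent
  for (i in seq_len(spec$n_cases)) {
    f <- gt[, fathers[i]]
    m <- gt[, mothers[i]]
    gt[, cases[i]] <- rbinom(nv, 1L, f / 2) + rbinom(nv, 1L, m / 2)
  }
  # plant the causal genotypes
  pidx <- which(variants$planted)
  truth <- list()
  for (i in seq_len(spec$n_cases)) {
    if (spec$causal_mode == "compound_het") {
      gt[pidx[1], cases[i]] <- 1L
      gt[pidx[2], cases[i]] <- 1L
      gt[pidx[1], fathers[i]] <- 1L
      gt[pidx[2], mothers[i]] <- 1L
      zyg <- c("het", "het")
    } else {
      gt[pidx, cases[i]] <- 2L
      gt[pidx, fathers[i]] <- 1L
      gt[pidx, mothers[i]] <- 1L
      zyg <- "hom"
    }
    truth[[i]] <- data.frame(
      sample = cases[i], gene = spec$causal_gene,
      c_hgvs = planted$c_hgvs, zygosity = zyg,
      chrom = planted$chrom, pos = planted$pos,
      ref = planted$ref, alt = planted$alt, true_maf = planted$true_maf,
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth)
  if (spec$missing_rate > 0) {
    mask <- matrix(runif(nv * ns) < spec$missing_rate, nrow = nv)
    mask[pidx, ] <- FALSE # planted genotypes stay observed
    gt[mask] <- NA_integer_
  }

  # ---- population frequency table -----------------------------------------
  freq <- .build_freq_table(variants, spec)

  # ---- panel regions and gene list ----------------------------------------
  regions <- .bait_regions(tx_set, pad = 25L)
  cilia_bg <- bg_genes[seq_along(bg_genes) %% 5L == 0L]
  n_cilia <- round(spec$cilia_gene_fraction * length(bg_genes))
  gene_list <- c(spec$causal_gene, utils::head(cilia_bg, n_cilia))

  structure(
    list(spec = spec, tx_set = tx_set, genomes = genomes,
         variants = variants, gt = gt, samples = samples, ped = ped,
         freq = freq, gene_list = gene_list, regions = regions, truth = truth),
    class = "pcd_cohort"
  )
}

#' @export
print.pcd_cohort <- function(x, ...) {
  cat(sprintf(
    "pcd_cohort: %d cases (+2 parents each), %d controls; %d variants in %d genes\n",
    x$spec$n_cases, x$spec$n_controls, nrow(x$variants), length(x$tx_set)
  ))
  cat(sprintf("  causal gene %s, mode %s; seed %d\n",
              x$spec$causal_gene, x$spec$causal_mode, x$spec$seed))
  invisible(x)
}

# trio pedigrees, with the first family extended into a consanguineous
# loop (first-cousin parents, one affected and one unaffected sib) when the
# causal mode is homozygous -- ancestors beyond the trio are not genotyped
.build_pedigrees <- function(spec, samples) {
  rows <- list()
  for (i in seq_len(spec$n_cases)) {
    fam <- sprintf("FAM%02d", i)
    ca <- sprintf("CASE%02d", i)
    fa <- sprintf("FA%02d", i)
    mo <- sprintf("MO%02d", i)
    if (i == 1L && spec$causal_mode == "homozygous") {
      # consanguineous topology: the parents are first cousins
      rows[[length(rows) + 1L]] <- data.frame(
        fid = fam,
        iid = c("GGF", "GGM", "A1", "A2", "S1", "S2", fa, mo, ca, "SIB1a", "SIB1u"),
        pat = c("0", "0", "GGF", "GGF", "0", "0", "A1", "A2", fa, fa, fa),
        mat = c("0", "0", "GGM", "GGM", "0", "0", "S1", "S2", mo, mo, mo),
        sex = c(1L, 2L, 1L, 2L, 2L, 1L, 1L, 2L, 2L, 2L, 1L),
        pheno = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 1L),
        stringsAsFactors = FALSE
      )
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        fid = fam, iid = c(fa, mo, ca),
        pat = c("0", "0", fa), mat = c("0", "0", mo),
        sex = c(1L, 2L, 2L), pheno = c(1L, 1L, 2L),
        stringsAsFactors = FALSE
      )
    }
  }
  ctrl <- samples[samples$role == "control", , drop = FALSE]
  if (nrow(ctrl)) {
    rows[[length(rows) + 1L]] <- data.frame(
      fid = ctrl$family, iid = ctrl$sample, pat = "0", mat = "0",
      sex = rep_len(c(1L, 2L), nrow(ctrl)), pheno = 1L,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# long frequency table (chrom, pos, ref, alt, resource, maf): background
# variants are reported by KG1000 (always, at the true frequency) and EVS
# (60% of variants, with sampling jitter); 5% of the pool is novel. Planted
# alleles carry the heterozygous-carrier-derived EVS frequencies, and the
# exon-4 nonsense allele is novel (absent from every resource).
.build_freq_table <- function(variants, spec) {
  bgv <- variants[!variants$planted, , drop = FALSE]
  u <- runif(nrow(bgv))
  u2 <- runif(nrow(bgv))
  jit <- runif(nrow(bgv), 0.8, 1.2)
  rows <- list()
  known <- u >= 0.05
  if (any(known)) {
    rows[[1]] <- data.frame(
      chrom = bgv$chrom[known], pos = bgv$pos[known], ref = bgv$ref[known],
      alt = bgv$alt[known], resource = "KG1000",
      maf = round(bgv$true_maf[known], 6), stringsAsFactors = FALSE
    )
    evs <- known & u2 < 0.6
    rows[[2]] <- data.frame(
      chrom = bgv$chrom[evs], pos = bgv$pos[evs], ref = bgv$ref[evs],
      alt = bgv$alt[evs], resource = "EVS",
      maf = round(pmin(bgv$true_maf[evs] * jit[evs], 0.5), 6),
      stringsAsFactors = FALSE
    )
  }
  plv <- variants[variants$planted & variants$true_maf > 0, , drop = FALSE]
  if (nrow(plv)) {
    rows[[3]] <- data.frame(
      chrom = plv$chrom, pos = plv$pos, ref = plv$ref, alt = plv$alt,
      resource = "EVS", maf = round(plv$true_maf, 6), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- out[order(out$chrom, out$pos, out$alt, out$resource), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# bait regions: exon intervals padded into the introns, merged per contig
.bait_regions <- function(tx_set, pad = 25L) {
  grl <- lapply(tx_set, function(tx) {
    GenomicRanges::GRanges(
      seqnames = tx$contig,
      ranges = IRanges::IRanges(
        start = pmax(tx$exons$start - pad, 1L),
        end = tx$exons$end + pad
      )
    )
  })
  # contigs are disjoint (one per transcript); combining across sequence
  # levels is intended
  GenomicRanges::reduce(suppressWarnings(do.call(c, unname(grl))))
}
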