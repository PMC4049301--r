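test_that("the three hallmark panel variants get their canonical names", {
  g281 <- coding_to_genomic(FX$tx, 281L)
  r <- classify_consequence(FX$tx, g281, "G", "A", genome = FX$genome)
  expect_equal(r$class, "stop_gained")
  expect_equal(r$p_hgvs, "p.Trp94*")
  expect_equal(r$c_hgvs, "c.281G>A")
  expect_equal(r$codon_ordinal, 94L)
  expect_equal(r$alt_aa, "*")

  g85 <- coding_to_genomic(FX$tx, 85L)
  r <- classify_consequence(FX$tx, g85, "G", "T", genome = FX$genome)
  expect_equal(r$class, "stop_gained")
  expect_equal(r$p_hgvs, "p.Glu29*")
  expect_equal(r$codon_ordinal, 29L)

  g_acc <- coding_to_genomic(FX$tx, 275L, -2L)
  r <- classify_consequence(FX$tx, g_acc, "A", "C", genome = FX$genome)
  expect_equal(r$class, "canonical_splice")
  expect_equal(r$c_hgvs, "c.275-2A>C")
  expect_true(is.na(r$p_hgvs))
  expect_true(abs(r$intron_offset) %in% c(1L, 2L))
})

test_that("a third-position change preserving the amino acid is synonymous", {
  # codon 29 is GAG (Glu); GAG -> GAA is still Glu
  g87 <- coding_to_genomic(FX$tx, 87L)
  r <- classify_consequence(FX$tx, g87, "G", "A", genome = FX$genome)
  expect_equal(r$class, "synonymous")
  expect_equal(r$p_hgvs, "p.Glu29=")
})

test_that("reference mismatches are rejected with the position named", {
  g281 <- coding_to_genomic(FX$tx, 281L)
  expect_error(classify_consequence(FX$tx, g281, "C", "A"),
               paste0("reference mismatch.*", g281))
})

test_that("classification agrees with the full-CDS-rebuild oracle for all CDS SNVs", {
  bases <- c("A", "C", "G", "T")
  for (tx in list(FX$tx, FXM$tx)) {
    cds <- transcript_cds(tx)
    step <- if (tx$strand == "+") 1L else 3L # minus strand thinned for speed
    positions <- seq(1L, nchar(cds), by = step)
    gpos <- vapply(positions, function(cp) coding_to_genomic(tx, cp), integer(1))
    for (alt_t in bases) {
      ref_t <- substring(cds, positions, positions)
      use <- ref_t != alt_t
      if (!any(use)) next
      ref_g <- if (tx$strand == "-") ciliaseek:::.complement(ref_t[use]) else ref_t[use]
      alt_g <- if (tx$strand == "-") ciliaseek:::.complement(alt_t) else alt_t
      got <- ciliaseek:::.classify_snv_tx(tx, gpos[use], ref_g,
                                          rep(alt_g, sum(use)))
      want <- vapply(positions[use], function(cp) oracle_snv_class(tx, cp, alt_t),
                     character(1))
      expect_identical(got$class, want)
      # every stop_gained alt codon must translate to a stop
      sg <- got$class == "stop_gained"
      if (any(sg)) expect_true(all(got$alt_aa[sg] == "*"))
    }
  }
})

test_that("indel classes follow the reading-frame rule", {
  # single-base deletion in the CDS -> frameshift
  g <- coding_to_genomic(FX$tx, 100L)
  gseq <- FX$genome[[1]]
  ref2 <- substring(gseq, g - 1L, g)
  r <- classify_consequence(FX$tx, g - 1L, ref2, substring(ref2, 1, 1))
  expect_equal(r$class, "frameshift")
  expect_match(r$p_hgvs, "^p\\..*fs$")
  # three-base deletion -> in-frame
  ref4 <- substring(gseq, g - 1L, g + 2L)
  r <- classify_consequence(FX$tx, g - 1L, ref4, substring(ref4, 1, 1))
  expect_equal(r$class, "inframe_indel")
  # insertion of 3 bases -> in-frame; of 2 -> frameshift
  anchor <- substring(gseq, g, g)
  r <- classify_consequence(FX$tx, g, anchor, paste0(anchor, "ACT"))
  expect_equal(r$class, "inframe_indel")
  r <- classify_consequence(FX$tx, g, anchor, paste0(anchor, "AC"))
  expect_equal(r$class, "frameshift")
})

test_that("deep intronic and near-splice indels are classed by distance", {
  ex <- ciliaseek:::.tx_exons(FX$tx)
  gseq <- FX$genome[[1]]
  deep <- ex$end[1] + 50L
  refd <- substring(gseq, deep, deep + 1L)
  r <- classify_consequence(FX$tx, deep, refd, substring(refd, 1, 1))
  expect_equal(r$class, "intronic")
  near <- ex$end[1] + 4L
  refn <- substring(gseq, near, near + 1L)
  r <- classify_consequence(FX$tx, near, refn, substring(refn, 1, 1))
  expect_equal(r$class, "splice_region")
})

test_that("annotate_variants assigns variants to every overlapping transcript", {
  co <- small_cohort(31)
  ann <- annotate_cohort(co)
  expect_true(all(ann$key %in%
    ciliaseek:::.variant_key(co$variants$chrom, co$variants$pos,
                             co$variants$ref, co$variants$alt)))
  # planted variants are annotated in the causal gene with LoF classes
  planted_keys <- with(co$variants[co$variants$planted, ],
                       ciliaseek:::.variant_key(chrom, pos, ref, alt))
  pl <- ann[ann$key %in% planted_keys, ]
  expect_setequal(pl$gene, "RSPH1")
  expect_setequal(pl$class, c("stop_gained", "canonical_splice"))
})
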