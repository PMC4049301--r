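make_regions <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

test_that("region restriction honours the window boundary exactly", {
  reg_df <- data.frame(chrom = "c1", start = 1000L, end = 2000L)
  reg <- make_regions(reg_df)
  v <- data.frame(chrom = "c1", pos = c(2100L, 2101L, 1500L, 899L, 900L),
                  id = paste0("v", 1:5))
  kept <- restrict_to_regions(v, reg, window = 100L)
  expect_setequal(kept$id, c("v1", "v3", "v5"))
  kept0 <- restrict_to_regions(v, reg, window = 0L)
  expect_setequal(kept0$id, "v3")
  # absent contig: dropped with a notice
  v2 <- data.frame(chrom = c("c1", "cX"), pos = c(1500L, 1500L),
                   id = c("a", "b"))
  expect_message(kept2 <- restrict_to_regions(v2, reg, window = 0L),
                 "absent from the region set")
  expect_identical(kept2$id, "a")
})

test_that("region restriction agrees with a naive membership oracle", {
  set.seed(51)
  for (rep in 1:5) {
    reg_df <- data.frame(
      chrom = sample(c("c1", "c2"), 8, TRUE),
      start = s <- sample(1:5000, 8), end = s + sample(10:400, 8)
    )
    v <- data.frame(chrom = sample(c("c1", "c2"), 60, TRUE),
                    pos = sample(1:6000, 60), id = sprintf("v%02d", 1:60))
    w <- sample(c(0L, 50L, 100L), 1)
    kept <- restrict_to_regions(v, make_regions(reg_df), window = w)
    want <- vapply(seq_len(nrow(v)), function(i) {
      oracle_in_regions(v$chrom[i], v$pos[i], reg_df, w)
    }, logical(1))
    expect_setequal(kept$id, v$id[want])
  }
})

test_that("the frequency rule keeps novel and rare, drops common", {
  v <- data.frame(chrom = "c1", pos = 1:4, ref = "A", alt = "T",
                  id = c("rare", "common", "novel", "evs_carrier"))
  freq <- data.frame(
    chrom = "c1", pos = c(1L, 2L, 2L, 4L), ref = "A", alt = "T",
    resource = c("EVS", "EVS", "KG1000", "EVS"),
    maf = c(0.005, 0.005, 0.02, 5 / 13000)
  )
  kept <- frequency_filter(v, freq, threshold = 0.01)
  expect_setequal(kept$id, c("rare", "novel", "evs_carrier"))
  expect_error(frequency_filter(v, freq, threshold = 0), "threshold")
})

test_that("the frequency rule matches a row-by-row oracle on random tables", {
  set.seed(52)
  for (rep in 1:5) {
    v <- data.frame(chrom = "c1", pos = sample(1:40, 30, TRUE),
                    ref = sample(c("A", "C"), 30, TRUE), alt = "T")
    v$id <- sprintf("v%02d", seq_len(nrow(v)))
    freq <- data.frame(chrom = "c1", pos = sample(1:40, 50, TRUE),
                       ref = sample(c("A", "C"), 50, TRUE), alt = "T",
                       resource = sample(c("EVS", "KG1000", "DBSNP"), 50, TRUE),
                       maf = round(runif(50, 0, 0.3), 4))
    kept <- frequency_filter(v, freq, threshold = 0.01)
    vkeys <- ciliaseek:::.variant_key(v$chrom, v$pos, v$ref, v$alt)
    fkeys <- ciliaseek:::.variant_key(freq$chrom, freq$pos, freq$ref, freq$alt)
    want <- vapply(vkeys, oracle_freq_keep, logical(1),
                   fkeys = fkeys, fmaf = freq$maf, threshold = 0.01)
    expect_setequal(kept$id, v$id[want])
  }
})

test_that("zygosity partition is a disjoint cover of carried variants", {
  v <- data.frame(chrom = "c1", pos = 1:5, ref = "A", alt = "T",
                  id = paste0("v", 1:5))
  gt <- matrix(c(1L, 2L, 0L, NA, 1L), ncol = 1,
               dimnames = list(v$id, "S1"))
  zp <- zygosity_partition(v, gt, "S1")
  expect_setequal(zp$het$id, c("v1", "v5"))
  expect_setequal(zp$hom$id, "v2")
  expect_length(intersect(zp$het$id, zp$hom$id), 0)
  carried <- sum(!is.na(gt[, 1]) & gt[, 1] >= 1L)
  expect_identical(nrow(zp$het) + nrow(zp$hom), carried)
  # half calls parse to missing
  expect_true(is.na(ciliaseek:::.gt_from_string("./1")))
  expect_true(is.na(ciliaseek:::.gt_from_string(".")))
  expect_identical(ciliaseek:::.gt_from_string("0|1"), 1L)
})

test_that("the functional class filter keeps LoF and splice, drops silent", {
  ann <- data.frame(
    key = paste0("k", 1:6),
    class = c("stop_gained", "synonymous", "canonical_splice", "utr",
              "splice_region", "frameshift")
  )
  kept <- functional_class_filter(ann)
  expect_setequal(kept$key, c("k1", "k3", "k6"))
  kept2 <- functional_class_filter(ann, keep_splice_region = TRUE)
  expect_setequal(kept2$key, c("k1", "k3", "k5", "k6"))
  expect_error(functional_class_filter(data.frame(key = "k")), "unannotated")
  expect_error(functional_class_filter(data.frame(key = "k", class = NA)),
               "unannotated")
})

test_that("frequency and class filters commute", {
  co <- small_cohort(53)
  ann <- annotate_cohort(co)
  f_then_c <- functional_class_filter(
    frequency_filter(ann, co$freq, 0.01))
  c_then_f <- frequency_filter(
    functional_class_filter(ann), co$freq, 0.01)
  expect_setequal(
    paste(f_then_c$key, f_then_c$transcript_id),
    paste(c_then_f$key, c_then_f$transcript_id)
  )
})

test_that("the gene-level recessive model requires >= 1 hom or >= 2 het", {
  het <- data.frame(key = c("a", "b", "c"), gene = c("G1", "G1", "G2"))
  hom <- data.frame(key = "d", gene = "G3")
  cand <- recessive_gene_candidates(het, hom)
  expect_setequal(cand$gene, c("G1", "G3"))
  expect_identical(cand$support[cand$gene == "G1"], "compound_het")
  expect_identical(cand$support[cand$gene == "G3"], "hom")
  # a duplicated key (same variant via two transcripts) is one variant
  het2 <- data.frame(key = c("a", "a"), gene = "G1")
  expect_identical(nrow(recessive_gene_candidates(het2, hom[0, ])), 0L)
})

test_that("the gene model matches brute-force enumeration on random matrices", {
  set.seed(54)
  for (rep in 1:10) {
    genes <- sprintf("G%d", 1:6)
    n <- 40
    tab <- data.frame(
      key = sprintf("k%02d", sample(1:30, n, TRUE)),
      gene = sample(genes, n, TRUE),
      zyg = sample(c("het", "hom"), n, TRUE, prob = c(0.8, 0.2))
    )
    tab <- tab[!duplicated(tab[, c("key", "gene")]), ]
    cand <- recessive_gene_candidates(tab[tab$zyg == "het", ],
                                      tab[tab$zyg == "hom", ])
    want <- vapply(genes, function(g) {
      nh <- length(unique(tab$key[tab$gene == g & tab$zyg == "het"]))
      nm <- length(unique(tab$key[tab$gene == g & tab$zyg == "hom"]))
      nm >= 1L || nh >= 2L
    }, logical(1))
    expect_setequal(cand$gene, genes[want])
  }
})

test_that("panel intersection is case-insensitive set intersection", {
  expect_setequal(
    candidate_list_intersection(c("DNAH12", "RSPH1", "ABC1"),
                                c("rsph1", "DNAH5")),
    "RSPH1"
  )
  expect_length(candidate_list_intersection(character(0), "RSPH1"), 0)
  expect_error(candidate_list_intersection("RSPH1", character(0)), "empty")
  set.seed(55)
  for (rep in 1:5) {
    a <- sample(LETTERS, 10)
    b <- sample(LETTERS, 10)
    expect_setequal(candidate_list_intersection(a, b), intersect(a, b))
  }
})
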