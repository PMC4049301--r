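test_that("compound-het cases carry exactly two het LoF records in the causal gene", {
  co <- simulate_cohort(cohort_spec(n_cases = 4L, n_controls = 8L,
                                    n_genes = 8L, n_background_variants = 150L,
                                    causal_mode = "compound_het", seed = 0L))
  ann <- annotate_cohort(co)
  causal_ids <- unique(ann$id[ann$gene == "RSPH1"])
  for (s in co$samples$sample[co$samples$role == "case"]) {
    g <- co$gt[causal_ids, s]
    expect_identical(sum(g == 1L, na.rm = TRUE), 2L)
    expect_identical(sum(g == 2L, na.rm = TRUE), 0L)
    cls <- ann$class[ann$id %in% causal_ids[which(g == 1L)]]
    expect_true(all(cls %in% c("stop_gained", "canonical_splice")))
  }
  # controls carry no planted allele
  ctrl <- co$samples$sample[co$samples$role == "control"]
  expect_true(all(co$gt[co$variants$id[co$variants$planted], ctrl] == 0L))
})

test_that("simulation and written inputs are byte-deterministic in the seed", {
  spec <- cohort_spec(n_cases = 3L, n_controls = 6L, n_genes = 6L,
                      n_background_variants = 120L, seed = 9L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_inputs(simulate_cohort(spec), d1)
  write_inputs(simulate_cohort(spec), d2)
  for (f in c("cohort.vcf", "panel.bed", "cohort.ped", "frequencies.tsv",
              "gene_list.txt", "transcripts.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("written inputs read back losslessly", {
  co <- small_cohort(17)
  d <- withr::local_tempdir()
  write_inputs(co, d)
  inp <- read_cohort_inputs(d)
  expect_identical(inp$variants[, c("chrom", "pos", "ref", "alt")],
                   co$variants[, c("chrom", "pos", "ref", "alt")])
  expect_identical(unname(inp$gt), unname(co$gt))
  expect_identical(inp$gene_list, co$gene_list)
  # transcripts round-trip
  tx <- inp$tx_set[[1]]
  orig <- co$tx_set[[which(vapply(co$tx_set, `[[`, character(1),
                                  "transcript_id") == tx$transcript_id)]]
  expect_identical(tx$seq, orig$seq)
  expect_identical(tx$exons, orig$exons)
})

test_that("bait regions cover every simulated variant", {
  co <- small_cohort(23)
  kept <- restrict_to_regions(co$variants, co$regions, window = 0L)
  expect_identical(nrow(kept), nrow(co$variants))
})

test_that("missing genotypes appear at the requested rate and spare plants", {
  co <- small_cohort(29, missing_rate = 0.1)
  expect_gt(mean(is.na(co$gt)), 0.05)
  expect_lt(mean(is.na(co$gt)), 0.15)
  expect_true(all(!is.na(co$gt[co$variants$id[co$variants$planted], ])))
  d <- withr::local_tempdir()
  write_inputs(co, d)
  inp <- read_cohort_inputs(d)
  expect_identical(unname(inp$gt), unname(co$gt)) # "./." round-trips to NA
})

test_that("homozygous mode encodes a consanguineous first pedigree", {
  co <- simulate_cohort(cohort_spec(n_cases = 2L, n_controls = 4L,
                                    n_genes = 6L, n_background_variants = 100L,
                                    causal_mode = "homozygous", seed = 2L))
  ped <- co$ped
  fam1 <- ped[ped$fid == "FAM01", ]
  # affected sibs present
  expect_gte(sum(fam1$pheno == 2L), 2L)
  # the case's parents descend from shared grandparents (first cousins)
  fa <- fam1[fam1$iid == "FA01", ]
  mo <- fam1[fam1$iid == "MO01", ]
  gpf <- fam1[fam1$iid == fa$pat, ]
  gpm <- fam1[fam1$iid == mo$pat, ]
  expect_identical(gpf$pat, gpm$pat) # both grandfathers share a father
  # and the case is homozygous for the planted nonsense allele
  pid <- co$variants$id[co$variants$planted]
  expect_identical(unname(co$gt[pid, "CASE01"]), 2L)
  expect_identical(unname(co$gt[pid, "FA01"]), 1L)
  expect_identical(unname(co$gt[pid, "MO01"]), 1L)
})

test_that("control allele frequencies calibrate to the spectrum", {
  co <- simulate_cohort(cohort_spec(n_cases = 2L, n_controls = 2000L,
                                    n_genes = 6L, n_background_variants = 60L,
                                    seed = 4L))
  ctrl <- co$samples$sample[co$samples$role == "control"]
  bg <- !co$variants$planted
  q_hat <- rowMeans(co$gt[co$variants$id[bg], ctrl], na.rm = TRUE) / 2
  q <- co$variants$true_maf[bg]
  sd <- sqrt(q * (1 - q) / (2 * length(ctrl)))
  expect_true(all(abs(q_hat - q) <= 3 * sd + 1e-9))
})

test_that("truth-model soundness: every planted case passes the recessive cascade", {
  for (mode in c("compound_het", "homozygous")) {
    co <- small_cohort(41, mode = mode)
    ann <- annotate_cohort(co)
    for (s in co$samples$sample[co$samples$role == "case"]) {
      rep <- run_cascade(s, co$variants, ann, co$gt, co$freq, co$regions,
                         co$gene_list)
      expect_true("RSPH1" %in% candidate_genes(rep),
                  info = paste(mode, s))
    }
  }
})

test_that("an undersized variant pool warns rather than fails", {
  expect_warning(
    simulate_cohort(cohort_spec(n_cases = 1L, n_controls = 2L, n_genes = 10L,
                                n_background_variants = 5L, seed = 1L)),
    "too small to populate"
  )
})
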