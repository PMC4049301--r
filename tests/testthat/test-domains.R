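test_that("the bundled annotation carries seven MORN repeats", {
  ann <- load_domains()
  expect_identical(sum(ann$intervals$label == "MORN"), 7L)
  expect_identical(ann$protein_length, 309L)
  dev <- repeat_length_deviations(ann)
  expect_identical(nrow(dev), 7L)
  expect_identical(dev$length, c(18L, 23L, 23L, 23L, 21L, 16L, 23L))
  expect_identical(dev$deviation, dev$length - 23L)
})

test_that("nonsense residues fall in the published MORN repeats", {
  ann <- load_domains()
  h94 <- locate_residue(ann, 94L)
  expect_identical(h94$label[h94$label == "MORN"], "MORN")
  expect_identical(h94$ordinal[h94$label == "MORN"], 4L)
  expect_identical(h94$start[h94$label == "MORN"], 90L)
  h29 <- locate_residue(ann, 29L)
  expect_identical(h29$ordinal[h29$label == "MORN"], 1L)
  h200 <- locate_residue(ann, 200L)
  expect_identical(nrow(h200), 0L)
  expect_error(locate_residue(ann, 0L), "out of range")
  expect_error(locate_residue(ann, 310L), "out of range")
})

test_that("locate_residue agrees with a naive scan over every residue", {
  ann <- load_domains()
  iv <- ann$intervals
  for (res in seq_len(ann$protein_length)) {
    naive <- which(iv$start <= res & res <= iv$end)
    got <- locate_residue(ann, res)
    expect_identical(nrow(got), length(naive), info = res)
  }
})

test_that("truncation extent counts retained residues and lost domains", {
  ann <- load_domains()
  t29 <- truncation_extent(309L, 29L, ann)
  expect_equal(t29$retained_fraction, 28 / 309)
  expect_identical(sum(t29$domains_lost$label == "MORN"), 7L)
  t94 <- truncation_extent(309L, 94L, ann)
  expect_identical(sum(t94$domains_lost$label == "MORN"), 4L) # repeats 4-7
  t_end <- truncation_extent(309L, 309L, ann)
  expect_equal(t_end$retained_fraction, 308 / 309)
  expect_identical(nrow(t_end$domains_lost), 0L)
  # monotone non-decreasing in the stop ordinal
  fr <- vapply(1:310, function(s) truncation_extent(309L, s)$retained_fraction,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("annotation files are validated and filterable by source", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tstart\tend\tlabel\tsource",
               "P1\t5\t400\tMORN\tpfam"), f)
  expect_error(load_domains(f, protein_length = 309L), "out of range")
  writeLines("protein_id\tstart\tend\tlabel\tsource", f)
  empty <- load_domains(f, protein_length = 100L)
  expect_identical(nrow(empty$intervals), 0L)
  writeLines(c("protein_id\tstart\tend\tlabel\tsource",
               "P1\t5\t30\tMORN\tpfam", "P1\t10\t40\tMORN\tsmart"), f)
  both <- load_domains(f, protein_length = 100L)
  expect_identical(nrow(both$intervals), 2L)
  pfam_only <- load_domains(f, protein_length = 100L, source = "pfam")
  expect_identical(pfam_only$intervals$source, "pfam")
  writeLines(c("protein_id\tstart\tend\tlabel\tsource",
               "P1\t5\t30\tMORN\tpfam", "P1\t10\t40\tMORN\tpfam"), f)
  expect_error(load_domains(f, protein_length = 100L), "overlapping")
})

test_that("splice-acceptor variants map to the downstream exon's first codon", {
  sv <- splice_variant_residue(FX$tx, 275L)
  expect_identical(sv$residue, 92L)
  expect_true(sv$inferred)
  # residue 92 lies in MORN repeat 4, like the adjacent nonsense at 94
  ann <- load_domains()
  h <- locate_residue(ann, sv$residue)
  expect_identical(h$ordinal[h$label == "MORN"], 4L)
})
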