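test_that("Mendelian trio consistency matches the allele-assignment oracle", {
  expect_true(mendelian_check(2L, 1L, 1L)$consistent)
  r <- mendelian_check(1L, 0L, 0L)
  expect_false(r$consistent)
  expect_match(r$detail, "de novo")
  # exhaustive enumeration incl. missing genotypes
  vals <- c(0L, 1L, 2L, NA)
  for (ch in vals) for (fa in vals) for (mo in vals) {
    expect_identical(mendelian_check(ch, fa, mo)$consistent,
                     oracle_trio(ch, fa, mo),
                     info = paste(ch, fa, mo))
  }
})

test_that("trans/cis phase from parental carriage matches the truth table", {
  expect_identical(trans_phase_from_parents(c(1L, 0L), c(0L, 1L)), "trans")
  expect_identical(trans_phase_from_parents(c(1L, 1L), c(0L, 0L)), "cis")
  # enumerate all parental carriage patterns
  for (fa in 0:3) for (mo in 0:3) {
    f <- c(fa %/% 2L, fa %% 2L)
    m <- c(mo %/% 2L, mo %% 2L)
    got <- trans_phase_from_parents(f, m)
    fc <- f >= 1L; mc <- m >= 1L
    want <- if (sum(fc) == 1L && sum(mc) == 1L && !identical(fc, mc)) "trans"
            else if ((all(fc) && !any(mc)) || (all(mc) && !any(fc))) "cis"
            else "unknown"
    expect_identical(got, want, info = paste(fa, mo))
  }
  expect_identical(trans_phase_from_parents(c(NA, 1L), c(0L, 1L)), "unknown")
})

trio_ped <- function() {
  data.frame(fid = "F", iid = c("FA", "MO", "KID", "SIB"),
             pat = c("0", "0", "FA", "FA"), mat = c("0", "0", "MO", "MO"),
             sex = c(1L, 2L, 2L, 1L), pheno = c(1L, 1L, 2L, 1L),
             stringsAsFactors = FALSE)
}

test_that("a compound-het affected with trans-carrying parents supports the gene", {
  gt <- rbind(vA = c(FA = 1L, MO = 0L, KID = 1L, SIB = 0L),
              vB = c(FA = 0L, MO = 1L, KID = 1L, SIB = 1L))
  v <- cosegregation_test(trio_ped(), gt, gene = "RSPH1")
  expect_identical(v$status, "supports")
  expect_true(v$phase_verified)
})

test_that("biallelic unaffected relatives exclude the gene", {
  # unaffected sib homozygous for both candidate variants
  gt <- rbind(vA = c(FA = 1L, MO = 1L, KID = 2L, SIB = 2L),
              vB = c(FA = 1L, MO = 1L, KID = 2L, SIB = 2L))
  v <- cosegregation_test(trio_ped(), gt, gene = "WDR66")
  expect_identical(v$status, "excludes")
  expect_gte(length(v$reasons), 1L)
  expect_match(paste(v$reasons, collapse = " "), "unaffected SIB")
})

test_that("a non-biallelic affected excludes; no genotypes is uninformative", {
  gt <- rbind(vA = c(FA = 1L, MO = 0L, KID = 1L, SIB = 0L))
  v <- cosegregation_test(trio_ped(), gt, gene = "G")
  expect_identical(v$status, "excludes")
  gt_na <- rbind(vA = c(FA = NA, MO = NA, KID = NA, SIB = NA))
  expect_identical(cosegregation_test(trio_ped(), gt_na)$status,
                   "uninformative")
  expect_identical(cosegregation_test(trio_ped(),
                                      matrix(integer(0), nrow = 0))$status,
                   "uninformative")
})

test_that("phase-unknown double hets support with the phase flagged", {
  # parents ungenotyped: trans cannot be established
  gt <- rbind(vA = c(KID = 1L), vB = c(KID = 1L))
  v <- cosegregation_test(trio_ped(), gt)
  expect_identical(v$status, "supports")
  expect_false(v$phase_verified)
  # cis-carrying parent: the "double het" is one haplotype -> excludes
  gt2 <- rbind(vA = c(FA = 1L, MO = 0L, KID = 1L),
               vB = c(FA = 1L, MO = 0L, KID = 1L))
  expect_identical(cosegregation_test(trio_ped(), gt2)$status, "excludes")
})

test_that("verdicts are invariant to pedigree row order", {
  gt <- rbind(vA = c(FA = 1L, MO = 1L, KID = 2L, SIB = 2L))
  ped <- trio_ped()
  set.seed(71)
  v0 <- cosegregation_test(ped, gt)
  for (i in 1:5) {
    vp <- cosegregation_test(ped[sample(nrow(ped)), ], gt)
    expect_identical(vp$status, v0$status)
    expect_identical(sort(vp$reasons), sort(v0$reasons))
  }
})

test_that("simulated families support the causal gene; replanted unaffecteds exclude", {
  for (mode in c("compound_het", "homozygous")) {
    co <- small_cohort(73, mode = mode)
    ann <- annotate_cohort(co)
    pid <- co$variants$id[co$variants$planted]
    for (i in seq_len(co$spec$n_cases)) {
      fam <- sprintf("FAM%02d", i)
      fped <- co$ped[co$ped$fid == fam, ]
      gt <- co$gt[pid, , drop = FALSE]
      v <- cosegregation_test(fped, gt, gene = "RSPH1")
      expect_identical(v$status, "supports", info = paste(mode, fam))
      # replant the candidate variants into an unaffected parent in
      # homozygous form (the classic exclusion scenario) -> exclusion
      gt2 <- gt
      gt2[, sprintf("FA%02d", i)] <- 2L
      v2 <- cosegregation_test(fped, gt2, gene = "RSPH1")
      expect_identical(v2$status, "excludes", info = paste(mode, fam))
    }
  }
})
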