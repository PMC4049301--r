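# Shared fixtures, built once per test run (deterministic seeds).

FX <- make_rsph1_fixture()
FXM <- make_rsph1_fixture(fixture_spec(strand = "-"))

# a small cohort for unit tests (the full-size defaults are exercised in the
# acceptance suite)
small_cohort <- function(seed, mode = "compound_het", ...) {
  simulate_cohort(cohort_spec(
    n_cases = 4L, n_controls = 12L, n_genes = 10L,
    n_background_variants = 250L, causal_mode = mode, seed = seed, ...
  ))
}

annotate_cohort <- function(cohort, check_ref = TRUE) {
  ann <- annotate_variants(cohort$variants, cohort$tx_set,
                           genomes = cohort$genomes, check_ref = check_ref)
  ciliaseek:::.annotation_with_ids(ann, cohort$variants)
}
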