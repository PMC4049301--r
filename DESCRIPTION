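Package: ciliaseek
Title: Rare Recessive Variant Prioritization for Motile Ciliopathy Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the variant-prioritization strategy used in
    targeted gene-panel studies of primary ciliary dyskinesia (PCD): transcript-model
    based consequence annotation with HGVS c./p. nomenclature, a rare-recessive
    filtering cascade with stepwise per-sample count reporting, pedigree
    co-segregation testing under an autosomal recessive model, protein-domain mapping
    of truncating candidate mutations, and a Hardy-Weinberg carrier-frequency
    consistency check. Includes a deterministic synthetic-cohort generator that plants
    biallelic loss-of-function genotypes in a causal gene so the whole pipeline can be
    exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
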