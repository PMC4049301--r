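---
title: "Prioritizing rare recessive variants on a motile-cilia gene panel"
author: "ciliaseek"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing rare recessive variants on a motile-cilia gene panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliaseek)
```

## The problem

Primary ciliary dyskinesia (PCD) is an autosomal recessive disorder of motile
cilia with a birth prevalence of roughly 1/15,000-1/30,000 and mutations
reported in dozens of genes. Targeted gene-panel sequencing of undiagnosed
probands produces, per individual, thousands of variant calls that must be
reduced to a handful of credible candidates. The reduction strategy is
stereotyped across studies of this kind:

1. restrict calls to the capture (bait) regions plus a flanking window;
2. keep variants that are novel or rare (minor allele frequency below 0.01)
   in population exome resources;
3. split carried variants by zygosity;
4. keep functional consequences: non-synonymous substitutions, canonical
   splice-site changes, and coding indels;
5. keep genes compatible with a recessive genotype: at least one homozygous
   variant, or at least two heterozygous variants in the same individual
   (a putative compound heterozygote, phase unknown at this stage);
6. intersect the surviving genes with a motile-cilia candidate list;
7. test co-segregation of the surviving genotypes in the proband's pedigree
   under the recessive model.

`ciliaseek` implements this cascade as tested, composable functions, together
with the annotation machinery it depends on (transcript-model coordinate
arithmetic and HGVS c./p. naming), protein-domain mapping of truncating
candidates, a Hardy-Weinberg carrier-frequency consistency check, and a
deterministic cohort simulator used to validate the whole pipeline
end to end.

## The transcript fixture

All coordinate and consequence logic is exercised against a synthetic
RSPH1-like transcript whose printed anatomy matches the real gene: an 8-exon,
1.4 kb cDNA spanning 24 kb of genome and encoding 309 residues. Three facts
are pinned so that the canonical loss-of-function alleles of this gene are
reproducible by construction:

* residue 29 is glutamate, encoded GAG, so the substitution c.85G>T creates a
  stop (p.Glu29\*);
* residue 94 is tryptophan, encoded TGG, so c.281G>A creates a stop
  (p.Trp94\*);
* exon 4 begins at coding position 275, so the exon-4 splice acceptor
  occupies intronic positions c.275-2/-1 and c.275-2A>C destroys it.

Unpinned sequence content is drawn from a seeded generator; every intron
carries canonical GT...AG splice sites. A minus-strand twin fixture (same
cDNA, reverse-complemented contig) exercises strand handling.

```{r fixture}
fx <- make_rsph1_fixture()
fx$tx
classify_consequence(fx$tx, coding_to_genomic(fx$tx, 281), "G", "A",
                     genome = fx$genome)
```

## Consequence annotation

`map_genomic_to_coding()` converts genomic positions to HGVS-style coding
coordinates: exonic positions get intron offset 0; intronic positions are
expressed against the nearest exon boundary, negative on the acceptor side
and positive on the donor side, with ties broken toward the 5' exon.
`classify_consequence()` translates CDS substitutions against the transcript
codon; intronic changes within 2 nt of an exon boundary are canonical splice
variants, those at 3-8 nt are splice-region, and coding indels are
frameshift or in-frame by the net length modulo 3. Indel c. names are shifted
3' along the spliced sequence per the HGVS convention; complex MNVs are out
of scope. One engine serves both the scalar interface and the vectorized
table annotator, so they cannot drift apart; the test suite additionally
checks every possible CDS substitution of the fixture against an independent
oracle that rebuilds the full mutant CDS and diffs the translations.

Two vocabulary decisions are worth making explicit. "Non-synonymous" for the
functional filter means {missense, stop gained, stop lost, start lost}; this
is the standard usage under which nonsense alleles survive the filter.
Splice-region calls (intronic 3-8) are reported but do not pass the
functional filter by default; a flag (`keep_splice_region`) widens the filter
for analyses that want them, since published het-branch counts do not state
which definition was used.

## The filtering cascade

`run_cascade()` fixes the stage order: region restriction (bait regions
± 100 bp by default), frequency filter, zygosity split, class filter, gene
model, panel intersection. Decisions embedded in the implementation:

* "frequency < 0.01" is interpreted as *maximum* MAF across reporting
  resources below the threshold -- the strictest reading; a variant absent
  from every resource is novel and passes. Frequencies above 0.5 are folded.
* compound-het candidacy requires two distinct heterozygous variants in the
  *same* sample and gene, both of which have already passed the frequency and
  class filters;
* multi-allelic records are handled per alternate allele (the simulator and
  reader emit one row per alt);
* a missing genotype counts as non-carrier;
* a variant belongs to every gene whose transcript annotation it hits, so
  overlapping genes are both counted.

The report object validates its own identities on construction: counts are
non-increasing along each branch, and heterozygous + homozygous counts equal
the frequency-filtered total. Representative two-proband example counts
(462 + 125 = 587 and 514 + 155 = 669) are frozen as constructor inputs in
the tests.

## Pedigree co-segregation

`cosegregation_test()` evaluates one gene's candidate genotypes in one
family under a fully penetrant autosomal recessive model: `supports` requires
every genotyped affected to be biallelic and no genotyped unaffected to be
biallelic; `excludes` otherwise (with machine-readable reasons, e.g. an
unaffected relative homozygous for the candidate variants); `uninformative`
when no affected is genotyped. Phase for double heterozygotes is established
from parental genotypes where possible (`trans_phase_from_parents()`); a
double-het affected whose phase cannot be established still supports, but is
flagged `phase_verified = FALSE`, mirroring the pre-confirmation status of a
compound-het candidate. An unaffected double-het with unknown phase does
*not* trigger exclusion -- two rare alleles in cis are common enough that
exclusion on phase-unknown carriage would be unsafe. Consanguinity is
represented by pedigree structure only; no inbreeding coefficient is
computed.

## Domain mapping

The bundled annotation (`inst/extdata/rsph1_domains.tsv`) carries the
Pfam-consensus structure of RSPH1 -- seven MORN repeats (residues 26-43,
44-66, 67-89, 90-112, 113-133, 137-152, 159-181) and a low-complexity region
(238-251) on 309 residues. Alternative predictors describe six repeats but
publish no coordinate set usable here, so only the Pfam set ships;
`load_domains()` accepts external files and filters by `source`. A canonical
splice-acceptor variant has no protein position of its own: for domain
mapping it is assigned the codon of the first coding base of the downstream
exon (c.275 maps to residue 92), flagged `inferred = TRUE`. This inference is
this package's choice of rule; it reproduces the placement of the acceptor
variant inside MORN repeat 4 alongside the adjacent nonsense at residue 94.

## Carrier-frequency consistency

A recessive disease allele can legitimately appear in heterozygous carriers
of a control exome database. Under Hardy-Weinberg, prevalence P and locus
share s imply allele frequency q = sqrt(P*s) and carrier frequency 2q(1-q).
`carrier_consistency_test()` compares an observed het carrier count against
Binomial(n, 2q(1-q)) with a two-sided exact test at both prevalence bounds;
only an upper-tail excess ("too common to be pathogenic") can produce an
`inconsistent` verdict. The published argument is qualitative; the binomial
construction is this package's formalization of it. `locus_share` defaults
to 0.04 as an order-of-magnitude placeholder for one gene among many causing
the disease -- it is configurable, and flagged in printed output precisely
because it is not an estimate. Homozygous carriers in controls are flagged
separately regardless of the verdict.

```{r carriers}
carrier_consistency_test(carrier_observation(het = 9, n = 6500))
```

## What the simulator emulates, and what it does not

`simulate_cohort()` generates the full input set (VCF, BED, PED, frequency
table, gene list, transcript JSON) with the statistical structure the
cascade assumes. Defaults are fixed once, as the study conditions the
package targets:

* 70 affected unrelated probands, each with two genotyped unaffected
  parents, plus 100 unrelated controls;
* 60 background panel genes plus the causal gene; a shared pool of 3000
  background variants placed in exons (with a 5% near-splice intronic
  fraction), allele frequencies from a Beta(0.2, 1.8) spectrum scaled onto
  (0, 0.5] so both common (>0.01) and rare alleles occur and the MAF filter
  cuts in both directions;
* planted causal genotypes reusing the gene's canonical alleles: compound-het
  mode plants c.281G>A (novel) plus c.275-2A>C, one from each parent;
  homozygous mode plants c.85G>T from both carrier parents, under a
  consanguineous first pedigree with an affected sib. The frequency table
  reports the splice and early-nonsense alleles at their carrier-derived
  control frequencies (9/13,000 and 5/13,000) and omits the exon-4 nonsense
  entirely;
* founder genotypes are Hardy-Weinberg draws at the true frequency; trio
  offspring genotypes are gene-dropped from the parents, so simulated
  pedigrees are Mendelian-clean; controls never carry a planted allele.
* background variants are never placed in the causal gene, so a case's
  causal-gene genotype is exactly its plant.

Per-sample variant counts under these defaults are in the hundreds, not the
thousands a genome-wide panel produces: the published per-proband totals
derive from unpublished raw call sets, and the spectrum is calibrated only
loosely to their magnitudes. The simulator also omits sequencing error,
capture-efficiency variation, genotyping batch effects, population
stratification and linkage between background variants. Passing tests on
simulated cohorts therefore demonstrate the correctness of the filtering
logic under its own model assumptions, not performance on real call sets.

## Numerical and testing choices

Determinism is part of every contract: a spec plus seed yields byte-identical
files (no timestamps in any output header). Coordinates are 1-based inclusive
everywhere except the BED boundary, which is handled by `rtracklayer`.
Degenerate inputs are defined rather than accidental: empty variant sets pass
through every filter as empty; an empty panel list is a configuration error;
malformed frequency rows are skipped with a warning and behave as absent;
half-called genotypes are missing.

Problem sizes in the test suite are the package's own choices: unit tests
run on 4-case/12-control cohorts with 250-variant pools; the acceptance
suite runs twenty full-size default cohorts (seeds 0-19, alternating causal
modes) and checks 100% planted-gene recovery, a median of at most 5
non-causal candidate genes per case, supporting co-segregation verdicts in
every simulated family, cascade monotonicity and frequency/class filter
commutation, plus an exhaustive substitution sweep of the fixture CDS
against the rebuild-and-translate oracle.

## Limitations

* Single-engine, single-transcript annotation: no consequence ranking across
  multiple overlapping transcripts, no pathogenicity scores, no
  splice-strength prediction.
* The HGVS surface covers substitutions and simple del/ins/dup/delins of
  explicit sequences; complex rearrangements are rejected explicitly.
* The recessive model assumes complete penetrance; X-linked and dominant
  models, linkage/LOD computation, and inbreeding coefficients are out of
  scope.
* The carrier-frequency check inherits all Hardy-Weinberg assumptions and
  the arbitrariness of `locus_share`; it frames a consistency argument, not
  an estimate.
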