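#' Specification for a synthetic RSPH1-like transcript fixture
#'
#' The default spec reproduces the printed anatomy of human RSPH1: an 8-exon,
#' 1.4 kb cDNA spanning 24 kb of genome, encoding a 309-residue protein, with
#' Glu pinned at residue 29 (codon GAG, so a G>T at c.85 creates a stop), Trp
#' pinned at residue 94 (codon TGG, so a G>A at c.281 creates a stop), and
#' exon 4 beginning at coding position 275 (so the exon-4 splice acceptor is
#' the intronic AG at c.275-2/-1).
#'
#' @param exon_count Number of exons.
#' @param cdna_length Spliced transcript length in nucleotides.
#' @param genomic_span Genomic footprint (first exon start to last exon end).
#' @param cds_codons Coding codons excluding the stop (protein length).
#' @param utr5_length 5'UTR length in nucleotides.
#' @param pinned_residues Named character vector: protein position ->
#'   single-letter amino acid that the generated CDS must encode there.
#' @param pinned_exon_starts Named integer vector: exon ordinal -> coding
#'   position of that exon's first base.
#' @param domain_intervals `data.frame` of labelled protein-residue ranges
#'   (columns `start`, `end`, `label`, `source`).
#' @param strand `"+"` (default) or `"-"`.
#' @param contig Synthetic contig name.
#' @param gene Gene symbol of the fixture.
#' @param seed Integer seed; fully determines the generated sequence.
#'
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(exon_count = 8L, cdna_length = 1400L,
                         genomic_span = 24000L, cds_codons = 309L,
                         utr5_length = 60L,
                         pinned_residues = c(`29` = "E", `94` = "W"),
                         pinned_exon_starts = c(`4` = 275L),
                         domain_intervals = rsph1_domain_defaults(),
                         strand = "+", contig = "chr21_syn",
                         gene = "RSPH1", seed = 1L) {
  cds_length <- 3L * (cds_codons + 1L) # incl. stop codon
  if (cds_length + utr5_length > cdna_length) {
    stop("CDS (", cds_length, " nt) plus 5'UTR does not fit in cDNA of ",
         cdna_length, " nt")
  }
  if (genomic_span < cdna_length) stop("genomic_span must be >= cdna_length")
  for (r in names(pinned_residues)) {
    if (as.integer(r) < 1L || as.integer(r) > cds_codons) {
      stop("pinned residue ", r, " outside protein of ", cds_codons, " residues")
    }
    if (!pinned_residues[[r]] %in% names(.CANONICAL_CODON)) {
      stop("pinned residue ", r, ": unknown amino acid '", pinned_residues[[r]], "'")
    }
  }
  for (e in names(pinned_exon_starts)) {
    p <- as.integer(pinned_exon_starts[[e]])
    if (as.integer(e) < 2L || as.integer(e) > exon_count) {
      stop("pinned exon start for exon ", e, ": no such internal exon")
    }
    if (p < 2L || p > cds_length) {
      stop("pinned exon ", e, " start at coding position ", p,
           " lies beyond the CDS (", cds_length, " nt)")
    }
  }
  structure(
    list(
      exon_count = as.integer(exon_count), cdna_length = as.integer(cdna_length),
      genomic_span = as.integer(genomic_span), cds_codons = as.integer(cds_codons),
      cds_length = cds_length, utr5_length = as.integer(utr5_length),
      pinned_residues = pinned_residues,
      pinned_exon_starts = pinned_exon_starts,
      domain_intervals = domain_intervals,
      strand = strand, contig = contig, gene = gene, seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

# exon start positions in spliced-transcript coordinates: pinned starts act as
# fixed anchors, remaining boundaries are interpolated between them
.fixture_exon_tx_starts <- function(spec) {
  n <- spec$exon_count
  b <- rep(NA_integer_, n + 1L)
  b[1] <- 1L
  b[n + 1L] <- spec$cdna_length + 1L
  for (e in names(spec$pinned_exon_starts)) {
    b[as.integer(e)] <- spec$utr5_length + as.integer(spec$pinned_exon_starts[[e]])
  }
  anchors <- which(!is.na(b))
  for (i in seq_len(length(anchors) - 1L)) {
    a <- anchors[i]
    z <- anchors[i + 1L]
    if (b[z] - b[a] < z - a) {
      stop("pinned exon start for exon ", z, " at transcript position ", b[z],
           " leaves no room for exons ", a, "..", z - 1L)
    }
    if (z - a > 1L) {
      fill <- as.integer(round(seq(b[a], b[z], length.out = z - a + 1L)))
      b[(a + 1L):(z - 1L)] <- fill[2:(z - a)]
    }
  }
  if (any(diff(b) < 1L)) {
    stop("pinned exon starts produce a non-increasing exon layout; ",
         "check pinned_exon_starts against cdna_length/exon_count")
  }
  b[seq_len(n)]
}

#' Generate the RSPH1-like transcript fixture
#'
#' Builds a fully synthetic genomic contig plus transcript model satisfying the
#' spec's pins: the translation carries the pinned residues, exon boundaries
#' fall at the pinned coding positions, and every intron has canonical GT...AG
#' splice sites (so the acceptor A of exon 4 sits at c.275-2). Deterministic
#' for a given seed.
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `rsph1_fixture` with elements `tx` (the
#'   [transcript_model()]), `genome` (named character vector contig ->
#'   sequence), `domains` (the domain interval table) and `spec`.
#' @export
make_rsph1_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)

  # --- coding sequence: ATG + sense codons + pinned codons + stop ------------
  codons <- c("ATG", sample(setdiff(.SENSE_CODONS, "ATG"), spec$cds_codons - 1L,
                            replace = TRUE))
  for (r in names(spec$pinned_residues)) {
    codons[as.integer(r)] <- .CANONICAL_CODON[[spec$pinned_residues[[r]]]]
  }
  cds <- paste(c(codons, "TAA"), collapse = "")

  utr3_length <- spec$cdna_length - spec$utr5_length - spec$cds_length
  cdna <- paste0(.random_bases(spec$utr5_length), cds, .random_bases(utr3_length))

  # --- exon/intron layout ----------------------------------------------------
  tx_starts <- .fixture_exon_tx_starts(spec)
  tx_ends <- c(tx_starts[-1] - 1L, spec$cdna_length)
  exon_w <- tx_ends - tx_starts + 1L
  n_introns <- spec$exon_count - 1L
  intron_total <- spec$genomic_span - spec$cdna_length
  intron_w <- rep(intron_total %/% n_introns, n_introns)
  rem <- intron_total - sum(intron_w)
  if (rem > 0L) intron_w[seq_len(rem)] <- intron_w[seq_len(rem)] + 1L
  if (any(intron_w < 10L)) stop("genomic_span leaves introns shorter than 10 nt")

  flank <- 200L
  g_start <- flank + 1L
  exon_g_start <- integer(spec$exon_count)
  exon_g_end <- integer(spec$exon_count)
  pos <- g_start
  for (k in seq_len(spec$exon_count)) {
    exon_g_start[k] <- pos
    exon_g_end[k] <- pos + exon_w[k] - 1L
    pos <- exon_g_end[k] + 1L + if (k < spec$exon_count) intron_w[k] else 0L
  }
  contig_len <- exon_g_end[spec$exon_count] + flank

  # --- assemble plus-strand contig ------------------------------------------
  g <- strsplit(.random_bases(contig_len), "", fixed = TRUE)[[1]]
  cdna_chars <- strsplit(cdna, "", fixed = TRUE)[[1]]
  for (k in seq_len(spec$exon_count)) {
    g[exon_g_start[k]:exon_g_end[k]] <- cdna_chars[tx_starts[k]:tx_ends[k]]
  }
  for (k in seq_len(n_introns)) {
    donor <- exon_g_end[k] + 1L
    acceptor <- exon_g_start[k + 1L] - 1L
    g[donor] <- "G"; g[donor + 1L] <- "T"        # GT donor
    g[acceptor - 1L] <- "A"; g[acceptor] <- "G"  # AG acceptor
  }
  genome_seq <- paste(g, collapse = "")
  exons <- data.frame(start = exon_g_start, end = exon_g_end)

  if (spec$strand == "-") {
    genome_seq <- .revcomp(genome_seq)
    exons <- data.frame(
      start = contig_len - exon_g_end + 1L,
      end = contig_len - exon_g_start + 1L
    )
    exons <- exons[order(exons$start), , drop = FALSE]
  }

  tx <- transcript_model(
    transcript_id = paste0("TX_", spec$gene), gene = spec$gene,
    contig = spec$contig, strand = spec$strand, exons = exons,
    cds_start = spec$utr5_length + 1L,
    cds_end = spec$utr5_length + spec$cds_length,
    seq = cdna
  )

  # verify pins against the assembled model
  prot <- translate_transcript(tx)
  for (r in names(spec$pinned_residues)) {
    got <- substring(prot, as.integer(r), as.integer(r))
    if (got != spec$pinned_residues[[r]]) {
      stop("pin violated: residue ", r, " is ", got, ", expected ",
           spec$pinned_residues[[r]])
    }
  }

  structure(
    list(tx = tx, genome = stats::setNames(genome_seq, spec$contig),
         domains = spec$domain_intervals, spec = spec),
    class = "rsph1_fixture"
  )
}

#' @export
print.rsph1_fixture <- function(x, ...) {
  cat("rsph1_fixture:\n  ")
  print(x$tx)
  cat(sprintf("  contig %s: %d nt; %d domain intervals; seed %d\n",
              x$spec$contig, nchar(x$genome[[1]]), nrow(x$domains), x$spec$seed))
  invisible(x)
}

#' Generate a generic background-gene transcript fixture
#'
#' Smaller, unpinned transcripts used to populate the synthetic panel around
#' the causal gene. Same machinery and invariants as [make_rsph1_fixture()].
#'
#' @param gene Gene symbol.
#' @param contig Contig name (one synthetic contig per transcript).
#' @param seed Integer seed.
#' @param strand `"+"` or `"-"`.
#' @return A list with `tx` and `genome`, as in [make_rsph1_fixture()].
#' @export
make_background_transcript <- function(gene, contig = paste0("ctg_", gene),
                                       seed = 1L, strand = "+") {
  spec <- fixture_spec(
    exon_count = 5L, cdna_length = 1000L, genomic_span = 4000L,
    cds_codons = 299L, utr5_length = 50L,
    pinned_residues = character(0), pinned_exon_starts = integer(0),
    domain_intervals = data.frame(start = integer(0), end = integer(0),
                                  label = character(0), source = character(0)),
    strand = strand, contig = contig, gene = gene, seed = seed
  )
  fx <- make_rsph1_fixture(spec)
  list(tx = fx$tx, genome = fx$genome)
}
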