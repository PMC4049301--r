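#' Construct a transcript model
#'
#' A transcript model is the strand-aware exon/CDS structure on which all
#' coordinate arithmetic and consequence calls are made: ordered genomic exon
#' intervals (1-based, inclusive), a CDS interval in spliced-transcript
#' coordinates, and the spliced (cDNA) sequence read 5'→3' on the coding
#' strand.
#'
#' @param transcript_id Transcript identifier.
#' @param gene Gene symbol.
#' @param contig Name of the genomic contig the transcript lies on.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with columns `start`, `end`: genomic exon
#'   intervals, 1-based inclusive, in ascending genomic order, non-overlapping.
#' @param cds_start,cds_end CDS boundaries in spliced-transcript coordinates
#'   (1-based, inclusive; `cds_start` is the A of the ATG).
#' @param seq Spliced cDNA sequence (character, 5'→3' on the coding strand).
#'
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene, contig, strand, exons,
                             cds_start, cds_end, seq) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end < exons$start)) {
    stop("exon with end < start in transcript ", transcript_id)
  }
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("overlapping or unsorted exons in transcript ", transcript_id)
  }
  widths <- exons$end - exons$start + 1L
  if (sum(widths) != nchar(seq)) {
    stop("spliced sequence length (", nchar(seq), ") != total exon width (",
         sum(widths), ") in transcript ", transcript_id)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  cds_len <- cds_end - cds_start + 1L
  if (cds_start < 1L || cds_end > nchar(seq) || cds_len < 3L) {
    stop("CDS interval [", cds_start, ",", cds_end, "] outside transcript")
  }
  if (cds_len %% 3L != 0L) {
    stop("CDS length ", cds_len, " not divisible by 3 in ", transcript_id)
  }
  structure(
    list(
      transcript_id = transcript_id, gene = gene, contig = contig,
      strand = strand, exons = exons,
      cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
      seq = toupper(seq)
    ),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "transcript_model %s (%s) on %s[%s]: %d exons, cDNA %d nt, CDS %d..%d (%d codons)\n",
    x$transcript_id, x$gene, x$contig, x$strand, nrow(x$exons), nchar(x$seq),
    x$cds_start, x$cds_end, (x$cds_end - x$cds_start + 1L) %/% 3L
  ))
  invisible(x)
}

#' Coding sequence of a transcript model
#' @param tx A [transcript_model()].
#' @return CDS as a character string (includes the stop codon).
#' @export
transcript_cds <- function(tx) substring(tx$seq, tx$cds_start, tx$cds_end)

#' Translate a transcript's CDS
#'
#' Translation is delegated to [Biostrings::translate()]; the terminal stop is
#' dropped, so the returned length is the protein length in residues.
#'
#' @param tx A [transcript_model()].
#' @return Amino-acid sequence (single-letter codes) without the final stop.
#' @export
translate_transcript <- function(tx) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(transcript_cds(tx))))
  sub("\\*$", "", aa)
}

#' Write transcript models to JSON
#'
#' Serializes a list of transcript models to the interchange format used by all
#' pipeline inputs: 1-based inclusive genomic exon coordinates, strand, CDS
#' boundaries in transcript coordinates, and the spliced sequence.
#'
#' @param tx_set List of [transcript_model()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcript_json <- function(tx_set, path) {
  payload <- lapply(tx_set, function(tx) {
    list(
      transcript_id = tx$transcript_id, gene = tx$gene, contig = tx$contig,
      strand = tx$strand,
      exon_starts = tx$exons$start, exon_ends = tx$exons$end,
      cds_start = tx$cds_start, cds_end = tx$cds_end, sequence = tx$seq
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read transcript models from JSON
#' @param path File written by [write_transcript_json()].
#' @return Named list of [transcript_model()] objects (names = transcript ids).
#' @export
read_transcript_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  out <- lapply(payload, function(p) {
    transcript_model(
      transcript_id = p$transcript_id, gene = p$gene, contig = p$contig,
      strand = p$strand,
      exons = data.frame(start = unlist(p$exon_starts), end = unlist(p$exon_ends)),
      cds_start = p$cds_start, cds_end = p$cds_end, seq = p$sequence
    )
  })
  names(out) <- vapply(out, `[[`, character(1), "transcript_id")
  out
}
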