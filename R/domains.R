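# Protein-domain mapping: place candidate-mutation residues onto annotated
# domain intervals (MORN repeats, low-complexity regions) and quantify how
# much of the protein -- and which domains -- a truncating allele removes.

#' Default RSPH1 domain annotation
#'
#' The Pfam-consensus structure of RSPH1: seven MORN (membrane occupation and
#' recognition nexus) repeats at residues 26-43, 44-66, 67-89, 90-112,
#' 113-133, 137-152 and 159-181, plus a low-complexity region at 238-251, on
#' a 309-residue protein.
#'
#' @return `data.frame` with columns `start`, `end`, `label`, `source`.
#' @export
rsph1_domain_defaults <- function() {
  data.frame(
    start = c(26L, 44L, 67L, 90L, 113L, 137L, 159L, 238L),
    end = c(43L, 66L, 89L, 112L, 133L, 152L, 181L, 251L),
    label = c(rep("MORN", 7L), "low_complexity"),
    source = c(rep("pfam", 7L), "seg"),
    stringsAsFactors = FALSE
  )
}

#' Load a protein domain annotation
#'
#' Reads a TSV of labelled residue ranges (`protein_id, start, end, label,
#' source`) and validates every interval against the protein length. When no
#' file is given, the bundled RSPH1 annotation is loaded. The `source` filter
#' selects among alternative domain definitions when an annotation carries
#' more than one (e.g. Pfam vs other motif predictors).
#'
#' @param path TSV file; default: the annotation bundled with the package.
#' @param protein_length Protein length in residues (default 309, RSPH1).
#' @param source Optional source filter (e.g. `"pfam"`).
#' @return An object of class `domain_annotation`: `protein_id`, `intervals`
#'   (`data.frame`), `protein_length`.
#' @export
load_domains <- function(path = system.file("extdata", "rsph1_domains.tsv",
                                            package = "ciliaseek"),
                         protein_length = 309L, source = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (nrow(d)) {
    bad <- d$start < 1L | d$end < d$start | d$end > protein_length
    if (any(bad)) {
      i <- which(bad)[1]
      stop("domain interval out of range: ", d$label[i], " ", d$start[i], "-",
           d$end[i], " on a protein of ", protein_length, " residues")
    }
    if (!is.null(source)) d <- d[d$source %in% source, , drop = FALSE]
    # within one source, intervals must not overlap
    for (s in unique(d$source)) {
      ds <- d[d$source == s, , drop = FALSE]
      ds <- ds[order(ds$start), , drop = FALSE]
      if (nrow(ds) > 1L && any(ds$start[-1] <= ds$end[-nrow(ds)])) {
        stop("overlapping intervals within source '", s, "'")
      }
    }
  }
  structure(
    list(protein_id = if (nrow(d)) d$protein_id[1] else NA_character_,
         intervals = d[order(d$start), setdiff(names(d), "protein_id"),
                       drop = FALSE],
         protein_length = as.integer(protein_length)),
    class = "domain_annotation"
  )
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat(sprintf("domain_annotation %s (%d aa): %d intervals\n",
              x$protein_id, x$protein_length, nrow(x$intervals)))
  if (nrow(x$intervals)) print(x$intervals)
  invisible(x)
}

#' Deviations of repeat lengths from a consensus length
#'
#' MORN repeats have a consensus length of 23 residues; this reports each
#' labelled interval's length and its deviation from the consensus.
#'
#' @param annotation A [load_domains()] result.
#' @param label Interval label to report on (default `"MORN"`).
#' @param consensus_length Consensus repeat length in residues (default 23).
#' @return `data.frame` with `ordinal`, `start`, `end`, `length`, `deviation`.
#' @export
repeat_length_deviations <- function(annotation, label = "MORN",
                                     consensus_length = 23L) {
  iv <- annotation$intervals[annotation$intervals$label == label, , drop = FALSE]
  iv <- iv[order(iv$start), , drop = FALSE]
  len <- iv$end - iv$start + 1L
  data.frame(ordinal = seq_len(nrow(iv)), start = iv$start, end = iv$end,
             length = len, deviation = len - as.integer(consensus_length))
}

#' Domain intervals containing a residue
#'
#' @param annotation A [load_domains()] result.
#' @param residue Protein position (1-based).
#' @return `data.frame` of the hit intervals with the ordinal index of each
#'   repeat among intervals sharing its label (so residue 94 falls in MORN
#'   repeat 4 of the default annotation).
#' @export
locate_residue <- function(annotation, residue) {
  if (residue < 1L || residue > annotation$protein_length) {
    stop("residue ", residue, " out of range 1..", annotation$protein_length)
  }
  iv <- annotation$intervals
  if (!nrow(iv)) return(cbind(iv, ordinal = integer(0)))
  iv <- iv[order(iv$start), , drop = FALSE]
  ord <- stats::ave(seq_len(nrow(iv)), iv$label, FUN = seq_along)
  hit <- iv$start <= residue & residue <= iv$end
  out <- iv[hit, , drop = FALSE]
  out$ordinal <- ord[hit]
  rownames(out) <- NULL
  out
}

#' Truncation extent of a premature stop codon
#'
#' Fraction of residues retained and the domains lost or truncated by a stop
#' at a given codon ordinal: a domain is lost/truncated when it ends at or
#' after the stop position.
#'
#' @param protein_length Protein length in residues.
#' @param stop_ordinal Codon ordinal of the premature stop (1-based).
#' @param annotation Optional [load_domains()] result for the domain census.
#' @return List with `retained_fraction`, `retained_residues`, and (when an
#'   annotation is given) `domains_lost` (`data.frame`).
#' @export
truncation_extent <- function(protein_length, stop_ordinal, annotation = NULL) {
  stopifnot(stop_ordinal >= 1L, stop_ordinal <= protein_length + 1L)
  retained <- stop_ordinal - 1L
  out <- list(
    retained_fraction = retained / protein_length,
    retained_residues = as.integer(retained)
  )
  if (!is.null(annotation)) {
    iv <- annotation$intervals
    out$domains_lost <- iv[iv$end >= stop_ordinal, , drop = FALSE]
    rownames(out$domains_lost) <- NULL
  }
  out
}

#' Protein residue attributed to a canonical splice-acceptor variant
#'
#' A splice variant has no protein position of its own; for domain mapping it
#' is assigned the codon of the first coding base of the downstream exon (the
#' exon whose acceptor it disrupts), flagged as inferred.
#'
#' @param tx A [transcript_model()].
#' @param c_pos Coding position anchoring the acceptor (e.g. 275 for
#'   `c.275-2A>C`).
#' @return List with `residue` (codon ordinal of `c_pos`) and
#'   `inferred = TRUE`.
#' @export
splice_variant_residue <- function(tx, c_pos) {
  ci <- codon_index(c_pos, cds_length = tx$cds_end - tx$cds_start + 1L)
  list(residue = ci$codon_ordinal, inferred = TRUE)
}
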