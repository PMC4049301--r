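# Variant -> transcript consequence calls. A single engine classifies
# substitutions (vectorized) and simple indels (scalar), producing the
# consequence class plus HGVS c./p. names, e.g. c.281G>A; p.Trp94* on a TGG
# codon, or c.275-2A>C as a canonical splice-acceptor change.

.CONSEQUENCE_CLASSES <- c(
  "synonymous", "missense", "stop_gained", "stop_lost", "start_lost",
  "canonical_splice", "splice_region", "intronic", "utr",
  "frameshift", "inframe_indel"
)

# trim shared suffix then shared prefix from a VCF-style ref/alt pair,
# adjusting pos; returns minimal (left-parsimonious) representation
.normalize_alleles <- function(pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substring(ref, nchar(ref)) == substring(alt, nchar(alt))) {
    ref <- substring(ref, 1L, nchar(ref) - 1L)
    alt <- substring(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) >= 1L && nchar(alt) >= 1L &&
         substring(ref, 1L, 1L) == substring(alt, 1L, 1L) &&
         (nchar(ref) > 1L || nchar(alt) > 1L)) {
    ref <- substring(ref, 2L)
    alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

# vectorized SNV classification on one transcript
.classify_snv_tx <- function(tx, g_pos, ref, alt, genome = NULL,
                             check_ref = TRUE, flank = 5000L) {
  n <- length(g_pos)
  stopifnot(length(ref) == n, length(alt) == n)
  ref <- toupper(ref); alt <- toupper(alt)
  # transcript-strand alleles
  ref_t <- if (tx$strand == "-") .complement(ref) else ref
  alt_t <- if (tx$strand == "-") .complement(alt) else alt

  m <- .g2t(tx, g_pos, flank = flank)
  cc <- .t2c(tx, m$tx_pos)
  exonic <- m$offset == 0L

  if (check_ref) {
    if (any(exonic)) {
      seen <- substring(tx$seq, m$tx_pos[exonic], m$tx_pos[exonic])
      bad <- seen != ref_t[exonic]
      if (any(bad)) {
        i <- which(exonic)[which(bad)[1]]
        stop("reference mismatch at ", tx$contig, ":", g_pos[i], " (",
             tx$transcript_id, "): variant ref ", ref[i],
             " vs transcript base ", if (tx$strand == "-")
               .complement(seen[which(bad)[1]]) else seen[which(bad)[1]])
      }
    }
    if (!is.null(genome) && any(!exonic)) {
      gs <- genome[[tx$contig]]
      seen_g <- substring(gs, g_pos[!exonic], g_pos[!exonic])
      bad <- seen_g != ref[!exonic]
      if (any(bad)) {
        i <- which(!exonic)[which(bad)[1]]
        stop("reference mismatch at ", tx$contig, ":", g_pos[i],
             ": variant ref ", ref[i], " vs genomic base ",
             substring(gs, g_pos[i], g_pos[i]))
      }
    }
  }

  cls <- character(n)
  c_hgvs <- character(n)
  p_hgvs <- rep(NA_character_, n)
  codon_ord <- rep(NA_integer_, n)
  codon_off <- rep(NA_integer_, n)
  ref_aa <- rep(NA_character_, n)
  alt_aa <- rep(NA_character_, n)

  # intronic
  intr <- !exonic
  if (any(intr)) {
    ao <- abs(m$offset[intr])
    cls[intr] <- ifelse(ao <= 2L, "canonical_splice",
                        ifelse(ao <= 8L, "splice_region", "intronic"))
  }
  # exonic UTR
  eutr <- exonic & cc$region != "cds"
  cls[eutr] <- "utr"
  # exonic CDS
  ecds <- exonic & cc$region == "cds"
  if (any(ecds)) {
    ci <- codon_index(cc$c_pos[ecds])
    cds <- transcript_cds(tx)
    cstart <- 3L * (ci$codon_ordinal - 1L) + 1L
    codon <- substring(cds, cstart, cstart + 2L)
    mut <- paste0(
      substring(codon, 1L, ci$codon_offset - 1L),
      alt_t[ecds],
      substring(codon, ci$codon_offset + 1L, 3L)
    )
    raa <- unname(Biostrings::GENETIC_CODE[codon])
    aaa <- unname(Biostrings::GENETIC_CODE[mut])
    k <- ifelse(raa == aaa, "synonymous",
         ifelse(ci$codon_ordinal == 1L, "start_lost",
         ifelse(aaa == "*", "stop_gained",
         ifelse(raa == "*", "stop_lost", "missense"))))
    cls[ecds] <- k
    codon_ord[ecds] <- ci$codon_ordinal
    codon_off[ecds] <- ci$codon_offset
    ref_aa[ecds] <- raa
    alt_aa[ecds] <- aaa
    p_hgvs[ecds] <- ifelse(
      k == "start_lost", "p.Met1?",
      mapply(.format_p_sub, raa, ci$codon_ordinal, aaa, USE.NAMES = FALSE)
    )
  }
  for (i in seq_len(n)) {
    c_hgvs[i] <- paste0(
      format_c_position(cc$c_pos[i], m$offset[i], cc$region[i]),
      ref_t[i], ">", alt_t[i]
    )
  }
  data.frame(
    class = cls, c_hgvs = c_hgvs, p_hgvs = p_hgvs,
    codon_ordinal = codon_ord, codon_offset = codon_off,
    ref_aa = ref_aa, alt_aa = alt_aa,
    c_pos = cc$c_pos, intron_offset = m$offset, region = cc$region,
    stringsAsFactors = FALSE
  )
}

# 3'-shift a deletion/duplication window [t1, t2] (transcript coords) along
# the spliced sequence, per HGVS most-3' convention
.shift3 <- function(seq, t1, t2) {
  L <- nchar(seq)
  while (t2 < L &&
         substring(seq, t2 + 1L, t2 + 1L) == substring(seq, t1, t1)) {
    t1 <- t1 + 1L
    t2 <- t2 + 1L
  }
  c(t1, t2)
}

.c_label <- function(tx, tx_pos) {
  cc <- .t2c(tx, tx_pos)
  sub("^c\\.", "", format_c_position(cc$c_pos, 0L, cc$region))
}

# scalar indel/delins classification on one transcript
.classify_indel_tx <- function(tx, pos, ref, alt, genome = NULL, flank = 5000L) {
  del_len <- nchar(ref)
  ins_len <- nchar(alt)
  net <- ins_len - del_len
  # genomic footprint: deleted bases, or the two bases flanking an insertion
  g_lo <- if (del_len > 0L) pos else pos - 1L
  g_hi <- if (del_len > 0L) pos + del_len - 1L else pos
  m <- .g2t(tx, c(g_lo, g_hi), flank = flank)
  offs <- m$offset
  any_exonic <- any(offs == 0L)
  cc <- .t2c(tx, m$tx_pos)
  cds_len <- tx$cds_end - tx$cds_start + 1L
  touches_cds <- any_exonic && any(cc$region[offs == 0L] == "cds")

  if (!any_exonic) {
    ao <- min(abs(offs))
    cls <- if (ao <= 2L) "canonical_splice"
           else if (ao <= 8L) "splice_region" else "intronic"
    lab1 <- format_c_position(cc$c_pos[1], offs[1], cc$region[1])
    lab2 <- sub("^c\\.", "", format_c_position(cc$c_pos[2], offs[2], cc$region[2]))
    core <- if (g_lo == g_hi && del_len <= 1L) lab1 else paste0(lab1, "_", lab2)
    kind <- if (del_len > 0L && ins_len > 0L) "delins"
            else if (del_len > 0L) "del" else "ins"
    chg <- paste0(core, kind, if (ins_len > 0L) alt else "")
  } else if (any(offs != 0L)) {
    # footprint partially exonic, partially intronic: the indel disrupts an
    # exon/intron boundary and with it the splice site
    cls <- "canonical_splice"
    chg <- paste0("c.", .c_label(tx, min(m$tx_pos)), "_",
                  .c_label(tx, max(m$tx_pos)), "del")
  } else if (!touches_cds) {
    cls <- "utr"
    chg <- paste0(format_c_position(cc$c_pos[1], 0L, cc$region[1]),
                  if (del_len > 0L) "del" else paste0("ins", alt))
  } else {
    cls <- if (net %% 3L != 0L) "frameshift" else "inframe_indel"
    # transcript-order coordinates of the affected window
    tpos <- sort(m$tx_pos)
    if (del_len > 0L && ins_len == 0L) {
      w <- .shift3(tx$seq, tpos[1], tpos[2])
      l1 <- .c_label(tx, w[1]); l2 <- .c_label(tx, w[2])
      chg <- if (w[1] == w[2]) paste0("c.", l1, "del")
             else paste0("c.", l1, "_", l2, "del")
    } else if (del_len == 0L && ins_len > 0L) {
      ins_t <- if (tx$strand == "-") .revcomp(alt) else alt
      t_after <- if (tx$strand == "-") min(m$tx_pos) + 1L else max(m$tx_pos)
      t_before <- t_after - 1L
      if (t_before >= ins_len &&
          substring(tx$seq, t_before - ins_len + 1L, t_before) == ins_t) {
        l1 <- .c_label(tx, t_before - ins_len + 1L)
        l2 <- .c_label(tx, t_before)
        chg <- if (ins_len == 1L) paste0("c.", l2, "dup")
               else paste0("c.", l1, "_", l2, "dup")
      } else {
        chg <- paste0("c.", .c_label(tx, t_before), "_", .c_label(tx, t_after),
                      "ins", ins_t)
      }
    } else {
      alt_t <- if (tx$strand == "-") .revcomp(alt) else alt
      chg <- paste0("c.", .c_label(tx, tpos[1]), "_", .c_label(tx, tpos[2]),
                    "delins", alt_t)
    }
  }
  p_h <- NA_character_
  ord <- NA_integer_
  if (cls %in% c("frameshift", "inframe_indel")) {
    first_cds <- min(cc$c_pos[offs == 0L & cc$region == "cds"])
    ord <- codon_index(first_cds)$codon_ordinal
    if (cls == "frameshift") {
      aa <- substring(translate_transcript(tx), ord, ord)
      p_h <- paste0("p.", .aa3(aa), ord, "fs")
    }
  }
  data.frame(
    class = cls, c_hgvs = chg, p_hgvs = p_h,
    codon_ordinal = ord, codon_offset = NA_integer_,
    ref_aa = NA_character_, alt_aa = NA_character_,
    c_pos = cc$c_pos[1], intron_offset = offs[1], region = cc$region[1],
    stringsAsFactors = FALSE
  )
}

#' Classify the consequence of one variant on a transcript
#'
#' Normalizes the allele pair, maps it through the transcript model and
#' returns the consequence class with HGVS c. and (where defined) p. names.
#' Substitutions in the CDS are translated against the transcript codon;
#' intronic changes within 2 nt of an exon boundary are canonical splice
#' variants (no protein name); coding-length-changing indels are frameshift
#' when the net length change is not a multiple of 3. Minus-strand transcripts
#' are handled by complementing alleles into transcript space.
#'
#' @param tx A [transcript_model()].
#' @param pos Genomic position (VCF POS).
#' @param ref,alt Reference and alternate alleles (VCF style; single alt).
#' @param genome Optional named character vector of contig sequences, used to
#'   verify the reference allele at intronic positions.
#' @param check_ref Verify the reference allele against the transcript
#'   sequence (error on mismatch).
#' @return An object of class `consequence_record`: fields `class`, `c_hgvs`,
#'   `p_hgvs`, `codon_ordinal`, `codon_offset`, `ref_aa`, `alt_aa`, `c_pos`,
#'   `intron_offset`, `region`, `transcript_id`, `gene`.
#' @export
classify_consequence <- function(tx, pos, ref, alt, genome = NULL,
                                 check_ref = TRUE) {
  stopifnot(length(pos) == 1L)
  v <- .normalize_alleles(pos, ref, alt)
  row <- if (nchar(v$ref) == 1L && nchar(v$alt) == 1L) {
    .classify_snv_tx(tx, v$pos, v$ref, v$alt, genome = genome,
                     check_ref = check_ref)
  } else {
    .classify_indel_tx(tx, v$pos, v$ref, v$alt, genome = genome)
  }
  rec <- as.list(row)
  rec$transcript_id <- tx$transcript_id
  rec$gene <- tx$gene
  structure(rec, class = "consequence_record")
}

#' @export
print.consequence_record <- function(x, ...) {
  cat(sprintf("%s (%s): %s%s\n", x$gene, x$transcript_id, x$c_hgvs,
              if (!is.na(x$p_hgvs)) paste0("; ", x$p_hgvs) else ""),
      sprintf("  class: %s\n", x$class))
  invisible(x)
}

#' Annotate a variant table against a set of transcript models
#'
#' Each variant is classified against every transcript whose genomic span
#' (plus flank) contains it; a variant therefore belongs to every gene whose
#' transcript it hits. Variants landing on no transcript are dropped with a
#' message.
#'
#' @param variants `data.frame` with columns `chrom`, `pos`, `ref`, `alt`.
#' @param tx_set List of [transcript_model()] objects.
#' @param genomes Optional named list/vector of contig sequences for intronic
#'   reference checks.
#' @param check_ref Passed through to the classifier.
#' @param flank Flanking distance (nt) within which a variant is assigned to a
#'   transcript.
#' @return `data.frame`: one row per variant x transcript, with `key`, `gene`,
#'   `transcript_id`, `class`, `c_hgvs`, `p_hgvs`, `codon_ordinal` and the
#'   coordinate fields.
#' @export
annotate_variants <- function(variants, tx_set, genomes = NULL,
                              check_ref = TRUE, flank = 500L) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  out <- list()
  hit <- logical(nrow(variants))
  for (tx in tx_set) {
    span_lo <- min(tx$exons$start) - flank
    span_hi <- max(tx$exons$end) + flank
    sel <- which(variants$chrom == tx$contig &
                 variants$pos >= span_lo & variants$pos <= span_hi)
    if (!length(sel)) next
    hit[sel] <- TRUE
    vv <- variants[sel, , drop = FALSE]
    norm <- Map(.normalize_alleles, vv$pos, vv$ref, vv$alt)
    npos <- vapply(norm, `[[`, integer(1), "pos")
    nref <- vapply(norm, `[[`, character(1), "ref")
    nalt <- vapply(norm, `[[`, character(1), "alt")
    snv <- nchar(nref) == 1L & nchar(nalt) == 1L
    rows <- vector("list", 2L)
    if (any(snv)) {
      r <- .classify_snv_tx(tx, npos[snv], nref[snv], nalt[snv],
                            genome = genomes, check_ref = check_ref,
                            flank = flank + 1L)
      r <- cbind(vv[snv, c("chrom", "pos", "ref", "alt"), drop = FALSE], r)
      rows[[1]] <- r
    }
    if (any(!snv)) {
      idx <- which(!snv)
      r <- do.call(rbind, lapply(idx, function(i) {
        .classify_indel_tx(tx, npos[i], nref[i], nalt[i], genome = genomes,
                           flank = flank + 1L)
      }))
      r <- cbind(vv[idx, c("chrom", "pos", "ref", "alt"), drop = FALSE], r)
      rows[[2]] <- r
    }
    res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    res$gene <- tx$gene
    res$transcript_id <- tx$transcript_id
    out[[length(out) + 1L]] <- res
  }
  if (any(!hit)) {
    message(sum(!hit), " variant(s) hit no transcript and were dropped")
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  }
  res <- do.call(rbind, out)
  res$key <- .variant_key(res$chrom, res$pos, res$ref, res$alt)
  rownames(res) <- NULL
  res[order(res$chrom, res$pos, res$alt, res$transcript_id), , drop = FALSE]
}
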