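# Coordinate arithmetic between genomic, spliced-transcript and CDS ("c.")
# coordinate systems. All public surfaces are 1-based inclusive; HGVS intronic
# positions are written relative to the nearest exon boundary (c.pos+k on the
# donor side, c.pos-k on the acceptor side).

# transcript-order exon table: for "-" strand transcripts exon 1 is the
# genomically last interval. Returns data.frame(start, end, tx_start, tx_end)
# in transcript order with genomic coords still ascending within each row.
.tx_exons <- function(tx) {
  ex <- tx$exons
  if (tx$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  w <- ex$end - ex$start + 1L
  tx_end <- cumsum(w)
  ex$tx_start <- tx_end - w + 1L
  ex$tx_end <- tx_end
  rownames(ex) <- NULL
  ex
}

# genomic position(s) -> data.frame(tx_pos, offset, exon_ordinal)
# offset 0 = exonic; offset > 0 = intronic, donor side of the anchoring exon;
# offset < 0 = intronic, acceptor side. Ties between flanking exons break
# toward the 5' (donor) exon. Positions outside transcript span +/- flank
# raise an error.
.g2t <- function(tx, g_pos, flank = 5000L) {
  ex <- .tx_exons(tx)
  n <- nrow(ex)
  span_lo <- min(tx$exons$start)
  span_hi <- max(tx$exons$end)
  bad <- g_pos < span_lo - flank | g_pos > span_hi + flank
  if (any(bad)) {
    stop("genomic position ", g_pos[which(bad)[1]], " outside span of ",
         tx$transcript_id, " (+/- ", flank, " nt flank)")
  }
  tx_pos <- integer(length(g_pos))
  offset <- integer(length(g_pos))
  exon_ord <- integer(length(g_pos))
  # exon membership against genomic-ascending order
  asc <- ex[order(ex$start), , drop = FALSE]
  idx <- findInterval(g_pos, asc$start)
  for (i in seq_along(g_pos)) {
    g <- g_pos[i]
    j <- idx[i]
    if (j >= 1L && g <= asc$end[j]) { # exonic
      row <- asc[j, ]
      tx_pos[i] <- if (tx$strand == "+") row$tx_start + (g - row$start)
                   else row$tx_start + (row$end - g)
      offset[i] <- 0L
      exon_ord[i] <- which(ex$start == row$start)
    } else {
      # intronic or flanking: distances to nearest exon edges
      if (j < 1L || j >= nrow(asc) && g > asc$end[nrow(asc)]) {
        # upstream/downstream of the transcript: anchor to terminal exon
        if (g < asc$start[1]) {
          row <- asc[1, ]; d <- row$start - g; side_next <- TRUE
        } else {
          row <- asc[nrow(asc), ]; d <- g - row$end; side_next <- FALSE
        }
        if (tx$strand == "+") {
          tx_pos[i] <- if (side_next) row$tx_start else row$tx_end
          offset[i] <- if (side_next) -d else d
        } else {
          tx_pos[i] <- if (side_next) row$tx_end else row$tx_start
          offset[i] <- if (side_next) d else -d
        }
        exon_ord[i] <- which(ex$start == row$start)
      } else {
        prev <- asc[j, ]; nxt <- asc[j + 1L, ]
        d_prev <- g - prev$end      # distance to genomically-previous exon
        d_next <- nxt$start - g     # distance to genomically-next exon
        if (tx$strand == "+") {
          # previous exon is transcript-5' (donor side, positive offset)
          if (d_prev <= d_next) {
            tx_pos[i] <- prev$tx_end; offset[i] <- d_prev
            exon_ord[i] <- which(ex$start == prev$start)
          } else {
            tx_pos[i] <- nxt$tx_start; offset[i] <- -d_next
            exon_ord[i] <- which(ex$start == nxt$start)
          }
        } else {
          # genomically-next exon is transcript-5' (donor side)
          if (d_next <= d_prev) {
            tx_pos[i] <- nxt$tx_end; offset[i] <- d_next
            exon_ord[i] <- which(ex$start == nxt$start)
          } else {
            tx_pos[i] <- prev$tx_start; offset[i] <- -d_prev
            exon_ord[i] <- which(ex$start == prev$start)
          }
        }
      }
    }
  }
  data.frame(tx_pos = tx_pos, offset = offset, exon_ordinal = exon_ord)
}

# spliced-transcript position -> CDS-relative coordinate
# region: "cds" (pos >= 1), "utr5" (pos < 0, HGVS c.-n), "utr3" (pos > 0, c.*n)
.t2c <- function(tx, tx_pos) {
  region <- ifelse(tx_pos < tx$cds_start, "utr5",
                   ifelse(tx_pos > tx$cds_end, "utr3", "cds"))
  pos <- ifelse(region == "cds", tx_pos - tx$cds_start + 1L,
                ifelse(region == "utr5", tx_pos - tx$cds_start,
                       tx_pos - tx$cds_end))
  data.frame(c_pos = as.integer(pos), region = region)
}

#' Map a genomic position to a coding (c.) coordinate
#'
#' Exonic positions get `intron_offset` 0; intronic positions are expressed
#' relative to the nearest exon boundary (ties broken toward the 5' exon), with
#' negative offsets on the acceptor side and positive on the donor side, as in
#' HGVS `c.275-2`. Strand-aware.
#'
#' @param tx A [transcript_model()].
#' @param g_pos Genomic position (1-based) on the transcript's contig.
#' @param flank Maximum distance outside the transcript span before an
#'   out-of-range error is raised.
#' @return An object of class `coding_coordinate`: list with `pos` (coding
#'   nucleotide, 1-based from the A of the ATG; negative for 5'UTR, stored
#'   against the stop for 3'UTR), `intron_offset`, `region` (`"cds"`,
#'   `"utr5"`, `"utr3"`), and `tx_pos` (spliced-transcript position of the
#'   anchoring exonic base).
#' @export
map_genomic_to_coding <- function(tx, g_pos, flank = 5000L) {
  stopifnot(length(g_pos) == 1L)
  t <- .g2t(tx, g_pos, flank = flank)
  c <- .t2c(tx, t$tx_pos)
  structure(
    list(pos = c$c_pos, intron_offset = t$offset, region = c$region,
         tx_pos = t$tx_pos),
    class = "coding_coordinate"
  )
}

#' @export
print.coding_coordinate <- function(x, ...) {
  cat("coding_coordinate:", format_c_position(x$pos, x$intron_offset, x$region), "\n")
  invisible(x)
}

# label for the coding part of an HGVS c. position
format_c_position <- function(c_pos, intron_offset = 0L, region = "cds") {
  base <- switch(region,
    cds = as.character(c_pos),
    utr5 = as.character(c_pos),             # already negative -> "-12"
    utr3 = paste0("*", c_pos)
  )
  if (intron_offset == 0L) paste0("c.", base)
  else paste0("c.", base, sprintf("%+d", intron_offset))
}

#' Map a coding coordinate back to a genomic position
#'
#' Inverse of [map_genomic_to_coding()] on the supported range.
#'
#' @param tx A [transcript_model()].
#' @param c_pos Coding position (negative values = 5'UTR as in HGVS `c.-n`).
#' @param intron_offset Signed intronic offset (0 for exonic).
#' @param region `"cds"`, `"utr5"` or `"utr3"` (for `"utr3"`, `c_pos` counts
#'   from the base after the stop codon, HGVS `c.*n`).
#' @return Genomic position (integer).
#' @export
coding_to_genomic <- function(tx, c_pos, intron_offset = 0L, region = "cds") {
  tx_pos <- switch(region,
    cds = tx$cds_start + c_pos - 1L,
    utr5 = tx$cds_start + c_pos,
    utr3 = tx$cds_end + c_pos,
    stop("unknown region: ", region)
  )
  if (tx_pos < 1L || tx_pos > nchar(tx$seq)) {
    stop("coding position maps outside transcript (tx_pos = ", tx_pos, ")")
  }
  ex <- .tx_exons(tx)
  k <- which(tx_pos >= ex$tx_start & tx_pos <= ex$tx_end)
  g <- if (tx$strand == "+") ex$start[k] + (tx_pos - ex$tx_start[k])
       else ex$end[k] - (tx_pos - ex$tx_start[k])
  # positive offset = transcript-downstream-of-exon-end direction (donor);
  # on the genome that is +offset for "+" strand, -offset for "-" strand
  if (tx$strand == "+") as.integer(g + intron_offset)
  else as.integer(g - intron_offset)
}

#' Codon ordinal and within-codon offset of a coding position
#'
#' `codon_ordinal = floor((c_pos - 1)/3) + 1`;
#' `codon_offset = ((c_pos - 1) mod 3) + 1`. The arithmetic behind protein-level
#' HGVS names: c.281 lies at offset 2 of codon 94, c.85 at offset 1 of codon 29.
#'
#' @param c_pos Coding nucleotide position(s), 1-based from the A of the ATG.
#' @param cds_length Optional CDS length (nt); positions beyond it error.
#' @return `data.frame` with columns `codon_ordinal`, `codon_offset`.
#' @export
codon_index <- function(c_pos, cds_length = NULL) {
  c_pos <- as.integer(c_pos)
  if (any(c_pos < 1L)) stop("coding position must be >= 1")
  if (!is.null(cds_length) && any(c_pos > cds_length)) {
    stop("coding position ", c_pos[which(c_pos > cds_length)[1]],
         " beyond CDS length ", cds_length)
  }
  data.frame(
    codon_ordinal = (c_pos - 1L) %/% 3L + 1L,
    codon_offset = (c_pos - 1L) %% 3L + 1L
  )
}
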