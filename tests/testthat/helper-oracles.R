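# Independent brute-force oracles used to cross-check the implementation.

# consequence of a CDS substitution by rebuilding the whole mutant CDS and
# diffing the translations (independent of the codon-arithmetic path)
oracle_snv_class <- function(tx, c_pos, alt_t) {
  cds <- transcript_cds(tx)
  stopifnot(c_pos >= 1, c_pos <= nchar(cds))
  mut <- paste0(substring(cds, 1, c_pos - 1), alt_t, substring(cds, c_pos + 1))
  # translate codon 1 literally: an altered initiator must not be rescued by
  # the alternative-initiation rule, or a lost start looks synonymous
  p_ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                              no.init.codon = TRUE))
  p_mut <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                              no.init.codon = TRUE))
  if (p_ref == p_mut) return("synonymous")
  a <- strsplit(p_ref, "")[[1]]
  b <- strsplit(p_mut, "")[[1]]
  d <- which(a != b)[1]
  if (d == 1 && a[1] == "M") return("start_lost")
  if (b[d] == "*") return("stop_gained")
  if (a[d] == "*") return("stop_lost")
  "missense"
}

# naive O(n*m) interval membership with a window
oracle_in_regions <- function(chrom, pos, reg_df, window) {
  any(reg_df$chrom == chrom &
        pos >= reg_df$start - window & pos <= reg_df$end + window)
}

# frequency rule applied row by row
oracle_freq_keep <- function(key, fkeys, fmaf, threshold) {
  m <- fmaf[fkeys == key]
  length(m) == 0L || max(m) < threshold
}

# trio consistency by enumerating transmitted-allele assignments
oracle_trio <- function(child, father, mother) {
  if (is.na(child)) return(TRUE)
  alleles <- function(g) switch(as.character(g),
                                `0` = list(c(0, 0)), `1` = list(c(0, 1)),
                                `2` = list(c(1, 1)))
  opts <- function(g) if (is.na(g)) c(0, 1) else unique(alleles(g)[[1]])
  ch <- sort(alleles(child)[[1]])
  for (a in opts(father)) for (b in opts(mother)) {
    if (all(sort(c(a, b)) == ch)) return(TRUE)
  }
  FALSE
}

# two-sided exact binomial p-value by direct summation of the mass function
oracle_binom_p <- function(x, n, p) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= dbinom(x, n, p) * (1 + 1e-7)])
}
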