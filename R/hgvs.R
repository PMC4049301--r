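# HGVS coding-DNA (c.) nomenclature: a parser/formatter for the subset used
# throughout panel filtering reports: substitutions (c.281G>A, c.275-2A>C,
# c.-12A>G, c.*33T>C), and deletions/insertions/duplications of explicit
# sequences (c.10_12del, c.10_11insACT, c.8_10dup).

.HGVS_POS_RE <- "(\\*?-?\\d+)([+-]\\d+)?"

.parse_c_position <- function(pos_txt, off_txt) {
  region <- "cds"
  if (startsWith(pos_txt, "*")) {
    region <- "utr3"
    pos <- as.integer(substring(pos_txt, 2L))
  } else {
    pos <- as.integer(pos_txt)
    if (pos < 0L) region <- "utr5"
  }
  offset <- if (is.na(off_txt) || off_txt == "") 0L else as.integer(off_txt)
  list(pos = pos, region = region, offset = offset)
}

#' Parse an HGVS c. variant description
#'
#' Supported grammar: substitutions `c.<pos>R>A` with optional intronic offset
#' (`c.275-2A>C`) and UTR positions (`c.-12`, `c.*33`); `del`, `ins` and `dup`
#' of explicit sequences with single or `start_end` positions. Anything else
#' raises an unsupported-syntax error.
#'
#' @param text HGVS string beginning `c.`.
#' @return List with `type` (`"sub"`, `"del"`, `"ins"`, `"dup"`), `pos`,
#'   `offset`, `region` and, per type, `ref`/`alt` or `seq`, plus `end_pos`,
#'   `end_offset`, `end_region` for ranged forms.
#' @export
parse_hgvs_c <- function(text) {
  stopifnot(length(text) == 1L)
  sub_re <- paste0("^c\\.", .HGVS_POS_RE, "([ACGT])>([ACGT])$")
  if (grepl(sub_re, text)) {
    m <- regmatches(text, regexec(sub_re, text))[[1]]
    p <- .parse_c_position(m[2], m[3])
    return(list(type = "sub", pos = p$pos, offset = p$offset, region = p$region,
                ref = m[4], alt = m[5]))
  }
  range_re <- paste0("^c\\.", .HGVS_POS_RE, "(?:_", .HGVS_POS_RE,
                     ")?(delins|del|dup|ins)([ACGT]*)$")
  if (grepl(range_re, text, perl = TRUE)) {
    m <- regmatches(text, regexec(range_re, text, perl = TRUE))[[1]]
    p1 <- .parse_c_position(m[2], m[3])
    has_end <- m[4] != ""
    p2 <- if (has_end) .parse_c_position(m[4], m[5]) else p1
    kind <- m[6]
    seq <- m[7]
    if (kind == "ins" && (!has_end || seq == "")) {
      stop("unsupported HGVS syntax: ", text,
           " (ins requires a start_end range and an explicit sequence)")
    }
    return(list(type = kind, pos = p1$pos, offset = p1$offset, region = p1$region,
                end_pos = p2$pos, end_offset = p2$offset, end_region = p2$region,
                seq = if (seq == "") NA_character_ else seq))
  }
  stop("unsupported HGVS syntax: ", text)
}

#' Format a parsed HGVS c. description back to text
#'
#' Inverse of [parse_hgvs_c()] on the supported subset:
#' `format_hgvs_c(parse_hgvs_c(x)) == x`.
#'
#' @param x List as returned by [parse_hgvs_c()].
#' @return HGVS string.
#' @export
format_hgvs_c <- function(x) {
  p1 <- format_c_position(x$pos, x$offset, x$region)
  if (x$type == "sub") {
    return(paste0(p1, x$ref, ">", x$alt))
  }
  ranged <- !is.null(x$end_pos) &&
    !(x$end_pos == x$pos && x$end_offset == x$offset && x$end_region == x$region)
  p2 <- if (ranged || x$type == "ins") {
    sub("^c\\.", "", format_c_position(x$end_pos, x$end_offset, x$end_region))
  } else NULL
  core <- if (is.null(p2)) p1 else paste0(p1, "_", p2)
  seq <- if (is.null(x$seq) || is.na(x$seq)) "" else x$seq
  paste0(core, x$type, seq)
}

# protein-level HGVS for a single-codon substitution
.format_p_sub <- function(ref_aa, ord, alt_aa) {
  if (ref_aa == alt_aa) return(paste0("p.", .aa3(ref_aa), ord, "="))
  if (alt_aa == "*") return(paste0("p.", .aa3(ref_aa), ord, "*"))
  if (ref_aa == "*") return(paste0("p.*", ord, .aa3(alt_aa), "ext*?"))
  paste0("p.", .aa3(ref_aa), ord, .aa3(alt_aa))
}
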