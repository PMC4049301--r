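# Pedigree-based Mendelian consistency and autosomal-recessive co-segregation
# testing: the logic that keeps a candidate gene when every genotyped affected
# family member is biallelic and no genotyped unaffected member is, and throws
# it out otherwise (e.g. unaffected relatives homozygous for both candidate
# variants).

.gt_alleles <- function(code) {
  # alt allele count -> unordered allele pair (0 = ref, 1 = alt)
  switch(as.character(code), `0` = c(0L, 0L), `1` = c(0L, 1L), `2` = c(1L, 1L),
         stop("malformed genotype code: ", code))
}

#' Mendelian consistency of a parent-offspring trio at one biallelic site
#'
#' A trio is consistent when the child's two alleles can be drawn one from
#' each parent. A missing parental genotype leaves that allele unconstrained
#' (consistent by default).
#'
#' @param child,father,mother Genotypes as alt allele counts (0, 1, 2) or
#'   `NA` for missing.
#' @return List with `consistent` (logical) and `detail` (character; e.g. a
#'   de novo flag when both parents lack an allele the child carries).
#' @export
mendelian_check <- function(child, father, mother) {
  if (is.na(child)) return(list(consistent = TRUE, detail = "child ungenotyped"))
  ch <- .gt_alleles(child)
  # candidate transmitted alleles per parent (NA genotype -> either allele)
  opts <- function(g) if (is.na(g)) c(0L, 1L) else unique(.gt_alleles(g))
  fo <- opts(father)
  mo <- opts(mother)
  ok <- any(vapply(fo, function(a) {
    any(vapply(mo, function(b) all(sort(c(a, b)) == sort(ch)), logical(1)))
  }, logical(1)))
  detail <- if (ok) "" else if (child >= 1L && !is.na(father) && !is.na(mother) &&
                                father == 0L && mother == 0L) {
    "de novo: child alt allele absent from both parents"
  } else "allele not traceable to a parent"
  list(consistent = ok, detail = detail)
}

#' Phase two heterozygous variants from parental genotypes
#'
#' For a proband heterozygous at two sites in one gene: `trans` when each
#' parent carries exactly one of the two variants (a true compound
#' heterozygote), `cis` when one parent carries both and the other neither,
#' `unknown` otherwise (including any missing parental genotype).
#'
#' @param father,mother Length-2 vectors: the parent's alt allele counts at
#'   variant A and variant B (`NA` = missing).
#' @return `"trans"`, `"cis"`, or `"unknown"`.
#' @export
trans_phase_from_parents <- function(father, mother) {
  stopifnot(length(father) == 2L, length(mother) == 2L)
  if (anyNA(father) || anyNA(mother)) return("unknown")
  fc <- father >= 1L
  mc <- mother >= 1L
  if (sum(fc) == 1L && sum(mc) == 1L && !identical(fc, mc)) return("trans")
  if ((all(fc) && !any(mc)) || (all(mc) && !any(fc))) return("cis")
  "unknown"
}

# biallelic status of one individual for a set of gene variants
# returns list(status = "biallelic"|"carrier"|"none"|"ungenotyped",
#              phase_verified = logical)
.biallelic_status <- function(g, ped_row = NULL, gt = NULL, variant_ids = NULL) {
  if (all(is.na(g))) return(list(status = "ungenotyped", phase_verified = NA))
  if (any(!is.na(g) & g == 2L)) {
    return(list(status = "biallelic", phase_verified = TRUE))
  }
  het_idx <- which(!is.na(g) & g == 1L)
  if (length(het_idx) >= 2L) {
    phase <- "unknown"
    if (!is.null(ped_row) && !is.null(gt)) {
      pat <- ped_row$pat
      mat <- ped_row$mat
      if (pat %in% colnames(gt) && mat %in% colnames(gt)) {
        ids <- variant_ids[het_idx[1:2]]
        phase <- trans_phase_from_parents(gt[ids, pat], gt[ids, mat])
      }
    }
    if (phase == "cis") {
      return(list(status = "carrier", phase_verified = TRUE))
    }
    return(list(status = "biallelic", phase_verified = phase == "trans"))
  }
  if (length(het_idx) == 1L) return(list(status = "carrier", phase_verified = TRUE))
  list(status = "none", phase_verified = TRUE)
}

#' Autosomal-recessive co-segregation test for one gene in one pedigree
#'
#' The candidate genotype configuration `supports` the gene when every
#' genotyped affected individual is biallelic (homozygous alternate, or
#' carrying two heterozygous variants -- established in trans where both
#' parents are genotyped) and no genotyped unaffected individual is
#' biallelic; it `excludes` the gene when any genotyped unaffected individual
#' is biallelic or any genotyped affected is not; it is `uninformative` when
#' no affected individual is genotyped. Double-het affecteds whose phase
#' cannot be established still support, flagged `phase_verified = FALSE`.
#'
#' @param ped Pedigree `data.frame` (one family) as from [read_ped()].
#' @param gt Integer genotype matrix for the gene's candidate variants
#'   (variants x individuals; alt allele counts, `NA` missing). Individuals
#'   absent from the columns are treated as ungenotyped.
#' @param gene Gene symbol (carried through to the verdict).
#' @return An object of class `segregation_verdict`: `gene`, `model`
#'   (`"autosomal_recessive"`), `status` (`supports` / `excludes` /
#'   `uninformative`), `phase_verified`, and `reasons` (character vector; at
#'   least one reason accompanies every exclusion).
#' @export
cosegregation_test <- function(ped, gt, gene = "gene") {
  stopifnot(is.matrix(gt))
  if (nrow(gt) == 0L) {
    return(structure(
      list(gene = gene, model = "autosomal_recessive",
           status = "uninformative", phase_verified = NA,
           reasons = "no candidate variants genotyped for this gene"),
      class = "segregation_verdict"
    ))
  }
  ped <- ped[order(ped$iid), , drop = FALSE] # verdict invariant to file order
  reasons <- character(0)
  affected_seen <- 0L
  affected_ok <- TRUE
  unaffected_biallelic <- FALSE
  phase_all_verified <- TRUE
  for (i in seq_len(nrow(ped))) {
    iid <- ped$iid[i]
    if (!iid %in% colnames(gt)) next
    g <- gt[, iid]
    if (all(is.na(g))) next
    st <- .biallelic_status(g, ped_row = ped[i, ], gt = gt,
                            variant_ids = rownames(gt))
    if (ped$pheno[i] == 2L) {
      affected_seen <- affected_seen + 1L
      if (st$status != "biallelic") {
        affected_ok <- FALSE
        reasons <- c(reasons, paste0("affected ", iid,
                                     " is not biallelic (status: ", st$status, ")"))
      } else if (!isTRUE(st$phase_verified)) {
        phase_all_verified <- FALSE
      }
    } else if (ped$pheno[i] == 1L) {
      if (st$status == "biallelic" && isTRUE(st$phase_verified)) {
        unaffected_biallelic <- TRUE
        reasons <- c(reasons, paste0("unaffected ", iid,
                                     " carries the candidate variants in biallelic form"))
      }
    }
  }
  status <- if (affected_seen == 0L) "uninformative"
            else if (unaffected_biallelic || !affected_ok) "excludes"
            else "supports"
  structure(
    list(gene = gene, model = "autosomal_recessive", status = status,
         phase_verified = if (status == "supports") phase_all_verified else NA,
         reasons = if (length(reasons)) reasons else
           if (status == "uninformative") "no genotyped affected individual"
           else character(0)),
    class = "segregation_verdict"
  )
}

#' @export
print.segregation_verdict <- function(x, ...) {
  cat(sprintf("segregation_verdict: %s under %s -> %s%s\n", x$gene, x$model,
              x$status,
              if (identical(x$phase_verified, FALSE)) " (phase unverified)" else ""))
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}

#' Co-segregation verdicts for candidate genes across all families
#'
#' @param ped Full pedigree table (all families).
#' @param gt Cohort genotype matrix (variants x samples).
#' @param annotation Variant annotation table (must contain `gene` and the
#'   variant ids in an `id` column).
#' @param genes_by_family Named list: family id -> character vector of
#'   candidate genes to test in that family.
#' @return `data.frame` with columns `family, gene, status, phase_verified,
#'   reasons` (reasons collapsed with "; ").
#' @export
segregation_table <- function(ped, gt, annotation, genes_by_family) {
  rows <- list()
  for (fam in names(genes_by_family)) {
    fped <- ped[ped$fid == fam, , drop = FALSE]
    for (gene in genes_by_family[[fam]]) {
      ids <- unique(annotation$id[annotation$gene == gene])
      ids <- ids[ids %in% rownames(gt)]
      sub <- gt[ids, , drop = FALSE]
      # restrict to variants actually carried by a genotyped family member
      fam_cols <- intersect(fped$iid, colnames(sub))
      carried <- rowSums(sub[, fam_cols, drop = FALSE] >= 1L, na.rm = TRUE) > 0L
      v <- cosegregation_test(fped, sub[carried, , drop = FALSE], gene = gene)
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, gene = gene, status = v$status,
        phase_verified = v$phase_verified,
        reasons = paste(v$reasons, collapse = "; "),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(family = character(0), gene = character(0),
                      status = character(0), phase_verified = logical(0),
                      reasons = character(0)))
  }
  do.call(rbind, rows)
}
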