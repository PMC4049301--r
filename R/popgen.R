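# Hardy-Weinberg carrier-frequency consistency: is the heterozygous carrier
# count of a putatively pathogenic allele in a control exome database
# compatible with the disease prevalence under a recessive model?

#' Prevalence model for a recessive disease locus
#'
#' @param prevalence_low,prevalence_high Birth-incidence bounds as fractions
#'   (defaults 1/30000 and 1/15000, the cited PCD prevalence range).
#' @param locus_share Fraction of disease attributable to this gene/allele in
#'   (0, 1]. The default 0.04 is an order-of-magnitude placeholder for one
#'   gene among the many that cause the disease; it is configurable and
#'   flagged in output.
#' @return A list of class `prevalence_model`.
#' @export
prevalence_model <- function(prevalence_low = 1 / 30000,
                             prevalence_high = 1 / 15000,
                             locus_share = 0.04) {
  stopifnot(prevalence_low > 0, prevalence_low <= prevalence_high,
            prevalence_high < 1, locus_share > 0, locus_share <= 1)
  structure(
    list(prevalence_low = prevalence_low, prevalence_high = prevalence_high,
         locus_share = locus_share),
    class = "prevalence_model"
  )
}

#' Carrier observation from a control database
#'
#' @param het Heterozygous carriers observed.
#' @param n Individuals sampled.
#' @param hom Homozygous carriers observed (expected 0 for a fully penetrant
#'   pathogenic allele in unaffected controls).
#' @return A list of class `carrier_observation`.
#' @export
carrier_observation <- function(het, n, hom = 0L) {
  stopifnot(n > 0, het >= 0, hom >= 0, het + hom <= n)
  structure(list(het = as.integer(het), n = as.integer(n),
                 hom = as.integer(hom)),
            class = "carrier_observation")
}

#' Allele frequency from carrier counts
#'
#' `q = (het + 2*hom) / (2*n)`.
#'
#' @param obs A [carrier_observation()].
#' @return Estimated allele frequency.
#' @export
allele_freq_from_carriers <- function(obs) {
  stopifnot(inherits(obs, "carrier_observation"))
  if (obs$n <= 0) stop("individuals sampled must be positive")
  (obs$het + 2 * obs$hom) / (2 * obs$n)
}

#' Expected carrier-frequency range under Hardy-Weinberg equilibrium
#'
#' For each prevalence bound P, the pathogenic allele frequency is
#' `q = sqrt(P * locus_share)` and the carrier frequency `2q(1 - q)`.
#' As P -> 0 this approaches `2*sqrt(P*share)`.
#'
#' @param model A [prevalence_model()].
#' @return Named numeric vector `c(low = ..., high = ...)`.
#' @export
expected_carrier_freq <- function(model) {
  stopifnot(inherits(model, "prevalence_model"))
  q <- sqrt(c(low = model$prevalence_low, high = model$prevalence_high) *
            model$locus_share)
  2 * q * (1 - q)
}

#' Carrier-frequency consistency test
#'
#' Tests the observed heterozygous carrier count against
#' `Binomial(n, expected carrier frequency)` at each prevalence bound
#' (two-sided exact binomial test, [stats::binom.test()]). The observation is
#' `consistent` with a pathogenic allele when it does not exceed the upper
#' `1 - alpha` binomial quantile at the high-prevalence bound, or when the
#' exact test is non-significant at either bound: only an upper-tail excess
#' ("too common to be pathogenic") drives inconsistency. Homozygous carriers
#' in a control set are flagged separately.
#'
#' @param obs A [carrier_observation()].
#' @param model A [prevalence_model()].
#' @param alpha Significance level (default 0.05).
#' @return List of class `carrier_verdict`: `verdict` (`"consistent"` /
#'   `"inconsistent"`), `p_low`, `p_high` (exact p-values at the two
#'   prevalence bounds), `expected_carrier_freq` (range), `observed_freq`,
#'   `upper_bound` (count), `hom_flag`, `locus_share`.
#' @export
carrier_consistency_test <- function(obs, model = prevalence_model(),
                                     alpha = 0.05) {
  stopifnot(inherits(obs, "carrier_observation"),
            inherits(model, "prevalence_model"))
  cf <- expected_carrier_freq(model)
  p_low <- stats::binom.test(obs$het, obs$n, cf[["low"]])$p.value
  p_high <- stats::binom.test(obs$het, obs$n, cf[["high"]])$p.value
  ub <- stats::qbinom(1 - alpha, obs$n, cf[["high"]])
  consistent <- obs$het <= ub || max(p_low, p_high) > alpha
  structure(
    list(
      verdict = if (consistent) "consistent" else "inconsistent",
      p_low = p_low, p_high = p_high,
      expected_carrier_freq = cf,
      observed_freq = obs$het / obs$n,
      upper_bound = ub,
      hom_flag = obs$hom > 0L,
      locus_share = model$locus_share, alpha = alpha
    ),
    class = "carrier_verdict"
  )
}

#' @export
print.carrier_verdict <- function(x, ...) {
  cat(sprintf(
    paste0("carrier_verdict: %s (observed carrier freq %.5f vs expected ",
           "%.5f-%.5f at locus share %.2f)\n"),
    x$verdict, x$observed_freq, x$expected_carrier_freq[["low"]],
    x$expected_carrier_freq[["high"]], x$locus_share
  ))
  cat(sprintf("  exact binomial p: %.3g (low bound), %.3g (high bound)\n",
              x$p_low, x$p_high))
  if (x$hom_flag) {
    cat("  NOTE: homozygous carriers observed in the control set\n")
  }
  cat("  NOTE: locus_share is a configurable placeholder, not an estimate\n")
  invisible(x)
}
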