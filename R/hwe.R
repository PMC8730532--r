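#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on the heterozygote count conditional on the allele
#' counts (the Wigginton-style exact test): the p-value is the sum of the
#' probabilities of all heterozygote configurations no more probable than the
#' observed one.  The exact test is used by default because the usual QC
#' threshold (1e-6) sits far in the tail where the chi-square approximation is
#' unreliable; `method = "chisq"` gives the 1-df goodness-of-fit test instead.
#'
#' @param n_hom_ref count of reference-homozygote genotypes
#' @param n_het count of heterozygotes
#' @param n_hom_alt count of alternate-homozygote genotypes
#' @param method `"exact"` (default) or `"chisq"`
#' @return p-value in `[0, 1]`; monomorphic input returns 1
#' @examples
#' hwe_test(0, 0, 100)    # monomorphic -> 1
#' hwe_test(25, 50, 25)   # the most probable configuration
#' @export
hwe_test <- function(n_hom_ref, n_het, n_hom_alt,
                     method = c("exact", "chisq")) {
  method <- match.arg(method)
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_herimap("genotype counts must be non-negative integers",
                 "herimap_value_error")
  }
  n <- sum(counts)
  if (n == 0) {
    stop_herimap("all genotype counts are zero", "herimap_value_error")
  }
  rare <- min(2 * n_hom_alt + n_het, 2 * n_hom_ref + n_het)
  if (rare == 0) return(1)
  if (method == "chisq") {
    p <- (2 * n_hom_alt + n_het) / (2 * n)
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((counts - e)^2 / e)
    return(pchisq(stat, df = 1, lower.tail = FALSE))
  }
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(het = h | n genotypes, `rare` copies of the rare allele)
  logp <- hets * log(2) + lfactorial(n) -
    lfactorial((rare - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (rare + hets) / 2) +
    lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- match(n_het, hets)
  if (is.na(obs)) {
    stop_herimap("heterozygote count inconsistent with allele counts",
                 "herimap_value_error")
  }
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-12)]))
}
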