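#' Quality-filter a genotype matrix
#'
#' Applies the standard marker- and sample-level filters in a fixed order:
#' first variants (folded MAF, per-variant missingness, exact Hardy-Weinberg
#' test), then samples (per-sample missingness on the retained variants).  A
#' variant is attributed to the first filter it fails, in the order
#' MAF -> missingness -> HWE.  Missing dosages are retained through QC; they
#' are mean-imputed only at standardization time.
#'
#' @param g a [genotype_matrix()]
#' @param maf_min variants with folded MAF `<= maf_min` are removed
#' @param variant_missing_max variants with missing fraction `> this` removed
#'   (call rate below `1 - variant_missing_max`)
#' @param hwe_alpha variants with exact HWE p `< hwe_alpha` removed
#' @param sample_missing_max samples with missing fraction `>= this` removed
#' @return list with elements `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (a `qc_report`)
#' @export
qc_filter <- function(g, maf_min = 0.001, variant_missing_max = 0.02,
                      hwe_alpha = 1e-6, sample_missing_max = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  dos <- g$dosages
  n0 <- nrow(dos); m0 <- ncol(dos)
  if (n0 == 0 || m0 == 0) {
    stop_herimap("empty genotype matrix", "herimap_value_error")
  }

  maf <- variant_maf(dos)
  vmiss <- colMeans(is.na(dos))
  fail_maf <- maf <= maf_min
  fail_miss <- !fail_maf & vmiss > variant_missing_max
  todo <- which(!fail_maf & !fail_miss)
  hwe_p <- rep(NA_real_, m0)
  for (j in todo) {
    x <- dos[, j]
    hwe_p[j] <- hwe_test(sum(x == 0, na.rm = TRUE),
                         sum(x == 1, na.rm = TRUE),
                         sum(x == 2, na.rm = TRUE))
  }
  fail_hwe <- !fail_maf & !fail_miss & !is.na(hwe_p) & hwe_p < hwe_alpha
  keep_v <- !(fail_maf | fail_miss | fail_hwe)
  if (!any(keep_v)) {
    stop_herimap(
      "all variants removed by QC; review maf_min/variant_missing_max/hwe_alpha",
      "herimap_qc_error")
  }

  dos_v <- dos[, keep_v, drop = FALSE]
  smiss <- rowMeans(is.na(dos_v))
  keep_s <- smiss < sample_missing_max
  if (!any(keep_s)) {
    stop_herimap("all samples removed by QC; review sample_missing_max",
                 "herimap_qc_error")
  }

  out <- genotype_matrix(dos_v[keep_s, , drop = FALSE],
                         g$variants[keep_v, ],
                         samples = g$samples[keep_s])
  report <- structure(list(
    variants = list(input = m0,
                    removed_maf = sum(fail_maf),
                    removed_missing = sum(fail_miss),
                    removed_hwe = sum(fail_hwe),
                    retained = sum(keep_v)),
    samples = list(input = n0,
                   removed_missing = sum(!keep_s),
                   retained = sum(keep_s)),
    thresholds = list(maf_min = maf_min,
                      variant_missing_max = variant_missing_max,
                      hwe_alpha = hwe_alpha,
                      sample_missing_max = sample_missing_max)),
    class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  v <- x$variants; s <- x$samples; t <- x$thresholds
  cat("<qc_report>\n")
  cat(sprintf("  variants: %d in, %d removed (MAF<=%g: %d; missing>%g: %d; HWE p<%g: %d), %d retained\n",
              v$input, v$input - v$retained, t$maf_min, v$removed_maf,
              t$variant_missing_max, v$removed_missing, t$hwe_alpha,
              v$removed_hwe, v$retained))
  cat(sprintf("  samples:  %d in, %d removed (missing>=%g), %d retained\n",
              s$input, s$removed_missing, t$sample_missing_max, s$retained))
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) {
  tibble(
    axis = c(rep("variant", 3L), "sample"),
    filter = c("maf", "missingness", "hwe", "missingness"),
    removed = c(x$variants$removed_maf, x$variants$removed_missing,
                x$variants$removed_hwe, x$samples$removed_missing))
}

#' Serialize a QC report to JSON
#' @param x a `qc_report`
#' @param path output file
#' @export
write_qc_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Flag samples with outlying heterozygosity
#'
#' Optional sample filter (off by default in the pipeline): reports samples
#' whose heterozygosity rate deviates more than `n_sd` standard deviations
#' from the sample mean.
#'
#' @param g a [genotype_matrix()]
#' @param n_sd deviation threshold in standard deviations
#' @return character vector of outlier sample IDs (possibly empty)
#' @export
het_outliers <- function(g, n_sd = 3) {
  het <- rowMeans(g$dosages == 1, na.rm = TRUE)
  dev <- abs(het - mean(het))
  g$samples[dev > n_sd * sd(het)]
}
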