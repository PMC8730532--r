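#' Standardize a genotype matrix
#'
#' Each dosage is centred and scaled by its variant's observed alternate-allele
#' frequency: `w = (x - 2p) / sqrt(2 p (1 - p))`, with `p` estimated over
#' non-missing calls in the sample itself (no external reference panel).
#' Missing dosages are mean-imputed, i.e. set to 0 after standardization.
#'
#' @param g a [genotype_matrix()] (post-QC: every variant polymorphic)
#' @return `N x M` numeric matrix with column means 0 over non-missing entries
#' @export
standardize_genotypes <- function(g) {
  dos <- g$dosages
  p <- colMeans(dos, na.rm = TRUE) / 2
  mono <- p <= 0 | p >= 1 | is.nan(p)
  if (any(mono)) {
    stop_herimap(
      sprintf("monomorphic variant(s) cannot be standardized: %s",
              paste(g$variants$id[mono], collapse = ", ")),
      "herimap_value_error")
  }
  w <- sweep(dos, 2, 2 * p, "-")
  w <- sweep(w, 2, sqrt(2 * p * (1 - p)), "/")
  w[is.na(w)] <- 0
  w
}

#' Compute the genetic relationship matrix
#'
#' The GRM entry for samples `k, l` is `(1/M_kl) * sum_j w_kj w_lj` over
#' standardized dosages, where `M_kl` counts variants non-missing in both
#' samples.  With complete data this is exactly `W W' / M`.  Pairwise-complete
#' denominators are used so that sparse missingness does not shrink
#' relatedness toward zero (with mean imputation the two conventions coincide
#' in expectation).
#'
#' @param g a [genotype_matrix()] that has passed QC
#' @return object of class `grm` with elements `values` (`N x N` symmetric),
#'   `samples`, and `pair_snp_counts`
#' @export
compute_grm <- function(g) {
  w <- standardize_genotypes(g)
  nonmiss <- 1 * !is.na(g$dosages)
  counts <- tcrossprod(nonmiss)
  if (any(counts == 0)) {
    stop_herimap("sample pair with zero shared non-missing variants",
                 "herimap_value_error")
  }
  values <- tcrossprod(w) / counts
  values <- (values + t(values)) / 2
  dimnames(values) <- list(g$samples, g$samples)
  structure(list(values = values, samples = g$samples,
                 pair_snp_counts = counts),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  n <- length(x$samples)
  od <- x$values[upper.tri(x$values)]
  cat(sprintf("<grm> %d samples; diag mean %.3f; off-diag range [%.3f, %.3f]\n",
              n, mean(diag(x$values)), min(od), max(od)))
  invisible(x)
}

as_grm_matrix <- function(a) {
  if (inherits(a, "grm")) a$values else as.matrix(a)
}

#' Principal components of the GRM
#'
#' Top-`k` eigenvectors of the relatedness matrix, used as population-structure
#' covariates.  Columns are unit-norm, ordered by descending eigenvalue, and
#' sign-fixed so each vector's largest-magnitude element is positive (ties on
#' a degenerate spectrum resolve by eigenvector index, making output
#' deterministic).
#'
#' @param a a `grm` or symmetric matrix
#' @param k number of components (`k < N`)
#' @return `N x k` matrix with columns `PC1..PCk` and attribute `eigenvalues`
#' @export
grm_pca <- function(a, k = 10) {
  av <- as_grm_matrix(a)
  n <- nrow(av)
  if (k >= n) {
    stop_herimap(sprintf("k = %d must be smaller than N = %d", k, n),
                 "herimap_value_error")
  }
  es <- eigen(av, symmetric = TRUE)
  vec <- es$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  colnames(vec) <- paste0("PC", seq_len(k))
  rownames(vec) <- rownames(av)
  attr(vec, "eigenvalues") <- es$values[seq_len(k)]
  vec
}

#' Greedy relatedness pruning
#'
#' Optional simplification of identity-by-descent pruning: repeatedly drops
#' one member of the most related remaining pair while any off-diagonal
#' relatedness exceeds `threshold` (the member with the higher mean
#' relatedness to everyone else is dropped).
#'
#' @param a a `grm`
#' @param threshold off-diagonal relatedness cutoff
#' @return character vector of sample IDs to drop (possibly empty)
#' @export
grm_prune <- function(a, threshold = 0.25) {
  v <- as_grm_matrix(a)
  ids <- a$samples %||% rownames(v)
  keep <- rep(TRUE, nrow(v))
  repeat {
    vv <- v[keep, keep, drop = FALSE]
    od <- vv; diag(od) <- -Inf
    if (all(od <= threshold)) break
    ij <- which(od == max(od), arr.ind = TRUE)[1, ]
    drop_local <- ij[which.max(c(mean(vv[ij[1], ]), mean(vv[ij[2], ]))) ]
    keep[which(keep)[drop_local]] <- FALSE
  }
  ids[!keep]
}

#' Assemble the fixed-effect covariate matrix
#'
#' Builds the design matrix used by the mixed model: an intercept, the named
#' covariate columns (e.g. age, sex) and the population-structure PCs.
#'
#' @param covariates data frame with a `sample_id` column plus covariates
#' @param pcs optional `N x k` PC matrix from [grm_pca()] (rows in sample order)
#' @param columns covariate column names to include
#' @return numeric matrix of class `covariate_matrix` with full column rank
#' @export
build_covariates <- function(covariates, pcs = NULL,
                             columns = setdiff(names(covariates), "sample_id")) {
  x <- cbind(`(Intercept)` = 1,
             as.matrix(covariates[, columns, drop = FALSE]))
  if (!is.null(pcs)) x <- cbind(x, pcs)
  storage.mode(x) <- "double"
  rownames(x) <- covariates$sample_id
  if (qr(x)$rank < ncol(x)) {
    stop_herimap("covariate matrix is rank deficient", "herimap_value_error")
  }
  class(x) <- c("covariate_matrix", class(x))
  x
}

# ---- GRM import/export -------------------------------------------------------

#' Export a GRM in GCTA binary format
#'
#' Writes `prefix.grm.bin` (float32 lower triangle, row by row including the
#' diagonal), `prefix.grm.N.bin` (float32 pair SNP counts) and
#' `prefix.grm.id`.
#' @param a a `grm`
#' @param prefix output path prefix
#' @export
write_grm_gcta <- function(a, prefix) {
  n <- length(a$samples)
  lt <- which(lower.tri(a$values, diag = TRUE), arr.ind = TRUE)
  lt <- lt[order(lt[, 1], lt[, 2]), , drop = FALSE]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(a$values[lt]), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(a$pair_snp_counts[lt]), con, size = 4)
  close(con)
  write.table(data.frame(a$samples, a$samples),
              paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GCTA binary GRM
#' @param prefix path prefix of `.grm.bin/.grm.N.bin/.grm.id`
#' @return a `grm` (float32 precision)
#' @export
read_grm_gcta <- function(prefix) {
  ids <- read.delim(paste0(prefix, ".grm.id"), header = FALSE,
                    colClasses = "character")[[2]]
  n <- length(ids)
  nel <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = nel, size = 4)
  cnts <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", n = nel, size = 4)
  if (length(vals) != nel) {
    stop_herimap(sprintf("%s.grm.bin: expected %d entries, found %d",
                         prefix, nel, length(vals)), "herimap_format_error")
  }
  v <- matrix(0, n, n); cn <- matrix(0, n, n)
  idx <- which(lower.tri(v, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  v[idx] <- vals; cn[idx] <- cnts
  v <- v + t(v) - diag(diag(v))
  cn <- cn + t(cn) - diag(diag(cn))
  dimnames(v) <- list(ids, ids)
  structure(list(values = v, samples = ids, pair_snp_counts = cn),
            class = "grm")
}

#' Export a GRM as TSV (long format: id1, id2, n_snps, relatedness)
#' @param a a `grm`
#' @param path output file
#' @export
write_grm_tsv <- function(a, path) {
  lt <- which(lower.tri(a$values, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(id1 = a$samples[lt[, 1]], id2 = a$samples[lt[, 2]],
                   n_snps = a$pair_snp_counts[lt],
                   relatedness = a$values[lt])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
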