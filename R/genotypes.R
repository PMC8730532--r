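#' Construct a genotype matrix object
#'
#' Bundles an `N x M` dosage matrix (counted alternate alleles, values 0/1/2 or
#' `NA` for missing) with its per-variant metadata.  The minor allele frequency
#' stored per variant is always the folded frequency (`<= 0.5`) recomputed from
#' the observed dosages.
#'
#' @param dosages Numeric matrix, samples in rows, variants in columns; entries
#'   must be 0, 1, 2 or `NA`.
#' @param variants Data frame with one row per variant and columns `id`,
#'   `chrom`, `pos`, `ref`, `alt`.  `maf` is (re)computed here.
#' @param samples Character vector of unique sample IDs; defaults to the
#'   dosage row names.
#' @return An object of class `genotype_matrix` with elements `dosages`
#'   (rownames = samples, colnames = variant ids), `variants` (tibble) and
#'   `samples`.
#' @export
genotype_matrix <- function(dosages, variants, samples = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(samples)) {
    samples <- paste0("S", seq_len(nrow(dosages)))
  }
  samples <- as.character(samples)
  variants <- as_tibble(variants)
  if (nrow(variants) != ncol(dosages)) {
    stop_herimap(
      sprintf("variant table has %d rows but dosage matrix has %d columns",
              nrow(variants), ncol(dosages)),
      "herimap_dim_error")
  }
  if (length(samples) != nrow(dosages)) {
    stop_herimap("sample ID count does not match dosage row count",
                 "herimap_dim_error")
  }
  if (anyDuplicated(samples)) {
    stop_herimap("duplicate sample IDs", "herimap_id_error")
  }
  if (anyDuplicated(variants$id)) {
    stop_herimap("duplicate variant IDs", "herimap_id_error")
  }
  if (any(variants$pos < 1)) {
    stop_herimap("variant positions must be >= 1", "herimap_value_error")
  }
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) {
    stop_herimap("dosages must be 0, 1, 2 or NA", "herimap_value_error")
  }
  dimnames(dosages) <- list(samples, variants$id)
  variants$maf <- variant_maf(dosages)
  structure(
    list(dosages = dosages, variants = variants, samples = samples),
    class = "genotype_matrix")
}

#' Folded minor-allele frequency per variant
#'
#' @param dosages dosage matrix (samples x variants), `NA` allowed
#' @return numeric vector of folded alternate-allele frequencies in `[0, 0.5]`
#' @export
variant_maf <- function(dosages) {
  p <- colMeans(dosages, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  unname(pmin(p, 1 - p))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# ---- PLINK 1.9 binary triple -------------------------------------------------

# 2-bit codes in a SNP-major .bed, with A1 = alt allele:
#   00 -> hom A1 (dosage 2), 10 -> het (1), 11 -> hom A2 (0), 01 -> missing
.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

#' Write a genotype matrix as a PLINK binary triple
#'
#' Writes SNP-major `.bed` plus companion `.bim`/`.fam` files.  A1 in the
#' `.bim` is the alternate (dosage-counted) allele.
#'
#' @param g a [genotype_matrix()]
#' @param prefix output path prefix (files `prefix.bed/.bim/.fam`)
#' @return `prefix`, invisibly
#' @export
write_plink <- function(g, prefix) {
  n <- nrow(g$dosages); m <- ncol(g$dosages)
  fam <- data.frame(fid = g$samples, iid = g$samples,
                    pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = g$variants$chrom, id = g$variants$id, cm = 0,
                    pos = g$variants$pos, a1 = g$variants$alt,
                    a2 = g$variants$ref)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  codes <- matrix(3L, n, m)                 # 11 = hom A2 (dosage 0)
  codes[g$dosages == 1] <- 2L               # 10 = het
  codes[g$dosages == 2] <- 0L               # 00 = hom A1
  codes[is.na(g$dosages)] <- 1L             # 01 = missing
  bpv <- ceiling(n / 4)
  pad <- matrix(0L, 4L * bpv - n, m)        # pad samples to byte boundary
  codes <- rbind(codes, pad)
  shift <- rep(c(1L, 4L, 16L, 64L), bpv)    # 2-bit fields, LSB first
  bytes <- codes * shift
  grp <- rep(seq_len(bpv), each = 4L)
  packed <- rowsum(bytes, grp, reorder = FALSE)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(as.raw(as.vector(packed)), con)
  invisible(prefix)
}

read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) {
      stop_herimap(sprintf("missing PLINK companion file: %s", p),
                   "herimap_io_error")
    }
  }
  fam <- read.delim(fam_path, header = FALSE, sep = "",
                    colClasses = "character")
  bim <- read.delim(bim_path, header = FALSE, sep = "",
                    col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                    colClasses = c("character", "character", "character",
                                   "integer", "character", "character"))
  n <- nrow(fam); m <- nrow(bim)
  bpv <- ceiling(n / 4)
  expected <- 3 + bpv * m
  actual <- file.size(bed_path)
  raw <- readBin(bed_path, "raw", n = actual)
  if (!identical(raw[1:3], .bed_magic)) {
    stop_herimap(sprintf("%s: bad magic bytes (not a SNP-major PLINK .bed)",
                         bed_path), "herimap_format_error")
  }
  if (actual != expected) {
    stop_herimap(
      sprintf("%s: size %d does not match %d samples x %d variants (expected %d)",
              bed_path, actual, n, m, expected),
      "herimap_format_error")
  }
  body <- as.integer(raw[-(1:3)])
  # unpack 2-bit fields, LSB first
  two <- vapply(0:3, function(k) bitwAnd(body %/% (4L ^ k), 3L), integer(length(body)))
  codes <- matrix(t(two), nrow = 4L * bpv)[seq_len(n), , drop = FALSE]
  dos <- matrix(NA_real_, n, m)
  dos[codes == 0L] <- 2
  dos[codes == 2L] <- 1
  dos[codes == 3L] <- 0
  rownames(dos) <- fam[[2]]
  genotype_matrix(
    dos,
    tibble(id = bim$id, chrom = bim$chrom, pos = bim$pos,
           ref = bim$a2, alt = bim$a1),
    samples = fam[[2]])
}

# ---- plain dosage table ------------------------------------------------------

#' Write a genotype matrix as a TSV dosage table
#'
#' Rows are samples (first column `sample_id`), remaining columns one per
#' variant, missing written as `NA`.
#' @param g a [genotype_matrix()]
#' @param path output file
#' @export
write_dosage_table <- function(g, path) {
  df <- data.frame(sample_id = g$samples, g$dosages, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_dosage_table <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   na.strings = "NA")
  if (ncol(df) < 2) {
    stop_herimap(sprintf("%s: dosage table needs a sample column plus variants",
                         path), "herimap_format_error")
  }
  ids <- as.character(df[[1]])
  dos <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  vids <- colnames(dos)
  genotype_matrix(
    dos,
    tibble(id = vids, chrom = "0", pos = seq_along(vids),
           ref = "A", alt = "B"),
    samples = ids)
}

#' Read genotype data
#'
#' @param path for `"plink-bed"` the path prefix of the `.bed/.bim/.fam`
#'   triple (a trailing `.bed` is stripped); for `"dosage-table"` a TSV file.
#' @param format input format
#' @return a [genotype_matrix()]
#' @export
read_genotypes <- function(path, format = c("plink-bed", "dosage-table")) {
  format <- match.arg(format)
  switch(format,
    "plink-bed" = read_plink(sub("\\.bed$", "", path)),
    "dosage-table" = read_dosage_table(path))
}
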