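#' Describe a synthetic study design
#'
#' Bundles every knob of the synthetic-data generator.  The defaults define a
#' desk-scale cohort with enough relatedness structure for variance-component
#' estimation to be well conditioned: 50 sibships of 8 full siblings
#' (N = 400) typed at M = 2000 independent biallelic variants, a 16^3 volume
#' with a centred spherical brain mask, and two spherical high-heritability
#' blobs (h2 = 0.8 and 0.6) on a non-heritable background.  Demographic
#' covariates emulate an elderly imaging cohort (age ~ N(76.9, 7.5^2), sex
#' balanced).
#'
#' @param n_samples number of subjects
#' @param n_variants number of biallelic variants
#' @param maf_range range the per-variant allele frequency is drawn from
#' @param n_blocks,block_size number and size of full-sibling family blocks
#'   (remaining subjects are unrelated)
#' @param volume_shape 3D grid extents
#' @param blobs list of `list(center, radius, true_h2)` with 0-based centers
#' @param background_h2 true heritability of in-mask voxels outside all blobs
#' @param noise_sd residual standard deviation before variance normalization
#' @param beta_age,beta_sex fixed covariate effects per unit
#' @param seed RNG seed; all simulators are pure functions of it
#' @return list of class `simulation_design`
#' @export
simulation_design <- function(n_samples = 400L, n_variants = 2000L,
                              maf_range = c(0.05, 0.5),
                              n_blocks = 50L, block_size = 8L,
                              volume_shape = c(16L, 16L, 16L),
                              blobs = list(
                                list(center = c(5, 5, 5), radius = 3,
                                     true_h2 = 0.8),
                                list(center = c(10, 10, 10), radius = 3,
                                     true_h2 = 0.6)),
                              background_h2 = 0, noise_sd = 1,
                              beta_age = 0.01, beta_sex = 0.1,
                              seed = 1L) {
  if (n_blocks * block_size > n_samples) {
    stop_herimap("family blocks exceed n_samples", "herimap_value_error")
  }
  for (b in blobs) {
    if (any(b$center - b$radius < 0) ||
        any(b$center + b$radius > volume_shape - 1)) {
      stop_herimap("blob extends outside the volume", "herimap_value_error")
    }
    stopifnot(b$true_h2 >= 0, b$true_h2 <= 1)
  }
  structure(list(
    n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
    maf_range = maf_range, n_blocks = as.integer(n_blocks),
    block_size = as.integer(block_size),
    volume_shape = as.integer(volume_shape), blobs = blobs,
    background_h2 = background_h2, noise_sd = noise_sd,
    beta_age = beta_age, beta_sex = beta_sex, seed = as.integer(seed)),
    class = "simulation_design")
}

#' Simulate genotypes with family-block relatedness
#'
#' Per-variant allele frequencies are uniform on `maf_range`.  Within a family
#' block all subjects are full siblings: each variant's dosage is the sum of
#' one haplotype drawn from a shared paternal pair and one from a shared
#' maternal pair, so the expected genomic relatedness within a block is 0.5
#' and 0 across blocks.  Subjects beyond the blocks are unrelated
#' Hardy-Weinberg draws.
#'
#' @param design a [simulation_design()]
#' @return a [genotype_matrix()], deterministic given `design$seed`
#' @export
simulate_genotypes <- function(design) {
  with_seed(design$seed, {
    n <- design$n_samples; m <- design$n_variants
    p <- runif(m, design$maf_range[1], design$maf_range[2])
    dos <- matrix(0, n, m)
    row <- 1L
    for (b in seq_len(design$n_blocks)) {
      hap <- matrix(rbinom(4L * m, 1L, rep(p, each = 4L)), nrow = 4L)
      for (s in seq_len(design$block_size)) {
        pat <- hap[cbind(sample.int(2L, m, replace = TRUE), seq_len(m))]
        mat <- hap[cbind(2L + sample.int(2L, m, replace = TRUE), seq_len(m))]
        dos[row, ] <- pat + mat
        row <- row + 1L
      }
    }
    n_rest <- n - (row - 1L)
    if (n_rest > 0) {
      dos[row:n, ] <- matrix(
        rbinom(n_rest * m, 2L, rep(p, each = n_rest)), n_rest, m)
    }
    genotype_matrix(
      dos,
      tibble(id = sprintf("snp%05d", seq_len(m)),
             chrom = "1", pos = seq_len(m) * 1000L,
             ref = "A", alt = "B"),
      samples = sprintf("sim%04d", seq_len(n)))
  })
}

#' Spherical brain mask used by the simulators
#'
#' Logical array marking voxels whose Euclidean distance from the grid centre
#' is at most half the smallest extent (so the "brain" is the inscribed
#' sphere and the shell outside it is exact-zero background).
#'
#' @param shape 3 integer extents
#' @return logical 3D array
#' @export
default_brain_mask <- function(shape) {
  ctr <- (shape - 1) / 2
  r <- min(shape) / 2 - 0.5 + 1e-9
  g <- expand.grid(i = seq_len(shape[1]) - 1, j = seq_len(shape[2]) - 1,
                   k = seq_len(shape[3]) - 1)
  d2 <- (g$i - ctr[1])^2 + (g$j - ctr[2])^2 + (g$k - ctr[3])^2
  array(d2 <= r^2, dim = shape)
}

blob_mask <- function(shape, center, radius) {
  g <- expand.grid(i = seq_len(shape[1]) - 1, j = seq_len(shape[2]) - 1,
                   k = seq_len(shape[3]) - 1)
  d2 <- (g$i - center[1])^2 + (g$j - center[2])^2 + (g$k - center[3])^2
  array(d2 <= radius^2, dim = shape)
}

#' Simulate voxel phenotypes with known heritability structure
#'
#' For each voxel the phenotype follows the additive model
#' `y_v = beta_age * age + beta_sex * sex + sqrt(h2_v) * g + sqrt(1 - h2_v) * e_v`
#' where `g = L z` with `L` an eigen square root of the GRM derived from the
#' supplied genotypes (eigenvalues clipped at zero if numerically negative)
#' and `z` a standard normal vector *shared by all voxels of a blob*, so blob
#' averages are at least as heritable as member voxels.  Genetic and residual
#' parts are rescaled to unit sample variance, making the realized genetic
#' variance fraction equal `h2_v`.  Voxels outside the spherical brain mask
#' are exactly 0 for every subject.
#'
#' @param g a [genotype_matrix()]
#' @param design a [simulation_design()]
#' @return list with `volumes` (named list of subject arrays), `covariates`
#'   (tibble `sample_id`, `age`, `sex`), `truth` (list: `h2_map` a
#'   [brain_map()], `blob_masks` list of logical arrays, `mask`)
#' @export
simulate_voxel_phenotypes <- function(g, design) {
  with_seed(design$seed + 1L, {
    n <- nrow(g$dosages)
    shape <- design$volume_shape
    # the generative GRM uses the variants polymorphic in this realization
    # (finite haplotype pools can fix an allele even at maf_range > 0)
    poly <- variant_maf(g$dosages) > 0
    gp <- genotype_matrix(g$dosages[, poly, drop = FALSE],
                          g$variants[poly, ], g$samples)
    a <- compute_grm(gp)
    es <- eigen(a$values, symmetric = TRUE)
    if (min(es$values) < -1e-8) {
      message(sprintf("GRM numerically non-PSD (min eigenvalue %.2e); clipped at 0",
                      min(es$values)))
    }
    l <- es$vectors %*% diag(sqrt(pmax(es$values, 0)))

    mask <- default_brain_mask(shape)
    blob_masks <- lapply(design$blobs, function(b)
      blob_mask(shape, b$center, b$radius) & mask)
    h2_vol <- array(0, shape)
    h2_vol[mask] <- design$background_h2
    blob_id <- array(0L, shape)
    for (bi in seq_along(blob_masks)) {
      h2_vol[blob_masks[[bi]]] <- design$blobs[[bi]]$true_h2
      blob_id[blob_masks[[bi]]] <- bi
    }

    age <- rnorm(n, 76.9, 7.5)
    sex <- rbinom(n, 1L, 0.5)
    fixed <- design$beta_age * age + design$beta_sex * sex

    unit_var <- function(v) (v - mean(v)) / sd(v)
    blob_g <- lapply(seq_along(blob_masks), function(bi)
      unit_var(drop(l %*% rnorm(n))))

    vox <- which(mask)
    vals <- matrix(0, n, length(vox))
    for (vv in seq_along(vox)) {
      h2 <- h2_vol[vox[vv]]
      gen <- if (h2 > 0 && blob_id[vox[vv]] > 0) {
        blob_g[[blob_id[vox[vv]]]]
      } else if (h2 > 0) {
        unit_var(drop(l %*% rnorm(n)))    # background with nonzero h2
      } else {
        0
      }
      e <- unit_var(rnorm(n, sd = design$noise_sd))
      vals[, vv] <- fixed + sqrt(h2) * gen + sqrt(1 - h2) * e
    }

    ids <- g$samples
    volumes <- lapply(seq_len(n), function(s) {
      vol <- array(0, shape)
      vol[vox] <- vals[s, ]
      vol
    })
    names(volumes) <- ids
    list(volumes = volumes,
         covariates = tibble(sample_id = ids, age = age, sex = sex),
         truth = list(h2_map = brain_map(h2_vol, "heritability"),
                      blob_masks = blob_masks, mask = mask))
  })
}

#' Generate a toy contiguous-label atlas
#'
#' Voronoi-style partition of the in-mask volume: `n_regions` seed voxels are
#' sampled uniformly from the mask and every mask voxel is assigned to the
#' nearest seed (Euclidean distance, ties to the lowest seed index).  Since
#' the mask is convex, each cell is spatially contiguous.
#'
#' @param shape 3 integer extents
#' @param n_regions number of labels
#' @param seed RNG seed
#' @return a [brain_map()] with label semantics
#' @export
make_toy_atlas <- function(shape, n_regions, seed = 1L) {
  shape <- as.integer(shape)
  mask <- default_brain_mask(shape)
  vox <- which(mask)
  if (n_regions < 1 || n_regions > length(vox)) {
    stop_herimap(sprintf("n_regions must be in [1, %d]", length(vox)),
                 "herimap_value_error")
  }
  with_seed(seed, {
    seeds <- linear_to_coord(sort(sample(vox, n_regions)), shape)
    coords <- linear_to_coord(vox, shape)
    d2 <- outer(rowSums(coords^2), rowSums(seeds^2), "+") -
      2 * coords %*% t(seeds)
    lab <- max.col(-d2, ties.method = "first")
    vol <- array(0L, shape)
    vol[vox] <- lab
    brain_map(vol, "label", fill = 0)
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper chaining [simulate_genotypes()] and
#' [simulate_voxel_phenotypes()].
#'
#' @param design a [simulation_design()]
#' @return list with `genotypes`, `volumes`, `covariates`, `truth`
#' @export
simulate_dataset <- function(design = simulation_design()) {
  g <- simulate_genotypes(design)
  ph <- simulate_voxel_phenotypes(g, design)
  c(list(genotypes = g), ph)
}

#' Write a simulated dataset to disk
#'
#' Writes the PLINK triple, one NIfTI volume per subject, the covariate TSV
#' and a ground-truth JSON (blob definitions and mask size).
#'
#' @param dataset result of [simulate_dataset()]
#' @param design the [simulation_design()] used
#' @param dir output directory (created if needed)
#' @export
write_dataset <- function(dataset, design, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_plink(dataset$genotypes, file.path(dir, "genotypes"))
  vdir <- file.path(dir, "volumes")
  dir.create(vdir, showWarnings = FALSE)
  for (id in names(dataset$volumes)) {
    RNifti::writeNifti(RNifti::asNifti(dataset$volumes[[id]]),
                       file.path(vdir, paste0(id, ".nii.gz")))
  }
  write.table(dataset$covariates, file.path(dir, "covariates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(blobs = design$blobs, volume_shape = design$volume_shape,
         background_h2 = design$background_h2,
         n_mask_voxels = sum(dataset$truth$mask), seed = design$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
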