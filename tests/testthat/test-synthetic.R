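test_that("full siblings show ~0.5 genomic relatedness, blocks are unrelated", {
  # sib pairs embedded in a mostly-unrelated cohort, so the sample allele
  # frequencies used for standardization are nearly unbiased
  d <- simulation_design(n_samples = 100, n_variants = 2000, n_blocks = 10,
                         block_size = 2, seed = 17)
  g <- simulate_genotypes(d)
  a <- compute_grm(qc_filter(g)$genotypes)
  sib_rel <- vapply(seq_len(10), function(b)
    a$values[2 * b - 1, 2 * b], numeric(1))
  expect_lt(abs(mean(sib_rel) - 0.5), 0.1)
  between <- a$values[seq(1, 19, 2), seq(2, 20, 2)]
  diag(between) <- NA                       # skip the sib pairs themselves
  expect_lt(abs(mean(between, na.rm = TRUE)), 0.1)
  # unrelated tail samples
  tail_block <- a$values[21:100, 21:100]
  diag(tail_block) <- NA
  expect_lt(abs(mean(tail_block, na.rm = TRUE)), 0.1)
})

test_that("simulators are pure functions of the seed", {
  d <- simulation_design(n_samples = 24, n_variants = 100, n_blocks = 2,
                         block_size = 8, volume_shape = c(8, 8, 8),
                         blobs = list(list(center = c(3, 3, 3), radius = 2,
                                           true_h2 = 0.7)), seed = 19)
  set.seed(777)
  before <- .Random.seed
  g1 <- simulate_genotypes(d)
  expect_identical(.Random.seed, before)    # caller RNG stream untouched
  g2 <- simulate_genotypes(d)
  expect_identical(g1$dosages, g2$dosages)
  d2 <- d; d2$seed <- 20L
  expect_false(identical(simulate_genotypes(d2)$dosages, g1$dosages))
  ph1 <- simulate_voxel_phenotypes(g1, d)
  ph2 <- simulate_voxel_phenotypes(g1, d)
  expect_identical(ph1$volumes, ph2$volumes)
})

test_that("phenotypes honor the mask, blob structure and variance model", {
  d <- simulation_design(n_samples = 48, n_variants = 300, n_blocks = 6,
                         block_size = 8, volume_shape = c(10, 10, 10),
                         blobs = list(
                           list(center = c(4, 4, 4), radius = 2, true_h2 = 0.8),
                           list(center = c(7, 7, 7), radius = 1, true_h2 = 0)),
                         seed = 21)
  g <- simulate_genotypes(d)
  ph <- simulate_voxel_phenotypes(g, d)
  mask <- ph$truth$mask
  # out-of-mask voxels are exactly zero for every subject
  for (s in c(1, 24, 48)) {
    expect_true(all(ph$volumes[[s]][!mask] == 0))
    expect_true(all(ph$volumes[[s]][mask] != 0))
  }
  # vectorize removes exactly the mask complement
  vqt <- vectorize(ph$volumes)
  expect_equal(length(vqt$index), sum(mask))
  # truth map carries blob h2 values
  expect_equal(ph$truth$h2_map$volume[5, 5, 5], 0.8)
  expect_equal(sum(ph$truth$blob_masks[[1]]), sum(ph$truth$h2_map$volume == 0.8))
  # null blob: voxel variance is purely non-genetic by construction;
  # phenotype variance ~ 1 plus the covariate contribution
  centre <- ph$truth$blob_masks[[2]]
  vals <- sapply(ph$volumes, function(v) v[which(centre)[1]])
  expect_lt(abs(var(vals) - (1 + var(d$beta_age * ph$covariates$age +
                                       d$beta_sex * ph$covariates$sex))), 0.6)
})

test_that("a blob-sharing genetic factor makes region averages heritable", {
  # the blob average has less residual noise than a single voxel, so its
  # heritability estimate should exceed the per-voxel truth on average
  d <- simulation_design(n_samples = 160, n_variants = 800, n_blocks = 20,
                         block_size = 8, volume_shape = c(10, 10, 10),
                         blobs = list(list(center = c(4, 4, 4), radius = 2,
                                           true_h2 = 0.6)),
                         seed = 23)
  g <- qc_filter(simulate_genotypes(d))$genotypes
  ph <- simulate_voxel_phenotypes(g, d)
  vqt <- vectorize(ph$volumes)
  a <- compute_grm(g)
  x <- build_covariates(ph$covariates, grm_pca(a, 5))
  blob <- ph$truth$blob_masks[[1]]
  pos <- array(0L, dim(blob))
  pos[vqt$index$coords + 1L] <- seq_len(length(vqt$index))
  avg <- rowMeans(vqt$values[, pos[blob], drop = FALSE])
  f <- fit_reml(avg, x, a)
  expect_gt(f$h2, 0.6)
})

test_that("toy atlas labels partition the mask into connected cells", {
  at1 <- make_toy_atlas(c(8, 8, 8), 1, seed = 25)
  mask <- default_brain_mask(c(8, 8, 8))
  expect_true(all(at1$volume[mask] == 1))
  expect_true(all(at1$volume[!mask] == 0))
  at <- make_toy_atlas(c(10, 10, 10), 5, seed = 26)
  mask10 <- default_brain_mask(c(10, 10, 10))
  expect_setequal(unique(at$volume[mask10]), 1:5)
  expect_true(all(at$volume[!mask10] == 0))
  for (l in 1:5) {
    cell <- array(0L, c(10, 10, 10))
    cell[at$volume == l] <- 1L
    expect_equal(max(flood_fill_oracle(cell, 26)), 1)   # contiguous
  }
  expect_identical(make_toy_atlas(c(10, 10, 10), 5, seed = 26)$volume,
                   at$volume)
  expect_error(make_toy_atlas(c(4, 4, 4), 1e6, seed = 1),
               class = "herimap_value_error")
})

test_that("a written dataset reloads consistently", {
  d <- simulation_design(n_samples = 16, n_variants = 80, n_blocks = 2,
                         block_size = 8, volume_shape = c(6, 6, 6),
                         blobs = list(list(center = c(3, 3, 3), radius = 1,
                                           true_h2 = 0.5)),
                         seed = 27)
  ds <- simulate_dataset(d)
  td <- withr::local_tempdir()
  write_dataset(ds, d, td)
  g2 <- read_genotypes(file.path(td, "genotypes.bed"), "plink-bed")
  expect_identical(unname(g2$dosages), unname(ds$genotypes$dosages))
  id1 <- ds$genotypes$samples[1]
  vol1 <- read_nifti_volumes(file.path(td, "volumes",
                                       paste0(id1, ".nii.gz")))[[1]]
  expect_equal(vol1, ds$volumes[[id1]], tolerance = 1e-6, ignore_attr = TRUE)
  covs <- read.delim(file.path(td, "covariates.tsv"))
  expect_equal(covs$age, ds$covariates$age, tolerance = 1e-6)
  truth <- jsonlite::read_json(file.path(td, "truth.json"))
  expect_equal(truth$n_mask_voxels, sum(ds$truth$mask))
})
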