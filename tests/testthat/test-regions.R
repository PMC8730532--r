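random_pmap <- function(shape, seed, frac_bg = 0.3) {
  set.seed(seed)
  vol <- array(runif(prod(shape)), shape)
  brain_map(vol, "p_value", fill = 1)
}

test_that("smoothing a constant map leaves it unchanged", {
  bm <- brain_map(array(0.42, c(6, 6, 6)), "p_value")
  sm <- smooth_pmap(bm, sigma = 0.5)
  expect_equal(sm$volume, bm$volume, tolerance = 1e-12)
  expect_error(smooth_pmap(bm, sigma = 0), class = "herimap_value_error")
  expect_error(smooth_pmap(brain_map(array(1, c(2, 2, 2)), "label")),
               class = "herimap_value_error")
})

test_that("smoothing matches the dense direct-convolution oracle", {
  # single low-p voxel in a field of 1s
  vol <- array(1, c(7, 7, 7))
  vol[4, 4, 4] <- 0.01
  sm <- smooth_pmap(brain_map(vol, "p_value"), sigma = 0.5)
  expect_equal(sm$volume, smooth_oracle(vol, 0.5), tolerance = 1e-10)
  # random maps, including boundary handling
  for (s in 1:2) {
    pm <- random_pmap(c(6, 5, 7), seed = s)
    sm <- smooth_pmap(pm, sigma = 0.5)
    expect_equal(sm$volume, smooth_oracle(pm$volume, 0.5), tolerance = 1e-10)
  }
})

test_that("two passes at sigma compose like one pass at sigma*sqrt(2)", {
  # the Gaussian semigroup property holds for the discrete kernel once the
  # standard deviation is large enough that sampling error drops below the
  # 4-sigma truncation error; very narrow kernels (sigma ~ 0.5) are too
  # coarsely sampled for it
  pm <- random_pmap(c(20, 20, 20), seed = 9)
  twice <- smooth_pmap(smooth_pmap(pm, 2), 2)
  once <- smooth_pmap(pm, 2 * sqrt(2))
  expect_lt(max(abs(twice$volume - once$volume)), 1e-3)
})

test_that("voxel selection follows the threshold, ceil and ranking rules", {
  shape <- c(2, 2, 1)
  idx <- voxel_index(shape, rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                  c(1, 1, 0)))
  pm <- devectorize(c(0.01, 0.02, 0.03, 0.2), idx, semantics = "p_value")
  sel <- select_voxels(pm, idx, alpha = 0.05, top_fraction = 1,
                       arm = "significant")
  expect_equal(sum(sel$volume), 3)
  sel2 <- select_voxels(pm, idx, alpha = 0.05, top_fraction = 0.5,
                        arm = "significant")
  expect_equal(sum(sel2$volume), 2)        # ceil(0.5 * 3)
  # values bind to the canonical (lexicographic) index order, so the two
  # smallest p sit at coordinates (0,0,0) and (0,1,0)
  expect_equal(sel2$volume[1, 1, 1] + sel2$volume[1, 2, 1], 2)
  insig <- select_voxels(pm, idx, alpha = 0.05, top_fraction = 1,
                         arm = "insignificant")
  expect_equal(sum(insig$volume), 1)
  expect_equal(insig$volume[2, 2, 1], 1)
  expect_error(select_voxels(pm, idx, alpha = 1e-9, top_fraction = 1,
                             arm = "significant"),
               "significant", class = "herimap_empty_error")
})

test_that("voxel selection equals an independent sort-and-slice oracle", {
  shape <- c(6, 6, 6)
  for (s in 1:20) {
    set.seed(s)
    coords <- unique(cbind(sample(0:5, 40, TRUE), sample(0:5, 40, TRUE),
                           sample(0:5, 40, TRUE)))
    idx <- voxel_index(shape, coords)
    p <- runif(length(idx))
    pm <- devectorize(p, idx, semantics = "p_value")
    fr <- sample(c(0.1, 0.3, 0.5, 1), 1)
    arm <- sample(c("significant", "insignificant"), 1)
    sel <- select_voxels(pm, idx, alpha = 0.5, top_fraction = fr, arm = arm)
    # oracle: sort candidate p-values and slice
    pv <- pm$volume[idx$coords + 1L]
    cand <- if (arm == "significant") which(pv < 0.5) else which(pv >= 0.5)
    ranked <- cand[order(if (arm == "significant") pv[cand] else -pv[cand])]
    keep <- ranked[seq_len(ceiling(fr * length(cand)))]
    marked <- idx$coords[keep, , drop = FALSE]
    expect_equal(sum(sel$volume), length(keep))
    expect_true(all(sel$volume[marked + 1L] == 1))
  }
})

test_that("selected voxel sets are nested across fractions", {
  pm <- random_pmap(c(8, 8, 8), seed = 11)
  coords <- as.matrix(expand.grid(0:7, 0:7, 0:7))
  idx <- voxel_index(c(8, 8, 8), coords)
  prev <- NULL
  for (fr in c(0.1, 0.2, 0.3, 1)) {
    sel <- select_voxels(pm, idx, alpha = 0.5, top_fraction = fr,
                         arm = "significant")
    if (!is.null(prev)) expect_true(all(sel$volume[prev == 1] == 1))
    prev <- sel$volume
  }
})

test_that("connected components respect the neighborhood definition", {
  empty <- brain_map(array(0, c(4, 4, 4)), "label")
  expect_equal(nrow(connected_components(empty)$regions), 0L)
  # two voxels sharing only a corner
  vol <- array(0, c(4, 4, 4))
  vol[1, 1, 1] <- 1; vol[2, 2, 2] <- 1
  bm <- brain_map(vol, "label")
  expect_equal(nrow(connected_components(bm, 26)$regions), 1L)
  expect_equal(nrow(connected_components(bm, 6)$regions), 2L)
  # labels are assigned in lexicographic first-encounter order
  vol2 <- array(0, c(5, 5, 1))
  vol2[1, 1, 1] <- 1
  vol2[5, 5, 1] <- 1
  vol2[1, 4, 1] <- 1
  rs <- connected_components(brain_map(vol2, "label"), 6)
  expect_equal(rs$labels$volume[1, 1, 1], 1L)
  expect_equal(rs$labels$volume[1, 4, 1], 2L)
  expect_equal(rs$labels$volume[5, 5, 1], 3L)
})

test_that("component labeling agrees with a BFS flood-fill oracle", {
  for (s in 1:4) {
    set.seed(s)
    vol <- array(rbinom(20^3, 1, 0.2), c(20, 20, 20))
    bm <- brain_map(vol, "label")
    for (conn in c(6, 26)) {
      rs <- connected_components(bm, conn)
      oracle <- flood_fill_oracle(vol, conn)
      expect_equal(max(oracle), nrow(rs$regions))
      expect_identical(partition_signature(rs$labels$volume),
                       partition_signature(oracle))
    }
  }
})

test_that("region labels partition the marked voxels", {
  set.seed(30)
  vol <- array(rbinom(12^3, 1, 0.25), c(12, 12, 12))
  rs <- connected_components(brain_map(vol, "label"), 26)
  expect_equal(sum(rs$regions$size), sum(vol))
  all_coords <- do.call(rbind, rs$voxels)
  expect_equal(nrow(all_coords), sum(vol))
  expect_false(anyDuplicated(all_coords) > 0)
  expect_true(all(vol[all_coords + 1L] == 1))
})

test_that("region QTs are member-voxel means", {
  vols <- lapply(1:3, function(i) array(i * (1:8), c(2, 2, 2)))
  names(vols) <- paste0("s", 1:3)
  vqt <- vectorize(vols)
  # singleton region
  vol <- array(0, c(2, 2, 2)); vol[1, 1, 1] <- 1
  rs1 <- connected_components(brain_map(vol, "label"))
  q1 <- region_qts(rs1, vqt)
  expect_equal(unname(q1[, 1]), c(1, 2, 3))
  # two-voxel region with subject values 1 and 3 averages to 2
  vqt2 <- vectorize(list(a = array(c(1, 3, 0, 0, 0, 0, 0, 1), c(2, 2, 2))))
  vol2 <- array(0, c(2, 2, 2)); vol2[1:2, 1, 1] <- 1
  rs2 <- connected_components(brain_map(vol2, "label"))
  expect_equal(unname(region_qts(rs2, vqt2)[1, 1]), 2)
  # group-by oracle on a random fixture
  set.seed(31)
  vols3 <- lapply(1:4, function(i) array(rnorm(27) + 1, c(3, 3, 3)))
  names(vols3) <- paste0("s", 1:4)
  vqt3 <- vectorize(vols3)
  lab <- array(sample(0:3, 27, TRUE), c(3, 3, 3))
  rs3 <- connected_components(brain_map(1 * (lab > 0), "label"))
  q3 <- region_qts(rs3, vqt3)
  for (r in seq_len(nrow(rs3$regions))) {
    member <- rs3$voxels[[r]] + 1L
    oracle <- sapply(vols3, function(v) mean(v[member]))
    expect_equal(unname(q3[, r]), unname(oracle), tolerance = 1e-12)
  }
})

test_that("region voxels outside the mask are dropped with a warning", {
  vols <- list(a = array(c(0, 1, 1, 1, 1, 1, 1, 1), c(2, 2, 2)),
               b = array(c(0, 2, 2, 2, 2, 2, 2, 2), c(2, 2, 2)))
  vqt <- vectorize(vols)                   # voxel (0,0,0) is background
  vol <- array(1, c(2, 2, 2))
  rs <- connected_components(brain_map(vol, "label"))
  expect_warning(q <- region_qts(rs, vqt), "outside")
  expect_equal(unname(q[, 1]), c(1, 2))
  # region entirely outside the mask is an error naming the region
  vol2 <- array(0, c(2, 2, 2)); vol2[1, 1, 1] <- 1
  rs2 <- connected_components(brain_map(vol2, "label"))
  expect_error(suppressWarnings(region_qts(rs2, vqt)), "region 1",
               class = "herimap_value_error")
})

test_that("atlas regions intersect labels with the mask", {
  set.seed(32)
  vols <- lapply(1:3, function(i) array(rnorm(64, mean = 2), c(4, 4, 4)))
  names(vols) <- paste0("s", 1:3)
  vols <- lapply(vols, function(v) { v[1, , ] <- 0; v })   # slab of background
  vqt <- vectorize(vols)
  # single label covering everything: one region, QT = per-subject mask mean
  atlas1 <- brain_map(array(1L, c(4, 4, 4)), "label")
  res1 <- atlas_regions(atlas1, vqt)
  expect_equal(nrow(res1$region_set$regions), 1L)
  expect_equal(unname(res1$qts[, 1]),
               unname(rowMeans(vqt$values)), tolerance = 1e-12)
  # 4-label atlas with oracle-verified means; one label outside the mask
  lab <- array(0L, c(4, 4, 4))
  lab[2, , ] <- 1L; lab[3, , ] <- 2L; lab[4, 1:2, ] <- 3L; lab[1, , ] <- 4L
  expect_message(res <- atlas_regions(brain_map(lab, "label"), vqt), "4")
  expect_equal(nrow(res$region_set$regions), 3L)
  for (r in 1:3) {
    member <- res$region_set$voxels[[r]] + 1L
    oracle <- sapply(vols, function(v) mean(v[member]))
    expect_equal(unname(res$qts[, r]), unname(oracle), tolerance = 1e-12)
  }
  bad <- brain_map(array(1L, c(3, 3, 3)), "label")
  expect_error(atlas_regions(bad, vqt), class = "herimap_dim_error")
})
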