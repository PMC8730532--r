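# 1D Gaussian kernel with scipy-style truncation: radius = floor(4*sigma + 0.5)
gaussian_kernel <- function(sigma, truncate = 4) {
  r <- as.integer(truncate * sigma + 0.5)
  t <- seq(-r, r)
  w <- exp(-t^2 / (2 * sigma^2))
  w / sum(w)
}

# map out-of-range 1-based positions by 'reflect' boundary (edge repeated:
# position 0 -> 1, -1 -> 2, n+1 -> n, ...), valid for any overshoot
reflect_positions <- function(p, n) {
  while (any(p < 1L) || any(p > n)) {
    p <- ifelse(p < 1L, 1L - p, p)
    p <- ifelse(p > n, 2L * n + 1L - p, p)
  }
  p
}

convolve_axis <- function(arr, w, axis) {
  r <- (length(w) - 1L) / 2L
  n <- dim(arr)[axis]
  out <- array(0, dim(arr))
  for (t in seq_along(w)) {
    src <- reflect_positions(seq_len(n) + (t - 1L - r), n)
    args <- rep(list(quote(expr = )), 3)
    args[[axis]] <- src
    out <- out + w[t] * do.call(`[`, c(list(arr), args, list(drop = FALSE)))
  }
  out
}

#' Smooth a p-value brain map with a Gaussian kernel
#'
#' Separable Gaussian convolution over the full array (background fill
#' included), kernel truncated at 4 standard deviations, reflect boundary
#' handling.  The output is clamped to `(0, 1]`.
#'
#' @param pmap a [brain_map()] with p-value semantics
#' @param sigma kernel standard deviation in voxels
#' @return smoothed p-value [brain_map()]
#' @export
smooth_pmap <- function(pmap, sigma = 0.5) {
  stopifnot(inherits(pmap, "brain_map"))
  if (pmap$semantics != "p_value") {
    stop_herimap("smooth_pmap expects a p-value map", "herimap_value_error")
  }
  if (sigma <= 0) {
    stop_herimap("sigma must be positive", "herimap_value_error")
  }
  w <- gaussian_kernel(sigma)
  vol <- pmap$volume
  for (ax in 1:3) vol <- convolve_axis(vol, w, ax)
  vol <- pmin(pmax(vol, 1e-300), 1)
  brain_map(vol, semantics = "p_value", fill = pmap$fill)
}

#' Select top-fraction voxels by smoothed significance
#'
#' For the `"significant"` arm the candidates are in-mask voxels with
#' `p < alpha`, ranked by ascending p; for the `"insignificant"` arm,
#' voxels with `p >= alpha` ranked by descending p.  The first
#' `ceil(top_fraction * n_candidates)` are marked, ties at the cut broken by
#' lexicographic coordinate order.
#'
#' @param pmap_smoothed smoothed p-value [brain_map()]
#' @param index the [voxel_index()] defining the mask
#' @param alpha significance threshold
#' @param top_fraction fraction of candidates to keep, in `(0, 1]`
#' @param arm `"significant"` or `"insignificant"`
#' @return binary [brain_map()] (label semantics, marked voxels = 1)
#' @export
select_voxels <- function(pmap_smoothed, index, alpha = 0.05,
                          top_fraction = 1,
                          arm = c("significant", "insignificant")) {
  arm <- match.arg(arm)
  stopifnot(top_fraction > 0, top_fraction <= 1)
  p <- map_values(pmap_smoothed, index)
  cand <- if (arm == "significant") which(p < alpha) else which(p >= alpha)
  if (length(cand) == 0) {
    stop_herimap(sprintf("no candidate voxels in arm '%s' at alpha = %g",
                         arm, alpha), "herimap_empty_error")
  }
  # stable sort; index order is lexicographic, so ties break lexicographically
  ord <- if (arm == "significant") order(p[cand]) else order(-p[cand])
  keep <- cand[ord][seq_len(ceiling(top_fraction * length(cand)))]
  marked <- numeric(length(index))
  marked[keep] <- 1
  devectorize(marked, index, fill = 0, semantics = "label")
}

neighbor_offsets <- function(connectivity = c(26, 6, 18)) {
  connectivity <- as.integer(match.arg(as.character(connectivity[1]),
                                       c("26", "6", "18")))
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- switch(as.character(connectivity), "6" = 1L, "18" = 2L, "26" = 3L)
  g[rowSums(abs(g)) <= ord, , drop = FALSE]
}

#' Label connected components of a binary map
#'
#' Maximal connected components of marked (value 1) voxels under a 6-, 18- or
#' 26-neighborhood.  Labels are assigned in first-encounter order of a
#' lexicographic scan, starting at 1.  Internally the voxel adjacency graph is
#' handed to [igraph::components()].
#'
#' @param binary a binary [brain_map()]
#' @param connectivity 6, 18 or 26 (default)
#' @param provenance optional list describing how the binary map was made
#' @return object of class `region_set`: `labels` (label [brain_map()]),
#'   `regions` (tibble `region_id`, `size`), `voxels` (list of 0-based
#'   coordinate matrices), `provenance`
#' @export
connected_components <- function(binary, connectivity = 26,
                                 provenance = list()) {
  stopifnot(inherits(binary, "brain_map"))
  shape <- dim(binary$volume)
  marked_lin <- which(binary$volume != 0)
  prov <- utils::modifyList(list(connectivity = connectivity), provenance)
  if (length(marked_lin) == 0) {
    return(structure(list(
      labels = brain_map(array(0, shape), "label", fill = 0),
      regions = tibble(region_id = integer(), size = integer()),
      voxels = list(), provenance = prov), class = "region_set"))
  }
  coords <- linear_to_coord(marked_lin, shape)
  ord <- coord_order(coords)
  coords <- coords[ord, , drop = FALSE]          # scan order
  k <- nrow(coords)
  pos <- array(0L, shape)
  pos[coords + 1L] <- seq_len(k)

  offs <- neighbor_offsets(connectivity)
  edges <- list()
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[o, ], "+")
    ok <- nb[, 1] >= 0 & nb[, 2] >= 0 & nb[, 3] >= 0 &
      nb[, 1] < shape[1] & nb[, 2] < shape[2] & nb[, 3] < shape[3]
    if (!any(ok)) next
    tgt <- integer(k)
    tgt[ok] <- pos[nb[ok, , drop = FALSE] + 1L]
    hit <- which(tgt > 0)
    if (length(hit)) edges[[length(edges) + 1L]] <- cbind(hit, tgt[hit])
  }
  el <- if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2)
  gr <- igraph::graph_from_edgelist(el, directed = FALSE)
  gr <- igraph::add_vertices(gr, k - igraph::vcount(gr))
  memb <- igraph::components(gr)$membership
  relabel <- match(memb, unique(memb))           # first-encounter = scan order

  labels <- array(0L, shape)
  labels[coords + 1L] <- relabel
  vox <- split.data.frame(coords, relabel)
  names(vox) <- NULL
  structure(list(
    labels = brain_map(labels, "label", fill = 0),
    regions = tibble(region_id = seq_along(vox),
                     size = vapply(vox, nrow, integer(1))),
    voxels = vox, provenance = prov), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d regions, %d voxels total",
              nrow(x$regions), sum(x$regions$size)))
  if (!is.null(x$provenance$arm)) {
    cat(sprintf(" [arm: %s, fraction: %s]", x$provenance$arm,
                x$provenance$top_fraction %||% NA))
  }
  cat("\n")
  invisible(x)
}

#' Region-averaged quantitative traits
#'
#' Each region's QT is the unweighted per-subject mean of its member voxel
#' columns.  Region voxels outside the mask are dropped with a warning count;
#' a region with no in-mask voxel is an error.
#'
#' @param rs a `region_set`
#' @param vqt a `voxel_qt`
#' @return `N x R` matrix (rownames = samples, colnames = region ids)
#' @export
region_qts <- function(rs, vqt) {
  shape <- vqt$index$shape
  pos <- array(0L, shape)
  pos[vqt$index$coords + 1L] <- seq_len(length(vqt$index))
  out <- matrix(NA_real_, nrow(vqt$values), nrow(rs$regions))
  dropped <- 0L
  for (r in seq_len(nrow(rs$regions))) {
    cols <- pos[rs$voxels[[r]] + 1L]
    dropped <- dropped + sum(cols == 0)
    cols <- cols[cols > 0]
    if (length(cols) == 0) {
      stop_herimap(sprintf("region %d has no voxel inside the mask",
                           rs$regions$region_id[r]), "herimap_value_error")
    }
    out[, r] <- rowMeans(vqt$values[, cols, drop = FALSE])
  }
  if (dropped > 0) {
    warn(sprintf("%d region voxel(s) outside the phenotype mask were dropped",
                 dropped))
  }
  rownames(out) <- vqt$samples
  colnames(out) <- paste0("region_", rs$regions$region_id)
  out
}

#' Regions and region QTs from a labeled atlas
#'
#' One region per distinct nonzero atlas label, intersected with the
#' phenotype mask; labels with no in-mask voxel are omitted (with a message).
#' Region QTs are computed as in [region_qts()].
#'
#' @param atlas a [brain_map()] with integer label semantics
#' @param vqt a `voxel_qt` on the same grid
#' @return list with `region_set` and `qts`
#' @export
atlas_regions <- function(atlas, vqt) {
  stopifnot(inherits(atlas, "brain_map"))
  shape <- vqt$index$shape
  if (!identical(dim(atlas$volume), as.integer(shape))) {
    stop_herimap("atlas shape does not match the phenotype mask shape",
                 "herimap_dim_error")
  }
  lab_in_mask <- atlas$volume[vqt$index$coords + 1L]
  labs <- sort(unique(lab_in_mask[lab_in_mask != 0]))
  all_labs <- sort(unique(atlas$volume[atlas$volume != 0]))
  missing_labs <- setdiff(all_labs, labs)
  if (length(labs) == 0) {
    stop_herimap("no atlas label overlaps the phenotype mask",
                 "herimap_value_error")
  }
  if (length(missing_labs)) {
    message(sprintf("atlas label(s) entirely outside mask omitted: %s",
                    paste(missing_labs, collapse = ", ")))
  }
  vox <- lapply(labs, function(l) {
    keep <- lab_in_mask == l
    vqt$index$coords[keep, , drop = FALSE]
  })
  labels <- array(0L, shape)
  for (r in seq_along(vox)) labels[vox[[r]] + 1L] <- r
  rs <- structure(list(
    labels = brain_map(labels, "label", fill = 0),
    regions = tibble(region_id = seq_along(vox),
                     size = vapply(vox, nrow, integer(1)),
                     atlas_label = labs),
    voxels = vox,
    provenance = list(arm = "atlas", connectivity = NA)),
    class = "region_set")
  list(region_set = rs, qts = region_qts(rs, vqt))
}

#' Dice overlap between a region and a reference mask
#'
#' For a ground-truth voxel mask, finds the region with the largest overlap
#' and returns `2|A∩B| / (|A| + |B|)`.
#'
#' @param rs a `region_set`
#' @param mask logical 3D array (reference voxels)
#' @return list with `dice` and the matched `region_id` (dice 0, id `NA` when
#'   the region set is empty)
#' @export
dice_overlap <- function(rs, mask) {
  if (nrow(rs$regions) == 0) return(list(dice = 0, region_id = NA_integer_))
  nref <- sum(mask)
  best <- 0; best_id <- NA_integer_
  for (r in seq_len(nrow(rs$regions))) {
    inter <- sum(mask[rs$voxels[[r]] + 1L])
    d <- 2 * inter / (nref + nrow(rs$voxels[[r]]))
    if (d > best) { best <- d; best_id <- rs$regions$region_id[r] }
  }
  list(dice = best, region_id = best_id)
}

#' Export a region set as a labeled NIfTI volume plus JSON provenance
#' @param rs a `region_set`
#' @param path output NIfTI path; provenance is written next to it as
#'   `<path>.json`
#' @export
write_region_set <- function(rs, path) {
  write_brain_map(rs$labels, path)
  meta <- c(rs$provenance,
            list(n_regions = nrow(rs$regions), sizes = rs$regions$size))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
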