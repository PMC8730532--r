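#' Voxel index: the mask and its vector order
#'
#' Records the one-to-one map between positions in a subject-by-voxel matrix
#' and 0-based 3D coordinates.  Coordinates are kept in lexicographic order
#' (first axis, then second, then third) so matrices are reproducible across
#' runs.
#'
#' @param shape integer vector of 3 positive extents
#' @param coords `V x 3` matrix of 0-based coordinates
#' @return object of class `voxel_index`
#' @export
voxel_index <- function(shape, coords) {
  shape <- as.integer(shape)
  coords <- matrix(as.integer(coords), ncol = 3)
  stopifnot(length(shape) == 3, all(shape > 0))
  if (nrow(coords) > 0) {
    if (any(coords < 0) || any(sweep(coords, 2, shape, ">="))) {
      stop_herimap("voxel coordinates outside volume shape",
                   "herimap_value_error")
    }
    lin <- coord_to_linear(coords, shape)
    if (anyDuplicated(lin)) {
      stop_herimap("duplicate voxel coordinates", "herimap_value_error")
    }
    coords <- coords[coord_order(coords), , drop = FALSE]
  }
  colnames(coords) <- c("i", "j", "k")
  structure(list(shape = shape, coords = coords), class = "voxel_index")
}

#' @export
length.voxel_index <- function(x) nrow(x$coords)

#' @export
print.voxel_index <- function(x, ...) {
  cat(sprintf("<voxel_index> %d voxels in a %s volume\n", length(x),
              paste(x$shape, collapse = "x")))
  invisible(x)
}

#' A 3D map with semantics
#'
#' Wraps a 3D array together with the value used outside the mask and what the
#' values mean (`"heritability"` in `[0,1]`, `"p_value"` in `(0,1]`, or
#' integer `"label"`s).
#'
#' @param volume 3D array
#' @param semantics one of `"heritability"`, `"p_value"`, `"label"`
#' @param fill background fill value (default 0; 1 for p-value maps)
#' @return object of class `brain_map`
#' @export
brain_map <- function(volume,
                      semantics = c("heritability", "p_value", "label"),
                      fill = NULL) {
  semantics <- match.arg(semantics)
  fill <- fill %||% if (semantics == "p_value") 1 else 0
  stopifnot(length(dim(volume)) == 3)
  structure(list(volume = volume, fill = fill, semantics = semantics),
            class = "brain_map")
}

#' @export
print.brain_map <- function(x, ...) {
  cat(sprintf("<brain_map> %s, %s map, fill = %g\n",
              paste(dim(x$volume), collapse = "x"), x$semantics, x$fill))
  invisible(x)
}

#' Vectorize subject volumes into a subject-by-voxel matrix
#'
#' Voxels whose measurement is exactly 0 in every subject are treated as
#' background and excluded; all remaining voxels are kept (a voxel nonzero in
#' even a single subject is retained).  Columns are ordered lexicographically
#' by coordinate and the mapping is preserved in the returned `voxel_index`.
#'
#' @param volumes named list of subject 3D arrays sharing one shape (names =
#'   sample IDs)
#' @return object of class `voxel_qt` with `values` (`N x V`), `samples`, and
#'   `index`
#' @export
vectorize <- function(volumes) {
  stopifnot(length(volumes) >= 1)
  shape <- dim(volumes[[1]])
  nm <- names(volumes) %||% paste0("S", seq_along(volumes))
  for (s in seq_along(volumes)) {
    if (!identical(dim(volumes[[s]]), shape)) {
      stop_herimap(sprintf("subject '%s' volume shape differs from the first",
                           nm[s]), "herimap_dim_error")
    }
  }
  flat <- vapply(volumes, as.vector, numeric(prod(shape)))  # voxels x N
  keep <- rowSums(flat != 0) > 0
  coords <- linear_to_coord(which(keep), shape)
  ord <- coord_order(coords)
  idx <- voxel_index(shape, coords)                          # sorts internally
  values <- t(flat[which(keep)[ord], , drop = FALSE])
  rownames(values) <- nm
  colnames(values) <- NULL
  structure(list(values = values, samples = nm, index = idx),
            class = "voxel_qt")
}

#' @export
print.voxel_qt <- function(x, ...) {
  cat(sprintf("<voxel_qt> %d subjects x %d in-mask voxels (%s volume)\n",
              nrow(x$values), ncol(x$values),
              paste(x$index$shape, collapse = "x")))
  invisible(x)
}

#' Map a per-voxel vector back onto the 3D grid
#'
#' @param values vector of length `length(index)`
#' @param index a [voxel_index()]
#' @param fill value outside the mask (defaults per `semantics`: 1 for
#'   p-value maps so smoothing near mask edges dilutes toward insignificance,
#'   0 otherwise)
#' @param semantics map semantics, see [brain_map()]
#' @return a [brain_map()]
#' @export
devectorize <- function(values, index, fill = NULL,
                        semantics = c("heritability", "p_value", "label")) {
  semantics <- match.arg(semantics)
  if (length(values) != length(index)) {
    stop_herimap(sprintf("got %d values for %d indexed voxels",
                         length(values), length(index)),
                 "herimap_dim_error")
  }
  fill <- fill %||% if (semantics == "p_value") 1 else 0
  vol <- array(fill, dim = index$shape)
  vol[index$coords + 1L] <- values
  brain_map(vol, semantics = semantics, fill = fill)
}

#' Extract the in-mask values of a brain map
#' @param bm a [brain_map()]
#' @param index a [voxel_index()]
#' @return numeric vector in index (lexicographic) order
#' @export
map_values <- function(bm, index) {
  bm$volume[index$coords + 1L]
}

# ---- I/O --------------------------------------------------------------------

#' Read subject volumes from NIfTI files
#' @param paths character vector of `.nii`/`.nii.gz` files
#' @param ids sample IDs (defaults to file names without extension)
#' @return named list of 3D arrays
#' @export
read_nifti_volumes <- function(paths, ids = NULL) {
  ids <- ids %||% sub("\\.nii(\\.gz)?$", "", basename(paths))
  vols <- lapply(paths, function(p) {
    v <- RNifti::readNifti(p)
    array(as.vector(v), dim = dim(v))
  })
  setNames(vols, ids)
}

#' Write a brain map as NIfTI
#' @param bm a [brain_map()]
#' @param path output `.nii`/`.nii.gz` file
#' @export
write_brain_map <- function(bm, path) {
  RNifti::writeNifti(RNifti::asNifti(bm$volume), path)
  invisible(path)
}

#' Write a voxel index as TSV (`vector_pos`, `i`, `j`, `k`; 0-based)
#' @param index a [voxel_index()]
#' @param path output file
#' @export
write_voxel_index <- function(index, path) {
  df <- data.frame(vector_pos = seq_len(length(index)) - 1L, index$coords)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a voxel index written by [write_voxel_index()]
#' @param path TSV file
#' @param shape volume shape (3 integers)
#' @export
read_voxel_index <- function(path, shape) {
  df <- read.delim(path)
  voxel_index(shape, as.matrix(df[, c("i", "j", "k")]))
}
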