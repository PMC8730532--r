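# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.  All simulators route their randomness through this so
# reruns with the same seed are byte-identical.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# lexicographic order of 0-based voxel coordinate rows (i, then j, then k)
coord_order <- function(coords) {
  order(coords[, 1L], coords[, 2L], coords[, 3L])
}

# linear (column-major, 1-based) index of 0-based coordinates in a 3D array
coord_to_linear <- function(coords, shape) {
  1L + coords[, 1L] + shape[1L] * (coords[, 2L] + shape[2L] * coords[, 3L])
}

linear_to_coord <- function(idx, shape) {
  arrayInd(idx, .dim = shape) - 1L
}

stop_herimap <- function(msg, class) {
  abort(msg, class = c(class, "herimap_error"))
}
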