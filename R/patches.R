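#' Extract the 9x9 in-plane patch around a voxel
#'
#' The texture unit of the method is the two-dimensional 9x9 window in the
#' voxel's own slice, read row-major as an 81-vector of HU values. Windows
#' that overrun the grid are edge-clamped (border rows/columns replicated),
#' and window values come from the full volume — the centre voxel must lie in
#' the grid but the window may extend past the segmentation into surrounding
#' lung.
#'
#' Voxel indices are 1-based `(slice, row, column)` triples.
#'
#' @param volume a [ct_volume()].
#' @param voxel integer triple `(slice, row, column)`.
#' @return numeric length-81 patch vector.
#' @export
patch_at <- function(volume, voxel) {
  d <- dim(volume$voxels)
  voxel <- as.integer(voxel)
  if (length(voxel) != 3L || any(voxel < 1L) || any(voxel > d)) {
    stop("voxel (", paste(voxel, collapse = ","), ") outside grid ",
         paste(d, collapse = "x"))
  }
  rows <- pmin(pmax(voxel[2] + (-4:4), 1L), d[2])
  cols <- pmin(pmax(voxel[3] + (-4:4), 1L), d[3])
  as.vector(t(volume$voxels[voxel[1], rows, cols]))
}

#' Similarity between two patches
#'
#' Negative squared Euclidean distance over the 81 HU values — the canonical
#' affinity propagation similarity. Zero iff the patches are identical,
#' symmetric, and more negative the more the textures differ.
#'
#' @param p,q numeric length-81 patch vectors.
#' @return scalar similarity (<= 0).
#' @export
patch_similarity <- function(p, q) {
  if (length(p) != length(q)) {
    stop("patch length mismatch: ", length(p), " vs ", length(q))
  }
  -sum((p - q)^2)
}

# Patch matrix for a set of voxels: one row per voxel, 81 columns.
# Vectorised edge-clamped gather over the full volume.
patch_matrix <- function(volume, voxels) {
  d <- dim(volume$voxels)
  n <- nrow(voxels)
  out <- matrix(NA_real_, n, 81L)
  j <- 0L
  for (dr in -4:4) {
    rr <- pmin(pmax(voxels[, 2] + dr, 1L), d[2])
    for (dc in -4:4) {
      j <- j + 1L
      cc <- pmin(pmax(voxels[, 3] + dc, 1L), d[3])
      out[, j] <- volume$voxels[cbind(voxels[, 1], rr, cc)]
    }
  }
  out
}

#' Sample training patches from inside a segmented nodule
#'
#' Draws `n` patch centres uniformly from the in-mask voxels, without
#' replacement while possible; if `n` exceeds the number of mask voxels the
#' sampler falls back to drawing with replacement and warns.
#'
#' @param volume a [ct_volume()].
#' @param mask a [nodule_mask()] over the same grid.
#' @param n number of patches.
#' @param seed integer RNG seed; the same seed reproduces the same patches.
#' @return list of numeric length-81 patch vectors, with the sampled voxel
#'   index triples attached as attribute `"centers"`.
#' @export
extract_training_patches <- function(volume, mask, n, seed = 1L) {
  if (!identical(dim(mask$indicator), dim(volume$voxels))) {
    stop("mask shape does not match volume shape")
  }
  if (n < 1L) stop("n must be >= 1")
  inside <- which(mask$indicator, arr.ind = TRUE)
  if (nrow(inside) == 0L) stop("empty segmentation")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  if (n > nrow(inside)) {
    warning("requested ", n, " patches from ", nrow(inside),
            " mask voxels; sampling with replacement")
    idx <- sample.int(nrow(inside), n, replace = TRUE)
  } else {
    idx <- sample.int(nrow(inside), n, replace = FALSE)
  }
  centers <- inside[idx, , drop = FALSE]
  pm <- patch_matrix(volume, centers)
  patches <- lapply(seq_len(n), function(i) pm[i, ])
  attr(patches, "centers") <- centers
  patches
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
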