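#' CT volume container
#'
#' A 3D grid of CT attenuation values in Hounsfield units (HU), stored in
#' `(slice, row, column)` axis order together with the physical voxel spacing.
#' Spacing is carried explicitly and never assumed isotropic: clinical chest
#' CTs are reconstructed with in-plane spacing well below the section
#' thickness (0.625-1.5 mm sections are typical).
#'
#' @param voxels numeric 3D array, dimensions `(slice, row, column)`, HU.
#' @param spacing numeric length-3, physical step in mm per axis in the same
#'   `(slice, row, column)` order; all entries must be strictly positive.
#' @param id opaque identifier string.
#' @return an object of class `ct_volume` with fields `voxels`, `spacing`,
#'   `id`.
#' @export
ct_volume <- function(voxels, spacing, id = "volume") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("voxels must be a 3D array in (slice, row, column) order")
  }
  if (any(dim(voxels) == 0L)) stop("voxel grid is empty")
  if (!all(is.finite(voxels))) stop("HU values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three strictly positive mm values")
  }
  structure(
    list(voxels = voxels, spacing = spacing, id = as.character(id)[1]),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume '%s'> %d x %d x %d voxels (slice, row, col), spacing %.4g x %.4g x %.4g mm, HU range [%.0f, %.0f]\n",
    x$id, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

#' Binary nodule segmentation mask
#'
#' @param indicator logical or 0/1 numeric 3D array, same shape as the paired
#'   [ct_volume()]. Any nonzero value marks a voxel as inside the nodule.
#' @param volume optional paired `ct_volume`; if given, shapes must match.
#' @return an object of class `nodule_mask` with fields `indicator` (logical
#'   array) and `voxel_count`.
#' @export
nodule_mask <- function(indicator, volume = NULL) {
  if (!is.array(indicator) || length(dim(indicator)) != 3L) {
    stop("mask must be a 3D array")
  }
  ind <- indicator != 0
  ind[is.na(ind)] <- FALSE
  if (!is.null(volume)) {
    if (!identical(dim(ind), dim(volume$voxels))) {
      stop("mask shape ", paste(dim(ind), collapse = "x"),
           " does not match volume shape ",
           paste(dim(volume$voxels), collapse = "x"))
    }
  }
  n <- sum(ind)
  if (n < 1L) stop("empty segmentation: mask selects no voxels")
  structure(
    list(indicator = ind, voxel_count = as.integer(n)),
    class = "nodule_mask"
  )
}

#' @export
print.nodule_mask <- function(x, ...) {
  cat(sprintf("<nodule_mask> %d voxels set of %s grid\n",
              x$voxel_count, paste(dim(x$indicator), collapse = "x")))
  invisible(x)
}

# mm^3 volume of one voxel
voxel_volume_mm3 <- function(spacing) prod(spacing)
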