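#' Read a CT volume from NIfTI or a DICOM series
#'
#' NIfTI volumes are read with the `RNifti` backend; the on-disk `(i, j, k)`
#' axes are mapped onto the package's `(slice, row, column)` convention with
#' `i` = column, `j` = row, `k` = slice, and `pixdim` supplies the spacing.
#' DICOM directories must contain exactly one coherent axial series of
#' uncompressed slices; stored values are converted to HU with the per-slice
#' rescale slope and intercept, and slices are stacked by physical position.
#'
#' @param path file path (NIfTI) or directory (DICOM series).
#' @param format `"nifti"` or `"dicom-series"`; default guesses from `path`.
#' @return a [ct_volume()].
#' @export
read_ct_volume <- function(path, format = c("auto", "nifti", "dicom-series")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom-series" else "nifti"
  }
  if (format == "nifti") {
    if (!file.exists(path)) stop("no such file: ", path)
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume: ", path)
    pd <- RNifti::pixdim(img)
    vox <- aperm(arr, c(3L, 2L, 1L))
    ct_volume(vox, spacing = pd[c(3L, 2L, 1L)],
              id = sub("\\.nii(\\.gz)?$", "", basename(path)))
  } else {
    read_dicom_series(path)
  }
}

#' Read a nodule segmentation mask from NIfTI
#'
#' Any nonzero value is treated as inside the nodule.
#'
#' @param path NIfTI file path.
#' @param volume optional paired [ct_volume()] for shape checking.
#' @return a [nodule_mask()].
#' @export
read_mask <- function(path, volume = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI mask: ", path)
  nodule_mask(aperm(arr, c(3L, 2L, 1L)), volume = volume)
}

#' Write a CT volume (or any 3D grid) to NIfTI
#'
#' @param volume a [ct_volume()], or a plain 3D array with `spacing` given.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing spacing override when `volume` is a bare array.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(volume, path, spacing = NULL) {
  if (inherits(volume, "ct_volume")) {
    arr <- volume$voxels
    spacing <- volume$spacing
  } else {
    arr <- volume
    if (is.null(spacing)) stop("spacing required for a bare array")
  }
  img <- RNifti::asNifti(aperm(arr, c(3L, 2L, 1L)))
  RNifti::pixdim(img) <- spacing[c(3L, 2L, 1L)]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a nodule mask to NIfTI
#'
#' @param mask a [nodule_mask()].
#' @param path output path.
#' @param spacing mm spacing triple to record.
#' @return `path`, invisibly.
#' @export
write_nifti_mask <- function(mask, path, spacing = c(1, 1, 1)) {
  write_nifti_volume(array(as.integer(mask$indicator), dim(mask$indicator)),
                     path, spacing = spacing)
}
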