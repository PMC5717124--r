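#' Classify one patch by its nearest exemplar
#'
#' Returns the colour code of the exemplar maximising [patch_similarity()].
#' Exact ties break by the fixed colour order `C, B, G, P, Y, O, R, I, V`.
#'
#' @param patch numeric length-81 vector.
#' @param exemplars an [exemplar_set()].
#' @return single colour code.
#' @export
classify_voxel <- function(patch, exemplars) {
  stopifnot(inherits(exemplars, "exemplar_set"))
  if (length(patch) != 81L) stop("patch must have length 81")
  sims <- -colSums((t(exemplars$exemplars) - patch)^2)
  exemplars$labels[which.max(sims)]  # which.max takes the first of ties
}

#' Label every in-mask voxel by its nearest exemplar
#'
#' For each voxel inside the segmentation the 9x9 in-plane patch around it is
#' compared to the nine exemplars and the voxel receives the colour code of
#' the most similar one. Out-of-mask voxels are unlabelled. The computation
#' is deterministic.
#'
#' @param volume a [ct_volume()].
#' @param mask a [nodule_mask()] on the same grid (>= 1 voxel).
#' @param exemplars an [exemplar_set()].
#' @return a `voxel_label_map`: list with `codes` (integer 3D array, 0
#'   outside the mask, 1-9 = rank of the colour in the canonical order
#'   inside), `colors` (the canonical colour order giving code -> colour),
#'   and `spacing`.
#' @export
classify_nodule <- function(volume, mask, exemplars) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "nodule_mask"),
            inherits(exemplars, "exemplar_set"))
  if (!identical(dim(mask$indicator), dim(volume$voxels))) {
    stop("mask shape does not match volume shape")
  }
  inside <- which(mask$indicator, arr.ind = TRUE)
  if (nrow(inside) == 0L) stop("empty segmentation")
  P <- patch_matrix(volume, inside)
  E <- exemplars$exemplars
  # squared distance matrix N x 9 via the expansion |p|^2 + |e|^2 - 2 p.e
  d2 <- matrix(rowSums(P^2), nrow(P), 9L) +
    matrix(rowSums(E^2), nrow(P), 9L, byrow = TRUE) - 2 * P %*% t(E)
  nearest <- max.col(-d2, ties.method = "first")
  codes <- array(0L, dim(volume$voxels))
  codes[inside] <- nearest
  structure(list(codes = codes, colors = exemplars$labels,
                 spacing = volume$spacing),
            class = "voxel_label_map")
}

#' @export
print.voxel_label_map <- function(x, ...) {
  n <- sum(x$codes > 0L)
  cat(sprintf("<voxel_label_map> %d labelled voxels of %s grid\n", n,
              paste(dim(x$codes), collapse = "x")))
  tab <- tabulate(x$codes[x$codes > 0L], 9L)
  cat("  ", paste(sprintf("%s:%d", x$colors, tab), collapse = " "), "\n")
  invisible(x)
}

#' Aggregate voxel labels into the three risk components
#'
#' Counts labelled voxels per risk group through the fixed colour partition
#' and converts counts to absolute volumes (mL, using the exact voxel volume
#' from the spacing) and relative percentages of the labelled volume.
#'
#' @param labelmap a `voxel_label_map` from [classify_nodule()].
#' @param spacing mm spacing triple; defaults to the label map's own.
#' @return a `risk_components`: list with `absolute` (named mL triple),
#'   `relative` (named percentage triple summing to 100), `voxel_counts`.
#' @export
aggregate_risk <- function(labelmap, spacing = labelmap$spacing) {
  codes <- labelmap$codes[labelmap$codes > 0L]
  if (length(codes) == 0L) stop("label map has no labelled voxels")
  groups <- risk_group_of(labelmap$colors[codes])
  counts <- c(low = sum(groups == "low"),
              intermediate = sum(groups == "intermediate"),
              high = sum(groups == "high"))
  ml_per_voxel <- voxel_volume_mm3(spacing) / 1000
  structure(list(absolute = counts * ml_per_voxel,
                 relative = 100 * counts / length(codes),
                 voxel_counts = counts),
            class = "risk_components")
}

#' @export
print.risk_components <- function(x, ...) {
  cat("<risk_components>\n")
  for (g in names(x$relative)) {
    cat(sprintf("  %-12s %6.1f %%  %8.3f mL\n", g, x$relative[[g]],
                x$absolute[[g]]))
  }
  invisible(x)
}
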