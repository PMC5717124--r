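#' Write the per-nodule classification report
#'
#' Writes three artifacts to `out`: `components.json` with the absolute (mL)
#' and relative (%) volume of each risk component, `labelmap.nii.gz` with
#' integer codes 1-9 (density rank in the canonical colour order, 0 outside
#' the mask), and one PNG per mask-bearing slice showing the CT in lung
#' window with the nine-colour overlay.
#'
#' @param components a `risk_components` from [aggregate_risk()].
#' @param labelmap a `voxel_label_map` from [classify_nodule()].
#' @param out output directory (created if needed).
#' @param volume optional [ct_volume()] for the PNG background; without it
#'   overlays are drawn on black.
#' @param window lung window `(center, width)` in HU for the background.
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(components, labelmap, out, volume = NULL,
                         window = c(-500, 1500)) {
  stopifnot(inherits(components, "risk_components"),
            inherits(labelmap, "voxel_label_map"))
  if (any(labelmap$codes < 0L | labelmap$codes > 9L)) {
    stop("label map codes must lie in 0-9")
  }
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out)) stop("cannot create output directory: ", out)

  paths <- character(0)
  jpath <- file.path(out, "components.json")
  jsonlite::write_json(list(
    absolute_ml = as.list(components$absolute),
    relative_pct = as.list(components$relative),
    voxel_counts = as.list(as.integer(components$voxel_counts))
  ), jpath, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, jpath)

  lpath <- file.path(out, "labelmap.nii.gz")
  write_nifti_volume(labelmap$codes, lpath, spacing = labelmap$spacing)
  paths <- c(paths, lpath)

  slices <- which(apply(labelmap$codes > 0L, 1, any))
  pal <- grDevices::col2rgb(CANARY_PALETTE[labelmap$colors]) / 255
  for (s in slices) {
    codes <- labelmap$codes[s, , ]
    if (is.null(volume)) {
      bg <- array(0, dim(codes))
    } else {
      lo <- window[1] - window[2] / 2
      bg <- pmin(pmax((volume$voxels[s, , ] - lo) / window[2], 0), 1)
    }
    img <- array(rep(bg, 3), c(dim(codes), 3L))
    lab <- which(codes > 0L, arr.ind = TRUE)
    if (nrow(lab) > 0) {
      for (ch in 1:3) {
        img[cbind(lab, ch)] <- pal[ch, codes[lab]]
      }
    }
    ppath <- file.path(out, sprintf("overlay_slice_%03d.png", s))
    png::writePNG(img, ppath)
    paths <- c(paths, ppath)
  }
  invisible(paths)
}

# Cohort table columns, in the on-disk CSV order.
COHORT_COLUMNS <- c("id", "subtype", "low_pct", "int_pct", "high_pct",
                    "low_ml", "int_ml", "high_ml", "invasive_focus_mm",
                    "avg_diameter_mm")

#' Read a per-nodule cohort table from CSV
#'
#' Columns: `id, subtype, low_pct, int_pct, high_pct, low_ml, int_ml,
#' high_ml, invasive_focus_mm, avg_diameter_mm` (the last is optional).
#' Subtypes must be AIS, MIA or IAC and ids unique.
#'
#' @param path CSV path.
#' @return data.frame of nodule records.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' Write a cohort table to CSV
#'
#' @param cohort data.frame of nodule records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  cols <- intersect(COHORT_COLUMNS, names(cohort))
  utils::write.csv(cohort[, cols], path, row.names = FALSE)
  invisible(path)
}

validate_cohort <- function(df) {
  need <- c("id", "subtype", "low_pct", "int_pct", "high_pct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop("cohort ids must be unique")
  bad <- setdiff(unique(df$subtype), c("AIS", "MIA", "IAC"))
  if (length(bad)) stop("unknown subtype(s): ", paste(bad, collapse = ", "))
  pct <- df[, c("low_pct", "int_pct", "high_pct")]
  if (any(pct < 0 | pct > 100)) stop("percentages must lie in [0, 100]")
  sums <- rowSums(pct)
  if (nrow(df) && any(abs(sums - 100) > 0.2)) {
    stop("component percentages must sum to 100 within 0.2")
  }
  df
}
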