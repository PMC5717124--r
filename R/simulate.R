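# Truncated-normal draws by inverse CDF on the truncated range; sd = 0
# degenerates to the clamped mean.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm((lower - mean) / sd)
  phi <- stats::pnorm((upper - mean) / sd)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qnorm(u) * sd + mean, lower), upper)
}

#' Per-subtype component distribution parameters
#'
#' Mean, SD and range of each risk-component percentage and volume (mL) for
#' AIS, MIA and IAC, plus default group sizes (28, 26, 10). The defaults are
#' the published per-subtype summaries for resected pure ground-glass
#' adenocarcinomas; pass a modified copy to explore other cohorts.
#'
#' @return nested list `params[[subtype]][[representation]][[component]]` =
#'   `c(mean, sd, min, max)`, with `$n` holding the default group sizes.
#' @export
subtype_params <- function() {
  list(
    AIS = list(
      pct = list(low  = c(78.5, 17.6, 45.2, 100.0),
                 int  = c(21.5, 17.6,  0.0,  54.8),
                 high = c( 0.0,  0.0,  0.0,   0.1)),
      ml  = list(low  = c(1.1, 1.2, 0.2, 7.1),
                 int  = c(0.3, 0.5, 0.0, 2.7),
                 high = c(0.0, 0.0, 0.0, 0.0))
    ),
    MIA = list(
      pct = list(low  = c(65.3, 27.0, 15.5, 100.0),
                 int  = c(32.3, 23.5,  0.0,  71.0),
                 high = c( 2.4,  6.6,  0.0,  29.6)),
      ml  = list(low  = c(1.5, 1.7, 0.2, 7.1),
                 int  = c(0.9, 1.6, 0.0, 8.2),
                 high = c(0.1, 0.3, 0.0, 1.6))
    ),
    IAC = list(
      pct = list(low  = c(46.6, 22.9, 20.1, 90.0),
                 int  = c(49.9, 19.8, 10.0, 66.9),
                 high = c( 3.4,  5.5,  0.0,  17.1)),
      ml  = list(low  = c(2.3, 2.8, 0.3, 7.4),
                 int  = c(3.9, 6.9, 0.1, 23.3),
                 high = c(0.7, 1.9, 0.0, 6.3))
    ),
    n = c(AIS = 28L, MIA = 26L, IAC = 10L)
  )
}

# Rescale a percentage triple to sum 100 while respecting per-component
# truncation ranges: proportional scaling, clamping, then distributing the
# (tiny) residual over the components with slack.
renormalize_pct <- function(p, lo, hi) {
  for (i in 1:50) {
    p <- p * 100 / sum(p)
    q <- pmin(pmax(p, lo), hi)
    if (max(abs(q - p)) < 1e-12) { p <- q; break }
    p <- q
  }
  resid <- 100 - sum(p)
  if (abs(resid) > 1e-12) {
    slack <- if (resid > 0) hi - p else p - lo
    if (sum(slack) < abs(resid)) stop("percentage ranges cannot reach 100")
    p <- p + resid * slack / sum(slack)
  }
  p
}

#' Simulate a per-nodule cohort table
#'
#' For each nodule the three component percentages are drawn from the
#' subtype's truncated normal distributions and renormalised to sum to 100
#' within the truncation ranges (the AIS high-risk share stays within its
#' 0-0.1 range). Invasive focus size is 0 for AIS, uniform on (0, 5] mm for
#' MIA and (5, 15] mm for IAC, rank-coupled within subtype to the
#' intermediate-plus-high percentage so that focus size and high-risk share
#' correlate positively at the cohort level. Component volumes are the
#' percentages applied to a drawn total nodule volume.
#'
#' @param params parameter set from [subtype_params()].
#' @param n named per-subtype counts `(AIS, MIA, IAC)`; defaults to
#'   `params$n`.
#' @param seed integer seed.
#' @return cohort data.frame (see [read_cohort()] for the columns).
#' @export
simulate_cohort <- function(params = subtype_params(), n = params$n,
                            seed = 1L) {
  if (any(n < 0)) stop("subtype counts must be nonnegative")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  rows <- list()
  for (st in c("AIS", "MIA", "IAC")) {
    k <- n[[st]]
    if (k == 0) next
    pp <- params[[st]]$pct
    lo <- vapply(pp, `[`, numeric(1), 3)
    hi <- vapply(pp, `[`, numeric(1), 4)
    pct <- matrix(NA_real_, k, 3)
    for (i in seq_len(k)) {
      draw <- vapply(pp, function(v) rtruncnorm(1, v[1], v[2], v[3], v[4]),
                     numeric(1))
      pct[i, ] <- renormalize_pct(draw, lo, hi)
    }
    ml_par <- params[[st]]$ml
    tot_mean <- sum(vapply(ml_par, `[`, numeric(1), 1))
    tot_sd <- sqrt(sum(vapply(ml_par, `[`, numeric(1), 2)^2))
    tot_lo <- sum(vapply(ml_par, `[`, numeric(1), 3))
    tot_hi <- sum(vapply(ml_par, `[`, numeric(1), 4))
    total_ml <- rtruncnorm(k, tot_mean, tot_sd, max(tot_lo, 0.05), tot_hi)

    focus <- switch(st,
      AIS = rep(0, k),
      MIA = stats::runif(k, 0, 5),
      IAC = stats::runif(k, 5, 15))
    if (st != "AIS" && k > 1) {
      # rank-couple focus size to the invasive (int + high) share
      focus <- sort(focus)[rank(pct[, 2] + pct[, 3], ties.method = "first")]
    }
    diam <- rtruncnorm(k, 14.4, 5.3, 5, 30)

    rows[[st]] <- data.frame(
      id = sprintf("%s-%03d", st, seq_len(k)),
      subtype = st,
      low_pct = pct[, 1], int_pct = pct[, 2], high_pct = pct[, 3],
      low_ml = pct[, 1] / 100 * total_ml,
      int_ml = pct[, 2] / 100 * total_ml,
      high_ml = pct[, 3] / 100 * total_ml,
      invasive_focus_mm = focus,
      avg_diameter_mm = diam,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    out <- data.frame(id = character(), subtype = character(),
                      low_pct = numeric(), int_pct = numeric(),
                      high_pct = numeric(), low_ml = numeric(),
                      int_ml = numeric(), high_ml = numeric(),
                      invasive_focus_mm = numeric(),
                      avg_diameter_mm = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Phantom specification for a synthetic ground-glass nodule
#'
#' Describes an ellipsoidal ground-glass nodule of lepidic texture embedded
#' in aerated-lung background, with an optional denser central spherical
#' invasive focus. Hounsfield levels are synthetic texture parameters chosen
#' to reproduce the density contrast between aerated lung (about -870 HU),
#' lepidic ground-glass (about -650 HU) and solid invasive tissue (about
#' -150 HU); they are configuration, not measurements.
#'
#' @param subtype `"AIS"`, `"MIA"` or `"IAC"`.
#' @param diameter_mm overall nodule diameter; `NULL` draws near the cohort
#'   mean 14.4 +/- 5.3 mm.
#' @param focus_mm invasive-focus diameter; `NULL` draws per subtype (0 for
#'   AIS, (0, 5] for MIA, (5, 15] for IAC). Must be consistent with the
#'   subtype and smaller than the nodule.
#' @param spacing mm voxel spacing `(slice, row, column)`.
#' @param hu named list of texture levels: `lung`, `lepidic`, `focus`, each
#'   `c(mean, sd)` in HU, and `smoothing_mm` (Gaussian scale).
#' @param seed integer seed.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(subtype = c("AIS", "MIA", "IAC"),
                         diameter_mm = NULL, focus_mm = NULL,
                         spacing = c(1.25, 0.7, 0.7),
                         hu = list(lung = c(-870, 40), lepidic = c(-650, 50),
                                   focus = c(-150, 80), smoothing_mm = 0.8),
                         seed = 1L) {
  subtype <- match.arg(subtype)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed) + 90199L)  # spec-level draws, distinct stream
  if (is.null(focus_mm)) {
    focus_mm <- switch(subtype, AIS = 0,
                       MIA = stats::runif(1, 1, 5),
                       IAC = stats::runif(1, 5.5, 10))
  }
  if (subtype == "AIS" && focus_mm != 0) stop("AIS phantoms have no focus")
  if (subtype == "MIA" && (focus_mm <= 0 || focus_mm > 5)) {
    stop("MIA focus must lie in (0, 5] mm")
  }
  if (subtype == "IAC" && focus_mm <= 5) stop("IAC focus must exceed 5 mm")
  if (is.null(diameter_mm)) {
    diameter_mm <- rtruncnorm(1, 14.4, 5.3, max(8, focus_mm + 3), 30)
  }
  if (focus_mm >= diameter_mm) {
    stop("focus (", focus_mm, " mm) must be smaller than the nodule (",
         diameter_mm, " mm)")
  }
  structure(list(subtype = subtype, diameter_mm = diameter_mm,
                 focus_mm = focus_mm, spacing = spacing, hu = hu,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Separable Gaussian smoothing with edge replication.
gauss_smooth_3d <- function(a, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 1e-8) next
    r <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(-r:r, sd = s); w <- w / sum(w)
    d <- dim(a); nn <- d[axis]
    out <- array(0, d)
    for (j in seq_along(w)) {
      idx <- pmin(pmax(seq_len(nn) + (j - r - 1L), 1L), nn)
      out <- out + w[j] * switch(axis,
        a[idx, , , drop = FALSE],
        a[, idx, , drop = FALSE],
        a[, , idx, drop = FALSE])
    }
    a <- out
  }
  a
}

#' Simulate a ground-glass nodule phantom
#'
#' Builds a lung-background volume, inserts an ellipsoidal lepidic nodule
#' and, for invasive subtypes, a central spherical denser focus, then applies
#' Gaussian smoothing at the configured scale. The same seed reproduces the
#' volume bit for bit, and the lepidic field is drawn before any focus
#' values, so phantoms differing only in focus size share their background
#' and lepidic texture.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([ct_volume()]), `mask` ([nodule_mask()], the
#'   ellipsoid), and `truth` (subtype, diameters, and the focus voxel
#'   indicator).
#' @export
simulate_nodule <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  sp <- spec$spacing
  margin <- 6L
  half <- spec$diameter_mm / 2
  dims <- as.integer(ceiling(spec$diameter_mm / sp) + 2L * margin)
  ctr <- (dims + 1) / 2

  # physical offset of every voxel from the nodule centre, per axis
  off <- lapply(1:3, function(k) (seq_len(dims[k]) - ctr[k]) * sp[k])
  d2 <- outer(outer(off[[1]]^2, off[[2]]^2, "+"), off[[3]]^2, "+")
  rel2 <- outer(outer((off[[1]] / half)^2, (off[[2]] / half)^2, "+"),
                (off[[3]] / half)^2, "+")
  inside <- rel2 <= 1

  hu <- spec$hu
  vox <- array(stats::rnorm(prod(dims), hu$lung[1], hu$lung[2]), dims)
  n_in <- sum(inside)
  vox[inside] <- stats::rnorm(n_in, hu$lepidic[1], hu$lepidic[2])
  focus_ind <- array(FALSE, dims)
  if (spec$focus_mm > 0) {
    focus_ind <- d2 <= (spec$focus_mm / 2)^2
    vox[focus_ind] <- stats::rnorm(sum(focus_ind), hu$focus[1], hu$focus[2])
  }
  vox <- gauss_smooth_3d(vox, hu$smoothing_mm / sp)

  vol <- ct_volume(vox, spacing = sp,
                   id = sprintf("phantom-%s-seed%d", spec$subtype, spec$seed))
  mask <- nodule_mask(inside, volume = vol)
  list(volume = vol, mask = mask,
       truth = list(subtype = spec$subtype, diameter_mm = spec$diameter_mm,
                    focus_mm = spec$focus_mm, focus_voxels = focus_ind,
                    nodule_voxels = inside))
}

# In-plane erosion of a convex mask by the patch half-width: keeps voxels
# whose whole 9x9 window lies inside the mask (checked at the 4 window
# corners, sufficient for convex in-plane cross-sections).
erode_mask_inplane <- function(indicator, r = 4L) {
  d <- dim(indicator)
  idx <- which(indicator, arr.ind = TRUE)
  corner_in <- function(dr, dc) {
    rr <- idx[, 2] + dr; cc <- idx[, 3] + dc
    ok <- rr >= 1L & rr <= d[2] & cc >= 1L & cc <= d[3]
    out <- rep(FALSE, nrow(idx))
    out[ok] <- indicator[cbind(idx[ok, 1], rr[ok], cc[ok])]
    out
  }
  keep <- corner_in(-r, -r) & corner_in(-r, r) &
    corner_in(r, -r) & corner_in(r, r)
  out <- array(FALSE, d)
  out[idx[keep, , drop = FALSE]] <- TRUE
  out
}

#' Simulate a training patch set spanning the nodule density range
#'
#' Generates `n_nodules` single-texture phantoms whose lepidic density sweeps
#' the spectrum from near-aerated ground glass to solid invasive tissue, and
#' samples a fixed total number of patches spread evenly across them. Patch
#' centres are restricted to nodule interiors (the whole 9x9 window inside
#' the segmentation) so the learned exemplars are homogeneous textures whose
#' mean HU orders them along the density axis; without this restriction
#' boundary patches with strong spatial gradients become exemplars and the
#' nearest-exemplar rule loses its density semantics. The defaults (37
#' nodules, 774 patches) mirror the size of the original exemplar-derivation
#' training set.
#'
#' @param n_nodules number of phantoms.
#' @param patches_per_set total number of 9x9 patches.
#' @param seed integer seed.
#' @return list of numeric length-81 patches.
#' @export
simulate_training_set <- function(n_nodules = 37L, patches_per_set = 774L,
                                  seed = 1L) {
  if (n_nodules < 1L || patches_per_set < 1L) stop("counts must be >= 1")
  if (n_nodules == 1L) {
    warning("all training patches drawn from a single phantom")
  }
  means <- if (n_nodules == 1L) -650 else
    seq(-800, -150, length.out = n_nodules)
  per <- rep(patches_per_set %/% n_nodules, n_nodules)
  extra <- patches_per_set %% n_nodules
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  patches <- vector("list", 0L)
  for (i in seq_len(n_nodules)) {
    if (per[i] == 0L) next
    spec <- phantom_spec("AIS", diameter_mm = 12, focus_mm = 0,
                         hu = list(lung = c(-870, 40),
                                   lepidic = c(means[i], 50),
                                   focus = c(-150, 80), smoothing_mm = 0.8),
                         seed = seed * 1000L + i)
    ph <- simulate_nodule(spec)
    interior <- erode_mask_inplane(ph$mask$indicator)
    msk <- if (sum(interior) >= per[i]) {
      nodule_mask(interior, volume = ph$volume)
    } else {
      ph$mask
    }
    patches <- c(patches, suppressWarnings(extract_training_patches(
      ph$volume, msk, per[i], seed = seed * 1000L + 500L + i)))
  }
  patches
}
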