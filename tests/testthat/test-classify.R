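# colours indexed by code, as classify_nodule emits them
CANARY_COLOR_ORDER_test <- function() c("C", "B", "G", "P", "Y", "O", "R", "I", "V")

test_that("classify_voxel matches identity, tie rule and brute force", {
  es <- flat_exemplar_set()
  # a patch equal to an exemplar returns that exemplar's label
  for (i in c(1, 5, 9)) {
    expect_identical(classify_voxel(es$exemplars[i, ], es), es$labels[i])
  }
  # exactly midway between the two least dense exemplars: first in the
  # colour order (C) wins
  mid <- (es$exemplars[1, ] + es$exemplars[2, ]) / 2
  expect_identical(classify_voxel(mid, es), "C")
  # brute-force oracle over the nine similarities
  set.seed(6)
  for (i in 1:20) {
    p <- rnorm(81, mean = runif(1, -900, -100), sd = 60)
    sims <- vapply(1:9, function(k) patch_similarity(p, es$exemplars[k, ]),
                   numeric(1))
    expect_identical(classify_voxel(p, es), es$labels[which.max(sims)])
  }
})

test_that("classify_nodule labels exactly the mask and matches per-voxel brute force", {
  es <- flat_exemplar_set()
  set.seed(8)
  vox <- array(rnorm(4 * 16 * 16, -600, 150), c(4, 16, 16))
  vol <- ct_volume(vox, c(1.25, 0.7, 0.7))
  msk <- box_mask(vol)  # < 1000 voxels
  lm <- classify_nodule(vol, msk, es)
  expect_identical(lm$codes > 0L, msk$indicator)
  idx <- which(msk$indicator, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    expected <- classify_voxel(patch_at(vol, idx[i, ]), es)
    expect_identical(lm$colors[lm$codes[idx[i, , drop = FALSE]]], expected)
  }
  # determinism
  expect_identical(classify_nodule(vol, msk, es)$codes, lm$codes)
  # single-voxel mask
  one <- array(FALSE, dim(vox)); one[2, 8, 8] <- TRUE
  lm1 <- classify_nodule(vol, nodule_mask(one, vol), es)
  expect_identical(sum(lm1$codes > 0L), 1L)
})

test_that("uniform texture at an exemplar level classifies wholly to it", {
  es <- flat_exemplar_set()
  vol <- const_volume(rowMeans(es$exemplars)[2], dims = c(3, 14, 14))
  msk <- box_mask(vol)
  lm <- classify_nodule(vol, msk, es)
  expect_setequal(unique(lm$codes[msk$indicator]), 2L)  # "B"
})

test_that("aggregate_risk converts counts to mL and normalised percentages", {
  # hand-built label map: counts (320, 669, 11) over a 10x10x10 grid
  codes <- array(0L, c(10, 10, 10))
  groups_codes <- list(low = 1L, intermediate = 4L, high = 9L)
  flat <- c(rep(1L, 320), rep(4L, 669), rep(9L, 11))
  codes[seq_along(flat)] <- flat
  lm <- structure(list(codes = codes, colors = CANARY_COLOR_ORDER_test(),
                       spacing = c(1, 1, 1)), class = "voxel_label_map")
  rc <- aggregate_risk(lm)
  expect_equal(unname(rc$relative), c(32.0, 66.9, 1.1))
  expect_equal(unname(rc$absolute), c(0.320, 0.669, 0.011))
  expect_equal(sum(rc$relative), 100, tolerance = 1e-6)
  # 1000 voxels all low at 1 mm isotropic -> 1 mL low
  codes2 <- array(0L, c(10, 10, 10)); codes2[] <- 2L
  lm2 <- structure(list(codes = codes2, colors = CANARY_COLOR_ORDER_test(),
                        spacing = c(1, 1, 1)), class = "voxel_label_map")
  rc2 <- aggregate_risk(lm2)
  expect_equal(unname(rc2$absolute), c(1, 0, 0))
  expect_equal(unname(rc2$relative), c(100, 0, 0))
})

test_that("absolute component volumes conserve the mask volume", {
  es <- flat_exemplar_set()
  set.seed(9)
  for (rep in 1:3) {
    vox <- array(rnorm(4 * 15 * 15, runif(1, -800, -300), 120), c(4, 15, 15))
    vol <- ct_volume(vox, c(1.25, 0.7, 0.7))
    msk <- box_mask(vol)
    rc <- aggregate_risk(classify_nodule(vol, msk, es))
    total_ml <- msk$voxel_count * prod(vol$spacing) / 1000
    expect_equal(sum(rc$absolute), total_ml, tolerance = 1e-9)
    expect_equal(sum(rc$relative), 100, tolerance = 1e-6)
  }
})
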