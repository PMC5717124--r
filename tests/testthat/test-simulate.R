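test_that("simulated cohorts respect ranges, sums and subtype-focus rules", {
  for (s in 1:20) {
    co <- simulate_cohort(seed = s)
    expect_equal(nrow(co), 64)
    sums <- co$low_pct + co$int_pct + co$high_pct
    expect_true(all(abs(sums - 100) < 1e-6))
    prm <- subtype_params()
    for (st in c("AIS", "MIA", "IAC")) {
      sub <- co[co$subtype == st, ]
      for (cmp in c("low", "int", "high")) {
        v <- prm[[st]]$pct[[cmp]]
        x <- sub[[paste0(cmp, "_pct")]]
        expect_true(all(x >= v[3] - 1e-9 & x <= v[4] + 1e-9),
                    label = paste(st, cmp, "within range"))
      }
    }
    expect_true(all(co$invasive_focus_mm[co$subtype == "AIS"] == 0))
    expect_true(all(co$invasive_focus_mm[co$subtype == "MIA"] > 0 &
                      co$invasive_focus_mm[co$subtype == "MIA"] <= 5))
    expect_true(all(co$invasive_focus_mm[co$subtype == "IAC"] > 5 &
                      co$invasive_focus_mm[co$subtype == "IAC"] <= 15))
    # mL columns consistent with percentages
    tot <- co$low_ml + co$int_ml + co$high_ml
    expect_equal(co$low_ml, co$low_pct / 100 * tot, tolerance = 1e-9)
  }
  # determinism and empty case
  expect_identical(simulate_cohort(seed = 3), simulate_cohort(seed = 3))
  expect_equal(nrow(simulate_cohort(n = c(AIS = 0, MIA = 0, IAC = 0))), 0)
})

test_that("cohort moments track the generating truncated normals", {
  # Monte-Carlo oracle for the truncated-normal mean of the AIS low% draw
  set.seed(99)
  v <- subtype_params()$AIS$pct$low
  big <- canary:::rtruncnorm(2e5, v[1], v[2], v[3], v[4])
  oracle_mean <- mean(big)  # renormalisation shifts it only slightly
  means <- vapply(1:200, function(s) {
    co <- simulate_cohort(seed = s)
    mean(co$low_pct[co$subtype == "AIS"])
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - oracle_mean), 3 * se + 1)
})

test_that("focus size correlates positively with the high-risk share", {
  co <- simulate_cohort(seed = 5)
  inv <- co[co$subtype != "AIS", ]
  r <- spearman_correlation(inv$invasive_focus_mm, inv$high_pct)$rho
  expect_gt(r, 0)
  r_all <- spearman_correlation(co$invasive_focus_mm,
                                co$int_pct + co$high_pct)$rho
  expect_gt(r_all, 0)
})

test_that("phantoms are deterministic, subtype-consistent and focus-bearing", {
  a1 <- simulate_nodule(phantom_spec("AIS", seed = 7))
  a2 <- simulate_nodule(phantom_spec("AIS", seed = 7))
  expect_identical(a1$volume$voxels, a2$volume$voxels)  # bit-identical
  expect_false(any(a1$truth$focus_voxels))

  i1 <- simulate_nodule(phantom_spec("IAC", focus_mm = 8, diameter_mm = 16,
                                     seed = 7))
  expect_gt(sum(i1$truth$focus_voxels), 0)
  expect_true(all(i1$truth$focus_voxels[i1$truth$nodule_voxels] |
                    !i1$truth$focus_voxels[i1$truth$nodule_voxels]))
  # focus voxels lie inside the nodule
  expect_true(all(i1$mask$indicator[i1$truth$focus_voxels]))

  expect_error(phantom_spec("AIS", focus_mm = 3), "no focus")
  expect_error(phantom_spec("MIA", focus_mm = 7), "\\(0, 5\\]")
  expect_error(phantom_spec("IAC", focus_mm = 4), "exceed 5")
  expect_error(phantom_spec("IAC", focus_mm = 8, diameter_mm = 7), "smaller")
})

test_that("denser focus never raises the low-risk percentage (paired seeds)", {
  es <- trained_exemplars()
  lowpct <- function(ph)
    aggregate_risk(classify_nodule(ph$volume, ph$mask, es))$relative[["low"]]
  for (r in 1:8) {
    set.seed(r)
    diam <- canary:::rtruncnorm(1, 14.4, 5.3, 10, 22)
    f <- runif(1, 2, 8)
    st <- if (f > 5) "IAC" else "MIA"
    base <- lowpct(simulate_nodule(
      phantom_spec("AIS", diameter_mm = diam, focus_mm = 0, seed = r + 300)))
    with_focus <- lowpct(simulate_nodule(
      phantom_spec(st, diameter_mm = diam, focus_mm = f, seed = r + 300)))
    expect_lte(with_focus, base)
  }
})

test_that("training set has the requested size and is seeded", {
  p <- simulate_training_set(5, 40, seed = 2)
  expect_length(p, 40)
  expect_true(all(lengths(p) == 81))
  expect_identical(simulate_training_set(5, 40, seed = 2), p)
  expect_warning(simulate_training_set(1, 10, seed = 1), "single phantom")
})
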