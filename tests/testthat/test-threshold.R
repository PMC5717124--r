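test_that("invasiveness call is inclusive at the threshold", {
  expect_identical(classify_invasive(32.0, 45), "invasive")
  expect_identical(classify_invasive(99.8, 45), "non-invasive")
  expect_identical(classify_invasive(45.0, 45), "invasive")  # "45% or less"
  expect_error(classify_invasive(120), "0, 100")
})

test_that("diagnostic_counts cross-tabulates against AIS as the negative class", {
  co <- data.frame(
    id = paste0("n", 1:5),
    subtype = c("MIA", "MIA", "IAC", "AIS", "AIS"),
    low_pct = c(30, 40, 50, 60, 70),
    int_pct = c(70, 60, 50, 40, 30),
    high_pct = 0
  )
  cts <- diagnostic_counts(co, 45)
  expect_equal(cts, list(TP = 2L, FP = 0L, TN = 2L, FN = 1L))
  all_pos <- diagnostic_counts(co, 100)
  expect_equal(all_pos$FN, 0L); expect_equal(all_pos$TN, 0L)
  none <- diagnostic_counts(co, 10)
  expect_equal(none$TP, 0L); expect_equal(none$FP, 0L)
  expect_error(diagnostic_counts(co[co$subtype == "AIS", ], 45),
               "no invasive")
  expect_error(diagnostic_counts(co[co$subtype != "AIS", ], 45),
               "no non-invasive")
})

test_that("Clopper-Pearson bounds are exact Beta quantiles with analytic extremes", {
  # degenerate lower bound at x = n equals (alpha/2)^(1/n)
  for (n in 1:50) {
    ci <- clopper_pearson(n, n)
    expect_equal(ci[["lower"]], 0.025^(1 / n), tolerance = 1e-12)
    expect_equal(ci[["upper"]], 1)
  }
  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)
  # interval contains the point estimate
  set.seed(14)
  for (i in 1:20) {
    n <- sample(1:60, 1); x <- sample(0:n, 1)
    ci <- clopper_pearson(x, n)
    expect_lte(ci[["lower"]], x / n + 1e-12)
    expect_gte(ci[["upper"]], x / n - 1e-12)
  }
  # widths shrink with n at fixed proportion
  w <- vapply(c(10, 40, 160, 640), function(n) {
    ci <- clopper_pearson(round(0.3 * n), n); ci[["upper"]] - ci[["lower"]]
  }, numeric(1))
  expect_true(all(diff(w) < 0))
  expect_error(clopper_pearson(2, 0), "trials")
})

test_that("metrics_with_ci computes the four proportions and flags undefined ones", {
  row <- metrics_with_ci(list(TP = 12, FN = 24, TN = 28, FP = 0))
  expect_equal(row$sensitivity, 12 / 36)
  expect_equal(row$specificity, 1)
  expect_equal(row$ppv, 1)
  expect_equal(row$npv, 28 / 52)
  # FP = 0 with TP >= 1 forces PPV exactly 1
  expect_equal(metrics_with_ci(list(TP = 3, FN = 1, TN = 5, FP = 0))$ppv, 1)
  # zero denominator -> NA, not an error
  und <- metrics_with_ci(list(TP = 0, FP = 0, TN = 4, FN = 3))
  expect_true(is.na(und$ppv) && is.na(und$ppv_lower))
  expect_false(is.na(und$sensitivity))
  sym <- metrics_with_ci(list(TP = 1, FP = 1, TN = 1, FN = 1))
  expect_equal(unlist(sym[c("sensitivity", "specificity", "ppv", "npv")]),
               rep(0.5, 4), ignore_attr = TRUE)
})

test_that("threshold sweep rows are monotone in sensitivity and specificity", {
  co <- data.frame(
    id = paste0("n", 1:5),
    subtype = c("MIA", "MIA", "IAC", "AIS", "AIS"),
    low_pct = c(30, 40, 50, 60, 70),
    int_pct = c(70, 60, 50, 40, 30),
    high_pct = 0
  )
  sw <- threshold_sweep(co, thresholds = c(40, 45))
  expect_equal(nrow(sw), 2)
  expect_true(all(diff(sw$sensitivity) >= 0))
  sw7 <- threshold_sweep(co)  # default 40..70 by 5
  expect_equal(nrow(sw7), 7)
  expect_equal(sw7$threshold, seq(40, 70, by = 5))
  # monotonicity on random cohorts (set-inclusion property)
  set.seed(15)
  for (rep in 1:10) {
    nA <- sample(3:10, 1); nI <- sample(3:10, 1)
    lowA <- runif(nA, 30, 100); lowI <- runif(nI, 0, 90)
    rc <- data.frame(
      id = paste0("x", seq_len(nA + nI)),
      subtype = c(rep("AIS", nA), rep("MIA", nI)),
      low_pct = c(lowA, lowI), int_pct = 100 - c(lowA, lowI), high_pct = 0
    )
    sw <- threshold_sweep(rc)
    expect_true(all(diff(sw$sensitivity) >= -1e-12))
    expect_true(all(diff(sw$specificity) <= 1e-12))
  }
})
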