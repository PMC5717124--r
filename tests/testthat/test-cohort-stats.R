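test_that("Kruskal-Wallis matches the closed form and handles degeneracy", {
  kw <- kruskal_wallis(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2)
  expect_equal(kw$p, 1 - pchisq(7.2, 2))
  same <- kruskal_wallis(list(a = c(5, 5), b = c(5, 5), c = c(5, 5)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  expect_error(kruskal_wallis(list(a = 1:3)), "at least 2 groups")
  expect_error(kruskal_wallis(list(a = 1:3, b = numeric(0))), "non-empty")
})

test_that("Kruskal-Wallis p agrees with a permutation null on small data", {
  groups <- list(a = c(1.2, 3.4, 2.2, 4.8, 0.9),
                 b = c(5.1, 4.4, 3.9, 6.0, 2.8),
                 c = c(0.4, 6.3, 7.0, 5.5, 4.1, 3.3))
  obs <- kruskal_wallis(groups)
  x <- unlist(groups); sizes <- lengths(groups)
  set.seed(123)
  B <- 20000
  stat <- function(xs) {
    gs <- split(xs, rep(seq_along(sizes), sizes))
    kruskal_wallis(gs)$H
  }
  null <- replicate(B, stat(sample(x)))
  p_perm <- mean(null >= obs$H - 1e-12)
  # chi-square approximation within Monte-Carlo + approximation error
  expect_lt(abs(p_perm - obs$p), 0.05)
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(21)
  groups <- list(a = runif(6), b = runif(5) + 0.2, c = runif(7) - 0.1)
  h0 <- kruskal_wallis(groups)$H
  for (f in list(function(x) exp(x), function(x) x^3 + 5,
                 function(x) atan(x))) {
    expect_equal(kruskal_wallis(lapply(groups, f))$H, h0, tolerance = 1e-12)
  }
})

# independently coded Conover-Iman evaluation, first principles
conover_oracle <- function(samples) {
  x <- unlist(samples); g <- rep(seq_along(samples), lengths(samples))
  N <- length(x); k <- length(samples)
  r <- rank(x)
  H <- kruskal_wallis(samples)$H
  S2 <- (sum(r * r) - N * (N + 1)^2 / 4) / (N - 1)
  out <- matrix(NA_real_, k, k)
  for (i in 1:k) for (j in 1:k) {
    if (i == j) next
    num <- mean(r[g == i]) - mean(r[g == j])
    den <- sqrt(S2 * ((N - 1 - H) / (N - k)) *
                  (1 / sum(g == i) + 1 / sum(g == j)))
    out[i, j] <- 2 * (1 - pt(abs(num / den), N - k))
  }
  out
}

test_that("Conover-Iman matches an independent evaluation and is symmetric", {
  groups <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  p <- conover_iman(groups)
  expect_equal(unname(p), conover_oracle(groups), tolerance = 1e-12)
  expect_equal(p, t(p))
  # with ties
  set.seed(31)
  g2 <- list(a = sample(1:4, 6, TRUE), b = sample(2:6, 5, TRUE),
             c = sample(1:6, 7, TRUE))
  expect_equal(unname(conover_iman(g2)), conover_oracle(g2),
               tolerance = 1e-12)
  # two identical groups -> p = 1 for that pair
  g3 <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(10, 11, 12))
  expect_equal(conover_iman(g3)["a", "b"], 1, tolerance = 1e-9)
  # degenerate: all observations equal
  g4 <- list(a = c(2, 2), b = c(2, 2, 2))
  expect_true(all(conover_iman(g4)[upper.tri(diag(2))] == 1))
  # bonferroni flag caps at 1
  pb <- conover_iman(groups, adjust = "bonferroni")
  expect_true(all(pb[upper.tri(pb)] <= 1))
  expect_equal(unname(pb["a", "b"]), min(1, 3 * p["a", "b"]))
})

test_that("Spearman correlation matches rank-then-Pearson with t-based p", {
  r1 <- spearman_correlation(1:5, c(2, 4, 6, 8, 10))
  expect_equal(r1$rho, 1)
  expect_equal(r1$p_raw, 0)
  x <- c(1, 2, 3, 4, 5); y <- c(5, 6, 7, 8, 7)
  r2 <- spearman_correlation(x, y)
  expect_equal(r2$rho, cor(rank(x), rank(y)))
  tstat <- r2$rho * sqrt((5 - 2) / (1 - r2$rho^2))
  expect_equal(r2$p_raw, 2 * pt(-abs(tstat), 3))
  # family capping
  r3 <- spearman_correlation(c(1, 3, 2, 5, 4), c(2, 1, 4, 3, 6), m = 6)
  expect_equal(r3$p_adjusted, min(1, 6 * r3$p_raw))
  r4 <- list(p_raw = 0.2)
  expect_equal(min(1, 6 * r4$p_raw), 1)
  # self correlation is 1; zero variance errors
  expect_equal(spearman_correlation(x, x)$rho, 1)
  expect_error(spearman_correlation(rep(1, 4), 1:4), "zero variance")
})

test_that("cohort_statistics assembles the per-measure and correlation report", {
  co <- tiny_cohort()
  st <- cohort_statistics(co)
  expect_named(st, c("by_measure", "correlations"))
  expect_true(all(c("low_pct", "high_ml") %in% names(st$by_measure)))
  kw <- st$by_measure$low_pct$kruskal
  expect_true(kw$H >= 0 && kw$p >= 0 && kw$p <= 1)
  expect_equal(dim(st$by_measure$low_pct$pairwise), c(3, 3))
  expect_identical(st$correlations$high_pct$m, 6L)
})

test_that("simulated cohorts separate subtypes by low-risk percentage", {
  # power-style check: KW on low% rejects at alpha = .05 in >= 90% of
  # replicates at the published group sizes
  rej <- 0; B <- 200
  for (b in 1:B) {
    co <- simulate_cohort(n = c(AIS = 28, MIA = 26, IAC = 10), seed = b)
    kw <- kruskal_wallis(split(co$low_pct, co$subtype))
    rej <- rej + (kw$p < 0.05)
  }
  expect_gte(rej / B, 0.9)
})
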