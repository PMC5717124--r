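#' Kruskal-Wallis rank test across subtype groups
#'
#' Tie-corrected H on mid-ranks with the chi-square approximation on k - 1
#' degrees of freedom (delegated to [stats::kruskal.test()]). A fully
#' degenerate input (all observations identical) returns H = 0, p = 1 rather
#' than an error.
#'
#' @param samples named list of numeric vectors, one per group (k >= 2, each
#'   non-empty).
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(samples) {
  check_groups(samples)
  x <- unlist(samples, use.names = FALSE)
  if (length(x) < 3L) stop("need a total of at least 3 observations")
  if (length(unique(x)) == 1L) {
    return(list(H = 0, p = 1, df = length(samples) - 1L))
  }
  kt <- stats::kruskal.test(samples)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Conover-Iman post-hoc pairwise comparisons
#'
#' Rank-based pairwise tests following a Kruskal-Wallis test. For groups i
#' and j with mean pooled mid-ranks `Rbar`, pooled rank variance `S2` and
#' tie-corrected Kruskal-Wallis statistic `H`:
#' `t = (Rbar_i - Rbar_j) / sqrt(S2 * (N - 1 - H)/(N - k) * (1/n_i + 1/n_j))`
#' with a two-sided p-value from the t distribution on N - k degrees of
#' freedom. P-values are reported unadjusted by default; `adjust =
#' "bonferroni"` multiplies by the number of pairs (capped at 1).
#'
#' @param samples named list of numeric vectors (k >= 2, total N > k).
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return symmetric k x k matrix of p-values (diagonal NA).
#' @export
conover_iman <- function(samples, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  check_groups(samples)
  k <- length(samples)
  n <- lengths(samples)
  N <- sum(n)
  if (N <= k) stop("need more observations than groups")
  x <- unlist(samples, use.names = FALSE)
  g <- rep(seq_len(k), n)
  r <- rank(x)  # mid-ranks
  Rbar <- tapply(r, g, mean)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  p <- matrix(NA_real_, k, k, dimnames = list(names(samples), names(samples)))
  if (S2 <= 0) {  # all ranks equal: nothing to compare
    p[row(p) != col(p)] <- 1
    return(p)
  }
  H <- kruskal_wallis(samples)$H
  scale <- S2 * (N - 1 - H) / (N - k)
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      se <- sqrt(scale * (1 / n[i] + 1 / n[j]))
      pij <- if (se <= 0) 1 else {
        tij <- (Rbar[i] - Rbar[j]) / se
        2 * stats::pt(-abs(tij), df = N - k)
      }
      p[i, j] <- p[j, i] <- pij
    }
  }
  if (adjust == "bonferroni") {
    m <- k * (k - 1) / 2
    p[] <- pmin(1, p * m)
  }
  p
}

#' Spearman rank correlation with Bonferroni correction
#'
#' rho is the Pearson correlation of mid-ranks; the raw p-value uses the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of
#' freedom, and the adjusted p-value is `min(1, m * p_raw)` for a family of
#' `m` correlations.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param m family size for the Bonferroni correction (default 1).
#' @return list with `rho`, `p_raw`, `p_adjusted`, `m`, `n`.
#' @export
spearman_correlation <- function(x, y, m = 1L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (m < 1L) stop("family size m must be >= 1")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y: correlation undefined")
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-12) {
    p_raw <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p_raw <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_raw = p_raw, p_adjusted = min(1, m * p_raw),
       m = as.integer(m), n = n)
}

#' Full subtype comparison report for a cohort
#'
#' Kruskal-Wallis and Conover-Iman comparisons of every component measure
#' (mL and %) across AIS/MIA/IAC, plus the invasive-focus-size Spearman
#' correlations (Bonferroni family of six: three components x volume and
#' percentage).
#'
#' @param cohort cohort data.frame (see [read_cohort()]); mL columns and
#'   `invasive_focus_mm` required for the corresponding sections.
#' @param m Bonferroni family size for the correlations.
#' @return nested list: per-measure `kruskal` and `pairwise`, and
#'   `correlations` against invasive focus size.
#' @export
cohort_statistics <- function(cohort, m = 6L) {
  cohort <- validate_cohort(cohort)
  measures <- intersect(c("low_ml", "int_ml", "high_ml",
                          "low_pct", "int_pct", "high_pct"), names(cohort))
  out <- list(by_measure = list(), correlations = list())
  for (msr in measures) {
    groups <- split(cohort[[msr]], factor(cohort$subtype,
                                          levels = c("AIS", "MIA", "IAC")))
    groups <- groups[lengths(groups) > 0]
    if (length(groups) < 2) next
    out$by_measure[[msr]] <- list(
      kruskal = kruskal_wallis(groups),
      pairwise = conover_iman(groups)
    )
  }
  if ("invasive_focus_mm" %in% names(cohort)) {
    for (msr in measures) {
      out$correlations[[msr]] <- spearman_correlation(
        cohort$invasive_focus_mm, cohort[[msr]], m = m)
    }
  }
  out
}

check_groups <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L) {
    stop("need at least 2 groups")
  }
  if (any(lengths(samples) == 0L)) stop("every group must be non-empty")
  invisible(samples)
}
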