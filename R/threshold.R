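#' Invasiveness call from the low-risk percentage
#'
#' A nodule is called invasive when its low-risk component percentage is at
#' or below the threshold (inclusive: "45% or less").
#'
#' @param low_pct low-risk percentage in `[0, 100]` (vectorised).
#' @param threshold percentage cutoff, default 45.
#' @return character vector, `"invasive"` or `"non-invasive"`.
#' @export
classify_invasive <- function(low_pct, threshold = 45) {
  if (any(low_pct < 0 | low_pct > 100)) {
    stop("low_pct must lie in [0, 100]")
  }
  ifelse(low_pct <= threshold, "invasive", "non-invasive")
}

#' Confusion counts for one threshold
#'
#' Positive class = histologically invasive (MIA or IAC); test-positive =
#' `low_pct <= threshold`.
#'
#' @param cohort cohort data.frame with `subtype` and `low_pct`.
#' @param threshold percentage cutoff.
#' @return list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
diagnostic_counts <- function(cohort, threshold) {
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) == 0L) stop("empty cohort")
  invasive <- cohort$subtype != "AIS"
  if (!any(invasive)) stop("no invasive (MIA/IAC) records in cohort")
  if (all(invasive)) stop("no non-invasive (AIS) records in cohort")
  pos <- cohort$low_pct <= threshold
  list(TP = sum(pos & invasive), FP = sum(pos & !invasive),
       TN = sum(!pos & !invasive), FN = sum(!pos & invasive))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile interval: `lower = qbeta(alpha/2, x, n - x + 1)`,
#' `upper = qbeta(1 - alpha/2, x + 1, n - x)`, with `lower = 0` at `x = 0`
#' and `upper = 1` at `x = n`.
#'
#' @param successes number of successes.
#' @param trials number of trials (>= 1).
#' @param confidence confidence level, default 0.95.
#' @return numeric `(lower, upper)`.
#' @export
clopper_pearson <- function(successes, trials, confidence = 0.95) {
  if (trials < 1L) stop("trials must be >= 1")
  if (successes < 0L || successes > trials) {
    stop("successes must lie in [0, trials]")
  }
  alpha <- 1 - confidence
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

#' Diagnostic metrics with exact confidence intervals
#'
#' Sensitivity, specificity, PPV and NPV from the confusion counts, each with
#' a Clopper-Pearson interval on its own numerator/denominator. A metric
#' whose denominator is zero is reported as `NA` (undefined), not an error.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN` (see
#'   [diagnostic_counts()]).
#' @param confidence confidence level.
#' @return one-row data.frame with `<metric>`, `<metric>_lower`,
#'   `<metric>_upper` for the four metrics.
#' @export
metrics_with_ci <- function(counts, confidence = 0.95) {
  one <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    ci <- clopper_pearson(x, n, confidence)
    c(x / n, ci[["lower"]], ci[["upper"]])
  }
  vals <- c(
    sensitivity = one(counts$TP, counts$TP + counts$FN),
    specificity = one(counts$TN, counts$TN + counts$FP),
    ppv = one(counts$TP, counts$TP + counts$FP),
    npv = one(counts$TN, counts$TN + counts$FN)
  )
  names(vals) <- as.vector(t(outer(c("sensitivity", "specificity", "ppv", "npv"),
                                   c("", "_lower", "_upper"), paste0)))
  as.data.frame(as.list(vals))
}

#' Threshold sweep of the low-risk percentage
#'
#' One diagnostic row per cutoff, ascending: the printed-table layout of
#' sensitivity, specificity, PPV and NPV with exact 95% CIs at inclusive
#' low-risk-percentage cutoffs (default 40% to 70% in steps of five).
#'
#' @param cohort cohort data.frame.
#' @param thresholds ascending percentage cutoffs.
#' @param confidence confidence level.
#' @return data.frame, one row per threshold, column `threshold` followed by
#'   the [metrics_with_ci()] columns and the four confusion counts.
#' @export
threshold_sweep <- function(cohort, thresholds = seq(40, 70, by = 5),
                            confidence = 0.95) {
  thresholds <- sort(thresholds)
  rows <- lapply(thresholds, function(th) {
    counts <- diagnostic_counts(cohort, th)
    cbind(data.frame(threshold = th), metrics_with_ci(counts, confidence),
          as.data.frame(counts))
  })
  do.call(rbind, rows)
}
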