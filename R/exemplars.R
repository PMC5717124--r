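#' Exemplar set container
#'
#' Nine 81-value texture exemplars, each carrying one of the nine colour
#' codes and, through the fixed colour partition, a risk-group membership:
#' low = blue/green/cyan, intermediate = pink/yellow, high =
#' violet/indigo/red/orange. Exemplars are stored in ascending mean-HU order
#' (`C, B, G, P, Y, O, R, I, V`), which also serves as the deterministic
#' tie-break order during classification.
#'
#' @param exemplars 9 x 81 numeric matrix, one exemplar per row, rows in the
#'   canonical colour order.
#' @param labels character vector of the nine colour codes, a permutation of
#'   `C, B, G, P, Y, O, R, I, V`, aligned with the rows.
#' @return an `exemplar_set`.
#' @export
exemplar_set <- function(exemplars, labels = CANARY_COLOR_ORDER) {
  exemplars <- as.matrix(exemplars)
  if (!identical(dim(exemplars), c(9L, 81L))) {
    stop("exemplars must be a 9 x 81 matrix")
  }
  if (!all(is.finite(exemplars))) stop("exemplar values must be finite")
  labels <- as.character(labels)
  if (length(labels) != 9L || !setequal(labels, CANARY_COLOR_ORDER) ||
      anyDuplicated(labels)) {
    stop("labels must be a permutation of ",
         paste(CANARY_COLOR_ORDER, collapse = ", "))
  }
  # store rows in canonical colour order so row index == colour rank
  ord <- match(CANARY_COLOR_ORDER, labels)
  structure(list(exemplars = exemplars[ord, , drop = FALSE],
                 labels = CANARY_COLOR_ORDER,
                 risk_map = CANARY_RISK_MAP),
            class = "exemplar_set")
}

#' @export
print.exemplar_set <- function(x, ...) {
  mu <- rowMeans(x$exemplars)
  cat("<exemplar_set> 9 exemplars (9x9 HU patches)\n")
  for (i in 1:9) {
    cat(sprintf("  %s  mean %8.1f HU  risk %s\n", x$labels[i], mu[i],
                risk_group_of(x$labels[i])))
  }
  invisible(x)
}

#' Learn the nine texture exemplars from training patches
#'
#' Runs affinity propagation over the pairwise patch similarities, tuning the
#' preference by bisection on the bracket `[min similarity, median
#' similarity]` until exactly `target_k` exemplars emerge. Colour codes are
#' then assigned to the exemplars by ascending mean HU in the fixed order
#' `C, B, G, P, Y, O, R, I, V`, so the three lowest-density exemplars form
#' the low-risk component and the four densest the high-risk component; ties
#' in mean HU break by first occurrence. The colour-to-risk partition is
#' fixed.
#'
#' @param patches list of numeric length-81 patch vectors (>= `target_k`
#'   distinct vectors).
#' @param target_k number of exemplars to find (default 9; the classifier
#'   requires 9).
#' @param config an [ap_config()].
#' @param max_bisection bisection step cap for the preference tuning.
#' @return an [exemplar_set()] when `target_k` is 9, with attribute
#'   `"preference"` recording the tuned value; for other `target_k` a list
#'   with `exemplars`, `indices`, `preference`.
#' @export
learn_exemplar_set <- function(patches, target_k = 9L, config = ap_config(),
                               max_bisection = 60L) {
  if (length(patches) < target_k) {
    stop("need at least ", target_k, " patches, got ", length(patches))
  }
  X <- do.call(rbind, patches)
  if (nrow(unique(X)) < target_k) {
    stop("need at least ", target_k, " distinct patch value vectors, got ",
         nrow(unique(X)))
  }
  S <- similarity_matrix(patches)
  off <- S[row(S) != col(S)]

  run_k <- function(pref) {
    cfg <- config; cfg$preference <- pref
    res <- affinity_propagation(S, cfg)
    list(k = length(res$exemplars), res = res, pref = pref)
  }

  # cluster count grows with the preference; bracket and bisect
  lo <- min(off); hi <- stats::median(off)
  rlo <- run_k(lo); rhi <- run_k(hi)
  if (rhi$k < target_k) {
    # median preference too coarse for this set; raise towards the maximum
    hi <- max(off); rhi <- run_k(hi)
  }
  tries <- 0L
  while (rlo$k > target_k && tries < 12L) {
    # even the minimum similarity leaves too many exemplars (widely
    # separated tight clusters): push the preference further down
    tries <- tries + 1L
    lo <- lo * 4
    rlo <- run_k(lo)
  }
  if (rlo$k > target_k || rhi$k < target_k) {
    stop("cannot bracket ", target_k, " clusters: preference range [",
         signif(lo, 6), ", ", signif(hi, 6), "] yields ", rlo$k, "-", rhi$k,
         " exemplars")
  }
  hit <- NULL
  if (rlo$k == target_k) hit <- rlo
  if (is.null(hit) && rhi$k == target_k) hit <- rhi
  iter <- 0L
  while (is.null(hit)) {
    iter <- iter + 1L
    if (iter > max_bisection) {
      stop("preference tuning cap (", max_bisection,
           " bisection steps) exceeded without hitting k = ", target_k)
    }
    mid <- (lo + hi) / 2
    rm_ <- run_k(mid)
    if (rm_$k == target_k) {
      hit <- rm_
    } else if (rm_$k < target_k) {
      lo <- mid
    } else {
      hi <- mid
    }
  }

  idx <- hit$res$exemplars
  E <- X[idx, , drop = FALSE]
  if (target_k != 9L) {
    return(list(exemplars = E, indices = idx, result = hit$res,
                preference = hit$pref))
  }
  # colour by ascending mean HU; ties by first occurrence in the input order
  mu <- rowMeans(E)
  ord <- order(mu, seq_along(mu))
  es <- exemplar_set(E[ord, , drop = FALSE], labels = CANARY_COLOR_ORDER)
  attr(es, "indices") <- idx[ord]
  attr(es, "preference") <- hit$pref
  es
}

#' Serialise an exemplar set to JSON
#'
#' @param es an [exemplar_set()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_exemplars <- function(es, path) {
  stopifnot(inherits(es, "exemplar_set"))
  obj <- lapply(1:9, function(i) {
    list(label = es$labels[i],
         risk = risk_group_of(es$labels[i]),
         values = es$exemplars[i, ])
  })
  jsonlite::write_json(list(exemplars = obj), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read an exemplar set from JSON
#'
#' @param path JSON path produced by [write_exemplars()] (or a user-supplied
#'   file with the same schema, e.g. to override the density-rank colour
#'   mapping).
#' @return an [exemplar_set()].
#' @export
read_exemplars <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ex <- obj$exemplars
  E <- do.call(rbind, lapply(ex$values, as.numeric))
  exemplar_set(E, labels = ex$label)
}
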