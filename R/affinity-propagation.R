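#' Affinity propagation configuration
#'
#' Hyperparameters for the message-passing clustering. Defaults: damping 0.9,
#' at most 1000 sweeps, convergence declared after 50 sweeps with an
#' unchanged exemplar set, preference tuned automatically when learning a
#' fixed number of exemplars.
#'
#' @param damping update damping factor in `[0.5, 1)`.
#' @param max_iterations maximum message-passing sweeps.
#' @param convergence_iterations sweeps of unchanged exemplar set required to
#'   declare convergence.
#' @param preference diagonal self-similarity, a scalar or `"auto"` (median
#'   off-diagonal similarity).
#' @param seed integer seed for any randomised step.
#' @return an `ap_config` list.
#' @export
ap_config <- function(damping = 0.9, max_iterations = 1000L,
                      convergence_iterations = 50L,
                      preference = "auto", seed = 1L) {
  if (!is.numeric(damping) || damping < 0.5 || damping >= 1) {
    stop("damping must lie in [0.5, 1)")
  }
  if (max_iterations < 1L || convergence_iterations < 1L) {
    stop("iteration counts must be positive")
  }
  structure(list(damping = damping,
                 max_iterations = as.integer(max_iterations),
                 convergence_iterations = as.integer(convergence_iterations),
                 preference = preference,
                 seed = as.integer(seed)),
            class = "ap_config")
}

#' Affinity propagation clustering
#'
#' Standard responsibility/availability message passing with damping over a
#' similarity matrix. Exemplars are the points whose self responsibility plus
#' self availability is positive at exit; every other point is assigned to
#' the exemplar with which it is most similar, and exemplars are assigned to
#' themselves.
#'
#' @param similarity square similarity matrix, symmetric off the diagonal.
#'   The diagonal is overwritten with the preference.
#' @param config an [ap_config()]. A numeric `config$preference` is placed on
#'   the diagonal; `"auto"` uses the median off-diagonal similarity.
#' @return list with `exemplars` (indices into the input set), `assignment`
#'   (exemplar index per point), `iterations`, `converged`.
#' @export
affinity_propagation <- function(similarity, config = ap_config()) {
  S <- as.matrix(similarity)
  n <- nrow(S)
  if (ncol(S) != n) stop("similarity matrix must be square")
  if (n == 1L) {
    return(list(exemplars = 1L, assignment = 1L, iterations = 0L,
                converged = TRUE))
  }
  pref <- config$preference
  if (identical(pref, "auto")) {
    pref <- stats::median(S[row(S) != col(S)])
  }
  diag(S) <- pref
  off <- S[row(S) != col(S)]
  if (max(off) - min(off) == 0) {
    # fully degenerate input: every pairwise similarity identical, so the
    # net-similarity optimum is a single exemplar when self-similarity does
    # not beat the shared similarity (first index for determinism), and
    # all-self otherwise
    if (pref <= off[1]) {
      return(list(exemplars = 1L, assignment = rep(1L, n),
                  iterations = 0L, converged = TRUE))
    }
    return(list(exemplars = seq_len(n), assignment = seq_len(n),
                iterations = 0L, converged = TRUE))
  }
  # seeded tie-breaking jitter: degenerate or symmetric similarity
  # structures (e.g. identical points) otherwise oscillate without ever
  # electing an exemplar
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  rng <- max(S) - min(S)
  S <- S + (1e-12 * rng + .Machine$double.eps) *
    matrix(stats::rnorm(n * n), n, n)
  res <- ap_message_passing(S, config$damping, config$max_iterations,
                            config$convergence_iterations)
  if (length(res$exemplars) == 0L) {
    stop("affinity propagation failed to identify any exemplar after ",
         res$iterations, " iterations (damping ", config$damping,
         ", preference ", signif(pref, 6), ")")
  }
  res
}

# Pairwise similarity matrix (negative squared Euclidean distance) for a list
# of equal-length patch vectors.
similarity_matrix <- function(patches) {
  X <- do.call(rbind, patches)
  sq <- rowSums(X^2)
  S <- -(outer(sq, sq, "+") - 2 * tcrossprod(X))
  S[S > 0] <- 0  # numerical round-off: similarity is <= 0 by construction
  diag(S) <- 0
  S
}
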