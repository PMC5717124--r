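# Shared fixtures, built in code at test time.

# Constant-texture exemplar set: nine flat 81-patches at the given HU means,
# labelled in ascending density order.
flat_exemplar_set <- function(means = seq(-850, -50, by = 100)) {
  stopifnot(length(means) == 9)
  exemplar_set(matrix(rep(sort(means), each = 81), nrow = 9, byrow = TRUE))
}

# Small constant volume with a centred box mask.
const_volume <- function(value = -700, dims = c(6, 20, 20),
                         spacing = c(1, 1, 1)) {
  ct_volume(array(value, dims), spacing = spacing, id = "const")
}

box_mask <- function(volume, s = NULL, r = NULL, c = NULL) {
  d <- dim(volume$voxels)
  if (is.null(s)) s <- 2:(d[1] - 1)
  if (is.null(r)) r <- 5:(d[2] - 4)
  if (is.null(c)) c <- 5:(d[3] - 4)
  ind <- array(FALSE, d)
  ind[s, r, c] <- TRUE
  nodule_mask(ind, volume = volume)
}

# A tiny valid cohort with both classes present.
tiny_cohort <- function() {
  data.frame(
    id = c("a1", "a2", "m1", "m2", "i1"),
    subtype = c("AIS", "AIS", "MIA", "MIA", "IAC"),
    low_pct = c(60, 70, 30, 40, 50),
    int_pct = c(40, 30, 65, 55, 45),
    high_pct = c(0, 0, 5, 5, 5),
    low_ml = c(1, 1.2, 0.5, 0.6, 1.5),
    int_ml = c(0.6, 0.5, 1.1, 0.8, 1.3),
    high_ml = c(0, 0, 0.1, 0.07, 0.15),
    invasive_focus_mm = c(0, 0, 2, 4, 8),
    avg_diameter_mm = c(12, 14, 13, 15, 20),
    stringsAsFactors = FALSE
  )
}

# Cached exemplar set learned once per test run from the default-size
# training set; used by the end-to-end tests.
trained_exemplars <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      patches <- simulate_training_set(37, 774, seed = 1)
      cache <<- learn_exemplar_set(patches)
    }
    cache
  }
})
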