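#' Pipeline run configuration
#'
#' Flat key/value configuration for [run_full_pipeline()]. Unknown keys are
#' rejected at validation time, before any stage runs.
#'
#' @param seed global integer seed; each stage derives its own substream
#'   (`seed * 1000 + stage index`) so stages never reuse a stream.
#' @param out_dir output directory for all stage artifacts.
#' @param n_ais,n_mia,n_iac simulated cohort sizes per subtype.
#' @param n_train_nodules,n_train_patches training-set size for exemplar
#'   learning.
#' @param damping,max_iterations,convergence_iterations affinity propagation
#'   hyperparameters (see [ap_config()]).
#' @param thresholds ascending low-risk-percentage cutoffs for the sweep.
#' @param confidence confidence level for the exact intervals.
#' @param family_size Bonferroni family size for the focus-size correlations.
#' @return a validated `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = "canary-run",
                       n_ais = 28L, n_mia = 26L, n_iac = 10L,
                       n_train_nodules = 37L, n_train_patches = 774L,
                       damping = 0.9, max_iterations = 1000L,
                       convergence_iterations = 50L,
                       thresholds = seq(40, 70, by = 5),
                       confidence = 0.95, family_size = 6L) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              n_ais = as.integer(n_ais), n_mia = as.integer(n_mia),
              n_iac = as.integer(n_iac),
              n_train_nodules = as.integer(n_train_nodules),
              n_train_patches = as.integer(n_train_patches),
              damping = damping, max_iterations = as.integer(max_iterations),
              convergence_iterations = as.integer(convergence_iterations),
              thresholds = thresholds, confidence = confidence,
              family_size = as.integer(family_size))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  known <- names(formals(run_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  miss <- setdiff(known, names(cfg))
  if (length(miss)) {
    stop("missing config key(s): ", paste(miss, collapse = ", "))
  }
  if (is.unsorted(cfg$thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly ascending")
  }
  if (cfg$confidence <= 0 || cfg$confidence >= 1) {
    stop("confidence must lie in (0, 1)")
  }
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: (1) simulate the training patch set, (2)
#' learn the nine exemplars, (3) simulate one AIS/MIA/IAC phantom triple,
#' classify it and write per-nodule reports, (4) simulate the cohort table,
#' (5) rank-based cohort statistics, (6) the low-risk threshold sweep. A
#' `manifest.json` records the seed, a hash of the configuration and every
#' stage output, so a rerun with the same configuration reproduces all
#' artifacts deterministically.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return the manifest, invisibly.
#' @export
run_full_pipeline <- function(config = run_config(), quiet = FALSE) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stage_seed <- function(i) config$seed * 1000L + i
  t0 <- Sys.time()
  outputs <- list()
  stage <- function(name, fun) {
    say(sprintf("[%s] running ...", name))
    t <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    say(sprintf("[%s] done in %.1fs", name,
                as.numeric(difftime(Sys.time(), t, units = "secs"))))
    res
  }

  patches <- stage("simulate_training", function() {
    simulate_training_set(config$n_train_nodules, config$n_train_patches,
                          seed = stage_seed(1L))
  })

  exemplars <- stage("learn_exemplars", function() {
    es <- learn_exemplar_set(patches, config = ap_config(
      damping = config$damping, max_iterations = config$max_iterations,
      convergence_iterations = config$convergence_iterations,
      seed = stage_seed(2L)))
    write_exemplars(es, file.path(config$out_dir, "exemplars.json"))
    es
  })
  outputs$exemplars <- "exemplars.json"

  stage("classify_examples", function() {
    for (st in c("AIS", "MIA", "IAC")) {
      ph <- simulate_nodule(phantom_spec(st, seed = stage_seed(3L)))
      lm <- classify_nodule(ph$volume, ph$mask, exemplars)
      rc <- aggregate_risk(lm)
      sub <- file.path(config$out_dir, paste0("example_", st))
      write_report(rc, lm, sub, volume = ph$volume)
      outputs[[paste0("example_", st)]] <<- paste0("example_", st)
    }
  })

  cohort <- stage("simulate_cohort", function() {
    co <- simulate_cohort(n = c(AIS = config$n_ais, MIA = config$n_mia,
                                IAC = config$n_iac), seed = stage_seed(4L))
    write_cohort(co, file.path(config$out_dir, "cohort.csv"))
    co
  })
  outputs$cohort <- "cohort.csv"

  stage("cohort_stats", function() {
    st <- cohort_statistics(cohort, m = config$family_size)
    jsonlite::write_json(st, file.path(config$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  })
  outputs$stats <- "stats.json"

  stage("threshold_sweep", function() {
    sw <- threshold_sweep(cohort, thresholds = config$thresholds,
                          confidence = config$confidence)
    utils::write.csv(sw, file.path(config$out_dir, "threshold_sweep.csv"),
                     row.names = FALSE)
  })
  outputs$sweep <- "threshold_sweep.csv"

  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    stage_seeds = vapply(1:6, stage_seed, integer(1)),
    outputs = outputs,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
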