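#' Run configuration
#'
#' Collects the tunable parameters of the whole pipeline with the study
#' defaults: ensembles of 1024 network structures, 30 replicate simulations
#' per subject and gene, 10-fold knockdowns, an 80% annealing overlap
#' target, at most 2 parents per vertex and a 2.5% consensus threshold.
#'
#' @param max_parents maximum number of parents per network fragment.
#' @param fragments_per_child how many best-scoring fragments to retain per
#'   child variable (the root fragment is always kept).
#' @param ensemble_size number of network structures sampled at T = 1.
#' @param n_chains independent annealed chains contributing members.
#' @param n_replicates replicate simulations per subject and gene.
#' @param knockdown_fold linear-scale fold reduction of the target
#'   transcript.
#' @param overlap_target overlap coefficient between successive-temperature
#'   score distributions that the adaptive annealing schedule aims for.
#' @param consensus_threshold minimum ensemble edge frequency for the
#'   consensus topology export.
#' @param alpha significance level for the virtual trial tests.
#' @param call_rate_min,maf_min,hwe_alpha genotype QC thresholds.
#' @param seed integer seed, or `NULL` to use the session RNG.
#' @return A `rv_config` list.
#' @export
run_config <- function(max_parents = 2,
                       fragments_per_child = 16,
                       ensemble_size = 1024,
                       n_chains = 2,
                       n_replicates = 30,
                       knockdown_fold = 10,
                       overlap_target = 0.8,
                       consensus_threshold = 0.025,
                       alpha = 0.05,
                       call_rate_min = 0.95,
                       maf_min = 0.05,
                       hwe_alpha = 0.001,
                       seed = NULL) {
  cfg <- list(
    max_parents = as.integer(max_parents),
    fragments_per_child = as.integer(fragments_per_child),
    ensemble_size = as.integer(ensemble_size),
    n_chains = as.integer(n_chains),
    n_replicates = as.integer(n_replicates),
    knockdown_fold = as.numeric(knockdown_fold),
    overlap_target = as.numeric(overlap_target),
    consensus_threshold = as.numeric(consensus_threshold),
    alpha = as.numeric(alpha),
    call_rate_min = as.numeric(call_rate_min),
    maf_min = as.numeric(maf_min),
    hwe_alpha = as.numeric(hwe_alpha),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  stopifnot(
    cfg$max_parents >= 1,
    cfg$fragments_per_child >= 1,
    cfg$ensemble_size >= 1,
    cfg$n_chains >= 1,
    cfg$n_replicates >= 1,
    cfg$knockdown_fold > 0,
    cfg$overlap_target > 0, cfg$overlap_target < 1,
    cfg$consensus_threshold > 0, cfg$consensus_threshold <= 1,
    cfg$alpha > 0, cfg$alpha < 1
  )
  structure(cfg, class = "rv_config")
}

#' @export
print.rv_config <- function(x, ...) {
  cat("# ravnet run configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
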