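## topological order of the children under a model's parent map
topo_order <- function(parent_map) {
  indeg <- map_int(parent_map, ~ length(intersect(.x, names(parent_map))))
  kids <- list()
  for (ch in names(parent_map)) {
    for (p in intersect(parent_map[[ch]], names(parent_map))) {
      kids[[p]] <- c(kids[[p]], ch)
    }
  }
  queue <- names(indeg)[indeg == 0]
  out <- character()
  while (length(queue)) {
    node <- queue[[1]]; queue <- queue[-1]
    out <- c(out, node)
    for (k in kids[[node]]) {
      indeg[[k]] <- indeg[[k]] - 1L
      if (indeg[[k]] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) != length(parent_map)) abort("model graph is cyclic")
  out
}

frag_conditional <- function(f, values) {
  if (length(f$disc_parents)) {
    key <- state_key_of(values[f$disc_parents])
    row <- match(key, f$state_keys)
    if (is.na(row)) {
      abort(sprintf("unseen state '%s' for fragment of `%s`", key, f$child))
    }
  } else {
    row <- 1L
  }
  mu <- f$theta0[row]
  for (cp in f$cont_parents) mu <- mu + f$beta[row, cp] * values[[cp]]
  c(mu = unname(mu), sigma = unname(f$sigma[row]))
}

#' Forward-sample a network model
#'
#' Sweeps the model in topological order: clamped variables are copied
#' from `evidence`; every unclamped child is drawn from the normal
#' conditional of its assigned fragment, with the row of the parameter
#' table selected by the joint state of its discrete parents.  One full
#' sweep produces one sample of all variables.  SNPs carry no fragment
#' and must be clamped.
#'
#' @param model a `rv_network_model`.
#' @param library the `rv_fragment_library` it indexes.
#' @param evidence named numeric vector of clamped values on the
#'   modelling scale (genotypes in \{0,1,2\}).
#' @param n number of sweeps.
#' @return Tibble with `n` rows and one column per variable.
#' @export
forward_sample <- function(model, library, evidence = c(), n = 1) {
  v <- library$variables
  snps <- v$name[v$role == "snp"]
  unclamped_snps <- setdiff(snps, names(evidence))
  if (length(unclamped_snps)) {
    abort(sprintf("SNP `%s` must be clamped (no marginal model for genotypes)",
                  unclamped_snps[1]))
  }
  pm <- model_parent_map(model, library)
  frs <- setNames(model_fragments(model, library), names(model$assignment))
  ord <- topo_order(pm)
  free <- setdiff(ord, names(evidence))
  out <- matrix(NA_real_, n, nrow(v), dimnames = list(NULL, v$name))
  for (nm in names(evidence)) out[, nm] <- evidence[[nm]]
  if (length(free)) {
    for (i in seq_len(n)) {
      values <- out[i, ]
      for (ch in free) {
        cond <- frag_conditional(frs[[ch]], values)
        values[[ch]] <- rnorm(1, cond[["mu"]], cond[["sigma"]])
      }
      out[i, ] <- values
    }
  }
  as_tibble(as.data.frame(out))
}

#' Knockdown intervention by fragment removal
#'
#' Graph surgery for `do(target = reduced value)`: the target transcript's
#' incoming fragment is removed (it becomes a clamped root) and its value
#' is fixed at the subject's observed log-scale expression minus
#' `log(fold)` — transcripts are natural-log scale, so an f-fold
#' knockdown is a `-log(f)` shift (linear-scale ratio `f`).
#'
#' @param model a `rv_network_model`.
#' @param library the `rv_fragment_library`.
#' @param target transcript name to knock down.
#' @param evidence named numeric evidence vector; must contain the
#'   subject's observed value of `target`.
#' @param fold positive fold change (default 10).
#' @return List with the modified `model` and updated `evidence`.
#' @export
apply_intervention <- function(model, library, target, evidence, fold = 10) {
  v <- library$variables
  if (!target %in% v$name) abort(sprintf("unknown target `%s`", target))
  if (v$role[v$name == target] != "transcript") {
    abort("knockdown targets must be transcripts")
  }
  if (fold <= 0) abort("`fold` must be positive")
  if (!target %in% names(evidence)) {
    abort("evidence must contain the target's observed value")
  }
  frs <- library$children[[target]]
  root <- which(map_int(frs, ~ length(.x$parents)) == 0L)[1]
  model$score <- model$score - frs[[model$assignment[[target]]]]$score +
    frs[[root]]$score
  model$assignment[[target]] <- root
  evidence[[target]] <- evidence[[target]] - log(fold)
  list(model = model, evidence = evidence)
}

subject_evidence <- function(cohort, subject, roles = c("snp", "transcript")) {
  row <- which(cohort$subject == subject)
  if (length(row) != 1) abort(sprintf("unknown subject `%s`", subject))
  v <- cohort_variables(cohort)
  nm <- v$name[v$role %in% roles]
  vals <- as.numeric(as_tibble(cohort)[row, nm])
  setNames(vals, nm)
}

#' Replicate knockdown simulations for one subject
#'
#' Each replicate draws one member uniformly at random from the ensemble,
#' applies the knockdown (when `gene` is given), clamps the subject's
#' genotypes and — per the subject-conditioning rule — all transcript
#' values except the target, and forward-samples the phenotypes.  With
#' `propagate_transcripts = TRUE` downstream transcripts are left free to
#' respond instead (full do-operator semantics).
#'
#' @param ensemble a `rv_ensemble`.
#' @param cohort the modelling-scale cohort the ensemble was fitted on.
#' @param subject subject identifier.
#' @param gene transcript to knock down, or `NULL` for the untreated
#'   baseline simulation.
#' @param fold fold knockdown (default 10).
#' @param n_replicates replicate sweeps (default 30).
#' @param propagate_transcripts leave non-target transcripts free.
#' @param seed optional integer seed.
#' @return Tibble `(subject, gene, replicate, member, TJ, SJ, Pain, CRP)`
#'   on the modelling scale.
#' @export
simulate_subject <- function(ensemble, cohort, subject, gene = NULL,
                             fold = 10, n_replicates = 30,
                             propagate_transcripts = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lib <- ensemble$library
  v <- lib$variables
  if (!all(v$name %in% cohort_variables(cohort)$name)) {
    abort("cohort does not contain the ensemble's variables")
  }
  phens <- v$name[v$role == "phenotype"]
  ev_roles <- if (propagate_transcripts) "snp" else c("snp", "transcript")
  evidence <- subject_evidence(cohort, subject, ev_roles)
  if (!is.null(gene)) {
    obs <- subject_evidence(cohort, subject, "transcript")[gene]
    if (is.na(obs)) abort(sprintf("no observed expression for `%s`", gene))
    evidence[names(obs)] <- obs
  }
  K <- length(ensemble$members)
  picks <- sample.int(K, n_replicates, replace = TRUE)
  rows <- map(seq_len(n_replicates), function(r) {
    m <- ensemble$members[[picks[r]]]
    model <- structure(list(assignment = m$assignment, score = m$score),
                       class = "rv_network_model")
    ev <- evidence
    if (!is.null(gene)) {
      surgery <- apply_intervention(model, lib, gene, ev, fold)
      model <- surgery$model
      ev <- surgery$evidence
    }
    draw <- forward_sample(model, lib, ev, n = 1)
    dplyr::bind_cols(
      tibble(subject = subject, gene = gene %||% NA_character_,
             replicate = r, member = picks[r]),
      draw[phens]
    )
  })
  list_rbind(rows)
}

#' Median point predictions over replicates
#'
#' Per subject (and gene), the median of the replicate phenotype draws —
#' the robust point estimate used by the virtual trial.  Even replicate
#' counts use the mean of the two central order statistics.
#'
#' @param replicates tibble from [simulate_subject()] (rows may span
#'   several subjects/genes).
#' @return Tibble with one row per subject x gene and the median of each
#'   phenotype column.
#' @export
summarize_medians <- function(replicates) {
  if (nrow(replicates) == 0) abort("no replicates to summarise")
  num_cols <- setdiff(names(replicates),
                      c("subject", "gene", "replicate", "member"))
  replicates |>
    group_by(.data$subject, .data$gene) |>
    summarise(dplyr::across(dplyr::all_of(num_cols), median),
              .groups = "drop")
}
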