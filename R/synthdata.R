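#' Generate a ground-truth causal network
#'
#' Random DAG respecting the role ordering SNP -> transcript ->
#' \{transcript, phenotype\}: SNPs are Hardy-Weinberg sources with MAFs
#' drawn uniformly from `maf_range`; each transcript receives one
#' cis-eQTL SNP parent with probability `p_eqtl` and upstream-transcript
#' parents with probability `edge_density` (total in-degree capped at
#' `max_parents`); `n_planted` transcripts ("planted causes") get a
#' direct edge into one phenotype latent each, cycling through TJ, SJ,
#' Pain, CRP.  Edge coefficients are drawn from `effect_range` (planted
#' edges use `planted_effect`).  Phenotype latents are mapped to the
#' clinical scale by [generate_cohort()] so that the pipeline's logit/log
#' transforms are the correct inverses.
#'
#' @param n_snps,n_genes numbers of SNPs and transcripts.
#' @param n_planted transcripts with a direct phenotype effect.
#' @param p_eqtl probability a transcript has a cis-eQTL parent.
#' @param edge_density probability of each feasible transcript ->
#'   transcript edge.
#' @param effect_range range of absolute edge coefficients.
#' @param planted_effect coefficient of planted transcript -> phenotype
#'   edges (latent scale).
#' @param maf_range range of minor allele frequencies.
#' @param transcript_sd,phenotype_sd residual SDs of transcripts and
#'   phenotype latents.
#' @param max_parents in-degree cap for transcripts.
#' @param seed optional integer seed.
#' @return A `rv_ground_truth`: `nodes` (name, role, m, intercept, sigma,
#'   maf), `edges` (from, to, beta) and `planted` (named by target
#'   phenotype).
#' @export
generate_ground_truth <- function(n_snps = 20, n_genes = 30, n_planted = 3,
                                  p_eqtl = 0.8, edge_density = 0.08,
                                  effect_range = c(0.6, 1.2),
                                  planted_effect = 0.8,
                                  maf_range = c(0.1, 0.4),
                                  transcript_sd = 0.5, phenotype_sd = 0.6,
                                  max_parents = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_snps >= 1, n_genes >= 1, n_planted <= n_genes)
  snps <- sprintf("snp%02d", seq_len(n_snps))
  genes <- sprintf("g%02d", seq_len(n_genes))
  phens <- c("TJ", "SJ", "Pain", "CRP")
  draw_beta <- function(n) {
    runif(n, effect_range[1], effect_range[2]) * sample(c(-1, 1), n, TRUE)
  }
  edges <- list()
  ## cis-eQTL anchors: distinct SNPs while available
  snp_pool <- sample(snps)
  for (i in seq_len(n_genes)) {
    if (runif(1) < p_eqtl) {
      s <- if (length(snp_pool)) {
        out <- snp_pool[1]; snp_pool <- snp_pool[-1]; out
      } else sample(snps, 1)
      edges[[length(edges) + 1]] <-
        tibble(from = s, to = genes[i], beta = abs(draw_beta(1)))
    }
  }
  edge_tbl <- if (length(edges)) list_rbind(edges) else {
    tibble(from = character(), to = character(), beta = numeric())
  }
  ## sparse transcript cascade along the g01 < g02 < ... ordering
  for (j in seq_len(n_genes)[-1]) {
    indeg <- sum(edge_tbl$to == genes[j])
    if (indeg >= max_parents) next
    cand <- genes[seq_len(j - 1)]
    pick <- cand[runif(length(cand)) < edge_density]
    pick <- head(pick, max_parents - indeg)
    if (length(pick)) {
      edge_tbl <- bind_rows(edge_tbl, tibble(
        from = pick, to = genes[j], beta = draw_beta(length(pick))
      ))
    }
  }
  ## planted causal transcripts, each driving one phenotype latent
  planted <- character(0)
  if (n_planted > 0) {
    eqtl_genes <- intersect(genes, edge_tbl$to[edge_tbl$from %in% snps])
    pool <- if (length(eqtl_genes) >= n_planted) eqtl_genes else genes
    planted <- sample(pool, n_planted)
    targets <- phens[(seq_len(n_planted) - 1) %% 4 + 1]
    edge_tbl <- bind_rows(edge_tbl, tibble(
      from = planted, to = targets, beta = planted_effect
    ))
    names(planted) <- targets
  }
  nodes <- bind_rows(
    tibble(name = snps, role = "snp", m = NA_real_, intercept = 0,
           sigma = NA_real_, maf = runif(n_snps, maf_range[1], maf_range[2])),
    tibble(name = genes, role = "transcript", m = NA_real_, intercept = 0,
           sigma = transcript_sd, maf = NA_real_),
    tibble(name = phens, role = "phenotype",
           m = c(28, 28, 100, NA_real_),
           intercept = c(0, 0, 0, 1),
           sigma = phenotype_sd, maf = NA_real_)
  )
  structure(list(nodes = nodes, edges = edge_tbl, planted = planted,
                 seed = seed),
            class = "rv_ground_truth")
}

#' @export
print.rv_ground_truth <- function(x, ...) {
  cat(sprintf(
    "# Ground truth: %d SNPs, %d transcripts, 4 phenotypes, %d edges\n",
    sum(x$nodes$role == "snp"), sum(x$nodes$role == "transcript"),
    nrow(x$edges)
  ))
  if (length(x$planted)) {
    cat("  planted causes:",
        paste(sprintf("%s -> %s", x$planted, names(x$planted)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Simulate a cohort from a ground truth
#'
#' SNP dosages are binomial(2, MAF) (Hardy-Weinberg); transcripts are
#' linear combinations of their parents plus Gaussian noise on the
#' natural-log expression scale; phenotype latents likewise, then mapped
#' to the clinical scale: TJ/SJ through the inverse of the
#' logit-continuity transform, rounded to `[0, 28]`; Pain to `[0, 100]`;
#' CRP as `exp(latent)` in mg/L.  The preprocessing transforms therefore
#' recover approximately Gaussian modelling variables.
#'
#' @param truth a `rv_ground_truth`.
#' @param n_subjects number of subjects (>= 2).
#' @param seed optional integer seed.
#' @return An `rv_cohort` on the clinical scale.
#' @export
generate_cohort <- function(truth, n_subjects = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_subjects < 2) abort("need at least 2 subjects")
  nodes <- truth$nodes
  edges <- truth$edges
  vals <- matrix(NA_real_, n_subjects, nrow(nodes),
                 dimnames = list(NULL, nodes$name))
  for (i in which(nodes$role == "snp")) {
    vals[, nodes$name[i]] <- rbinom(n_subjects, 2, nodes$maf[i])
  }
  for (i in which(nodes$role != "snp")) {
    nm <- nodes$name[i]
    mu <- rep(nodes$intercept[i], n_subjects)
    par_rows <- edges[edges$to == nm, ]
    for (j in seq_len(nrow(par_rows))) {
      mu <- mu + par_rows$beta[j] * vals[, par_rows$from[j]]
    }
    noise <- if (nodes$sigma[i] > 0) rnorm(n_subjects, 0, nodes$sigma[i]) else 0
    vals[, nm] <- mu + noise
  }
  ## latent -> clinical mapping for the phenotypes
  for (i in which(nodes$role == "phenotype")) {
    nm <- nodes$name[i]
    if (!is.na(nodes$m[i])) {
      vals[, nm] <- inv_logit_count(vals[, nm], nodes$m[i], round = TRUE)
    } else {
      vals[, nm] <- exp(vals[, nm])
    }
  }
  variables <- tibble(
    name = nodes$name,
    role = nodes$role,
    domain = ifelse(nodes$role == "snp", "discrete", "continuous"),
    transform = dplyr::case_when(
      nodes$role == "phenotype" & !is.na(nodes$m) ~ "logit_count",
      nodes$role == "phenotype" ~ "log",
      TRUE ~ "none"
    ),
    m = nodes$m,
    chrom = NA_character_
  )
  data <- dplyr::bind_cols(
    tibble(subject = sprintf("s%03d", seq_len(n_subjects))),
    as_tibble(as.data.frame(vals))
  )
  new_cohort(data, variables)
}

#' Analytic latent-scale knockdown effect
#'
#' Expected shift of each phenotype latent under an f-fold knockdown of
#' `transcript`: the sum over all directed paths from the transcript to
#' the phenotype of the product of edge coefficients, times `-log(fold)`.
#' Zero when no path exists.  Computed in closed form from the adjacency
#' series `(I - A)^{-1}`.
#'
#' @param truth a `rv_ground_truth`.
#' @param transcript transcript name.
#' @param fold fold knockdown.
#' @return Tibble `(phenotype, latent_shift)`.
#' @export
analytic_intervention_effect <- function(truth, transcript, fold = 10) {
  nodes <- truth$nodes$name
  if (!transcript %in% nodes) abort(sprintf("unknown transcript `%s`", transcript))
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (j in seq_len(nrow(truth$edges))) {
    A[truth$edges$from[j], truth$edges$to[j]] <- truth$edges$beta[j]
  }
  total <- solve(diag(length(nodes)) - A)  # sum of all path products
  phens <- truth$nodes$name[truth$nodes$role == "phenotype"]
  tibble(
    phenotype = phens,
    latent_shift = unname(-log(fold) * total[transcript, phens])
  )
}

#' Ground truth as a single-member ensemble
#'
#' Packages the true structure and parameters as a one-member
#' `rv_ensemble` whose fragment library contains, per child, the true
#' fragment and the parentless root — useful as an exact oracle for the
#' simulation machinery (no fitting involved).  Transcript children with
#' a SNP parent get one parameter row per genotype state, with the
#' additive dosage effect folded into the per-state intercepts.
#'
#' @param truth a `rv_ground_truth`.
#' @return A `rv_ensemble` with one member carrying the true parameters.
#' @export
as_true_ensemble <- function(truth) {
  nodes <- truth$nodes
  edges <- truth$edges
  snps <- nodes$name[nodes$role == "snp"]
  children <- nodes$name[nodes$role != "snp"]
  lib <- list()
  assignment <- integer(0)
  for (nm in children) {
    i <- which(nodes$name == nm)
    par_rows <- edges[edges$to == nm, ]
    parents <- par_rows$from
    disc <- intersect(parents, snps)
    cont <- setdiff(parents, disc)
    sigma <- nodes$sigma[i]
    root <- new_fragment(nm, theta0 = nodes$intercept[i], sigma = sigma,
                         kappa = 2, score = 0)
    if (length(parents) == 0) {
      lib[[nm]] <- list(root)
      assignment[[nm]] <- 1L
      next
    }
    if (length(disc) > 1) abort("at most one discrete parent supported here")
    if (length(disc) == 1) {
      states <- c("0", "1", "2")
      b_snp <- par_rows$beta[match(disc, par_rows$from)]
      theta0 <- nodes$intercept[i] + b_snp * as.numeric(states)
      beta <- matrix(rep(par_rows$beta[match(cont, par_rows$from)], each = 3),
                     3, length(cont), dimnames = list(NULL, cont))
      frag <- new_fragment(nm, parents, disc, states, theta0, beta,
                           rep(sigma, 3), kappa = 3 * (2 + length(cont)),
                           score = 0)
    } else {
      beta <- matrix(par_rows$beta[match(cont, par_rows$from)], 1,
                     length(cont), dimnames = list(NULL, cont))
      frag <- new_fragment(nm, parents, character(), "",
                           nodes$intercept[i], beta, sigma,
                           kappa = 2 + length(cont), score = 0)
    }
    lib[[nm]] <- list(frag, root)
    assignment[[nm]] <- 1L
  }
  variables <- tibble(
    name = nodes$name, role = nodes$role,
    domain = ifelse(nodes$role == "snp", "discrete", "continuous"),
    transform = dplyr::case_when(
      nodes$role == "phenotype" & !is.na(nodes$m) ~ "logit_count",
      nodes$role == "phenotype" ~ "log",
      TRUE ~ "none"
    ),
    m = nodes$m, chrom = NA_character_,
    on_model_scale = nodes$role == "phenotype"
  )
  library <- structure(list(
    children = lib, variables = variables, n = NA_integer_,
    max_parents = 2L, fragments_per_child = 2L
  ), class = "rv_fragment_library")
  structure(list(
    members = list(list(assignment = assignment, score = 0, chain = 1L)),
    library = library,
    n_chains = 1L,
    overlap_target = NA_real_,
    seed = truth$seed,
    schedules = list()
  ), class = "rv_ensemble")
}
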