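#' DAS28-CRP composite disease-activity score
#'
#' `0.56*sqrt(TJ) + 0.28*sqrt(SJ) + 0.36*log(CRP + 1) + 0.014*Pain + 0.96`,
#' the standard clinician's equation with the pain visual-analogue scale
#' standing in for the global-health VAS.  Depends on the joint counts
#' only, not on which joints are involved.
#'
#' @param tj,sj tender/swollen joint counts in `[0, 28]`.
#' @param pain pain VAS in `[0, 100]`.
#' @param crp C-reactive protein in mg/L (>= 0).
#' @param coef named coefficient vector `(tj, sj, crp, pain, const)`.
#' @return Numeric DAS28 scores.
#' @export
das28 <- function(tj, sj, pain, crp,
                  coef = c(tj = 0.56, sj = 0.28, crp = 0.36,
                           pain = 0.014, const = 0.96)) {
  if (any(tj < 0 | tj > 28, na.rm = TRUE)) abort("TJ outside [0, 28]")
  if (any(sj < 0 | sj > 28, na.rm = TRUE)) abort("SJ outside [0, 28]")
  if (any(pain < 0 | pain > 100, na.rm = TRUE)) abort("Pain outside [0, 100]")
  if (any(crp < 0, na.rm = TRUE)) abort("CRP must be >= 0")
  coef[["tj"]] * sqrt(tj) + coef[["sj"]] * sqrt(sj) +
    coef[["crp"]] * log(crp + 1) + coef[["pain"]] * pain +
    coef[["const"]]
}

#' Paired sign-pattern chi-square for joint counts
#'
#' Among subjects whose (integer) count changed, compares the observed
#' split of decreases vs increases to the 50:50 null with a 1-df Pearson
#' chi-square — a sign test in chi-square form, measuring whether a
#' significant number of patients respond in a consistent direction.  If
#' no subject changed, the statistic is 0 and p = 1.
#'
#' @param baseline,perturbed paired integer counts per subject.
#' @return Tibble with `statistic` and `p_value`.
#' @export
test_joint_counts <- function(baseline, perturbed) {
  if (length(baseline) != length(perturbed)) abort("length mismatch")
  if (length(baseline) < 2) abort("need at least 2 subjects")
  d <- perturbed - baseline
  n_dec <- sum(d < 0); n_inc <- sum(d > 0)
  n_ch <- n_dec + n_inc
  if (n_ch == 0) return(tibble(statistic = 0, p_value = 1))
  e <- n_ch / 2
  chi2 <- (n_dec - e)^2 / e + (n_inc - e)^2 / e
  tibble(statistic = chi2,
         p_value = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Paired Student's t-test for continuous phenotypes
#'
#' Two-sided paired t-test of `perturbed - baseline`.  All-zero
#' differences give `t = 0, p = 1`; a constant nonzero difference is
#' degenerate (`p = 0`) and flagged with a warning.
#'
#' @param baseline,perturbed paired per-subject values (n >= 3).
#' @return Tibble with `statistic` and `p_value`.
#' @export
test_continuous <- function(baseline, perturbed) {
  if (length(baseline) != length(perturbed)) abort("length mismatch")
  n <- length(baseline)
  if (n < 3) abort("need at least 3 subjects")
  d <- perturbed - baseline
  if (sd(d) == 0) {
    if (all(d == 0)) return(tibble(statistic = 0, p_value = 1))
    warn("degenerate paired t-test: constant nonzero difference")
    return(tibble(statistic = sign(mean(d)) * Inf, p_value = 0))
  }
  tt <- t.test(perturbed, baseline, paired = TRUE)
  tibble(statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Paired t-test on the composed DAS28 score
#'
#' Composes per-subject DAS28 from the four clinical-scale component
#' medians, then applies the paired t-test.
#'
#' @param baseline,perturbed data frames with columns `TJ`, `SJ`, `Pain`,
#'   `CRP` on the clinical scale (counts already rounded).
#' @return Tibble with `statistic` and `p_value`.
#' @export
test_das28 <- function(baseline, perturbed) {
  b <- das28(baseline$TJ, baseline$SJ, baseline$Pain, baseline$CRP)
  p <- das28(perturbed$TJ, perturbed$SJ, perturbed$Pain, perturbed$CRP)
  test_continuous(b, p)
}

## ---------------------------------------------------------------------------
## fast phenotype sweep

## Pre-resolve a member's phenotype fragments into a flat structure.
resolve_member_phens <- function(member, lib, phens) {
  frs <- map(phens, function(ph) lib$children[[ph]][[member$assignment[[ph]]]])
  names(frs) <- phens
  pm <- map(frs, "parents")
  ord <- topo_order(pm)
  list(frags = frs, order = ord)
}

## k replicate sweeps of the phenotypes only; all other variables clamped
## in `evid` (named scalars).  Returns k x length(phens) matrix.
sweep_phens_k <- function(resolved, evid, k, phens) {
  vals <- matrix(NA_real_, k, length(phens), dimnames = list(NULL, phens))
  for (ch in resolved$order) {
    f <- resolved$frags[[ch]]
    if (length(f$disc_parents)) {
      key <- state_key_of(evid[f$disc_parents])
      row <- match(key, f$state_keys)
      if (is.na(row)) {
        abort(sprintf("unseen state '%s' for fragment of `%s`", key, ch))
      }
    } else row <- 1L
    mu <- rep(f$theta0[row], k)
    for (cp in f$cont_parents) {
      x <- if (cp %in% phens) vals[, cp] else evid[[cp]]
      mu <- mu + f$beta[row, cp] * x
    }
    vals[, ch] <- rnorm(k, mu, f$sigma[row])
  }
  vals
}

## medians of n_replicates phenotype sweeps for one subject under `evid`
replicate_medians <- function(resolved_members, evid, n_replicates, phens) {
  K <- length(resolved_members)
  picks <- tabulate(sample.int(K, n_replicates, replace = TRUE), K)
  draws <- matrix(NA_real_, n_replicates, length(phens),
                  dimnames = list(NULL, phens))
  at <- 1L
  for (mi in which(picks > 0)) {
    k <- picks[mi]
    draws[at:(at + k - 1L), ] <-
      sweep_phens_k(resolved_members[[mi]], evid, k, phens)
    at <- at + k
  }
  apply(draws, 2, median)
}

## model-scale medians -> clinical scale; counts rounded at reporting time
medians_to_clinical <- function(med_mat, vmeta) {
  out <- med_mat
  for (ph in colnames(med_mat)) {
    i <- which(vmeta$name == ph)
    if (vmeta$transform[i] == "logit_count") {
      x <- inv_logit_count(med_mat[, ph], vmeta$m[i],
                           round = ph %in% c("TJ", "SJ"))
      out[, ph] <- pmin(pmax(x, 0), vmeta$m[i])
    } else if (vmeta$transform[i] == "log") {
      out[, ph] <- exp(med_mat[, ph])
    }
  }
  out
}

#' Run the virtual clinical trial
#'
#' For every gene, simulates a `fold`-fold knockdown in every subject
#' (`n_replicates` replicate sweeps, each from a uniformly drawn ensemble
#' member, genotypes and non-target transcripts clamped to the subject's
#' observed values), summarises per-subject medians, back-transforms to
#' the clinical scale, and tests perturbed vs the simulated untreated
#' baseline: chi-square sign-pattern test for TJ and SJ, paired t-test
#' for Pain and CRP, and a paired t-test on the composed DAS28.  Genes
#' are then ranked and assigned to categories with
#' [rank_and_categorize()].
#'
#' @param ensemble a `rv_ensemble`.
#' @param cohort the modelling-scale cohort.
#' @param genes transcripts to knock down (default: all in the library).
#' @param fold fold knockdown (default 10).
#' @param n_replicates replicate simulations per subject and gene.
#' @param alpha significance level.
#' @param annotation optional tibble `(gene, class)` with class `"novel"`
#'   (category 1) or `"alternative"` (category 2) for DAS28-significant
#'   genes.
#' @param seed optional integer seed.
#' @return A `rv_trial` tibble (one row per gene) with test statistics,
#'   p-values, BH q-values, significance flags and categories; per-gene
#'   per-subject clinical medians are attached as attributes
#'   `"baseline_medians"` and `"perturbed_medians"`.
#' @export
run_trial <- function(ensemble, cohort, genes = NULL, fold = 10,
                      n_replicates = 30, alpha = 0.05, annotation = NULL,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lib <- ensemble$library
  v <- lib$variables
  phens <- v$name[v$role == "phenotype"]
  if (!all(v$on_model_scale[v$role == "phenotype"])) {
    abort("cohort/library must be on the modelling scale; run transform_phenotypes() first")
  }
  genes <- genes %||% v$name[v$role == "transcript"]
  bad <- setdiff(genes, v$name[v$role == "transcript"])
  if (length(bad)) abort(sprintf("not a transcript: %s", bad[1]))
  tbl <- as_tibble(cohort)
  cc <- complete.cases(tbl[v$name])
  if (!all(cc)) {
    inform(sprintf("dropping %d subject(s) with missing values", sum(!cc)))
    tbl <- tbl[cc, ]
  }
  subjects <- tbl$subject
  clamp_names <- v$name[v$role %in% c("snp", "transcript")]
  ev_mat <- as.matrix(as.data.frame(tbl[clamp_names]))
  rownames(ev_mat) <- subjects

  resolved <- map(ensemble$members, resolve_member_phens, lib = lib,
                  phens = phens)

  ## untreated baseline: same machinery, no intervention
  base_mod <- t(vapply(seq_along(subjects), function(si) {
    replicate_medians(resolved, ev_mat[si, ], n_replicates, phens)
  }, numeric(length(phens))))
  colnames(base_mod) <- phens
  base_clin <- medians_to_clinical(base_mod, v)
  base_df <- as_tibble(as.data.frame(base_clin))

  shift <- log(fold)
  gene_rows <- map(genes, function(g) {
    pert_mod <- t(vapply(seq_along(subjects), function(si) {
      ev <- ev_mat[si, ]
      ev[[g]] <- ev[[g]] - shift
      replicate_medians(resolved, ev, n_replicates, phens)
    }, numeric(length(phens))))
    colnames(pert_mod) <- phens
    pert_clin <- medians_to_clinical(pert_mod, v)
    pert_df <- as_tibble(as.data.frame(pert_clin))
    tj <- test_joint_counts(base_df$TJ, pert_df$TJ)
    sj <- test_joint_counts(base_df$SJ, pert_df$SJ)
    pain <- test_continuous(base_df$Pain, pert_df$Pain)
    crp <- test_continuous(base_df$CRP, pert_df$CRP)
    d28 <- test_das28(base_df, pert_df)
    list(
      stats = tibble(
        gene = g,
        chi2_TJ = tj$statistic, p_TJ = tj$p_value,
        chi2_SJ = sj$statistic, p_SJ = sj$p_value,
        t_Pain = pain$statistic, p_Pain = pain$p_value,
        t_CRP = crp$statistic, p_CRP = crp$p_value,
        t_DAS28 = d28$statistic, p_DAS28 = d28$p_value,
        das28_shift = mean(
          das28(pert_df$TJ, pert_df$SJ, pert_df$Pain, pert_df$CRP) -
            das28(base_df$TJ, base_df$SJ, base_df$Pain, base_df$CRP)
        )
      ),
      medians = dplyr::bind_cols(tibble(gene = g, subject = subjects),
                                 pert_df)
    )
  })
  stats <- list_rbind(map(gene_rows, "stats"))
  out <- rank_and_categorize(stats, annotation = annotation, alpha = alpha)
  attr(out, "baseline_medians") <-
    dplyr::bind_cols(tibble(subject = subjects), base_df)
  attr(out, "perturbed_medians") <- list_rbind(map(gene_rows, "medians"))
  attr(out, "alpha") <- alpha
  attr(out, "fold") <- fold
  attr(out, "n_replicates") <- n_replicates
  class(out) <- c("rv_trial", class(out))
  out
}

#' Rank genes and assign trial categories
#'
#' A gene is significant when any of the five tests (TJ, SJ, Pain, CRP,
#' DAS28) has p below `alpha` (raw p-values, mirroring the p<0.05 rule;
#' BH q-values are added as clearly separated extra columns).  Categories:
#' DAS28-significant genes are category 1 (`"novel"` annotation) or 2
#' (`"alternative"`), or `"1/2 (unresolved)"` without annotation; genes
#' significant for TJ or SJ but not DAS28 are category 3 (impact joint
#' health but not DAS28); everything else is `"none"`.  Output is sorted
#' by DAS28 p-value, then best component p-value, ties broken by gene
#' name.
#'
#' @param stats per-gene tibble with columns `p_TJ`, `p_SJ`, `p_Pain`,
#'   `p_CRP`, `p_DAS28` (as produced inside [run_trial()]).
#' @param annotation optional tibble `(gene, class)`; see [run_trial()].
#' @param alpha significance level.
#' @return The annotated, sorted tibble.
#' @export
rank_and_categorize <- function(stats, annotation = NULL, alpha = 0.05) {
  pcols <- c("p_TJ", "p_SJ", "p_Pain", "p_CRP", "p_DAS28")
  missing <- setdiff(pcols, names(stats))
  if (length(missing)) abort(sprintf("missing column `%s`", missing[1]))
  out <- stats
  for (pc in pcols) out[[sub("^p_", "q_", pc)]] <- p.adjust(out[[pc]], "BH")
  pm <- as.matrix(out[pcols])
  out$best_component_p <- apply(pm[, 1:4, drop = FALSE], 1, min)
  sig_joint <- out$p_TJ < alpha | out$p_SJ < alpha
  sig_das28 <- out$p_DAS28 < alpha
  out$significant <- apply(pm < alpha, 1, any)
  cls <- rep(NA_character_, nrow(out))
  if (!is.null(annotation)) {
    cls <- annotation$class[match(out$gene, annotation$gene)]
  }
  out$category <- dplyr::case_when(
    sig_das28 & !is.na(cls) & cls == "novel" ~ "1",
    sig_das28 & !is.na(cls) & cls == "alternative" ~ "2",
    sig_das28 ~ "1/2 (unresolved)",
    sig_joint ~ "3",
    TRUE ~ "none"
  )
  out <- out[order(out$p_DAS28, out$best_component_p, out$gene), ]
  out
}

#' @export
print.rv_trial <- function(x, ...) {
  cat(sprintf(
    "# Virtual clinical trial: %d genes, %d significant (alpha = %s)\n",
    nrow(x), sum(x$significant), format(attr(x, "alpha") %||% 0.05)
  ))
  NextMethod()
}
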