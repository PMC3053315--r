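#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom Pearson chi-square of observed genotype counts
#' against the Hardy-Weinberg expectation at the sample allele frequency.
#' Monomorphic SNPs are in exact equilibrium by convention (chi2 = 0,
#' p = 1).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectorised).
#' @return Tibble with columns `chi2` and `p`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(c(n_AA, n_Aa, n_aa) < 0)) abort("genotype counts must be >= 0")
  if (any(n == 0)) abort("total genotype count must be > 0")
  p_hat <- (2 * n_aa + n_Aa) / (2 * n) # frequency of the 'a' allele
  e_AA <- n * (1 - p_hat)^2
  e_Aa <- n * 2 * p_hat * (1 - p_hat)
  e_aa <- n * p_hat^2
  chi2 <- numeric(length(n))
  poly <- p_hat > 0 & p_hat < 1
  chi2[poly] <- (n_AA[poly] - e_AA[poly])^2 / e_AA[poly] +
    (n_Aa[poly] - e_Aa[poly])^2 / e_Aa[poly] +
    (n_aa[poly] - e_aa[poly])^2 / e_aa[poly]
  p <- ifelse(poly, pchisq(chi2, df = 1, lower.tail = FALSE), 1)
  tibble(chi2 = chi2, p = p)
}

#' Genotype quality control
#'
#' Removes SNPs on the X or Y chromosome (when chromosome metadata is
#' present), SNPs with call rate below `call_rate_min` (strict `<`), minor
#' allele frequency below `maf_min`, or a Hardy-Weinberg equilibrium
#' p-value below `hwe_alpha`.  The per-SNP report is attached as the
#' `"qc_report"` attribute and retrievable with [qc_report()].
#'
#' @param cohort an `rv_cohort` containing at least one SNP.
#' @param call_rate_min minimum fraction of non-missing calls.
#' @param maf_min minimum minor allele frequency.
#' @param hwe_alpha Hardy-Weinberg rejection level.
#' @return The filtered cohort with attribute `qc_report`.
#' @export
qc_snps <- function(cohort, call_rate_min = 0.95, maf_min = 0.05,
                    hwe_alpha = 0.001) {
  v <- cohort_variables(cohort)
  snps <- v$name[v$role == "snp"]
  if (length(snps) == 0) abort("cohort contains no SNPs")
  chrom <- setNames(v$chrom, v$name)
  rep_rows <- map(snps, function(s) {
    g <- cohort[[s]]
    call_rate <- mean(!is.na(g))
    g_obs <- g[!is.na(g)]
    counts <- c(sum(g_obs == 0), sum(g_obs == 1), sum(g_obs == 2))
    if (length(g_obs) == 0) {
      maf <- 0; hw <- tibble(chi2 = 0, p = 1)
    } else {
      af <- (2 * counts[3] + counts[2]) / (2 * length(g_obs))
      maf <- min(af, 1 - af)
      hw <- hwe_test(counts[1], counts[2], counts[3])
    }
    reason <- ""
    if (!is.na(chrom[s]) && chrom[s] %in% c("X", "Y", "chrX", "chrY", "23", "24")) {
      reason <- "sex_chromosome"
    } else if (call_rate < call_rate_min) {
      reason <- "call_rate"
    } else if (maf < maf_min) {
      reason <- "maf"
    } else if (hw$p < hwe_alpha) {
      reason <- "hwe"
    }
    tibble(snp = s, call_rate = call_rate, maf = maf,
           hwe_chi2 = hw$chi2, hwe_p = hw$p,
           kept = reason == "", reason = reason)
  })
  report <- list_rbind(rep_rows)
  kept_snps <- report$snp[report$kept]
  if (length(kept_snps) == 0) {
    warn("all SNPs removed by quality control")
  }
  out <- select_variables(
    cohort, c(kept_snps, v$name[v$role != "snp"])
  )
  attr(out, "qc_report") <- report
  out
}

#' @rdname qc_snps
#' @param x a cohort returned by [qc_snps()].
#' @export
qc_report <- function(x) {
  r <- attr(x, "qc_report")
  if (is.null(r)) abort("no QC report attached; run qc_snps() first")
  r
}

#' Armitage trend statistic for a dosage-coded SNP
#'
#' Trend test generalised to continuous phenotypes: the statistic is
#' `n * r^2` where `r` is the Pearson correlation between the allele dosage
#' and the (optionally covariate-residualised) phenotype, referred to a
#' 1-df chi-square.  With `covariates` (e.g. top genotype principal
#' components) both dosage and phenotype are residualised first, the
#' standard population-stratification adjustment.
#'
#' @param dosage numeric vector of dosages in \{0,1,2\}.
#' @param phenotype numeric phenotype vector of the same length.
#' @param covariates optional numeric matrix of adjustment covariates.
#' @return Tibble with columns `stat` and `p`.
#' @export
armitage_trend <- function(dosage, phenotype, covariates = NULL) {
  if (length(dosage) != length(phenotype)) abort("length mismatch")
  keep <- complete.cases(dosage, phenotype)
  d <- dosage[keep]; y <- phenotype[keep]
  n <- length(d)
  if (n < 3) abort("need at least 3 complete observations")
  if (sd(d) == 0) abort("no variance in genotype dosage")
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)[keep, , drop = FALSE]
    X <- cbind(1, cv)
    d <- stats::lm.fit(X, d)$residuals
    y <- stats::lm.fit(X, y)$residuals
    if (sd(d) == 0) abort("no variance in genotype dosage")
  }
  r <- if (sd(y) == 0) 0 else cor(d, y)
  stat <- n * r^2
  tibble(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Rank SNPs by their best trend-test association across phenotypes
#'
#' Computes the Armitage trend statistic of every SNP against every
#' phenotype and ranks SNPs by their smallest p-value (union-by-rank),
#' breaking ties lexicographically by SNP name.
#'
#' @param cohort an `rv_cohort` (phenotypes on either scale).
#' @param k number of top SNPs to flag as selected.
#' @param covariates optional covariate matrix passed to
#'   [armitage_trend()].
#' @return Tibble with one row per SNP: `snp`, `best_p`, `best_phenotype`,
#'   `rank`, `selected`, ordered by rank.
#' @export
rank_snps <- function(cohort, k, covariates = NULL) {
  if (k <= 0) abort("`k` must be positive")
  snps <- variables_by_role(cohort, "snp")
  phens <- variables_by_role(cohort, "phenotype")
  if (k > length(snps)) abort("`k` exceeds the number of SNPs")
  rows <- map(snps, function(s) {
    ps <- map_dbl(phens, function(ph) {
      res <- tryCatch(
        armitage_trend(cohort[[s]], cohort[[ph]], covariates),
        error = function(e) tibble(stat = NA_real_, p = NA_real_)
      )
      res$p
    })
    if (all(is.na(ps))) {
      tibble(snp = s, best_p = NA_real_, best_phenotype = NA_character_)
    } else {
      i <- which.min(ps)
      tibble(snp = s, best_p = ps[i], best_phenotype = phens[i])
    }
  })
  out <- list_rbind(rows)
  out <- out[order(out$best_p, out$snp), ]
  out$rank <- seq_len(nrow(out))
  out$selected <- out$rank <= k
  out
}

# ---------------------------------------------------------------------------
# phenotype transforms

#' Logit transform for bounded counts
#'
#' Maps a count `c` in `[0, m]` to the real line with the continuity
#' correction `logit((c + 0.5) / (m + 1))`, which keeps both boundary
#' counts finite and is symmetric about `m/2`.  [inv_logit_count()]
#' recovers the clinical scale; counts are rounded back to the integer
#' grid only when `round = TRUE` (reporting time).
#'
#' @param x counts in `[0, m]`.
#' @param m maximum count (28 for joint counts, 100 for the pain VAS).
#' @return Transformed values.
#' @export
logit_count <- function(x, m) {
  if (any(x < 0 | x > m, na.rm = TRUE)) {
    abort(sprintf("count outside [0, %s]", format(m)))
  }
  qlogis((x + 0.5) / (m + 1))
}

#' @rdname logit_count
#' @param y values on the transformed scale.
#' @param round round back to integers in `[0, m]` (reporting time only).
#' @export
inv_logit_count <- function(y, m, round = FALSE) {
  x <- plogis(y) * (m + 1) - 0.5
  if (round) x <- pmin(pmax(round(x), 0), m)
  x
}

#' Transform phenotypes onto the modelling scale
#'
#' Applies each phenotype's declared transform: `logit_count` for TJ, SJ
#' and Pain (with their respective maxima) and natural log for CRP.
#' [inverse_transform_phenotypes()] undoes it; `round_counts = TRUE`
#' additionally rounds `logit_count` phenotypes to their integer grid.
#'
#' @param cohort an `rv_cohort` on the clinical scale.
#' @return The cohort on the modelling scale (flagged in the metadata).
#' @export
transform_phenotypes <- function(cohort) {
  v <- cohort_variables(cohort)
  tbl <- as_tibble(cohort)
  for (i in which(v$role == "phenotype")) {
    if (v$on_model_scale[i]) next
    nm <- v$name[i]
    x <- tbl[[nm]]
    if (v$transform[i] == "logit_count") {
      bad <- which(!is.na(x) & (x < 0 | x > v$m[i]))
      if (length(bad)) {
        abort(sprintf("count out of range for `%s`, subject %s",
                      nm, tbl$subject[bad[1]]))
      }
      tbl[[nm]] <- logit_count(x, v$m[i])
    } else if (v$transform[i] == "log") {
      bad <- which(!is.na(x) & x <= 0)
      if (length(bad)) {
        abort(sprintf("non-positive value for `%s`, subject %s",
                      nm, tbl$subject[bad[1]]))
      }
      tbl[[nm]] <- log(x)
    }
    v$on_model_scale[i] <- TRUE
  }
  out <- new_cohort(tbl, v)
  attr(out, "qc_report") <- attr(cohort, "qc_report")
  out
}

#' @rdname transform_phenotypes
#' @param round_counts round count phenotypes to their integer grid.
#' @export
inverse_transform_phenotypes <- function(cohort, round_counts = FALSE) {
  v <- cohort_variables(cohort)
  tbl <- as_tibble(cohort)
  for (i in which(v$role == "phenotype")) {
    if (!v$on_model_scale[i]) next
    nm <- v$name[i]
    if (v$transform[i] == "logit_count") {
      tbl[[nm]] <- inv_logit_count(tbl[[nm]], v$m[i], round = round_counts)
    } else if (v$transform[i] == "log") {
      tbl[[nm]] <- exp(tbl[[nm]])
    }
    v$on_model_scale[i] <- FALSE
  }
  out <- new_cohort(tbl, v)
  attr(out, "qc_report") <- attr(cohort, "qc_report")
  out
}

#' Keep the most variable transcripts
#'
#' Variance-rank surrogate for informative-gene calling: retains the `k`
#' transcripts with the largest sample variance of (log-scale) expression,
#' ties broken lexicographically by name.
#'
#' @param cohort an `rv_cohort`.
#' @param k number of transcripts to keep.
#' @return The reduced cohort.
#' @export
filter_informative_transcripts <- function(cohort, k) {
  tr <- variables_by_role(cohort, "transcript")
  if (k > length(tr)) abort("`k` exceeds the number of transcripts")
  vars <- map_dbl(tr, ~ var(cohort[[.x]], na.rm = TRUE))
  ord <- order(-vars, tr)
  keep_tr <- tr[ord[seq_len(k)]]
  v <- cohort_variables(cohort)
  out <- select_variables(cohort, c(
    v$name[v$role == "snp"], keep_tr, v$name[v$role == "phenotype"]
  ))
  attr(out, "qc_report") <- attr(cohort, "qc_report")
  out
}
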