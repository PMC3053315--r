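#' Construct a cohort table
#'
#' A cohort is a tibble with one row per subject, a `subject` identifier
#' column and one numeric column per measured variable, together with a
#' variable-metadata table stored in the `"variables"` attribute.  Each
#' variable carries a role (`snp`, `transcript` or `phenotype`), a domain
#' (`discrete` or `continuous`) and, for phenotypes, the transform that maps
#' it onto the modelling scale (`logit_count` with a maximum count `m`, or
#' `log` for CRP).
#'
#' @param data data frame with a `subject` column and one column per
#'   variable; genotype columns must contain only 0, 1, 2 or `NA`.
#' @param variables tibble with columns `name`, `role`, `domain`,
#'   `transform`, `m` and optionally `chrom`; one row per non-subject
#'   column of `data`.
#' @return A `rv_cohort` tibble.
#' @export
new_cohort <- function(data, variables) {
  data <- as_tibble(data)
  if (!"subject" %in% names(data)) {
    abort("`data` must contain a `subject` column.")
  }
  variables <- as_tibble(variables)
  needed <- c("name", "role", "domain", "transform", "m")
  for (col in needed) {
    if (!col %in% names(variables)) {
      if (col == "transform") variables$transform <- "none"
      else if (col == "m") variables$m <- NA_real_
      else abort(sprintf("variable metadata lacks column `%s`", col))
    }
  }
  if (!"chrom" %in% names(variables)) variables$chrom <- NA_character_
  if (!"on_model_scale" %in% names(variables)) {
    variables$on_model_scale <- FALSE
  }
  if (anyDuplicated(variables$name)) {
    abort("duplicate variable names in cohort")
  }
  if (!setequal(variables$name, setdiff(names(data), "subject"))) {
    abort("variable metadata does not match data columns")
  }
  if (nrow(data) < 2) abort("a cohort needs at least 2 subjects")
  if (anyDuplicated(data$subject)) abort("duplicate subject identifiers")
  bad_role <- setdiff(variables$role, c("snp", "transcript", "phenotype"))
  if (length(bad_role)) abort(sprintf("unknown role: %s", bad_role[1]))
  for (s in variables$name[variables$role == "snp"]) {
    v <- data[[s]]
    ok <- is.na(v) | v %in% c(0, 1, 2)
    if (!all(ok)) {
      abort(sprintf(
        "genotype values outside {0,1,2,NA} for SNP `%s` (e.g. %s)",
        s, format(v[!ok][1])
      ))
    }
  }
  data <- data[c("subject", variables$name)]
  structure(data,
    variables = variables,
    class = c("rv_cohort", class(data))
  )
}

#' Variable metadata of a cohort
#' @param cohort an `rv_cohort`.
#' @return Tibble of per-variable metadata (name, role, domain, transform).
#' @export
cohort_variables <- function(cohort) {
  v <- attr(cohort, "variables")
  if (is.null(v)) abort("not an rv_cohort: no variable metadata")
  v
}

#' @export
print.rv_cohort <- function(x, ...) {
  v <- attr(x, "variables")
  cat(sprintf(
    "# Cohort: %d subjects, %d SNPs, %d transcripts, %d phenotypes (%s scale)\n",
    nrow(x), sum(v$role == "snp"), sum(v$role == "transcript"),
    sum(v$role == "phenotype"),
    if (any(v$on_model_scale)) "model" else "clinical"
  ))
  NextMethod()
}

variables_by_role <- function(cohort, role) {
  v <- cohort_variables(cohort)
  v$name[v$role %in% role]
}

#' Keep a subset of variables
#'
#' Drops all measured variables not named in `keep`, retaining subject
#' identifiers and metadata for the kept variables.
#'
#' @param cohort an `rv_cohort`.
#' @param keep character vector of variable names to retain.
#' @return The reduced `rv_cohort`.
#' @export
select_variables <- function(cohort, keep) {
  v <- cohort_variables(cohort)
  missing <- setdiff(keep, v$name)
  if (length(missing)) {
    abort(sprintf("unknown variable(s): %s", paste(missing, collapse = ", ")))
  }
  v2 <- v[v$name %in% keep, , drop = FALSE]
  new_cohort(as_tibble(cohort)[c("subject", v2$name)], v2)
}

## numeric matrix view (subjects x variables), rownames = subject ids
cohort_matrix <- function(cohort) {
  v <- cohort_variables(cohort)
  m <- as.matrix(as.data.frame(as_tibble(cohort)[v$name]))
  rownames(m) <- cohort$subject
  m
}

# ---------------------------------------------------------------------------
# file reading

read_table_checked <- function(path, what) {
  if (!file.exists(path)) abort(sprintf("%s file not found: %s", what, path))
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

## features x subjects table -> subjects x features tibble (subject col first)
read_feature_table <- function(path, what) {
  raw <- read_table_checked(path, what)
  feat <- raw[[1]]
  if (anyDuplicated(feat)) abort(sprintf("duplicate %s names in %s", what, path))
  subjects <- names(raw)[-1]
  out <- lapply(seq_along(feat), function(i) {
    vals <- suppressWarnings(as.numeric(unlist(raw[i, -1], use.names = FALSE)))
    raw_vals <- unlist(raw[i, -1], use.names = FALSE)
    bad <- which(is.na(vals) & !is.na(raw_vals) &
                   !raw_vals %in% c("NA", "."))
    if (length(bad)) {
      abort(sprintf(
        "non-numeric %s value '%s' at row %s, column %s of %s",
        what, raw_vals[bad[1]], feat[i], subjects[bad[1]], path
      ))
    }
    vals
  })
  tbl <- tibble(subject = subjects)
  for (i in seq_along(feat)) tbl[[feat[i]]] <- out[[i]]
  tbl
}

## subjects x SNPs dosage TSV (first column = subject id)
read_genotype_tsv <- function(path) {
  raw <- read_table_checked(path, "genotype")
  snps <- names(raw)[-1]
  tbl <- tibble(subject = raw[[1]])
  for (s in snps) {
    v <- raw[[s]]
    v[v %in% c(".", "NA")] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which((is.na(num) & !is.na(v)) | (!is.na(num) & !num %in% c(0, 1, 2)))
    if (length(bad)) {
      abort(sprintf("invalid genotype value '%s' for SNP `%s`", v[bad[1]], s))
    }
    tbl[[s]] <- num
  }
  attr(tbl, "chrom") <- setNames(rep(NA_character_, length(snps)), snps)
  tbl
}

read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF genotypes requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- v@fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    abort("multi-allelic sites are not supported; split or drop them first")
  }
  ids <- v@fix[, "ID"]
  blank <- is.na(ids) | ids == "." | ids == ""
  ids[blank] <- paste0(v@fix[blank, "CHROM"], "_", v@fix[blank, "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
    sum(as.numeric(strsplit(g, "[/|]")[[1]]))
  })
  rownames(dosage) <- ids
  tbl <- tibble(subject = colnames(dosage))
  for (i in seq_along(ids)) tbl[[ids[i]]] <- unname(dosage[i, ])
  attr(tbl, "chrom") <- setNames(as.character(v@fix[, "CHROM"]), ids)
  tbl
}

#' Read a three-table cohort
#'
#' Assembles a cohort from a genotype dosage table (TSV, subjects in rows;
#' or a VCF, whose GT field is converted to an alternate-allele dosage), an
#' expression table (TSV, transcripts in rows, header row of subject IDs)
#' and a phenotype table in the same orientation containing the DAS28
#' component rows `TJ`, `SJ`, `Pain` and `CRP`.  Only subjects present in
#' all three tables are kept.
#'
#' @param genotype_path path to a dosage TSV or `.vcf` file.
#' @param expression_path path to the transcripts-by-subjects TSV.
#' @param phenotype_path path to the phenotype TSV (rows TJ, SJ, Pain, CRP).
#' @param count_max maximum joint count for TJ/SJ (28 joints).
#' @param pain_max maximum of the pain visual-analogue scale.
#' @return An `rv_cohort` on the clinical (untransformed) scale.
#' @export
read_cohort <- function(genotype_path, expression_path, phenotype_path,
                        count_max = 28, pain_max = 100) {
  geno <- if (grepl("\\.vcf(\\.gz)?$", genotype_path)) {
    read_genotype_vcf(genotype_path)
  } else {
    read_genotype_tsv(genotype_path)
  }
  chrom <- attr(geno, "chrom")
  expr <- read_feature_table(expression_path, "expression")
  phen <- read_feature_table(phenotype_path, "phenotype")
  need <- c("TJ", "SJ", "Pain", "CRP")
  if (!all(need %in% names(phen))) {
    abort(sprintf(
      "phenotype table must contain rows %s", paste(need, collapse = ", ")
    ))
  }
  subjects <- intersect(intersect(geno$subject, expr$subject), phen$subject)
  if (length(subjects) == 0) {
    abort("no subjects shared by the genotype, expression and phenotype tables")
  }
  geno <- geno[match(subjects, geno$subject), ]
  expr <- expr[match(subjects, expr$subject), ]
  phen <- phen[match(subjects, phen$subject), need]
  snps <- setdiff(names(geno), "subject")
  transcripts <- setdiff(names(expr), "subject")
  variables <- bind_rows(
    tibble(name = snps, role = "snp", domain = "discrete",
           transform = "none", m = NA_real_,
           chrom = unname(chrom[snps])),
    tibble(name = transcripts, role = "transcript", domain = "continuous",
           transform = "none", m = NA_real_, chrom = NA_character_),
    tibble(name = need, role = "phenotype", domain = "continuous",
           transform = c("logit_count", "logit_count", "logit_count", "log"),
           m = c(count_max, count_max, pain_max, NA_real_),
           chrom = NA_character_)
  )
  data <- dplyr::bind_cols(tibble(subject = subjects),
                           geno[snps], expr[transcripts], phen)
  new_cohort(data, variables)
}

#' Write a cohort back to its three-table form
#'
#' Inverse of [read_cohort()]: writes `genotype.tsv` (subjects x SNPs),
#' `expression.tsv` and `phenotype.tsv` (features x subjects) into `dir`.
#'
#' @param cohort an `rv_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- cohort_variables(cohort)
  tbl <- as_tibble(cohort)
  paths <- c(
    genotype = file.path(dir, "genotype.tsv"),
    expression = file.path(dir, "expression.tsv"),
    phenotype = file.path(dir, "phenotype.tsv")
  )
  readr::write_tsv(tbl[c("subject", v$name[v$role == "snp"])],
                   paths[["genotype"]])
  feat_out <- function(roles, path) {
    nm <- v$name[v$role %in% roles]
    m <- t(as.matrix(as.data.frame(tbl[nm])))
    out <- as_tibble(as.data.frame(m), .name_repair = "minimal")
    names(out) <- tbl$subject
    out <- dplyr::bind_cols(tibble(feature = nm), out)
    readr::write_tsv(out, path)
  }
  feat_out("transcript", paths[["expression"]])
  feat_out("phenotype", paths[["phenotype"]])
  invisible(paths)
}
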