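write_three_tables <- function(dir, subjects,
                               geno_subjects = subjects,
                               phen_subjects = subjects,
                               bad_cell = NULL) {
  dir.create(dir, showWarnings = FALSE)
  g <- data.frame(subject = geno_subjects,
                  rs1 = rep_len(c(0, 1, 2), length(geno_subjects)),
                  rs2 = rep_len(c(1, 0), length(geno_subjects)))
  if (!is.null(bad_cell)) g$rs1[1] <- bad_cell
  readr::write_tsv(g, file.path(dir, "genotype.tsv"))
  e <- data.frame(feature = c("gA", "gB"))
  for (s in subjects) e[[s]] <- round(rnorm(2), 3)
  readr::write_tsv(e, file.path(dir, "expression.tsv"))
  p <- data.frame(feature = c("TJ", "SJ", "Pain", "CRP"))
  for (s in phen_subjects) p[[s]] <- c(5, 3, 40, 2.5)
  readr::write_tsv(p, file.path(dir, "phenotype.tsv"))
  dir
}

test_that("read_cohort intersects subjects and labels roles", {
  dir <- write_three_tables(withr::local_tempdir(), c("s1", "s2", "s3"))
  co <- read_cohort(file.path(dir, "genotype.tsv"),
                    file.path(dir, "expression.tsv"),
                    file.path(dir, "phenotype.tsv"))
  expect_equal(nrow(co), 3)
  v <- cohort_variables(co)
  expect_setequal(v$name[v$role == "snp"], c("rs1", "rs2"))
  expect_setequal(v$name[v$role == "transcript"], c("gA", "gB"))
  expect_setequal(v$name[v$role == "phenotype"], c("TJ", "SJ", "Pain", "CRP"))

  ## partial overlap keeps only the shared subjects
  dir2 <- write_three_tables(withr::local_tempdir(),
                             subjects = c("s1", "s2", "s3", "s4"),
                             geno_subjects = c("s2", "s3", "s4"),
                             phen_subjects = c("s1", "s2", "s3"))
  co2 <- read_cohort(file.path(dir2, "genotype.tsv"),
                     file.path(dir2, "expression.tsv"),
                     file.path(dir2, "phenotype.tsv"))
  expect_setequal(co2$subject, c("s2", "s3"))

  ## empty intersection is fatal
  dir3 <- write_three_tables(withr::local_tempdir(),
                             subjects = c("s1", "s2"),
                             geno_subjects = c("t1", "t2"))
  expect_error(
    read_cohort(file.path(dir3, "genotype.tsv"),
                file.path(dir3, "expression.tsv"),
                file.path(dir3, "phenotype.tsv")),
    "no subjects"
  )
})

test_that("invalid genotype values are rejected with the SNP named", {
  dir <- write_three_tables(withr::local_tempdir(), c("s1", "s2", "s3"),
                            bad_cell = 3)
  expect_error(
    read_cohort(file.path(dir, "genotype.tsv"),
                file.path(dir, "expression.tsv"),
                file.path(dir, "phenotype.tsv")),
    "rs1"
  )
  expect_error(
    new_cohort(
      tibble::tibble(subject = c("a", "b"), s1 = c(0, 7)),
      tibble::tibble(name = "s1", role = "snp", domain = "discrete",
                     transform = "none", m = NA_real_)
    ),
    "s1"
  )
})

test_that("non-numeric expression cells are fatal with row/column report", {
  dir <- withr::local_tempdir()
  write_three_tables(dir, c("s1", "s2"))
  e <- readr::read_tsv(file.path(dir, "expression.tsv"),
                       show_col_types = FALSE)
  e$s2[1] <- "oops"
  readr::write_tsv(e, file.path(dir, "expression.tsv"))
  expect_error(
    read_cohort(file.path(dir, "genotype.tsv"),
                file.path(dir, "expression.tsv"),
                file.path(dir, "phenotype.tsv")),
    "gA.*s2"
  )
})

test_that("read_cohort is idempotent on its own written output", {
  fix <- study_fixture()
  co <- inverse_transform_phenotypes(fix$cohort)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  co2 <- read_cohort(paths[["genotype"]], paths[["expression"]],
                     paths[["phenotype"]])
  expect_equal(co2$subject, co$subject)
  expect_equal(cohort_variables(co2)$name, cohort_variables(co)$name)
  expect_equal(as.data.frame(co2), as.data.frame(co), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("VCF genotypes convert to dosage and multi-allelic sites fail", {
  skip_if_not_installed("vcfR")
  dir <- withr::local_tempdir()
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "2\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1\t./.\t0/0"
  )
  writeLines(vcf, file.path(dir, "geno.vcf"))
  write_three_tables(dir, c("s1", "s2", "s3"))
  co <- read_cohort(file.path(dir, "geno.vcf"),
                    file.path(dir, "expression.tsv"),
                    file.path(dir, "phenotype.tsv"))
  expect_equal(co$rs1, c(0, 1, 2))
  expect_equal(co$rs2, c(1, NA, 0))
  vcf_bad <- vcf
  vcf_bad[4] <- "1\t100\trs1\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1"
  writeLines(vcf_bad, file.path(dir, "bad.vcf"))
  expect_error(
    read_cohort(file.path(dir, "bad.vcf"),
                file.path(dir, "expression.tsv"),
                file.path(dir, "phenotype.tsv")),
    "multi-allelic"
  )
})

test_that("ensemble JSON round-trip is lossless and versioned", {
  pair <- make_pair_library()
  ens <- suppressWarnings(
    sample_ensemble(pair$library, ensemble_size = 6, n_chains = 2, seed = 31)
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_equal(length(back$members), 6)
  for (k in seq_along(ens$members)) {
    expect_identical(back$members[[k]]$assignment, ens$members[[k]]$assignment)
    expect_identical(back$members[[k]]$score, ens$members[[k]]$score)
  }
  expect_equal(tidy(back$library)$score, tidy(ens$library)$score)
  expect_identical(back$seed, ens$seed)

  ## empty ensembles are not serialisable
  empty <- ens
  empty$members <- list()
  expect_error(write_ensemble(empty, path), "empty")

  ## version mismatch is fatal
  js <- jsonlite::read_json(path)
  js$version <- "something-else"
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_ensemble(path), "version mismatch")
})

test_that("consensus export thresholds edge frequencies correctly", {
  pair <- make_pair_library()
  lib <- pair$library
  ## fabricate a 100-member ensemble: edge a->b in exactly 2 members
  idx_edge <- which(vapply(lib$children$b, function(f) length(f$parents) > 0,
                           logical(1)))[1]
  idx_root_b <- which(vapply(lib$children$b, function(f) length(f$parents) == 0,
                             logical(1)))[1]
  idx_root_a <- which(vapply(lib$children$a, function(f) length(f$parents) == 0,
                             logical(1)))[1]
  members <- lapply(seq_len(100), function(k) {
    list(assignment = c(a = idx_root_a,
                        b = if (k <= 2) idx_edge else idx_root_b),
         score = 0)
  })
  ens <- structure(list(members = members, library = lib, n_chains = 1L,
                        overlap_target = 0.8, seed = 1L, schedules = list()),
                   class = "rv_ensemble")
  ef <- edge_frequencies(ens)
  expect_equal(ef$freq[ef$from == "a" & ef$to == "b"], 0.02)
  ## 0.02 < 0.025: edge absent at the default consensus threshold
  expect_equal(nrow(consensus_edges(ens, 0.025)), 0)
  expect_equal(nrow(consensus_edges(ens, 0.02)), 1)

  ## unanimity case and monotonicity in the threshold
  members_all <- lapply(seq_len(100), function(k) {
    list(assignment = c(a = idx_root_a, b = idx_edge), score = 0)
  })
  ens_all <- ens
  ens_all$members <- members_all
  ce <- consensus_edges(ens_all, 0.5)
  expect_equal(ce$freq, 1)
  thresholds <- c(0.01, 0.1, 0.5, 0.9, 1)
  sizes <- vapply(thresholds, function(th) nrow(consensus_edges(ens, th)),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))

  ## written files exist in both dialects
  gml <- withr::local_tempfile(fileext = ".graphml")
  dot <- withr::local_tempfile(fileext = ".dot")
  export_consensus(ens_all, gml, 0.5)
  export_consensus(ens_all, dot, 0.5)
  expect_true(file.size(gml) > 0)
  expect_true(any(grepl("digraph", readLines(dot))))
})
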