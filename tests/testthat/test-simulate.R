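# hand-built linear-Gaussian systems for exact moment checks

make_manual_library <- function(frags, roles = NULL) {
  children <- unique(vapply(frags, function(f) f$child, character(1)))
  all_names <- unique(c(children,
                        unlist(lapply(frags, function(f) f$parents))))
  roles <- roles %||% stats::setNames(rep("transcript", length(all_names)),
                                      all_names)
  lib <- lapply(children, function(ch) {
    Filter(function(f) f$child == ch, frags)
  })
  names(lib) <- children
  variables <- tibble::tibble(
    name = all_names,
    role = unname(roles[all_names]),
    domain = ifelse(roles[all_names] == "snp", "discrete", "continuous"),
    transform = "none", m = NA_real_, chrom = NA_character_,
    on_model_scale = TRUE
  )
  structure(list(children = lib, variables = variables, n = NA_integer_,
                 max_parents = 2L, fragments_per_child = 2L),
            class = "rv_fragment_library")
}

manual_model <- function(library) {
  assignment <- vapply(names(library$children), function(ch) 1L, integer(1))
  names(assignment) <- names(library$children)
  structure(list(assignment = assignment, score = 0),
            class = "rv_network_model")
}

test_that("forward sampling reproduces analytic moments on core motifs", {
  n <- 10000
  ## chain x -> y -> z: y = 1 + 2x + e(0.5), z = -1 + 0.5y + e(0.3)
  chain <- make_manual_library(list(
    new_fragment("x", theta0 = 0, sigma = 1, score = 0),
    new_fragment("y", parents = "x", theta0 = 1,
                 beta = matrix(2, 1, 1, dimnames = list(NULL, "x")),
                 sigma = 0.5, score = 0),
    new_fragment("z", parents = "y", theta0 = -1,
                 beta = matrix(0.5, 1, 1, dimnames = list(NULL, "y")),
                 sigma = 0.3, score = 0)
  ))
  withr::with_seed(101, {
    draws <- forward_sample(manual_model(chain), chain, n = n)
  })
  ## E[y] = 1, Var[y] = 4 + 0.25; E[z] = -0.5, Var[z] = 0.25*4.25 + 0.09
  expect_equal(mean(draws$y), 1, tolerance = 0.08)
  expect_equal(var(draws$y), 4.25, tolerance = 0.15)
  expect_equal(mean(draws$z), -0.5, tolerance = 0.05)
  expect_equal(var(draws$z), 0.25 * 4.25 + 0.09, tolerance = 0.06)
  expect_equal(cov(draws$x, draws$y), 2, tolerance = 0.1)

  ## fork y <- x -> z
  fork <- make_manual_library(list(
    new_fragment("x", theta0 = 0, sigma = 1, score = 0),
    new_fragment("y", parents = "x", theta0 = 0,
                 beta = matrix(1.5, 1, 1, dimnames = list(NULL, "x")),
                 sigma = 0.4, score = 0),
    new_fragment("z", parents = "x", theta0 = 0,
                 beta = matrix(-1, 1, 1, dimnames = list(NULL, "x")),
                 sigma = 0.4, score = 0)
  ))
  withr::with_seed(102, {
    draws <- forward_sample(manual_model(fork), fork, n = n)
  })
  expect_equal(cov(draws$y, draws$z), -1.5, tolerance = 0.1)
  expect_equal(var(draws$y), 1.5^2 + 0.16, tolerance = 0.1)

  ## collider x -> z <- y: z = x + y + e(0.5)
  collider <- make_manual_library(list(
    new_fragment("x", theta0 = 0, sigma = 1, score = 0),
    new_fragment("y", theta0 = 0, sigma = 1, score = 0),
    new_fragment("z", parents = c("x", "y"), theta0 = 0,
                 beta = matrix(c(1, 1), 1, 2,
                               dimnames = list(NULL, c("x", "y"))),
                 sigma = 0.5, score = 0)
  ))
  withr::with_seed(103, {
    draws <- forward_sample(manual_model(collider), collider, n = n)
  })
  expect_lt(abs(cov(draws$x, draws$y)), 0.05)
  expect_equal(var(draws$z), 2.25, tolerance = 0.1)

  ## clamped parents: child is exactly Normal(theta0 + sum(beta*y), sigma)
  withr::with_seed(104, {
    draws <- forward_sample(manual_model(chain), chain,
                            evidence = c(x = 2), n = n)
  })
  expect_true(all(draws$x == 2))
  expect_equal(mean(draws$y), 5, tolerance = 0.05)
  expect_equal(sd(draws$y), 0.5, tolerance = 0.02)

  ## clamping everything makes the sweep degenerate
  draws <- forward_sample(manual_model(chain), chain,
                          evidence = c(x = 1, y = 2, z = 3), n = 5)
  expect_true(all(draws$x == 1 & draws$y == 2 & draws$z == 3))
})

test_that("discrete parents switch parameter rows by state", {
  lib <- make_manual_library(list(
    new_fragment("t", parents = "s", disc_parents = "s",
                 state_keys = c("0", "1", "2"),
                 theta0 = c(0, 5, 20), sigma = c(0.1, 0.1, 0.1), score = 0)
  ), roles = c(s = "snp", t = "transcript"))
  withr::with_seed(105, {
    d0 <- forward_sample(manual_model(lib), lib, evidence = c(s = 0), n = 200)
    d2 <- forward_sample(manual_model(lib), lib, evidence = c(s = 2), n = 200)
  })
  expect_equal(mean(d0$t), 0, tolerance = 0.05)
  expect_equal(mean(d2$t), 20, tolerance = 0.05)
  ## unclamped SNPs are an error, as is an unseen state
  expect_error(forward_sample(manual_model(lib), lib, n = 1), "clamped")
  expect_error(forward_sample(manual_model(lib), lib, evidence = c(s = 7)),
               "unseen state")
})

test_that("knockdown surgery clamps at observed - log(fold)", {
  fix <- study_fixture()
  ens <- as_true_ensemble(fix$truth)
  lib <- ens$library
  model <- structure(list(assignment = ens$members[[1]]$assignment, score = 0),
                     class = "rv_network_model")
  gene <- fix$truth$planted[[1]]
  ev <- c(stats::setNames(1.25, gene))
  out <- apply_intervention(model, lib, gene, ev, fold = 10)
  expect_equal(out$evidence[[gene]], 1.25 - log(10))
  ## the target's fragment is removed: it becomes a parentless root
  frs <- lib$children[[gene]]
  expect_equal(length(frs[[out$model$assignment[[gene]]]]$parents), 0)
  ## linear-scale ratio is exactly the fold
  expect_equal(exp(ev[[gene]]) / exp(out$evidence[[gene]]), 10)
  ## fold = 1 clamps at the observed value
  out1 <- apply_intervention(model, lib, gene, ev, fold = 1)
  expect_equal(out1$evidence[[gene]], 1.25)
  ## SNPs and phenotypes are not valid targets
  expect_error(apply_intervention(model, lib, "snp01", c(snp01 = 1)),
               "transcripts")
  expect_error(apply_intervention(model, lib, "TJ", c(TJ = 0)), "transcripts")
})

test_that("interventions only move descendants; fold = 1 is a no-op", {
  fix <- study_fixture()
  truth <- fix$truth
  ens <- as_true_ensemble(truth)
  cohort <- fix$cohort
  subject <- cohort$subject[1]

  planted <- truth$planted[[1]]
  target_phen <- names(truth$planted)[1]
  other_phens <- setdiff(c("TJ", "SJ", "Pain", "CRP"), target_phen)
  ## direct-effect phenotypes of the other planted genes are descendants of
  ## those genes, not of this one
  non_desc <- setdiff(other_phens, names(truth$planted))

  base <- simulate_subject(ens, cohort, subject, gene = NULL,
                           n_replicates = 400, seed = 301)
  kd <- simulate_subject(ens, cohort, subject, gene = planted, fold = 10,
                         n_replicates = 400, seed = 302)
  ## the targeted phenotype shifts by beta * (-log 10) on the latent scale
  shift <- analytic_intervention_effect(truth, planted, 10)
  expected <- shift$latent_shift[shift$phenotype == target_phen]
  observed <- mean(kd[[target_phen]]) - mean(base[[target_phen]])
  expect_equal(observed, expected, tolerance = 0.12)
  ## non-descendant phenotypes keep their distribution (KS, Bonferroni)
  for (ph in non_desc) {
    expect_gt(suppressWarnings(
      stats::ks.test(base[[ph]], kd[[ph]])$p.value
    ), 0.01 / length(non_desc))
  }

  ## fold = 1 is distributionally a no-op
  same <- simulate_subject(ens, cohort, subject, gene = planted, fold = 1,
                           n_replicates = 400, seed = 303)
  for (ph in c("TJ", "SJ", "Pain", "CRP")) {
    expect_gt(suppressWarnings(
      stats::ks.test(base[[ph]], same[[ph]])$p.value
    ), 0.01 / 4)
  }
})

test_that("knockdown shifts match the analytic path-sum oracle", {
  ## under full propagation, indirect transcript-mediated paths contribute;
  ## the analytic oracle sums coefficient products over all directed paths
  truth <- generate_ground_truth(n_snps = 4, n_genes = 6, n_planted = 2,
                                 edge_density = 0.5, seed = 404)
  cohort <- transform_phenotypes(generate_cohort(truth, 50, seed = 405))
  ens <- as_true_ensemble(truth)
  ## pick a transcript with at least one downstream path to a phenotype
  genes <- truth$nodes$name[truth$nodes$role == "transcript"]
  effects <- lapply(genes, analytic_intervention_effect, truth = truth)
  has_eff <- vapply(effects, function(e) any(abs(e$latent_shift) > 1e-9),
                    logical(1))
  g <- genes[has_eff][1]
  eff <- analytic_intervention_effect(truth, g, 10)
  subject <- cohort$subject[3]
  ## fold = 1 baseline clamps the target at its observed value, so the
  ## knockdown contrast is exactly -log(10) on the target
  base <- simulate_subject(ens, cohort, subject, gene = g, fold = 1,
                           n_replicates = 600, propagate_transcripts = TRUE,
                           seed = 406)
  kd <- simulate_subject(ens, cohort, subject, gene = g, fold = 10,
                         n_replicates = 600, propagate_transcripts = TRUE,
                         seed = 407)
  for (ph in eff$phenotype) {
    expect_equal(mean(kd[[ph]]) - mean(base[[ph]]),
                 eff$latent_shift[eff$phenotype == ph],
                 tolerance = 0.15)
  }
})

test_that("simulate_subject bookkeeping and medians behave as specified", {
  fix <- study_fixture()
  ens <- as_true_ensemble(fix$truth)
  sims <- simulate_subject(ens, fix$cohort, fix$cohort$subject[1],
                           gene = fix$truth$planted[[1]], seed = 211)
  expect_equal(nrow(sims), 30)
  expect_setequal(c("TJ", "SJ", "Pain", "CRP") %in% names(sims), TRUE)

  med <- summarize_medians(tibble::tibble(
    subject = "s1", gene = "g", replicate = 1:3, TJ = c(1, 2, 3)
  ))
  expect_equal(med$TJ, 2)
  med4 <- summarize_medians(tibble::tibble(
    subject = "s1", gene = "g", replicate = 1:4, TJ = c(1, 2, 3, 4)
  ))
  expect_equal(med4$TJ, 2.5)
  medc <- summarize_medians(tibble::tibble(
    subject = "s1", gene = "g", replicate = 1:5, TJ = rep(7, 5)
  ))
  expect_equal(medc$TJ, 7)
})
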