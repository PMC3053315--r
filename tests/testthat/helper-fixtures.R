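# Shared fixtures: everything is generated in code at test time.

## small continuous-only cohort (transcripts x, y, z plus one SNP)
make_toy_cohort <- function(n = 60, seed = 42) {
  withr::with_seed(seed, {
    snp <- rbinom(n, 2, 0.4)
    x <- rnorm(n)
    y <- 1 + 2 * x + rnorm(n, 0, 0.5)
    z <- rnorm(n)
    new_cohort(
      tibble::tibble(
        subject = sprintf("s%02d", seq_len(n)),
        snp1 = snp, x = x, y = y, z = z
      ),
      tibble::tibble(
        name = c("snp1", "x", "y", "z"),
        role = c("snp", "transcript", "transcript", "transcript"),
        domain = c("discrete", rep("continuous", 3)),
        transform = "none", m = NA_real_
      )
    )
  })
}

## default-conditions synthetic study cohort, shared by heavier tests
study_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- generate_ground_truth(seed = 2024)
      cohort <- generate_cohort(truth, 100, seed = 2025)
      cache <<- list(truth = truth,
                     cohort = transform_phenotypes(qc_snps(cohort)))
    }
    cache
  }
})

## independent negative log-likelihood oracle: direct dnorm evaluation of a
## fragment's stored parameters on a cohort (no shared code with the package
## scoring path)
oracle_fragment_score <- function(frag, cohort) {
  tbl <- tibble::as_tibble(cohort)
  n <- nrow(tbl)
  nll <- 0
  for (i in seq_len(n)) {
    if (length(frag$disc_parents)) {
      key <- paste(unlist(tbl[i, frag$disc_parents]), collapse = "|")
      row <- match(key, frag$state_keys)
    } else {
      row <- 1L
    }
    mu <- frag$theta0[row]
    for (cp in frag$cont_parents) {
      mu <- mu + frag$beta[row, cp] * tbl[[cp]][i]
    }
    nll <- nll - dnorm(tbl[[frag$child]][i], mu, frag$sigma[row], log = TRUE)
  }
  nll + frag$kappa / 2 * log(n)
}

## hand-built two-variable continuous library for sampler tests:
## children a, b with fragments {root, other -> child}
make_pair_library <- function(n = 80, beta = 1.5, seed = 7) {
  co <- withr::with_seed(seed, {
    a <- rnorm(n)
    b <- beta * a + rnorm(n, 0, 0.6)
    new_cohort(
      tibble::tibble(subject = sprintf("s%02d", seq_len(n)), a = a, b = b),
      tibble::tibble(name = c("a", "b"), role = "transcript",
                     domain = "continuous", transform = "none", m = NA_real_)
    )
  })
  list(cohort = co, library = build_fragments(co, max_parents = 1))
}

## enumerate all acyclic assignments of a library and their Boltzmann weights
enumerate_structures <- function(library) {
  kids <- names(library$children)
  sizes <- vapply(library$children, length, integer(1))
  grid <- expand.grid(lapply(sizes, seq_len))
  names(grid) <- kids
  keep <- logical(nrow(grid))
  scores <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    assignment <- stats::setNames(as.integer(grid[r, ]), kids)
    model <- structure(list(assignment = assignment, score = 0),
                       class = "rv_network_model")
    pm <- lapply(kids, function(ch) {
      library$children[[ch]][[assignment[[ch]]]]$parents
    })
    names(pm) <- kids
    ok <- !is.null(tryCatch(ravnet:::topo_order(pm), error = function(e) NULL))
    keep[r] <- ok
    if (ok) {
      scores[r] <- sum(vapply(kids, function(ch) {
        library$children[[ch]][[assignment[[ch]]]]$score
      }, numeric(1)))
    }
  }
  grid <- grid[keep, , drop = FALSE]
  scores <- scores[keep]
  w <- exp(-(scores - min(scores)))
  list(assignments = grid, scores = scores, prob = w / sum(w))
}

assignment_key <- function(assignment) paste(assignment, collapse = "/")
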