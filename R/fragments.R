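#' Construct a network fragment from explicit parameters
#'
#' A fragment is a child variable, up to `max_parents` parents and a
#' conditional linear-Gaussian distribution: for every joint state of the
#' discrete parents it holds an intercept, one coefficient per continuous
#' parent and a residual standard deviation.  Discrete parents contribute
#' no linear term; their joint state switches the parameter set.  This
#' constructor is mainly useful for building ground-truth models by hand;
#' fitted fragments come from [fit_fragment()].
#'
#' @param child child variable name (never a SNP).
#' @param parents character vector of parent names (may be empty).
#' @param disc_parents which of `parents` are discrete.
#' @param state_keys joint discrete-parent states as strings, values joined
#'   by `"|"` in `disc_parents` order; `""` when there are none.
#' @param theta0 intercept per state.
#' @param beta matrix (states x continuous parents) of linear coefficients.
#' @param sigma residual SD per state (all > 0).
#' @param kappa,score,nll optional bookkeeping fields for fitted fragments.
#' @return A `rv_fragment`.
#' @export
new_fragment <- function(child, parents = character(), disc_parents = character(),
                         state_keys = "", theta0, beta = NULL, sigma,
                         kappa = NA_real_, score = NA_real_, nll = NA_real_) {
  cont_parents <- setdiff(parents, disc_parents)
  n_states <- length(state_keys)
  if (is.null(beta)) {
    beta <- matrix(0, n_states, length(cont_parents),
                   dimnames = list(NULL, cont_parents))
  }
  beta <- matrix(beta, n_states, length(cont_parents),
                 dimnames = list(NULL, cont_parents))
  stopifnot(length(theta0) == n_states, length(sigma) == n_states,
            all(sigma > 0))
  structure(list(
    child = child, parents = parents,
    disc_parents = disc_parents, cont_parents = cont_parents,
    state_keys = state_keys, theta0 = theta0, beta = beta, sigma = sigma,
    kappa = kappa, score = score, nll = nll
  ), class = "rv_fragment")
}

#' @export
print.rv_fragment <- function(x, ...) {
  cat(sprintf(
    "<fragment> %s <- {%s}  (%d state%s, kappa=%s, score=%s)\n",
    x$child,
    paste(x$parents, collapse = ", "),
    length(x$state_keys), if (length(x$state_keys) == 1) "" else "s",
    format(x$kappa), format(x$score, digits = 6)
  ))
  invisible(x)
}

state_key_of <- function(vals) paste(vals, collapse = "|")

## residual-SD floor: guards against degenerate -Inf scores on duplicated data
sigma_floor <- function(y) {
  s <- sd(y)
  if (!is.finite(s) || s == 0) 1e-12 else 1e-6 * s
}

## core fitter: y (child values), Xc (continuous-parent matrix or NULL),
## g (joint discrete state per subject, character), N = cohort size for the
## BIC penalty.  Per-state OLS with MLE residual SD.
fit_frag_core <- function(child, parents, disc_parents, y, Xc, g, N) {
  cont_parents <- setdiff(parents, disc_parents)
  p <- 1L + length(cont_parents)
  if (is.null(g)) {
    groups <- list(seq_along(y)); keys <- ""
  } else {
    groups <- split(seq_along(y), g)
    keys <- names(groups)
  }
  n_states <- length(groups)
  theta0 <- numeric(n_states)
  beta <- matrix(0, n_states, length(cont_parents),
                 dimnames = list(NULL, cont_parents))
  sigma <- numeric(n_states)
  nll <- 0
  floor_s <- sigma_floor(y)
  for (i in seq_len(n_states)) {
    idx <- groups[[i]]
    n_s <- length(idx)
    ## identifiability: strictly more observations than mean parameters,
    ## otherwise the state is interpolated and sigma degenerates to the floor
    if (n_s < p + 1) abort("insufficient state support")
    if (length(cont_parents)) {
      X <- cbind(1, Xc[idx, , drop = FALSE])
      fit <- stats::.lm.fit(X, y[idx])
      if (fit$rank < p) abort("collinear continuous parents")
      cf <- fit$coefficients
      theta0[i] <- cf[1]
      beta[i, ] <- cf[-1]
      rss <- sum(fit$residuals^2)
    } else {
      theta0[i] <- mean(y[idx])
      rss <- sum((y[idx] - theta0[i])^2)
    }
    sigma[i] <- max(sqrt(rss / n_s), floor_s)
    nll <- nll + n_s * log(sigma[i] * sqrt(2 * pi)) + rss / (2 * sigma[i]^2)
  }
  kappa <- n_states * (2 + length(cont_parents))
  score <- nll + kappa / 2 * log(N)
  new_fragment(child, parents, disc_parents, keys, theta0, beta, sigma,
               kappa = kappa, score = score, nll = nll)
}

#' Fit one conditional linear-Gaussian fragment
#'
#' Per joint discrete-parent state, ordinary least squares of the child on
#' the continuous parents (intercept only when there are none) with the
#' maximum-likelihood residual SD (division by the per-state n).  Every
#' joint state must be observed at least twice.  The fragment's score is
#' the BIC energy `S = -log L_max + kappa/2 * log N`, where `kappa` counts
#' one intercept, one coefficient per continuous parent and one residual
#' SD per state; lower scores are more likely.
#'
#' @param cohort an `rv_cohort` with complete data on the used variables.
#' @param child child variable name (must not be a SNP).
#' @param parents parent variable names (possibly empty: the root
#'   fragment).
#' @return A fitted `rv_fragment`.
#' @export
fit_fragment <- function(cohort, child, parents = character()) {
  v <- cohort_variables(cohort)
  if (!child %in% v$name) abort(sprintf("unknown child `%s`", child))
  if (v$role[v$name == child] == "snp") abort("SNPs cannot be children")
  missing <- setdiff(parents, v$name)
  if (length(missing)) abort(sprintf("unknown parent `%s`", missing[1]))
  if (child %in% parents) abort("child cannot be its own parent")
  dat <- as_tibble(cohort)[c(child, parents)]
  if (anyNA(dat)) abort("fragment fitting assumes complete data")
  N <- nrow(dat)
  if (N < 2) abort("need at least 2 subjects")
  domain <- setNames(v$domain, v$name)
  disc <- parents[domain[parents] == "discrete"]
  cont <- setdiff(parents, disc)
  y <- dat[[child]]
  Xc <- if (length(cont)) as.matrix(dat[cont]) else NULL
  g <- if (length(disc)) {
    apply(as.matrix(dat[disc]), 1, state_key_of)
  } else NULL
  fit_frag_core(child, parents, disc, y, Xc, g, N)
}

#' Evaluate a fragment's BIC score on a cohort
#'
#' Negative log-likelihood of the cohort's data under the fragment's
#' stored parameters plus the `kappa/2 * log N` complexity penalty.  For a
#' fragment fitted on the same cohort this equals its stored score.
#'
#' @param fragment a `rv_fragment`.
#' @param cohort an `rv_cohort`.
#' @return The scalar score.
#' @export
score_fragment <- function(fragment, cohort) {
  dat <- as_tibble(cohort)[c(fragment$child, fragment$parents)]
  if (anyNA(dat)) abort("fragment scoring assumes complete data")
  N <- nrow(dat)
  if (N < 2) abort("need at least 2 subjects")
  y <- dat[[fragment$child]]
  if (length(fragment$disc_parents)) {
    g <- apply(as.matrix(dat[fragment$disc_parents]), 1, state_key_of)
    row <- match(g, fragment$state_keys)
    if (anyNA(row)) abort("unseen state")
  } else {
    row <- rep(1L, N)
  }
  mu <- fragment$theta0[row]
  if (length(fragment$cont_parents)) {
    Xc <- as.matrix(dat[fragment$cont_parents])
    mu <- mu + rowSums(Xc * fragment$beta[row, , drop = FALSE])
  }
  s <- fragment$sigma[row]
  nll <- sum(log(s * sqrt(2 * pi)) + (y - mu)^2 / (2 * s^2))
  nll + fragment$kappa / 2 * log(N)
}

#' Enumerate and retain the best-scoring fragments per child
#'
#' Fits every parent set of size 0..`max_parents` for every non-SNP child,
#' drawing parents from all SNPs and all other non-SNP variables, with
#' SNPs constrained to be causally upstream (never children) and, by
#' default, phenotypes not allowed as parents of transcripts.  Per child
#' the `fragments_per_child` lowest-scoring fragments are retained, plus
#' the parentless root fragment unconditionally.  Per-fragment fit
#' failures (unsupported states, collinearity) are skipped.
#'
#' Subjects with missing values in any modelling variable are dropped
#' first, with a message (fitting assumes complete data).
#'
#' @param cohort an `rv_cohort` on the modelling scale.
#' @param max_parents maximum parents per fragment.
#' @param fragments_per_child library size per child.
#' @param allow_phenotype_parents_of_transcripts permit phenotype ->
#'   transcript fragments.
#' @return A `rv_fragment_library`.
#' @export
build_fragments <- function(cohort, max_parents = 2, fragments_per_child = 16,
                            allow_phenotype_parents_of_transcripts = FALSE) {
  v <- cohort_variables(cohort)
  tbl <- as_tibble(cohort)
  cc <- complete.cases(tbl[v$name])
  if (!all(cc)) {
    inform(sprintf("dropping %d subject(s) with missing values", sum(!cc)))
    tbl <- tbl[cc, ]
  }
  N <- nrow(tbl)
  if (N < 2) abort("fewer than 2 complete subjects")
  domain <- setNames(v$domain, v$name)
  role <- setNames(v$role, v$name)
  children <- v$name[v$role != "snp"]
  data_mat <- as.matrix(as.data.frame(tbl[v$name[v$domain == "continuous"]]))
  disc_mat <- as.matrix(as.data.frame(tbl[v$name[v$domain == "discrete"]]))
  mode(disc_mat) <- "character"

  lib <- list()
  for (child in children) {
    eligible <- setdiff(v$name, child)
    if (role[child] == "transcript" && !allow_phenotype_parents_of_transcripts) {
      eligible <- eligible[role[eligible] != "phenotype"]
    }
    sets <- list(character())
    for (sz in seq_len(max_parents)) {
      if (length(eligible) >= sz) {
        cmb <- combn(eligible, sz, simplify = FALSE)
        sets <- c(sets, cmb)
      }
    }
    y <- tbl[[child]]
    frags <- compact(map(sets, function(ps) {
      disc <- ps[domain[ps] == "discrete"]
      cont <- setdiff(ps, disc)
      Xc <- if (length(cont)) data_mat[, cont, drop = FALSE] else NULL
      g <- if (length(disc)) {
        if (length(disc) == 1) disc_mat[, disc]
        else do.call(paste, c(lapply(disc, function(d) disc_mat[, d]),
                              sep = "|"))
      } else NULL
      tryCatch(fit_frag_core(child, ps, disc, y, Xc, g, N),
               error = function(e) NULL)
    }))
    scores <- map_dbl(frags, "score")
    ord <- order(scores)
    frags <- frags[ord]
    root_pos <- which(map_int(frags, ~ length(.x$parents)) == 0L)[1]
    keep <- seq_len(min(fragments_per_child, length(frags)))
    if (!root_pos %in% keep) keep <- c(keep, root_pos)
    lib[[child]] <- frags[sort(keep)]
  }
  structure(list(
    children = lib,
    variables = v,
    n = N,
    max_parents = as.integer(max_parents),
    fragments_per_child = as.integer(fragments_per_child)
  ), class = "rv_fragment_library")
}

#' @export
print.rv_fragment_library <- function(x, ...) {
  sizes <- map_int(x$children, length)
  cat(sprintf(
    "# Fragment library: %d children, %d fragments (N = %d, max_parents = %d)\n",
    length(x$children), sum(sizes), x$n, x$max_parents
  ))
  invisible(x)
}

#' Tidy a fragment library into one row per fragment
#' @param x a `rv_fragment_library`.
#' @param ... unused.
#' @method tidy rv_fragment_library
#' @export
tidy.rv_fragment_library <- function(x, ...) {
  rows <- imap(x$children, function(fr_list, child) {
    tibble(
      child = child,
      parents = map_chr(fr_list, ~ paste(.x$parents, collapse = ",")),
      n_parents = map_int(fr_list, ~ length(.x$parents)),
      n_states = map_int(fr_list, ~ length(.x$state_keys)),
      kappa = map_dbl(fr_list, "kappa"),
      nll = map_dbl(fr_list, "nll"),
      score = map_dbl(fr_list, "score")
    )
  })
  list_rbind(rows)
}
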