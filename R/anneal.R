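#' Adaptive annealing temperature step
#'
#' Chooses the temperature decrement so that the score distribution at
#' `T + dT` is predicted to have overlap coefficient `overlap_target` with
#' the distribution at `T`.  Both distributions are approximated as
#' normals with the current variance; for two such normals a mean shift
#' `d` gives overlap `2 * pnorm(-|d| / (2 * sd))`, so the target shift is
#' `d = 2 * qnorm(1 - overlap/2) * sd`.  The mean's sensitivity
#' `d<S>/dT` is taken from finite differences across stages, or, for the
#' first stage, from the fluctuation-dissipation identity `Var(S) / T^2`.
#' Zero variance falls back to geometric cooling by 0.9.  The step never
#' overshoots below `T = 1`.
#'
#' @param scores equilibrated score samples at the current temperature.
#' @param temperature current temperature (> 1).
#' @param overlap_target desired overlap coefficient in (0, 1].
#' @param dmean_dt finite-difference estimate of `d<S>/dT`, or `NULL` to
#'   use `var(scores) / temperature^2`.
#' @return The (non-positive) temperature change `dT`.
#' @export
adapt_temperature <- function(scores, temperature, overlap_target = 0.8,
                              dmean_dt = NULL) {
  if (temperature <= 1) return(0)
  if (overlap_target >= 1) return(0)
  v <- var(scores)
  if (!is.finite(v) || v <= 0) {
    return(max(1, 0.9 * temperature) - temperature)
  }
  s <- sqrt(v)
  shift <- 2 * qnorm(1 - overlap_target / 2) * s
  if (is.null(dmean_dt) || !is.finite(dmean_dt) || dmean_dt <= 0) {
    dmean_dt <- v / temperature^2
  }
  dt <- -shift / dmean_dt
  max(1 - temperature, dt)
}

## overlap coefficient of two normal densities (used for reporting)
normal_overlap <- function(m1, s1, m2, s2) {
  f <- function(x) pmin(stats::dnorm(x, m1, s1), stats::dnorm(x, m2, s2))
  stats::integrate(f, min(m1, m2) - 8 * max(s1, s2),
                   max(m1, m2) + 8 * max(s1, s2))$value
}

## probe upward from T = 2 until the acceptance rate is >= 90%
initial_temperature <- function(model, library, n_probe = 60) {
  temp <- 2
  repeat {
    acc <- 0L
    m <- model
    for (i in seq_len(n_probe)) {
      m <- metropolis_step(m, library, temp)
      acc <- acc + attr(m, "accepted")
    }
    if (acc / n_probe >= 0.9 || temp > 1e6) return(temp)
    temp <- temp * 2
  }
}

run_stage <- function(model, library, temperature, n_steps) {
  scores <- numeric(n_steps)
  acc <- 0L
  for (i in seq_len(n_steps)) {
    model <- metropolis_step(model, library, temperature)
    acc <- acc + attr(model, "accepted")
    scores[i] <- model$score
  }
  list(model = model, scores = scores, acc_rate = acc / n_steps)
}

anneal_chain <- function(library, quota, overlap_target, steps_per_stage,
                         burn_in_factor, thin, max_stages) {
  n_child <- length(library$children)
  model <- new_network_model(library)
  temp <- initial_temperature(model, library)
  schedule <- list()
  mean_prev <- NA_real_
  temp_prev <- NA_real_
  stage <- 0L
  repeat {
    stage <- stage + 1L
    st <- run_stage(model, library, temp, steps_per_stage)
    model <- st$model
    eq <- st$scores[(length(st$scores) %/% 2 + 1):length(st$scores)]
    m_eq <- mean(eq); v_eq <- var(eq)
    schedule[[stage]] <- tibble(
      stage = stage, temperature = temp, mean_score = m_eq,
      var_score = v_eq, steps = steps_per_stage, acc_rate = st$acc_rate
    )
    if (temp <= 1 || stage >= max_stages) break
    dmdt <- if (is.na(mean_prev)) NULL else {
      (m_eq - mean_prev) / (temp - temp_prev)
    }
    dt <- adapt_temperature(eq, temp, overlap_target, dmdt)
    mean_prev <- m_eq; temp_prev <- temp
    temp <- max(1, temp + dt)
    ## numerical guard: force progress when the suggested step is tiny
    if (temp_prev - temp < 1e-9 * temp_prev) temp <- max(1, 0.95 * temp_prev)
  }
  final <- schedule[[length(schedule)]]
  if (final$acc_rate < 0.001) {
    warn("acceptance rate below 0.1% at T = 1; chain may not have converged")
  }
  ## burn-in at T = 1: wait for burn_in_factor * n_child accepted moves
  target_acc <- burn_in_factor * n_child
  acc <- 0L; steps <- 0L
  while (acc < target_acc && steps < 200L * n_child) {
    model <- metropolis_step(model, library, 1)
    acc <- acc + attr(model, "accepted")
    steps <- steps + 1L
  }
  members <- vector("list", quota)
  for (k in seq_len(quota)) {
    for (i in seq_len(thin)) model <- metropolis_step(model, library, 1)
    members[[k]] <- list(assignment = model$assignment, score = model$score)
  }
  list(members = members, schedule = list_rbind(schedule))
}

#' Sample an ensemble of network structures
#'
#' Runs `n_chains` independent Metropolis chains from root-only initial
#' models under the adaptive annealing schedule, stops cooling at `T = 1`
#' (where sampling corresponds to the structure posterior), burns in, and
#' records thinned models round-robin across chains until `ensemble_size`
#' members are collected.  Every recorded member is verified acyclic.
#'
#' @param library a `rv_fragment_library`.
#' @param ensemble_size number of members to collect (default 1024).
#' @param n_chains number of independent chains.
#' @param overlap_target annealing overlap coefficient target.
#' @param seed integer seed for reproducibility, or `NULL`.
#' @param steps_per_stage Metropolis steps per annealing stage; default
#'   `30 *` number of children.
#' @param burn_in_factor accepted moves per child required before
#'   recording at T = 1.
#' @param max_stages safety cap on annealing stages.
#' @return A `rv_ensemble`: members (assignments + scores), the library,
#'   the per-chain schedules, seed and per-edge frequency table.
#' @export
sample_ensemble <- function(library, ensemble_size = 1024, n_chains = 2,
                            overlap_target = 0.8, seed = NULL,
                            steps_per_stage = NULL, burn_in_factor = 10,
                            max_stages = 200) {
  n_child <- length(library$children)
  if (n_child == 0) abort("empty fragment library")
  steps_per_stage <- steps_per_stage %||% (30L * n_child)
  thin <- n_child
  quotas <- rep(ensemble_size %/% n_chains, n_chains)
  extra <- ensemble_size %% n_chains
  if (extra > 0) quotas[seq_len(extra)] <- quotas[seq_len(extra)] + 1L
  chain_seeds <- if (!is.null(seed)) {
    set.seed(seed)
    sample.int(.Machine$integer.max %/% 2, n_chains)
  } else NULL
  chains <- map(seq_len(n_chains), function(ci) {
    if (!is.null(chain_seeds)) set.seed(chain_seeds[ci])
    anneal_chain(library, quotas[ci], overlap_target, steps_per_stage,
                 burn_in_factor, thin, max_stages)
  })
  ## round-robin interleave so early members mix chains
  members <- vector("list", ensemble_size)
  idx <- 1L
  for (k in seq_len(max(quotas))) {
    for (ci in seq_len(n_chains)) {
      if (k <= quotas[ci]) {
        members[[idx]] <- c(chains[[ci]]$members[[k]], list(chain = ci))
        idx <- idx + 1L
      }
    }
  }
  ens <- structure(list(
    members = members,
    library = library,
    n_chains = n_chains,
    overlap_target = overlap_target,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    schedules = map(chains, "schedule")
  ), class = "rv_ensemble")
  ## invariant: every member acyclic, score = sum of fragment scores
  for (m in members) {
    mod <- structure(list(assignment = m$assignment, score = m$score),
                     class = "rv_network_model")
    if (!model_is_acyclic(mod, library)) {
      abort("internal error: sampled member contains a cycle")
    }
  }
  ens
}

#' @export
print.rv_ensemble <- function(x, ...) {
  sc <- map_dbl(x$members, "score")
  cat(sprintf(
    "# Network ensemble: %d members, %d chains, score %.2f +/- %.2f\n",
    length(x$members), x$n_chains, mean(sc), sd(sc)
  ))
  invisible(x)
}

#' Compare replicate ensembles for convergence
#'
#' Given two or more ensembles sampled from the same library and
#' configuration with different seeds, reports the per-edge frequency
#' differences, a Kolmogorov-Smirnov distance between total-score
#' distributions, and a pass/fail flag (maximum per-edge frequency
#' difference below `tol`).
#'
#' @param ensembles list of `rv_ensemble` objects (>= 2).
#' @param tol maximum tolerated per-edge frequency difference.
#' @return List with `edge_diff` (tibble), `max_freq_diff`, `score_ks`,
#'   and `pass`.
#' @export
convergence_check <- function(ensembles, tol = 0.1) {
  if (length(ensembles) < 2) abort("need at least 2 replicate ensembles")
  sizes <- map_int(ensembles, ~ length(.x$members))
  kids <- map(ensembles, ~ names(.x$library$children))
  if (length(unique(sizes)) != 1 ||
      !all(map_lgl(kids[-1], ~ identical(.x, kids[[1]])))) {
    abort("replicate ensembles were not built from identical configurations")
  }
  freqs <- map(ensembles, edge_frequencies)
  all_edges <- distinct(list_rbind(map(freqs, ~ .x[c("from", "to")])))
  fmat <- map(freqs, function(f) {
    key <- paste(f$from, f$to, sep = "->")
    setNames(f$freq, key)
  })
  key_all <- paste(all_edges$from, all_edges$to, sep = "->")
  mat <- vapply(fmat, function(f) {
    out <- f[key_all]
    out[is.na(out)] <- 0
    unname(out)
  }, numeric(length(key_all)))
  mat <- matrix(mat, nrow = length(key_all))
  diff <- apply(mat, 1, function(x) max(x) - min(x))
  edge_diff <- dplyr::bind_cols(all_edges, tibble(max_diff = diff))
  scores <- map(ensembles, ~ map_dbl(.x$members, "score"))
  ks <- suppressWarnings(ks.test(scores[[1]], scores[[2]])$statistic)
  list(
    edge_diff = arrange(edge_diff, desc(.data$max_diff)),
    max_freq_diff = if (length(diff)) max(diff) else 0,
    score_ks = unname(ks),
    pass = (if (length(diff)) max(diff) else 0) < tol
  )
}
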