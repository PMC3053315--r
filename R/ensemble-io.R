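ENSEMBLE_FORMAT_VERSION <- "ravnet-ensemble-1"

#' Per-edge frequencies across an ensemble
#'
#' @param ensemble a `rv_ensemble`.
#' @return Tibble with columns `from`, `to`, `n` (members containing the
#'   edge) and `freq` (fraction of members).
#' @export
edge_frequencies <- function(ensemble) {
  K <- length(ensemble$members)
  lib <- ensemble$library
  rows <- map(ensemble$members, function(m) {
    mod <- structure(list(assignment = m$assignment, score = m$score),
                     class = "rv_network_model")
    model_edges(mod, lib)
  })
  edges <- list_rbind(rows)
  if (nrow(edges) == 0) {
    return(tibble(from = character(), to = character(),
                  n = integer(), freq = numeric()))
  }
  edges |>
    count(.data$from, .data$to, name = "n") |>
    mutate(freq = .data$n / K) |>
    arrange(desc(.data$freq), .data$from, .data$to)
}

#' Consensus topology at a frequency threshold
#'
#' Directed edges whose ensemble frequency is at least `threshold`.
#'
#' @param ensemble a `rv_ensemble`.
#' @param threshold minimum edge frequency in (0, 1].
#' @return Tibble of consensus edges with frequencies.
#' @export
consensus_edges <- function(ensemble, threshold = 0.025) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  filter(edge_frequencies(ensemble), .data$freq >= threshold)
}

#' Export the consensus graph
#'
#' Writes the thresholded consensus topology as GraphML or DOT, each edge
#' annotated with its ensemble frequency.
#'
#' @param ensemble a `rv_ensemble`.
#' @param path output file; extension `.dot`/`.gv` selects DOT unless
#'   `format` is given.
#' @param threshold minimum edge frequency in (0, 1].
#' @param format `"graphml"` or `"dot"`.
#' @return Invisibly, the consensus edge tibble.
#' @export
export_consensus <- function(ensemble, path, threshold = 0.025,
                             format = NULL) {
  edges <- consensus_edges(ensemble, threshold)
  format <- format %||%
    (if (grepl("\\.(dot|gv)$", path)) "dot" else "graphml")
  format <- match.arg(format, c("graphml", "dot"))
  nodes <- union(edges$from, edges$to)
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges[c("from", "to", "freq")]),
    directed = TRUE,
    vertices = if (length(nodes)) data.frame(name = nodes) else NULL
  )
  igraph::write_graph(g, path, format = format)
  invisible(edges)
}

fragment_to_list <- function(f) {
  list(
    child = f$child,
    parents = as.list(f$parents),
    disc_parents = as.list(f$disc_parents),
    state_keys = as.list(f$state_keys),
    theta0 = f$theta0,
    beta = if (ncol(f$beta)) unname(as.list(as.data.frame(t(f$beta)))) else list(),
    sigma = f$sigma,
    kappa = f$kappa,
    score = f$score,
    nll = f$nll
  )
}

fragment_from_list <- function(l) {
  parents <- as.character(unlist(l$parents))
  disc <- as.character(unlist(l$disc_parents))
  cont <- setdiff(parents, disc)
  n_states <- length(l$state_keys)
  beta <- if (length(cont)) {
    do.call(rbind, map(l$beta, ~ as.numeric(unlist(.x))))
  } else {
    matrix(0, n_states, 0)
  }
  new_fragment(
    child = l$child, parents = parents, disc_parents = disc,
    state_keys = as.character(unlist(l$state_keys)),
    theta0 = as.numeric(l$theta0), beta = beta,
    sigma = as.numeric(l$sigma),
    kappa = as.numeric(l$kappa), score = as.numeric(l$score),
    nll = as.numeric(l$nll)
  )
}

#' Serialize an ensemble to versioned JSON
#'
#' Lossless round-trip: structures, parameters, scores, seed and schedule
#' metadata are preserved at full floating-point precision.
#' [read_ensemble()] refuses files with a different format version.
#'
#' @param ensemble a non-empty `rv_ensemble`.
#' @param path output `.json` path.
#' @return Invisibly, `path`.
#' @export
write_ensemble <- function(ensemble, path) {
  if (length(ensemble$members) == 0) abort("refusing to write an empty ensemble")
  lib <- ensemble$library
  payload <- list(
    version = ENSEMBLE_FORMAT_VERSION,
    n_chains = ensemble$n_chains,
    overlap_target = ensemble$overlap_target,
    seed = ensemble$seed,
    library = list(
      n = lib$n,
      max_parents = lib$max_parents,
      fragments_per_child = lib$fragments_per_child,
      variables = as.list(lib$variables),
      children = map(lib$children, ~ map(.x, fragment_to_list))
    ),
    schedules = map(ensemble$schedules, ~ as.list(.x)),
    members = map(ensemble$members, function(m) {
      list(assignment = as.list(m$assignment), score = m$score,
           chain = m$chain %||% 1L)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE,
                       digits = I(17), null = "null", na = "null")
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  payload <- jsonlite::read_json(path)
  if (!identical(payload$version, ENSEMBLE_FORMAT_VERSION)) {
    abort(sprintf("ensemble file version mismatch: found '%s', expected '%s'",
                  payload$version %||% "<none>", ENSEMBLE_FORMAT_VERSION))
  }
  lib_l <- payload$library
  variables <- as_tibble(map(lib_l$variables, ~ unlist(map(.x, ~ .x %||% NA))))
  variables$m <- as.numeric(variables$m)
  variables$on_model_scale <- as.logical(variables$on_model_scale)
  library <- structure(list(
    children = map(lib_l$children, ~ map(.x, fragment_from_list)),
    variables = variables,
    n = as.integer(lib_l$n),
    max_parents = as.integer(lib_l$max_parents),
    fragments_per_child = as.integer(lib_l$fragments_per_child)
  ), class = "rv_fragment_library")
  members <- map(payload$members, function(m) {
    list(
      assignment = setNames(as.integer(unlist(m$assignment)),
                            names(m$assignment)),
      score = as.numeric(m$score),
      chain = as.integer(m$chain)
    )
  })
  schedules <- map(payload$schedules, function(s) {
    as_tibble(map(s, ~ as.numeric(unlist(.x))))
  })
  structure(list(
    members = members,
    library = library,
    n_chains = as.integer(payload$n_chains),
    overlap_target = as.numeric(payload$overlap_target),
    seed = if (is.null(payload$seed)) NULL else as.integer(payload$seed),
    schedules = schedules
  ), class = "rv_ensemble")
}
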