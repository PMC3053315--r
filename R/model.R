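#' Root-only network model
#'
#' A network model assigns exactly one fragment from the library to every
#' non-SNP child; the implied directed graph must be acyclic and SNPs have
#' no incoming edges (they are never children).  The total score is the
#' sum of the assigned fragment scores.  The starting model assigns every
#' child its parentless root fragment (the empty graph).
#'
#' @param library a `rv_fragment_library`.
#' @return A `rv_network_model`.
#' @export
new_network_model <- function(library) {
  assignment <- map_int(library$children, function(frs) {
    i <- which(map_int(frs, ~ length(.x$parents)) == 0L)[1]
    if (is.na(i)) abort("library lacks a root fragment for some child")
    i
  })
  score <- sum(map_dbl(names(assignment), function(ch) {
    library$children[[ch]][[assignment[[ch]]]]$score
  }))
  structure(list(assignment = assignment, score = score),
            class = "rv_network_model")
}

#' @export
print.rv_network_model <- function(x, ...) {
  cat(sprintf("<network model> %d children, score %.4f\n",
              length(x$assignment), x$score))
  invisible(x)
}

## model must carry a "library" attr or be paired with one for edges;
## internal helpers take the library explicitly.
model_fragments <- function(model, library) {
  map2(names(model$assignment), model$assignment,
       function(ch, i) library$children[[ch]][[i]])
}

#' Edge list of a network model
#' @param model a `rv_network_model`.
#' @param library the `rv_fragment_library` it indexes.
#' @return Tibble with columns `from`, `to`.
#' @export
model_edges <- function(model, library) {
  frs <- model_fragments(model, library)
  rows <- compact(map(frs, function(f) {
    if (length(f$parents) == 0) return(NULL)
    tibble(from = f$parents, to = f$child)
  }))
  if (length(rows) == 0) return(tibble(from = character(), to = character()))
  list_rbind(rows)
}

## parent map: child -> character vector of parents
model_parent_map <- function(model, library) {
  map2(names(model$assignment), model$assignment,
       function(ch, i) library$children[[ch]][[i]]$parents) |>
    setNames(names(model$assignment))
}

## would assigning `new_parents` to `child` create a directed cycle?
## cycle iff some new parent is reachable FROM child in the graph formed by
## the other children's current fragments.
creates_cycle <- function(parent_map, child, new_parents) {
  targets <- intersect(new_parents, names(parent_map))
  if (length(targets) == 0) return(FALSE)
  ## children adjacency: node -> children (derived from parent sets)
  kids <- list()
  for (ch in names(parent_map)) {
    if (ch == child) next
    for (p in parent_map[[ch]]) kids[[p]] <- c(kids[[p]], ch)
  }
  seen <- character()
  stack <- child
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (k in kids[[node]]) {
      if (k %in% targets) return(TRUE)
      if (!k %in% seen) {
        seen <- c(seen, k)
        stack <- c(stack, k)
      }
    }
  }
  FALSE
}

#' Propose a fragment-reassignment move
#'
#' Picks a uniform random child and replaces its current fragment with a
#' different uniform random fragment from that child's library list — one
#' symmetric move type covering edge addition, deletion and swap.
#' Candidates whose implied graph is cyclic are flagged invalid (they are
#' rejected by [metropolis_step()] without score evaluation).
#'
#' @param model current `rv_network_model`.
#' @param library the `rv_fragment_library`.
#' @return List with elements `model` (candidate), `valid`, `noop`,
#'   `child` and `delta` (score change; `NA` when invalid/no-op).
#' @export
propose_move <- function(model, library) {
  children <- names(model$assignment)
  child <- children[[sample.int(length(children), 1)]]
  frs <- library$children[[child]]
  if (length(frs) < 2) {
    return(list(model = model, valid = FALSE, noop = TRUE,
                child = child, delta = NA_real_))
  }
  cur <- model$assignment[[child]]
  alt <- seq_along(frs)[-cur]
  j <- alt[[sample.int(length(alt), 1)]]
  new_parents <- frs[[j]]$parents
  pm <- model_parent_map(model, library)
  if (creates_cycle(pm, child, new_parents)) {
    return(list(model = model, valid = FALSE, noop = FALSE,
                child = child, delta = NA_real_))
  }
  cand <- model
  cand$assignment[[child]] <- j
  delta <- frs[[j]]$score - frs[[cur]]$score
  cand$score <- model$score + delta
  list(model = cand, valid = TRUE, noop = FALSE, child = child,
       delta = delta)
}

#' One Metropolis step at temperature T
#'
#' Proposes a move and accepts it with probability
#' `min(1, exp(-(S' - S) / T))`; cyclic candidates and no-ops are always
#' rejected.  The proposal kernel is symmetric, so no Hastings correction
#' is needed.
#'
#' @param model current `rv_network_model`.
#' @param library the `rv_fragment_library`.
#' @param temperature annealing temperature (>= 1).
#' @return The next model, with attribute `"accepted"`.
#' @export
metropolis_step <- function(model, library, temperature = 1) {
  if (temperature < 1) abort("temperature must be >= 1")
  prop <- propose_move(model, library)
  accepted <- FALSE
  if (prop$valid) {
    if (prop$delta <= 0 || runif(1) < exp(-prop$delta / temperature)) {
      model <- prop$model
      accepted <- TRUE
    }
  }
  attr(model, "accepted") <- accepted
  model
}

## verify acyclicity of a full model (used on every recorded member)
model_is_acyclic <- function(model, library) {
  pm <- model_parent_map(model, library)
  ## Kahn's algorithm over the children subgraph
  indeg <- map_int(pm, ~ length(intersect(.x, names(pm))))
  queue <- names(indeg)[indeg == 0]
  removed <- 0L
  kids <- list()
  for (ch in names(pm)) {
    for (p in intersect(pm[[ch]], names(pm))) kids[[p]] <- c(kids[[p]], ch)
  }
  while (length(queue)) {
    node <- queue[[1]]; queue <- queue[-1]
    removed <- removed + 1L
    for (k in kids[[node]]) {
      indeg[[k]] <- indeg[[k]] - 1L
      if (indeg[[k]] == 0L) queue <- c(queue, k)
    }
  }
  removed == length(pm)
}
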