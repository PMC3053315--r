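#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ensemble into its edge-frequency table
#' @param x a `rv_ensemble`.
#' @param ... unused.
#' @method tidy rv_ensemble
#' @export
tidy.rv_ensemble <- function(x, ...) edge_frequencies(x)

#' One-row ensemble summary
#' @param x a `rv_ensemble`.
#' @param ... unused.
#' @method glance rv_ensemble
#' @export
glance.rv_ensemble <- function(x, ...) {
  sc <- map_dbl(x$members, "score")
  ef <- edge_frequencies(x)
  tibble(
    n_members = length(x$members),
    n_chains = x$n_chains,
    mean_score = mean(sc),
    sd_score = sd(sc),
    min_score = min(sc),
    n_distinct_edges = nrow(ef),
    seed = x$seed %||% NA_integer_
  )
}

#' @rdname tidy.rv_ensemble
#' @method tidy rv_trial
#' @export
tidy.rv_trial <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "baseline_medians") <- NULL
  attr(out, "perturbed_medians") <- NULL
  out
}

#' One-row trial summary: gene counts per category
#' @param x a `rv_trial`.
#' @param ... unused.
#' @method glance rv_trial
#' @export
glance.rv_trial <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_significant = sum(x$significant),
    n_das28_significant = sum(x$p_DAS28 < (attr(x, "alpha") %||% 0.05)),
    n_category_3 = sum(x$category == "3"),
    fold = attr(x, "fold") %||% NA_real_,
    n_replicates = attr(x, "n_replicates") %||% NA_integer_
  )
}

#' Plot ensemble edge frequencies
#'
#' Dot plot of the most frequent directed edges with the consensus
#' threshold marked.
#'
#' @param object a `rv_ensemble`.
#' @param threshold consensus threshold to draw.
#' @param top_n number of edges to show.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot rv_ensemble
#' @export
autoplot.rv_ensemble <- function(object, threshold = 0.025, top_n = 30, ...) {
  ef <- head(edge_frequencies(object), top_n)
  ef$edge <- paste(ef$from, "→", ef$to)
  ggplot2::ggplot(ef, ggplot2::aes(
    x = .data$freq, y = stats::reorder(.data$edge, .data$freq)
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "ensemble edge frequency", y = NULL,
                  title = "Consensus topology support") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of virtual-trial results
#'
#' Mean predicted DAS28 shift against the DAS28 p-value per gene,
#' coloured by trial category.
#'
#' @param object a `rv_trial`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot rv_trial
#' @export
autoplot.rv_trial <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$das28_shift, y = -log10(pmax(.data$p_DAS28, 1e-300)),
    colour = .data$category
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(
      x = "mean predicted DAS28 shift (knockdown - baseline)",
      y = expression(-log[10] ~ "p (DAS28)"),
      colour = "category",
      title = "Virtual clinical trial"
    ) +
    ggplot2::theme_minimal()
}
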