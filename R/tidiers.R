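#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an alignment result
#'
#' @param x a `netq_alignment`.
#' @param ... unused.
#' @return the node mapping as a tibble (`query`, `target`, `evalue`,
#'   `bits_norm`).
#' @method tidy netq_alignment
#' @export
tidy.netq_alignment <- function(x, ...) x$mapping

#' One-row summary of an alignment result
#'
#' @param x a `netq_alignment`.
#' @param ... unused.
#' @return a one-row tibble with counts, scores, bound and gap.
#' @method glance netq_alignment
#' @export
glance.netq_alignment <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    e_max = x$e_max,
    n_mapped = nrow(x$mapping),
    n_conserved = x$n_conserved,
    edge_correctness = x$edge_correctness,
    sum_bits = x$sum_bits,
    total_score = x$total_score,
    score = x$score,
    upper_bound = x$upper_bound,
    gap = x$gap,
    optimal = x$optimal,
    status = x$solver_status
  )
}

#' Tidy a pipeline report
#'
#' @param x a `netq_report`.
#' @param ... unused.
#' @return the per-cutoff overview table (see [run_summary()]).
#' @method tidy netq_report
#' @export
tidy.netq_report <- function(x, ...) run_summary(x)

#' One-row summary of a pipeline report
#'
#' @param x a `netq_report`.
#' @param ... unused.
#' @return a one-row tibble with the settings and the best run's scores.
#' @method glance netq_report
#' @export
glance.netq_report <- function(x, ...) {
  s <- run_summary(x)
  best <- which.max(s$total_score)
  tibble::tibble(
    mode = x$settings$mode,
    c_min = x$settings$c_min,
    n_cutoffs = length(x$runs),
    best_e_max = s$e_max[best],
    best_total_score = s$total_score[best],
    best_edge_correctness = s$edge_correctness[best],
    all_optimal = all(s$optimal)
  )
}

#' Plot the score ladder of a pipeline report
#'
#' Edge correctness and total score against the E-value cutoff ladder.
#'
#' @param object a `netq_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot netq_report
#' @export
autoplot.netq_report <- function(object, ...) {
  s <- run_summary(object)
  s$cutoff <- factor(format(s$e_max, scientific = TRUE),
    levels = format(s$e_max, scientific = TRUE)
  )
  long <- tidyr::pivot_longer(
    s[, c("cutoff", "edge_correctness", "total_score")],
    cols = c("edge_correctness", "total_score"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$cutoff, y = .data$value,
    group = .data$metric, colour = .data$metric
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(E[max] ~ cutoff), y = "score",
      title = "Alignment score across the E-value cutoff ladder"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an alignment as the query/target union graph
#'
#' The union graph on query identifiers: conserved edges (`both`),
#' query-only edges and matched target-only edges (the predicted
#' interactions), with aligned nodes filled.
#'
#' @param object a `netq_alignment`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot netq_alignment
#' @export
autoplot.netq_alignment <- function(object, ...) {
  u <- union_graph(object)
  g <- igraph::graph_from_data_frame(
    u$edges[, c("from", "to")],
    directed = FALSE, vertices = u$nodes$id
  )
  xy <- with_local_seed(42, igraph::layout_with_fr(g)) # fixed layout
  nodes <- tibble::tibble(
    id = u$nodes$id, origin = u$nodes$origin,
    x = xy[, 1], y = xy[, 2]
  )
  pos <- stats::setNames(seq_len(nrow(nodes)), nodes$id)
  edges <- dplyr::mutate(u$edges,
    x = nodes$x[pos[.data$from]], y = nodes$y[pos[.data$from]],
    xend = nodes$x[pos[.data$to]], yend = nodes$y[pos[.data$to]]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
        colour = .data$origin
      )
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$origin),
      size = 3
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$id),
      vjust = -1, size = 3
    ) +
    ggplot2::scale_colour_manual(
      values = c(both = "#444444", query = "#d62728", target = "#1f77b4")
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "edge origin", shape = "node")
}
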