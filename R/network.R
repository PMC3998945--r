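#' Construct a PPI network
#'
#' A `ppi_network` is an undirected simple graph of proteins: a node table
#' (`id`, optional `description`) and an edge table (`from`, `to`,
#' `confidence`). Edges are stored canonically with `from < to`
#' (lexicographic), self-loops are dropped with a warning, duplicate edges
#' are merged keeping the maximum confidence, and all confidences must lie
#' in \[0, 1\]. Edges supplied without a confidence default to 1.
#'
#' @param edges data frame with columns `from`, `to` and optionally
#'   `confidence`.
#' @param nodes optional data frame with columns `id` and optionally
#'   `description`; nodes appearing only here become isolated nodes.
#' @return An object of class `ppi_network`: a list with tibbles `nodes`
#'   and `edges`.
#' @examples
#' net <- ppi_network(data.frame(from = c("A", "B"), to = c("B", "C"),
#'                               confidence = c(0.9, 0.4)))
#' net
#' @export
ppi_network <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to") %in% names(edges)))
  if (!"confidence" %in% names(edges)) edges$confidence <- 1
  edges$confidence[is.na(edges$confidence)] <- 1
  edges <- dplyr::mutate(edges,
    from = as.character(.data$from),
    to = as.character(.data$to),
    confidence = as.numeric(.data$confidence)
  )
  if (any(edges$confidence < 0 | edges$confidence > 1)) {
    stop("edge confidences must lie in [0, 1]", call. = FALSE)
  }
  loops <- edges$from == edges$to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical unordered representation, then merge duplicates on max confidence
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  if (nrow(edges)) {
    edges <- edges |>
      dplyr::group_by(.data$from, .data$to) |>
      dplyr::summarise(confidence = max(.data$confidence), .groups = "drop") |>
      dplyr::arrange(.data$from, .data$to)
  } else {
    edges <- empty_edges()
  }

  ids <- union(edges$from, edges$to)
  if (is.null(nodes)) {
    nodes <- tibble::tibble(id = ids, description = NA_character_)
  } else {
    nodes <- tibble::as_tibble(nodes)
    stopifnot("id" %in% names(nodes))
    if (!"description" %in% names(nodes)) nodes$description <- NA_character_
    nodes <- dplyr::distinct(
      dplyr::select(nodes, "id", "description"),
      .data$id, .keep_all = TRUE
    )
    missing <- setdiff(ids, nodes$id)
    if (length(missing)) {
      nodes <- dplyr::bind_rows(
        nodes, tibble::tibble(id = missing, description = NA_character_)
      )
    }
  }
  nodes <- dplyr::arrange(
    dplyr::mutate(nodes, id = as.character(.data$id)), .data$id
  )
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("<ppi_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n",
    sep = ""
  )
  print(x$edges, n = 5)
  invisible(x)
}

#' Number of nodes / edges of a network
#'
#' @param net a [ppi_network()].
#' @return integer count.
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Filter network edges by confidence
#'
#' Keeps exactly the edges whose confidence is strictly above `c_min`
#' ("above a threshold" is read strictly, so `c_min = 0` keeps every edge
#' of positive confidence). Isolated nodes are retained; the input is not
#' modified.
#'
#' @param net a [ppi_network()].
#' @param c_min confidence threshold in \[0, 1\].
#' @return a filtered `ppi_network` over the same node set.
#' @examples
#' net <- ppi_network(data.frame(from = c("A", "B"), to = c("B", "C"),
#'                               confidence = c(0.1, 0.5)))
#' n_edges(filter_confidence(net, 0.1)) # 1
#' @export
filter_confidence <- function(net, c_min) {
  stopifnot(inherits(net, "ppi_network"))
  if (!is.numeric(c_min) || length(c_min) != 1 || is.na(c_min) ||
    c_min < 0 || c_min > 1) {
    stop("c_min must be a single value in [0, 1]", call. = FALSE)
  }
  edges <- net$edges[net$edges$confidence > c_min, , drop = FALSE]
  structure(list(nodes = net$nodes, edges = edges), class = "ppi_network")
}

# unordered edge key, canonical orientation assumed (from < to)
edge_key <- function(from, to) paste(from, to, sep = "\r")

# adjacency test helper: returns a function(u, v) -> TRUE/FALSE on the
# canonicalised pair
adjacency_fun <- function(net) {
  keys <- edge_key(net$edges$from, net$edges$to)
  env <- new.env(parent = emptyenv(), size = max(1L, length(keys)))
  for (k in keys) assign(k, TRUE, envir = env)
  function(u, v) {
    if (u > v) {
      tmp <- u
      u <- v
      v <- tmp
    }
    exists(edge_key(u, v), envir = env, inherits = FALSE)
  }
}
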