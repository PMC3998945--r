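#' @importFrom rlang .data
NULL

# coefficient making the sequence term strictly subordinate to one
# conserved edge: 1 / ((1 + min(|E1|, |E2|)) * min(|V1|, |V2|))
sequence_coefficient <- function(query, target) {
  1 / ((1 + min(n_edges(query), n_edges(target))) *
    min(n_nodes(query), n_nodes(target)))
}

as_mapping <- function(mapping) {
  mapping <- tibble::as_tibble(mapping)
  stopifnot(all(c("query", "target") %in% names(mapping)))
  if (anyDuplicated(mapping$query) || anyDuplicated(mapping$target)) {
    stop("mapping is not injective", call. = FALSE)
  }
  mapping
}

# conserved query edges under the mapping, with their target images
conserved_edges_tbl <- function(mapping, query, target) {
  mapping <- as_mapping(mapping)
  qe <- query$edges
  if (!nrow(qe) || !nrow(mapping)) {
    return(tibble::tibble(
      from = character(), to = character(),
      target_from = character(), target_to = character(),
      query_confidence = numeric(), target_confidence = numeric()
    ))
  }
  img <- stats::setNames(mapping$target, mapping$query)
  fi <- unname(img[qe$from])
  ti <- unname(img[qe$to])
  adj2 <- adjacency_fun(target)
  keep <- vapply(seq_len(nrow(qe)), function(i) {
    !is.na(fi[i]) && !is.na(ti[i]) && adj2(fi[i], ti[i])
  }, logical(1))
  tconf <- stats::setNames(target$edges$confidence,
    edge_key(target$edges$from, target$edges$to))
  out <- qe[keep, , drop = FALSE]
  tibble::tibble(
    from = out$from, to = out$to,
    target_from = pmin(fi[keep], ti[keep]),
    target_to = pmax(fi[keep], ti[keep]),
    query_confidence = out$confidence,
    target_confidence = unname(tconf[edge_key(
      pmin(fi[keep], ti[keep]), pmax(fi[keep], ti[keep])
    )])
  )
}

#' Edge-conservation indicator for one query edge
#'
#' Returns 1 if both endpoints of the query edge `u`--`v` are mapped and
#' their images form an edge of the (confidence-filtered) target network,
#' and 0 otherwise.
#'
#' @param mapping tibble with columns `query`, `target`: a partial
#'   injective map.
#' @param u,v endpoints of a query edge.
#' @param query,target the two [ppi_network()]s.
#' @return 0 or 1.
#' @export
conservation_indicator <- function(mapping, u, v, query, target) {
  if (!adjacency_fun(query)(u, v)) {
    stop(u, "--", v, " is not a query edge", call. = FALSE)
  }
  mapping <- as_mapping(mapping)
  img <- stats::setNames(mapping$target, mapping$query)
  au <- img[u]
  av <- img[v]
  if (is.na(au) || is.na(av)) {
    return(0)
  }
  as.numeric(adjacency_fun(target)(unname(au), unname(av)))
}

#' Edge correctness of an alignment
#'
#' The fraction of edges of the smaller network that are conserved: the
#' number of query edges whose endpoint images form a target edge,
#' divided by `min(|E1|, |E2|)`. Both networks are taken as given, i.e.
#' already confidence-filtered.
#'
#' @inheritParams conservation_indicator
#' @return a number in \[0, 1\].
#' @export
edge_correctness <- function(mapping, query, target) {
  denom <- min(n_edges(query), n_edges(target))
  if (denom == 0) {
    stop("edge correctness undefined: a network has no edges", call. = FALSE)
  }
  nrow(conserved_edges_tbl(mapping, query, target)) / denom
}

#' Total alignment score
#'
#' Edge correctness plus the strictly subordinate sequence term:
#' `t(a) + sum(b(u, a(u))) / ((1 + min(|E1|, |E2|)) * min(|V1|, |V2|))`.
#' Because normalized bit scores sum to at most `min(|V1|, |V2|)`, the
#' sequence term is always smaller than the value of one conserved edge,
#' so maximizing the total score is equivalent to maximizing edge
#' correctness first and total bit score second.
#'
#' @inheritParams conservation_indicator
#' @param cand a `candidate_set` from [build_candidates()]; every mapped
#'   pair must be an allowed candidate (this supplies its `bits_norm`).
#' @return the total score.
#' @export
total_score <- function(mapping, query, target, cand) {
  mapping <- as_mapping(mapping)
  if (nrow(mapping)) {
    b <- dplyr::left_join(mapping, cand$pairs, by = c("query", "target"))
    if (anyNA(b$bits_norm)) {
      miss <- b[is.na(b$bits_norm), ]
      stop("mapped pair not in candidate set: ",
        miss$query[1], " -> ", miss$target[1],
        call. = FALSE
      )
    }
    bsum <- sum(b$bits_norm)
  } else {
    bsum <- 0
  }
  edge_correctness(mapping, query, target) +
    sequence_coefficient(query, target) * bsum
}
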