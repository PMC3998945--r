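# run expr with a local RNG state seeded from `seed`
with_local_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a planted-alignment test instance
#'
#' Builds a correlated network pair with known ground truth: the query
#' is an Erdős–Rényi-style random simple graph; the target embeds a copy
#' of the query under a hidden injective map (`truth`) with each
#' embedded edge independently deleted with probability `p_rewire`,
#' plus background nodes and edges (never between two embedded images,
#' so the image subgraph differs from the query by exactly the deleted
#' edges). The similarity table gives every true pair a top bit score
#' (100, perturbed with standard deviation `sigma * 100`) and
#' `k_decoys` random decoy pairs per query node a lower score
#' (uniform on 20–50); `n_inflated` query nodes additionally get one
#' decoy to a non-image target at 1.5 times their true-pair bit score,
#' so sequence-only alignment is pulled away from the planted mapping.
#' E-values are derived from bit scores by the fixed monotone map
#' `E = 10^(-bits / 5)`.
#'
#' @param n_query,n_target node counts, `n_query <= n_target`.
#' @param p_edge query edge probability (default 0.3).
#' @param p_rewire embedded-edge deletion probability.
#' @param k_decoys decoy candidate pairs per query node.
#' @param sigma relative bit-score noise for true pairs.
#' @param n_inflated number of query nodes given an inflated decoy.
#' @param p_background background target edge probability (default
#'   0.15).
#' @param seed integer seed; instances are fully reproducible.
#' @return a `planted_instance`: list with `query`, `target`
#'   ([ppi_network()]s), `truth` (named character vector, query id ->
#'   target id), `similarity` (tibble) and `params`.
#' @export
generate_planted <- function(n_query = 8, n_target = 20, p_edge = 0.3,
                             p_rewire = 0.1, k_decoys = 3, sigma = 0.1,
                             n_inflated = 0, p_background = 0.15,
                             seed = 1) {
  stopifnot(
    n_query >= 2, n_query <= n_target,
    p_edge >= 0, p_edge <= 1, p_rewire >= 0, p_rewire <= 1,
    p_background >= 0, p_background <= 1,
    k_decoys >= 0, sigma >= 0, n_inflated >= 0, n_inflated <= n_query
  )
  with_local_seed(seed, {
    q_ids <- sprintf("q%03d", seq_len(n_query))
    t_ids <- sprintf("t%03d", seq_len(n_target))
    qp <- utils::combn(q_ids, 2)
    keep <- stats::runif(ncol(qp)) < p_edge
    if (!any(keep)) keep[1] <- TRUE # guarantee a non-empty query
    q_edges <- tibble::tibble(
      from = qp[1, keep], to = qp[2, keep],
      confidence = stats::runif(sum(keep), 0.5, 1)
    )
    query <- ppi_network(q_edges, nodes = tibble::tibble(id = q_ids))

    truth <- stats::setNames(t_ids[sample.int(n_target, n_query)], q_ids)
    surviving <- stats::runif(nrow(q_edges)) >= p_rewire
    emb <- tibble::tibble(
      from = unname(truth[q_edges$from[surviving]]),
      to = unname(truth[q_edges$to[surviving]]),
      confidence = stats::runif(sum(surviving), 0.5, 1)
    )
    tp <- utils::combn(t_ids, 2)
    img <- tp[1, ] %in% truth & tp[2, ] %in% truth
    bg_keep <- !img & stats::runif(ncol(tp)) < p_background
    bg <- tibble::tibble(
      from = tp[1, bg_keep], to = tp[2, bg_keep],
      confidence = stats::runif(sum(bg_keep), 0.5, 1)
    )
    target <- ppi_network(dplyr::bind_rows(emb, bg),
      nodes = tibble::tibble(id = t_ids)
    )

    true_bits <- pmax(1, 100 * (1 + sigma * stats::rnorm(n_query)))
    sim <- tibble::tibble(
      query = q_ids, target = unname(truth[q_ids]), bits_raw = true_bits
    )
    if (k_decoys > 0) {
      decoys <- purrr::map_dfr(seq_len(n_query), function(i) {
        pool <- setdiff(t_ids, truth[q_ids[i]])
        picks <- sample(pool, min(k_decoys, length(pool)))
        tibble::tibble(
          query = q_ids[i], target = picks,
          bits_raw = stats::runif(length(picks), 20, 50)
        )
      })
      sim <- dplyr::bind_rows(sim, decoys)
    }
    if (n_inflated > 0) {
      images <- unname(truth)
      for (i in seq_len(n_inflated)) {
        pool <- setdiff(t_ids, c(images, truth[q_ids[i]]))
        v <- sample(pool, 1)
        sim <- dplyr::bind_rows(
          sim[!(sim$query == q_ids[i] & sim$target == v), ],
          tibble::tibble(
            query = q_ids[i], target = v, bits_raw = 1.5 * true_bits[i]
          )
        )
      }
    }
    sim <- dplyr::mutate(sim, evalue = 10^(-.data$bits_raw / 5)) |>
      dplyr::select("query", "target", "evalue", "bits_raw")
    sim <- dedup_similarity(sim)

    structure(list(
      query = query, target = target, truth = truth, similarity = sim,
      params = list(
        n_query = n_query, n_target = n_target, p_edge = p_edge,
        p_rewire = p_rewire, k_decoys = k_decoys, sigma = sigma,
        n_inflated = n_inflated, p_background = p_background, seed = seed
      )
    ), class = "planted_instance")
  })
}

#' @export
print.planted_instance <- function(x, ...) {
  cat("<planted_instance> query ", n_nodes(x$query), "x", n_edges(x$query),
    ", target ", n_nodes(x$target), "x", n_edges(x$target),
    ", seed ", x$params$seed, "\n",
    sep = ""
  )
  invisible(x)
}

#' The packaged Wnt-pathway query network
#'
#' An 11-protein, 17-interaction query network for the canonical Wnt
#' signaling pathway (WNT1, A2MR, FZD1, DVL1, AXIN1, GSK3B, CTNNB1,
#' APC, TCF7, TLE1, MYC): Wnt ligand binding to the Frizzled/LRP
#' receptor pair, Dishevelled activation, inhibition of the
#' GSK-3beta/axin/APC/beta-catenin degradation complex, beta-catenin/TCF
#' complex formation displacing Groucho, and induction of the c-myc
#' proto-oncogene. The interaction set is a reconstruction from the
#' pathway description; the node and edge counts (11 and 17) are the
#' authoritative facts, the individual reconstructed edges are not
#' ground truth. Shipped as an edge-list file under `extdata/`.
#'
#' @return a list with `network` (the [ppi_network()]) and `similarity`
#'   (an identity similarity table for self-alignment: each protein
#'   paired with itself at E-value 0 and bit score 100).
#' @examples
#' wnt <- wnt_fixture()
#' n_nodes(wnt$network) # 11
#' n_edges(wnt$network) # 17
#' @export
wnt_fixture <- function() {
  path <- system.file("extdata", "wnt_query.txt",
    package = "netquery", mustWork = TRUE
  )
  net <- read_network(path, format = "edgelist")
  sim <- tibble::tibble(
    query = net$nodes$id, target = net$nodes$id,
    evalue = 0, bits_raw = 100
  )
  list(network = net, similarity = sim)
}
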