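# shared fixture builders, all deterministic given a seed

net_from_pairs <- function(...) {
  pairs <- list(...)
  ppi_network(tibble::tibble(
    from = vapply(pairs, `[[`, "", 1),
    to = vapply(pairs, `[[`, "", 2),
    confidence = vapply(pairs, function(p) {
      if (length(p) > 2) as.numeric(p[3]) else 1
    }, 1)
  ))
}

# random query/target pair with random candidate sets (<= 4 per node)
mk_random_instance <- function(seed, n1_range = 4:7, n2_range = 5:9,
                               max_cand = 4) {
  set.seed(seed)
  pick <- function(x) if (length(x) == 1) x else sample(x, 1)
  n1 <- pick(n1_range)
  n2 <- pick(n2_range)
  q <- sprintf("q%02d", seq_len(n1))
  t <- sprintf("t%02d", seq_len(n2))
  qp <- utils::combn(q, 2)
  keep <- stats::runif(ncol(qp)) < 0.5
  if (!any(keep)) keep[1] <- TRUE
  qn <- ppi_network(tibble::tibble(from = qp[1, keep], to = qp[2, keep]),
    nodes = tibble::tibble(id = q)
  )
  tp <- utils::combn(t, 2)
  keep2 <- stats::runif(ncol(tp)) < 0.4
  if (!any(keep2)) keep2[1] <- TRUE
  tn <- ppi_network(tibble::tibble(from = tp[1, keep2], to = tp[2, keep2]),
    nodes = tibble::tibble(id = t)
  )
  rows <- lapply(q, function(u) {
    k <- sample(0:max_cand, 1)
    if (k == 0) return(NULL)
    tibble::tibble(query = u, target = sample(t, k),
      bits_raw = stats::runif(k, 1, 100))
  })
  pairs <- dplyr::bind_rows(rows)
  if (!nrow(pairs)) {
    pairs <- tibble::tibble(query = q[1], target = t[1], bits_raw = 50)
  }
  pairs$evalue <- 10^(-pairs$bits_raw / 5)
  sim <- normalize_bits(pairs[, c("query", "target", "evalue", "bits_raw")])
  list(query = qn, target = tn, sim = sim,
    cand = build_candidates(sim, 100))
}

# identity candidate set over a network's own nodes
identity_candidates <- function(net, e_max = 100) {
  sim <- normalize_bits(tibble::tibble(
    query = net$nodes$id, target = net$nodes$id,
    evalue = 0, bits_raw = 100
  ))
  build_candidates(sim, e_max)
}

# all permutations of 1:n (for tiny exhaustive assignment checks)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = k)
    }
  }
  out
}

# random similarity table (no networks)
mk_random_similarity <- function(seed, n = 20) {
  set.seed(seed)
  tab <- tibble::tibble(
    query = sprintf("q%02d", sample(1:8, n, replace = TRUE)),
    target = sprintf("t%02d", sample(1:12, n, replace = TRUE)),
    evalue = 10^stats::runif(n, -120, 2),
    bits_raw = stats::runif(n, 1, 500)
  )
  dplyr::distinct(tab, query, target, .keep_all = TRUE)
}
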