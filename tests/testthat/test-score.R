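test_that("the conservation indicator matches direct adjacency lookup", {
  q <- net_from_pairs(c("a", "b"), c("b", "c"))
  t <- net_from_pairs(c("x", "y"), c("y", "z"))
  m_partial <- tibble::tibble(query = "a", target = "x")
  expect_equal(conservation_indicator(m_partial, "a", "b", q, t), 0)

  m_full <- tibble::tibble(query = c("a", "b"), target = c("x", "y"))
  expect_equal(conservation_indicator(m_full, "a", "b", q, t), 1)
  expect_error(conservation_indicator(m_full, "a", "c", q, t), "not a query edge")

  # identity self-alignment conserves every edge
  wnt <- wnt_fixture()$network
  m_id <- tibble::tibble(query = wnt$nodes$id, target = wnt$nodes$id)
  for (i in seq_len(n_edges(wnt))) {
    expect_equal(conservation_indicator(
      m_id, wnt$edges$from[i], wnt$edges$to[i], wnt, wnt
    ), 1)
  }

  # random instance: agree with brute adjacency lookup for every edge
  inst <- mk_random_instance(17, n1_range = 5, n2_range = 7)
  res <- align_topology(inst$query, inst$target, inst$cand)
  img <- setNames(res$mapping$target, res$mapping$query)
  for (i in seq_len(n_edges(inst$query))) {
    u <- inst$query$edges$from[i]
    v <- inst$query$edges$to[i]
    direct <- if (u %in% names(img) && v %in% names(img)) {
      a <- min(img[u], img[v]); b <- max(img[u], img[v])
      as.numeric(any(
        inst$target$edges$from == a & inst$target$edges$to == b
      ))
    } else 0
    expect_equal(conservation_indicator(res$mapping, u, v,
      inst$query, inst$target), direct)
  }
})

test_that("edge correctness is conserved edges over the smaller edge count", {
  q <- net_from_pairs(c("a", "b"), c("b", "c"))
  t <- net_from_pairs(c("x", "y"), c("y", "z"), c("x", "z"))
  expect_equal(edge_correctness(
    tibble::tibble(query = character(), target = character()), q, t
  ), 0)
  # one conserved edge, min(|E1|, |E2|) = 2
  m <- tibble::tibble(query = c("a", "b", "c"), target = c("x", "y", "w"))
  t2 <- ppi_network(t$edges, nodes = tibble::tibble(id = c("w", "x", "y", "z")))
  expect_equal(edge_correctness(m, q, t2), 0.5)

  wnt <- wnt_fixture()$network
  m_id <- tibble::tibble(query = wnt$nodes$id, target = wnt$nodes$id)
  expect_equal(edge_correctness(m_id, wnt, wnt), 1.0)

  empty <- ppi_network(tibble::tibble(from = "a", to = "b", confidence = 0.05))
  expect_error(
    edge_correctness(m_id, wnt, filter_confidence(empty, 0.5)),
    "no edges"
  )
})

test_that("the total score follows the subordinate-sequence formula", {
  # |E1| = 2, |E2| = 3, |V1| = 3, |V2| = 4, 1 conserved edge, sum b = 1.5:
  # 0.5 + 1.5 / ((1 + 2) * 3) = 0.6667
  q <- net_from_pairs(c("a", "b"), c("b", "c"))
  t <- ppi_network(
    tibble::tibble(from = c("x", "y", "x"), to = c("y", "z", "z"),
      confidence = 1),
    nodes = tibble::tibble(id = c("w", "x", "y", "z"))
  )
  sim <- tibble::tibble(
    query = c("a", "b", "c"), target = c("x", "y", "w"),
    evalue = 0, bits_raw = c(100, 100, 100)
  )
  sim <- normalize_bits(sim)
  sim$bits_norm <- c(0.5, 0.5, 0.5) # sum 1.5 under a fixed normalization
  cand <- build_candidates(sim, 1)
  m <- tibble::tibble(query = c("a", "b", "c"), target = c("x", "y", "w"))
  expect_equal(total_score(m, q, t, cand), 0.5 + 1.5 / 9, tolerance = 1e-12)
  expect_equal(round(total_score(m, q, t, cand), 4), 0.6667)

  empty <- tibble::tibble(query = character(), target = character())
  expect_equal(total_score(empty, q, t, cand), 0)

  bad <- tibble::tibble(query = "a", target = "z")
  expect_error(total_score(bad, q, t, cand), "not in candidate set")
})

test_that("the sequence term is strictly subordinate to one conserved edge", {
  for (seed in 1:8) {
    inst <- mk_random_instance(seed, n1_range = 4:6, n2_range = 5:7)
    min_e <- min(n_edges(inst$query), n_edges(inst$target))
    # enumerate all feasible alignments and check the subordination bound
    bf <- brute_force_align(inst$query, inst$target, inst$cand, "topology")
    expect_lt(
      bf$score - bf$edge_correctness,
      1 / min_e
    )
    # any mapping: sequence term < 1 / min(|E1|, |E2|)
    m <- inst$cand$pairs |>
      dplyr::distinct(query, .keep_all = TRUE) |>
      dplyr::distinct(target, .keep_all = TRUE)
    m <- m[, c("query", "target")]
    ts <- total_score(m, inst$query, inst$target, inst$cand)
    ec <- edge_correctness(m, inst$query, inst$target)
    expect_lt(ts - ec, 1 / min_e)
  }
})

test_that("maximizing total score equals the lexicographic optimum", {
  enumerate_all <- function(inst) {
    # exhaustive enumeration, tracking (conserved, bits) per mapping
    q <- inst$query$nodes$id
    cand_of <- split(inst$cand$pairs$target, inst$cand$pairs$query)
    b_of <- inst$cand$pairs
    best <- NULL
    recurse <- function(i, map) {
      if (i > length(q)) {
        m <- tibble::tibble(
          query = names(map)[!is.na(map)],
          target = unname(map[!is.na(map)])
        )
        cons <- if (nrow(m) >= 2) {
          nrow(netquery:::conserved_edges_tbl(m, inst$query, inst$target))
        } else 0
        bits <- if (nrow(m)) {
          sum(dplyr::left_join(m, b_of, by = c("query", "target"))$bits_norm)
        } else 0
        if (is.null(best) || cons > best$cons + 0 ||
          (cons == best$cons && bits > best$bits + 1e-12)) {
          best <<- list(cons = cons, bits = bits)
        }
        return(invisible())
      }
      for (tgt in c(cand_of[[q[i]]], NA)) {
        if (!is.na(tgt) && tgt %in% map) next
        map[q[i]] <- tgt
        recurse(i + 1, map)
      }
      invisible()
    }
    recurse(1, stats::setNames(rep(NA_character_, length(q)), q))
    best
  }
  for (seed in c(2, 4, 6)) {
    inst <- mk_random_instance(seed, n1_range = 4:5, n2_range = 5:6,
      max_cand = 3)
    lex <- enumerate_all(inst)
    bf <- brute_force_align(inst$query, inst$target, inst$cand, "topology")
    expect_equal(bf$n_conserved, lex$cons)
    expect_equal(bf$sum_bits, lex$bits, tolerance = 1e-9)
  }
})

test_that("adding a conserved edge strictly increases the total score", {
  q <- net_from_pairs(c("a", "b"), c("b", "c"))
  t <- net_from_pairs(c("x", "y"), c("y", "z"))
  sim <- normalize_bits(tibble::tibble(
    query = c("a", "b", "c"), target = c("x", "y", "z"),
    evalue = 0, bits_raw = 100
  ))
  cand <- build_candidates(sim, 1)
  m2 <- tibble::tibble(query = c("a", "b"), target = c("x", "y"))
  m3 <- tibble::tibble(query = c("a", "b", "c"), target = c("x", "y", "z"))
  expect_gt(
    total_score(m3, q, t, cand),
    total_score(m2, q, t, cand) + 1 / min(n_edges(q), n_edges(t)) - 1e-9
  )
})
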