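test_that("format detection classifies minimal dialect cases", {
  p <- withr::local_tempfile(lines = c("A B", "B C"))
  expect_equal(detect_format(p), "edgelist")

  p <- withr::local_tempfile(lines = "A pp B")
  expect_equal(detect_format(p), "sif")

  p <- withr::local_tempfile(lines = "A B 0.5")
  expect_equal(detect_format(p), "edgelist")

  p <- withr::local_tempfile(lines = c(
    "protein1 protein2 combined_score", "p1 p2 172"
  ))
  expect_equal(detect_format(p), "string")

  p <- withr::local_tempfile(lines = "justonetoken")
  expect_error(detect_format(p), "unknown format")
})

test_that("detect_format is the identity on the four writers", {
  net <- net_from_pairs(c("A", "B", 1), c("B", "C", 1), c("A", "C", 0.5))
  for (fmt in c("edgelist", "sif", "mitab", "string")) {
    p <- withr::local_tempfile()
    write_network(net, p, fmt)
    expect_equal(detect_format(p), fmt, label = fmt)
  }
})

test_that("reading merges duplicates, drops self-loops, defaults confidence", {
  p <- withr::local_tempfile(lines = c("A B 0.5", "B A 0.9"))
  net <- read_network(p)
  expect_equal(n_nodes(net), 2)
  expect_equal(n_edges(net), 1)
  expect_equal(net$edges$confidence, 0.9)

  p <- withr::local_tempfile(lines = c("A A 0.5", "A B 0.7"))
  expect_warning(net <- read_network(p), "self-loop")
  expect_equal(n_edges(net), 1)

  p <- withr::local_tempfile(lines = "A B")
  expect_equal(read_network(p)$edges$confidence, 1)
})

test_that("STRING combined_score is normalized by division by 1000", {
  p <- withr::local_tempfile(lines = c(
    "protein1 protein2 combined_score", "p1 p2 172"
  ))
  net <- read_network(p)
  expect_equal(net$edges$confidence, 0.172)
})

test_that("SIF parsing handles multi-target lines and isolated nodes", {
  p <- withr::local_tempfile(lines = c("A pp B C", "LONER"))
  net <- read_network(p, "sif")
  expect_equal(n_nodes(net), 4)
  expect_equal(n_edges(net), 2)
  expect_true("LONER" %in% net$nodes$id)
})

test_that("MITAB parsing strips prefixes and reads column-15 scores", {
  row <- paste(c(
    "uniprotkb:P1", "uniprotkb:P2", rep("-", 12), "intact-miscore:0.56"
  ), collapse = "\t")
  p <- withr::local_tempfile(lines = row)
  net <- read_network(p)
  expect_setequal(net$nodes$id, c("P1", "P2"))
  expect_equal(net$edges$confidence, 0.56)
})

test_that("malformed lines fail with a line number", {
  p <- withr::local_tempfile(lines = c("A B", "A B C D"))
  expect_error(read_network(p, "edgelist"), "line 2")
  p <- withr::local_tempfile(lines = c("# comment", "", "A B"))
  expect_equal(n_edges(read_network(p)), 1) # comments and blanks skipped
})

test_that("round-trips preserve nodes, edges and confidences", {
  set.seed(7)
  pr <- utils::combn(sprintf("n%02d", 1:8), 2)
  keep <- runif(ncol(pr)) < 0.4
  conf <- round(runif(sum(keep), 0.1, 0.999), 3) # representable in STRING
  base <- ppi_network(tibble::tibble(
    from = pr[1, keep], to = pr[2, keep], confidence = conf
  ))
  unit <- ppi_network(dplyr::mutate(base$edges, confidence = 1))
  cases <- list(
    edgelist = base, mitab = base, string = base,
    sif = unit # SIF carries no confidence
  )
  for (fmt in names(cases)) {
    p <- withr::local_tempfile()
    write_network(cases[[fmt]], p, fmt)
    back <- read_network(p)
    expect_equal(back$nodes$id, cases[[fmt]]$nodes$id, label = fmt)
    expect_equal(back$edges$from, cases[[fmt]]$edges$from, label = fmt)
    expect_equal(back$edges$to, cases[[fmt]]$edges$to, label = fmt)
    expect_equal(back$edges$confidence, cases[[fmt]]$edges$confidence,
      tolerance = 1e-9, label = fmt
    )
  }
})

test_that("confidence filtering is strict, idempotent, and matches a scan", {
  net <- net_from_pairs(c("A", "B", 0.1), c("B", "C", 0.5))
  expect_equal(n_edges(filter_confidence(net, 0.1)), 1)

  set.seed(11)
  pr <- utils::combn(sprintf("n%02d", 1:12), 2)
  idx <- sample(ncol(pr), 50)
  net <- ppi_network(tibble::tibble(
    from = pr[1, idx], to = pr[2, idx], confidence = runif(50)
  ))
  expect_equal(n_edges(filter_confidence(net, 0)), 50)
  cmed <- stats::median(net$edges$confidence)
  filt <- filter_confidence(net, cmed)
  expect_equal(n_edges(filt), sum(net$edges$confidence > cmed))
  expect_identical(filter_confidence(filt, cmed)$edges, filt$edges)
  expect_equal(n_nodes(filt), n_nodes(net)) # isolated nodes retained
  expect_error(filter_confidence(net, 1.5), "c_min")
})

test_that("similarity tables read, deduplicate and round-trip", {
  p <- withr::local_tempfile(lines = "q1\tt1\t1e-50\t200")
  tab <- read_similarity(p)
  expect_equal(tab$evalue, 1e-50)
  expect_equal(tab$bits_raw, 200)

  p <- withr::local_tempfile(lines = c("q1\tt1\t1e-5\t100", "q1\tt1\t1e-9\t150"))
  expect_equal(read_similarity(p)$bits_raw, 150)

  p <- withr::local_tempfile(lines = "q1\tt1\t-1\t100")
  expect_error(read_similarity(p), "line 1")

  tab <- mk_random_similarity(3)
  p <- withr::local_tempfile()
  write_similarity(tab, p)
  back <- read_similarity(p)
  orig <- dplyr::arrange(tab, query, target)
  expect_equal(back$query, orig$query)
  expect_equal(back$evalue, orig$evalue, tolerance = 1e-9)
  expect_equal(back$bits_raw, orig$bits_raw, tolerance = 1e-9)
})

test_that("alignment tables partition the query edges", {
  wnt <- wnt_fixture()
  cand <- identity_candidates(wnt$network)
  res <- align_topology(wnt$network, wnt$network, cand)
  d <- withr::local_tempdir()
  paths <- write_alignment_tables(res, d)
  cons <- read.delim(paths[2])
  unq <- read.delim(paths[3])
  expect_equal(nrow(cons), 17)
  expect_equal(nrow(unq), 0)

  # planted instance: conserved + unaligned partition E1, checked by scan
  inst <- generate_planted(seed = 5, p_rewire = 0.3)
  cand <- build_candidates(normalize_bits(inst$similarity), 100)
  res <- align_topology(inst$query, inst$target, cand)
  d <- withr::local_tempdir()
  paths <- write_alignment_tables(res, d)
  cons <- read.delim(paths[2])
  unq <- read.delim(paths[3])
  qe <- inst$query$edges
  expect_equal(nrow(cons) + nrow(unq), nrow(qe))
  got <- sort(paste(c(cons$from, unq$from), c(cons$to, unq$to)))
  expect_equal(got, sort(paste(qe$from, qe$to)))
  img <- setNames(res$mapping$target, res$mapping$query)
  adj2 <- sapply(seq_len(nrow(qe)), function(i) {
    a <- img[qe$from[i]]; b <- img[qe$to[i]]
    if (is.na(a) || is.na(b)) return(FALSE)
    any(inst$target$edges$from == min(a, b) & inst$target$edges$to == max(a, b))
  })
  expect_equal(nrow(cons), sum(adj2)) # brute-force edge classification
})

test_that("empty alignment writes empty aligned-node and full query tables", {
  net <- net_from_pairs(c("A", "B"), c("B", "C"))
  tgt <- net_from_pairs(c("x", "y"))
  sim <- normalize_bits(tibble::tibble(
    query = "A", target = "x", evalue = 10, bits_raw = 5
  ))
  res <- align_topology(net, tgt, build_candidates(sim, 1)) # no pairs allowed
  d <- withr::local_tempdir()
  paths <- write_alignment_tables(res, d)
  expect_equal(nrow(read.delim(paths[1])), 0)
  expect_equal(nrow(read.delim(paths[3])), n_edges(net))
})

test_that("Cytoscape export marks origins and round-trips the union graph", {
  wnt <- wnt_fixture()
  cand <- identity_candidates(wnt$network)
  res <- align_topology(wnt$network, wnt$network, cand)
  d <- withr::local_tempdir()
  paths <- write_cytoscape(res, d)
  eda <- readLines(paths[3])[-1]
  expect_true(all(grepl("= both$", eda)))

  back <- read_network(paths[1], "sif")
  expect_equal(n_edges(back), 17)

  # alignment with zero conserved edges: nothing marked "both"
  net <- net_from_pairs(c("A", "B"))
  tgt <- ppi_network(tibble::tibble(from = "x", to = "z", confidence = 1),
    nodes = tibble::tibble(id = c("x", "y", "z"))
  )
  sim <- normalize_bits(tibble::tibble(
    query = c("A", "B"), target = c("x", "y"),
    evalue = 0, bits_raw = c(10, 10)
  ))
  res0 <- align_topology(net, tgt, build_candidates(sim, 1))
  d2 <- withr::local_tempdir()
  p2 <- write_cytoscape(res0, d2)
  expect_false(any(grepl("= both$", readLines(p2[3]))))
})
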