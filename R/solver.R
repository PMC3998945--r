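# Exact solvers for the global pairwise network alignment problem.
#
# The topology-mode problem is a quadratic-assignment-style combinatorial
# optimization: choose a partial injective map from query to target nodes,
# restricted to the candidate pairs, maximizing conserved edges with the
# subordinate sequence term. align_topology() solves it exactly by
# depth-first branch-and-bound; the relaxation bound at every search node
# is a linear sum assignment (Hungarian algorithm via clue::solve_LSAP)
# over per-pair profits in which each still-open query edge contributes
# half its potential value at each endpoint, which dominates any feasible
# completion and so certifies an upper bound on the optimum.

# integer-indexed view of (query, target, candidate set)
build_instance <- function(query, target, cand) {
  q_ids <- query$nodes$id
  t_ids <- target$nodes$id
  n1 <- length(q_ids)
  n2 <- length(t_ids)
  qi <- stats::setNames(seq_len(n1), q_ids)
  ti <- stats::setNames(seq_len(n2), t_ids)
  e1 <- cbind(unname(qi[query$edges$from]), unname(qi[query$edges$to]))
  adj1 <- lapply(seq_len(n1), function(i) {
    sort(c(e1[e1[, 1] == i, 2], e1[e1[, 2] == i, 1]))
  })
  A2 <- matrix(FALSE, n2, n2)
  if (nrow(target$edges)) {
    ef <- unname(ti[target$edges$from])
    et <- unname(ti[target$edges$to])
    A2[cbind(ef, et)] <- TRUE
    A2[cbind(et, ef)] <- TRUE
  }
  bmat <- matrix(NA_real_, n1, n2)
  p <- cand$pairs[cand$pairs$query %in% q_ids & cand$pairs$target %in% t_ids, ]
  if (nrow(p)) bmat[cbind(unname(qi[p$query]), unname(ti[p$target]))] <- p$bits_norm
  cand_idx <- lapply(seq_len(n1), function(i) sort(which(!is.na(bmat[i, ]))))
  list(
    q_ids = q_ids, t_ids = t_ids, n1 = n1, n2 = n2,
    e1 = e1, adj1 = adj1, A2 = A2, bmat = bmat, cand_idx = cand_idx,
    min_e = min(nrow(query$edges), nrow(target$edges)),
    seq_coef = sequence_coefficient(query, target)
  )
}

# package an integer assignment vector into the user-facing result object
new_alignment_result <- function(assign_idx, inst, mode, e_max, score,
                                 upper_bound, status, query, target, cand) {
  mapped <- which(assign_idx > 0)
  mapping <- tibble::tibble(
    query = inst$q_ids[mapped],
    target = inst$t_ids[assign_idx[mapped]]
  )
  mapping <- dplyr::left_join(mapping, cand$pairs, by = c("query", "target")) |>
    dplyr::arrange(.data$query)
  cons <- conserved_edges_tbl(mapping, query, target)
  sum_bits <- if (nrow(mapping)) sum(mapping$bits_norm) else 0
  ec <- if (inst$min_e > 0) nrow(cons) / inst$min_e else 0
  tot <- ec + inst$seq_coef * sum_bits
  gap <- max(0, upper_bound - score)
  structure(list(
    mapping = mapping,
    conserved_edges = cons,
    n_conserved = nrow(cons),
    edge_correctness = ec,
    sum_bits = sum_bits,
    total_score = tot,
    score = score,
    upper_bound = upper_bound,
    gap = gap,
    optimal = gap <= 1e-6,
    mode = mode,
    e_max = e_max,
    solver_status = status,
    query = query, target = target
  ), class = "netq_alignment")
}

#' @export
print.netq_alignment <- function(x, ...) {
  cat("<netquery alignment> mode = ", x$mode,
    ", e_max = ", format(x$e_max), "\n",
    "  mapped nodes: ", nrow(x$mapping),
    ", conserved edges: ", x$n_conserved,
    ", edge correctness: ", format(round(x$edge_correctness, 4)), "\n",
    "  score: ", format(x$score),
    ", upper bound: ", format(x$upper_bound),
    ", gap: ", format(x$gap),
    if (x$optimal) " (optimal)" else " (not proven optimal)", "\n",
    sep = ""
  )
  invisible(x)
}

#' Align a query network to a target network (topology mode)
#'
#' Finds the alignment maximizing the total score (edge correctness with
#' the subordinate sequence term) over all partial injective maps
#' respecting the candidate set, by exact depth-first branch-and-bound.
#' Every returned result carries a certified upper bound on the optimal
#' score; when the search completes within the time limit the bound
#' equals the score and `optimal` is `TRUE` (gap 0). On time-limit
#' expiry the incumbent is returned with the best bound proven so far
#' and `optimal = FALSE`.
#'
#' Ties between optimal mappings are broken deterministically: query
#' nodes are processed in lexicographic order and candidate targets in
#' lexicographic order (leaving a node unmapped is considered last), and
#' the first optimum encountered is kept.
#'
#' @param query,target confidence-filtered [ppi_network()]s; both must
#'   have at least one edge.
#' @param cand a `candidate_set` from [build_candidates()].
#' @param time_limit wall-clock budget in seconds (default 300).
#' @return a `netq_alignment` result object.
#' @export
align_topology <- function(query, target, cand, time_limit = 300) {
  stopifnot(inherits(query, "ppi_network"), inherits(target, "ppi_network"))
  if (min(n_edges(query), n_edges(target)) == 0) {
    stop("alignment score undefined: a network has no edges", call. = FALSE)
  }
  inst <- build_instance(query, target, cand)
  if (all(lengths(inst$cand_idx) == 0)) {
    return(new_alignment_result(
      integer(inst$n1), inst, "topology", cand$e_max,
      0, 0, "no_feasible_pairs", query, target, cand
    ))
  }
  st <- bnb_search(inst, time_limit)
  status <- if (st$complete) "optimal" else "time_limit"
  ub <- if (st$complete) st$best_score else max(st$best_score, st$open_bound)
  new_alignment_result(
    st$best_assign, inst, "topology", cand$e_max,
    st$best_score, ub, status, query, target, cand
  )
}

# depth-first branch-and-bound over partial injective maps
bnb_search <- function(inst, time_limit) {
  n1 <- inst$n1
  n2 <- inst$n2
  deadline <- Sys.time() + time_limit
  st <- new.env(parent = emptyenv())
  st$best_score <- -Inf
  st$best_assign <- integer(n1)
  st$complete <- TRUE
  st$open_bound <- -Inf
  assign_v <- integer(n1) # 0 = unmapped; positions >= d are undecided
  used <- logical(n2)

  recurse <- function(d, cons, bits) {
    if (d > n1) {
      sc <- cons / inst$min_e + inst$seq_coef * bits
      if (sc > st$best_score + 1e-12) {
        st$best_score <- sc
        st$best_assign <- assign_v
      }
      return(invisible())
    }
    if (Sys.time() > deadline) {
      st$complete <- FALSE
      ub <- bnb_bound(inst, d, assign_v, used, cons, bits)
      st$open_bound <- max(st$open_bound, ub)
      return(invisible())
    }
    ub <- bnb_bound(inst, d, assign_v, used, cons, bits)
    if (ub <= st$best_score + 1e-12) {
      return(invisible())
    }
    for (v in inst$cand_idx[[d]]) {
      if (used[v]) next
      fixed_nb <- inst$adj1[[d]]
      fixed_nb <- fixed_nb[fixed_nb < d & assign_v[fixed_nb] > 0]
      dcons <- if (length(fixed_nb)) sum(inst$A2[assign_v[fixed_nb], v]) else 0
      assign_v[d] <<- v
      used[v] <<- TRUE
      recurse(d + 1, cons + dcons, bits + inst$bmat[d, v])
      used[v] <<- FALSE
      assign_v[d] <<- 0L
    }
    recurse(d + 1, cons, bits) # leave node d unmapped
    invisible()
  }
  recurse(1L, 0, 0)
  st
}

# assignment-relaxation upper bound at a search node: query nodes before
# depth d are fixed; each remaining node picks at most one free candidate,
# with half-weights for open query edges and full weight for edges into
# the fixed part. Injectivity of the relaxation is enforced by the LSAP.
bnb_bound <- function(inst, d, assign_v, used, cons, bits) {
  base <- cons / inst$min_e + inst$seq_coef * bits
  n1 <- inst$n1
  if (d > n1) {
    return(base)
  }
  rem <- d:n1
  free_t <- which(!used)
  nr <- length(rem)
  if (!length(free_t)) {
    return(base)
  }
  P <- matrix(0, nr, length(free_t) + nr) # trailing dummy cols = unmapped
  pos <- integer(inst$n2)
  pos[free_t] <- seq_along(free_t)
  half <- 0.5 / inst$min_e
  full <- 1 / inst$min_e
  for (r in seq_len(nr)) {
    u <- rem[r]
    cu <- inst$cand_idx[[u]]
    cu <- cu[!used[cu]]
    if (!length(cu)) next
    prof <- inst$seq_coef * inst$bmat[u, cu]
    nb <- inst$adj1[[u]]
    fixed_nb <- nb[nb < d & assign_v[nb] > 0]
    if (length(fixed_nb)) {
      im <- assign_v[fixed_nb]
      prof <- prof + full * colSums(inst$A2[im, cu, drop = FALSE])
    }
    open_nb <- nb[nb >= d & nb != u]
    for (w in open_nb) {
      cw <- inst$cand_idx[[w]]
      cw <- cw[!used[cw]]
      if (!length(cw)) next
      reach <- rowSums(inst$A2[cu, cw, drop = FALSE]) > 0
      prof <- prof + half * reach
    }
    P[r, pos[cu]] <- prof
  }
  lsap <- clue::solve_LSAP(P, maximum = TRUE)
  base + sum(P[cbind(seq_len(nr), as.integer(lsap))])
}

#' Align by sequence similarity only
#'
#' Solves the maximum-weight injective assignment under the normalized
#' bit scores of the candidate set, ignoring topology: a linear sum
#' assignment solved exactly by the Hungarian algorithm
#' ([clue::solve_LSAP()]), so the result is always optimal (gap 0). The
#' `score` field holds the bit-score sum; when `query` and `target`
#' networks are supplied, conserved edges, edge correctness and the
#' total score of the resulting mapping are additionally reported for
#' comparison with topology mode.
#'
#' @param cand a `candidate_set` from [build_candidates()].
#' @param query,target optional confidence-filtered [ppi_network()]s.
#' @return a `netq_alignment` result object.
#' @export
align_sequence_only <- function(cand, query = NULL, target = NULL) {
  if (is.null(query)) {
    query <- network_from_candidates(cand, "query")
  }
  if (is.null(target)) {
    target <- network_from_candidates(cand, "target")
  }
  inst <- build_instance(query, target, cand)
  if (all(lengths(inst$cand_idx) == 0)) {
    res <- new_alignment_result(
      integer(inst$n1), inst, "sequence_only", cand$e_max,
      0, 0, "no_feasible_pairs", query, target, cand
    )
    return(res)
  }
  rows <- which(lengths(inst$cand_idx) > 0)
  free_t <- sort(unique(unlist(inst$cand_idx)))
  P <- matrix(0, length(rows), length(free_t) + length(rows))
  pos <- integer(inst$n2)
  pos[free_t] <- seq_along(free_t)
  for (r in seq_along(rows)) {
    cu <- inst$cand_idx[[rows[r]]]
    P[r, pos[cu]] <- inst$bmat[rows[r], cu]
  }
  lsap <- as.integer(clue::solve_LSAP(P, maximum = TRUE))
  assign_v <- integer(inst$n1)
  for (r in seq_along(rows)) {
    col <- lsap[r]
    if (col <= length(free_t)) {
      v <- free_t[col]
      if (v %in% inst$cand_idx[[rows[r]]]) assign_v[rows[r]] <- v
    }
  }
  score <- sum(inst$bmat[cbind(
    which(assign_v > 0), assign_v[assign_v > 0]
  )])
  if (!length(which(assign_v > 0))) score <- 0
  new_alignment_result(
    assign_v, inst, "sequence_only", cand$e_max,
    score, score, "optimal", query, target, cand
  )
}

# minimal network over the ids appearing in a candidate set (used when
# align_sequence_only is called without networks; scores that need edges
# are then reported as 0)
network_from_candidates <- function(cand, side) {
  ids <- sort(unique(cand$pairs[[side]]))
  structure(list(
    nodes = tibble::tibble(id = ids, description = NA_character_),
    edges = empty_edges()
  ), class = "ppi_network")
}

#' Exhaustive alignment (test oracle)
#'
#' Enumerates every partial injective map consistent with the candidate
#' set and returns the true optimum; the upper bound equals the score
#' and `optimal` is always `TRUE`. Guarded: the number of feasible maps
#' (product of candidate-set sizes plus one) must not exceed 1e7.
#'
#' @inheritParams align_topology
#' @param mode `"topology"` (total score) or `"sequence_only"`
#'   (bit-score sum).
#' @return a `netq_alignment` result object.
#' @export
brute_force_align <- function(query, target, cand,
                              mode = c("topology", "sequence_only")) {
  mode <- match.arg(mode)
  inst <- build_instance(query, target, cand)
  n_maps <- prod(lengths(inst$cand_idx) + 1)
  if (n_maps > 1e7) {
    stop("instance too large for exhaustive enumeration (", format(n_maps),
      " feasible maps); use align_topology()",
      call. = FALSE
    )
  }
  if (mode == "topology" && inst$min_e == 0) {
    stop("alignment score undefined: a network has no edges", call. = FALSE)
  }
  n1 <- inst$n1
  st <- new.env(parent = emptyenv())
  st$best_score <- -Inf
  st$best_assign <- integer(n1)
  assign_v <- integer(n1)
  used <- logical(inst$n2)
  leaf_score <- if (mode == "topology") {
    function(cons, bits) cons / inst$min_e + inst$seq_coef * bits
  } else {
    function(cons, bits) bits
  }
  recurse <- function(d, cons, bits) {
    if (d > n1) {
      sc <- leaf_score(cons, bits)
      if (sc > st$best_score + 1e-12) {
        st$best_score <- sc
        st$best_assign <- assign_v
      }
      return(invisible())
    }
    for (v in inst$cand_idx[[d]]) {
      if (used[v]) next
      fixed_nb <- inst$adj1[[d]]
      fixed_nb <- fixed_nb[fixed_nb < d & assign_v[fixed_nb] > 0]
      dcons <- if (length(fixed_nb)) sum(inst$A2[assign_v[fixed_nb], v]) else 0
      assign_v[d] <<- v
      used[v] <<- TRUE
      recurse(d + 1, cons + dcons, bits + inst$bmat[d, v])
      used[v] <<- FALSE
      assign_v[d] <<- 0L
    }
    recurse(d + 1, cons, bits)
    invisible()
  }
  recurse(1L, 0, 0)
  score <- if (is.finite(st$best_score)) st$best_score else 0
  new_alignment_result(
    st$best_assign, inst, mode, cand$e_max,
    score, score, "optimal", query, target, cand
  )
}
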