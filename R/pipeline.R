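pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full network-query pipeline
#'
#' The offline counterpart of a complete server run: read the query and
#' target networks and the precomputed similarity table, filter both
#' networks at the confidence threshold, normalize bit scores once, then
#' for each E-value cutoff build the candidate pairings and solve the
#' alignment in the chosen mode. A cutoff with no allowed pairs yields
#' an empty-alignment run, not an error.
#'
#' @param query_path,target_path network file paths (see
#'   [read_network()]).
#' @param similarity_path tab-separated similarity table (see
#'   [read_similarity()]).
#' @param c_min confidence threshold; edges must be strictly above it
#'   (default 0.1).
#' @param mode `"topology"` (default) or `"sequence_only"`.
#' @param cutoffs ascending E-value cutoffs (default
#'   [default_cutoffs()]).
#' @param time_limit per-cutoff solver budget in seconds.
#' @param query_format,target_format optional format tags overriding
#'   autodetection.
#' @return a `netq_report`: list with `runs` (one `netq_alignment` per
#'   cutoff), `query_stats`, `target_stats` and `settings`.
#' @export
run_pipeline <- function(query_path, target_path, similarity_path,
                         c_min = 0.1,
                         mode = c("topology", "sequence_only"),
                         cutoffs = default_cutoffs(),
                         time_limit = 300,
                         query_format = NULL, target_format = NULL) {
  mode <- match.arg(mode)
  cutoffs <- sort(cutoffs)
  query_raw <- pipeline_stage("read query network",
    read_network(query_path, query_format))
  target_raw <- pipeline_stage("read target network",
    read_network(target_path, target_format))
  sim <- pipeline_stage("read similarity table", read_similarity(similarity_path))
  query <- pipeline_stage("filter query", filter_confidence(query_raw, c_min))
  target <- pipeline_stage("filter target", filter_confidence(target_raw, c_min))
  sim <- pipeline_stage("normalize bit scores", normalize_bits(sim))
  runs <- vector("list", length(cutoffs))
  for (i in seq_along(cutoffs)) {
    cand <- pipeline_stage("build candidates", build_candidates(sim, cutoffs[i]))
    t0 <- Sys.time()
    runs[[i]] <- pipeline_stage(
      paste0("align at e_max=", format(cutoffs[i])),
      if (mode == "topology") {
        align_topology(query, target, cand, time_limit = time_limit)
      } else {
        align_sequence_only(cand, query = query, target = target)
      }
    )
    runs[[i]]$seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  stats_tbl <- function(raw, filt) {
    tibble::tibble(
      stage = c("raw", "filtered"),
      nodes = c(n_nodes(raw), n_nodes(filt)),
      edges = c(n_edges(raw), n_edges(filt))
    )
  }
  structure(list(
    runs = runs,
    query_stats = stats_tbl(query_raw, query),
    target_stats = stats_tbl(target_raw, target),
    settings = list(
      c_min = c_min, mode = mode, cutoffs = cutoffs,
      time_limit = time_limit
    )
  ), class = "netq_report")
}

#' @export
print.netq_report <- function(x, ...) {
  cat("<netquery report> mode = ", x$settings$mode,
    ", c_min = ", x$settings$c_min,
    ", ", length(x$runs), " cutoff run(s)\n",
    sep = ""
  )
  print(run_summary(x))
  invisible(x)
}

#' Predicted (missing) query interactions
#'
#' Every target edge whose endpoints are both images of mapped query
#' nodes but whose pre-images are not adjacent in the query network:
#' candidate interactions missed in the query species, reported with the
#' target edge confidence.
#'
#' @param result a `netq_alignment` result.
#' @param query,target the networks the alignment was computed on
#'   (default: the ones stored in the result).
#' @return tibble with columns `target_from`, `target_to`,
#'   `confidence`, `query_from`, `query_to`.
#' @export
predicted_interactions <- function(result, query = result$query,
                                   target = result$target) {
  m <- result$mapping
  pre <- stats::setNames(m$query, m$target)
  te <- target$edges
  fi <- unname(pre[te$from])
  ti <- unname(pre[te$to])
  both <- !is.na(fi) & !is.na(ti)
  if (any(both)) {
    adj1 <- adjacency_fun(query)
    in_query <- mapply(adj1, fi[both], ti[both], USE.NAMES = FALSE)
    keep <- which(both)[!in_query]
  } else {
    keep <- integer(0)
  }
  tibble::tibble(
    target_from = te$from[keep],
    target_to = te$to[keep],
    confidence = te$confidence[keep],
    query_from = fi[keep],
    query_to = ti[keep]
  ) |> dplyr::arrange(.data$target_from, .data$target_to)
}

#' Per-cutoff overview table
#'
#' One row per cutoff run: cutoff, conserved-edge count, edge
#' correctness, bit-score sum, total score, objective score, certified
#' upper bound, optimality gap, optimality flag and wall-clock seconds.
#'
#' @param report a `netq_report` from [run_pipeline()].
#' @return a tibble.
#' @export
run_summary <- function(report) {
  purrr::map_dfr(report$runs, function(r) {
    tibble::tibble(
      e_max = r$e_max,
      n_conserved = r$n_conserved,
      edge_correctness = r$edge_correctness,
      sum_bits = r$sum_bits,
      total_score = r$total_score,
      score = r$score,
      upper_bound = r$upper_bound,
      gap = r$gap,
      optimal = r$optimal,
      status = r$solver_status,
      seconds = if (is.null(r$seconds)) NA_real_ else r$seconds
    )
  })
}

#' Write all pipeline outputs to a directory
#'
#' Emits `summary.tsv` plus one sub-directory per cutoff containing the
#' four alignment tables ([write_alignment_tables()]), a
#' `predicted_interactions.tsv`, and optionally Cytoscape-compatible
#' files ([write_cytoscape()]). Output is deterministic: identical
#' reports produce byte-identical files.
#'
#' @param report a `netq_report`.
#' @param out_dir output directory.
#' @param cytoscape also write Cytoscape files per cutoff?
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, cytoscape = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- run_summary(report)
  summ$seconds <- NULL # wall-clock excluded so output is deterministic
  write_tsv_plain(summ, file.path(out_dir, "summary.tsv"))
  for (i in seq_along(report$runs)) {
    r <- report$runs[[i]]
    sub <- file.path(out_dir, sprintf("run_%02d_emax_%s", i, format(r$e_max)))
    write_alignment_tables(r, sub)
    pred <- predicted_interactions(r)
    write_tsv_plain(pred, file.path(sub, "predicted_interactions.tsv"))
    if (cytoscape) write_cytoscape(r, sub)
  }
  invisible(out_dir)
}
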