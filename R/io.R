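#' Detect the format of a network file
#'
#' Inspects the file content (never the extension): 15+ tab-separated
#' columns indicate MITAB; a header mentioning `protein1`/`protein2` or
#' `combined_score` indicates STRING's protein-links text format; three or
#' more whitespace-separated columns with a non-numeric third token
#' indicate Cytoscape SIF ("node type node ..."); two columns, or three
#' with a numeric third column, indicate a plain edge list.
#'
#' Blank lines and lines starting with `#` are skipped (the `#` rule also
#' covers MITAB's commented header line).
#'
#' @param path file path.
#' @return one of `"edgelist"`, `"sif"`, `"mitab"`, `"string"`.
#' @export
detect_format <- function(path) {
  lines <- read_content_lines(path)
  if (!length(lines$text)) stop("empty file: ", path, call. = FALSE)
  first <- lines$text[[1]]
  tabs <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (length(tabs) >= 15) {
    return("mitab")
  }
  if (grepl("protein1", first, ignore.case = TRUE) &&
    grepl("protein2", first, ignore.case = TRUE) ||
    grepl("combined_score", first, ignore.case = TRUE)) {
    return("string")
  }
  toks <- strsplit(trimws(first), "[ \t]+")[[1]]
  if (length(toks) == 2) {
    return("edgelist")
  }
  if (length(toks) == 3 && !is.na(suppressWarnings(as.numeric(toks[3])))) {
    return("edgelist")
  }
  if (length(toks) >= 3) {
    return("sif")
  }
  stop("unknown format: cannot classify line ", lines$lineno[[1]],
    " of ", path, ": \"", first, "\"",
    call. = FALSE
  )
}

# strip blank and #-comment lines, keeping original line numbers for errors
read_content_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(raw)) & !startsWith(trimws(raw), "#")
  list(text = raw[keep], lineno = which(keep))
}

#' Read a PPI network file
#'
#' Supports plain edge lists (2-3 whitespace-separated columns, optional
#' numeric confidence third column), Cytoscape SIF, IntAct MITAB (>= 15
#' tab-separated columns, identifiers from columns 1-2 with database
#' prefixes stripped, confidence parsed from a `score:x` entry in column
#' 15) and STRING protein-links text (integer `combined_score` normalized
#' by division by 1000). Duplicate edges are merged keeping the maximum
#' confidence; self-loops are dropped with a warning; edges without a
#' stated confidence get confidence 1.
#'
#' @param path file path.
#' @param format one of `"edgelist"`, `"sif"`, `"mitab"`, `"string"`, or
#'   `NULL` to autodetect via [detect_format()].
#' @return a [ppi_network()].
#' @export
read_network <- function(path, format = NULL) {
  if (is.null(format)) format <- detect_format(path)
  format <- match.arg(format, c("edgelist", "sif", "mitab", "string"))
  lines <- read_content_lines(path)
  if (!length(lines$text)) stop("empty file: ", path, call. = FALSE)
  parsed <- switch(format,
    edgelist = parse_edgelist(lines),
    sif = parse_sif(lines),
    mitab = parse_mitab(lines),
    string = parse_string(lines)
  )
  if (!nrow(parsed$edges) && !nrow(parsed$nodes)) {
    stop("no nodes or edges parsed from ", path, call. = FALSE)
  }
  net <- ppi_network(parsed$edges,
    nodes = if (nrow(parsed$nodes)) parsed$nodes else NULL
  )
  if (n_nodes(net) == 0) stop("empty graph after parsing ", path, call. = FALSE)
  net
}

empty_edges <- function() {
  tibble::tibble(from = character(), to = character(), confidence = numeric())
}

parse_edgelist <- function(lines) {
  from <- to <- character(0)
  conf <- numeric(0)
  for (i in seq_along(lines$text)) {
    toks <- strsplit(trimws(lines$text[[i]]), "[ \t]+")[[1]]
    if (length(toks) < 2 || length(toks) > 3) {
      stop("malformed edge-list line ", lines$lineno[[i]], call. = FALSE)
    }
    ci <- 1
    if (length(toks) == 3) {
      ci <- suppressWarnings(as.numeric(toks[3]))
      if (is.na(ci)) {
        stop("malformed edge-list line ", lines$lineno[[i]],
          ": non-numeric confidence",
          call. = FALSE
        )
      }
    }
    from <- c(from, toks[1])
    to <- c(to, toks[2])
    conf <- c(conf, ci)
  }
  list(
    edges = tibble::tibble(from = from, to = to, confidence = conf),
    nodes = tibble::tibble(id = character())
  )
}

parse_sif <- function(lines) {
  from <- to <- iso <- character(0)
  for (i in seq_along(lines$text)) {
    toks <- strsplit(trimws(lines$text[[i]]), "[ \t]+")[[1]]
    if (length(toks) == 1) {
      iso <- c(iso, toks[1]) # isolated node
    } else if (length(toks) >= 3) {
      # "source type target1 [target2 ...]"
      from <- c(from, rep(toks[1], length(toks) - 2))
      to <- c(to, toks[3:length(toks)])
    } else {
      stop("malformed SIF line ", lines$lineno[[i]], call. = FALSE)
    }
  }
  list(
    edges = tibble::tibble(from = from, to = to, confidence = 1),
    nodes = tibble::tibble(id = iso)
  )
}

strip_db_prefix <- function(x) sub("^[^:]*:", "", x)

parse_mitab <- function(lines) {
  from <- to <- character(0)
  conf <- numeric(0)
  for (i in seq_along(lines$text)) {
    toks <- strsplit(lines$text[[i]], "\t", fixed = TRUE)[[1]]
    if (length(toks) < 15) {
      stop("malformed MITAB line ", lines$lineno[[i]],
        ": fewer than 15 columns",
        call. = FALSE
      )
    }
    ci <- 1
    m <- regmatches(
      toks[15],
      regexpr("score:[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?", toks[15])
    )
    if (length(m)) ci <- as.numeric(sub("score:", "", m[[1]]))
    from <- c(from, strip_db_prefix(toks[1]))
    to <- c(to, strip_db_prefix(toks[2]))
    conf <- c(conf, ci)
  }
  list(
    edges = tibble::tibble(from = from, to = to, confidence = conf),
    nodes = tibble::tibble(id = character())
  )
}

parse_string <- function(lines) {
  from <- to <- character(0)
  conf <- numeric(0)
  start <- 1
  toks1 <- strsplit(trimws(lines$text[[1]]), "[ \t]+")[[1]]
  if (length(toks1) >= 3 && is.na(suppressWarnings(as.numeric(toks1[3])))) {
    start <- 2 # header row
  }
  if (start > length(lines$text)) {
    return(list(edges = empty_edges(), nodes = tibble::tibble(id = character())))
  }
  for (i in start:length(lines$text)) {
    toks <- strsplit(trimws(lines$text[[i]]), "[ \t]+")[[1]]
    if (length(toks) != 3) {
      stop("malformed STRING line ", lines$lineno[[i]], call. = FALSE)
    }
    s <- suppressWarnings(as.numeric(toks[3]))
    if (is.na(s)) {
      stop("malformed STRING line ", lines$lineno[[i]],
        ": non-numeric combined_score",
        call. = FALSE
      )
    }
    from <- c(from, toks[1])
    to <- c(to, toks[2])
    conf <- c(conf, s / 1000)
  }
  list(
    edges = tibble::tibble(from = from, to = to, confidence = conf),
    nodes = tibble::tibble(id = character())
  )
}

#' Write a PPI network file
#'
#' Counterparts of the four [read_network()] dialects. SIF carries no
#' confidence (it is lost on writing); STRING quantizes confidence to
#' integer thousandths.
#'
#' @param net a [ppi_network()].
#' @param path output file path.
#' @param format one of `"edgelist"`, `"sif"`, `"mitab"`, `"string"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path,
                          format = c("edgelist", "sif", "mitab", "string")) {
  format <- match.arg(format)
  e <- net$edges
  lines <- switch(format,
    edgelist = sprintf("%s\t%s\t%.10g", e$from, e$to, e$confidence),
    sif = {
      connected <- union(e$from, e$to)
      iso <- setdiff(net$nodes$id, connected)
      c(sprintf("%s pp %s", e$from, e$to), iso)
    },
    mitab = sprintf(
      "uniprotkb:%s\tuniprotkb:%s\t%s\tscore:%.10g",
      e$from, e$to, paste(rep("-", 12), collapse = "\t"), e$confidence
    ),
    string = c(
      "protein1 protein2 combined_score",
      sprintf("%s %s %d", e$from, e$to, as.integer(round(e$confidence * 1000)))
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a precomputed sequence-similarity table
#'
#' Tab-separated columns: query id, target id, E-value, bit score. Rows
#' duplicated on the same (query, target) pair keep the entry with the
#' larger bit score. E-values may be exactly 0.
#'
#' @param path file path.
#' @return tibble with columns `query`, `target`, `evalue`, `bits_raw`.
#' @export
read_similarity <- function(path) {
  lines <- read_content_lines(path)
  if (!length(lines$text)) stop("empty similarity file: ", path, call. = FALSE)
  query <- target <- character(0)
  evalue <- bits <- numeric(0)
  for (i in seq_along(lines$text)) {
    toks <- strsplit(lines$text[[i]], "[ \t]+")[[1]]
    if (length(toks) != 4) {
      stop("malformed similarity line ", lines$lineno[[i]],
        ": expected 4 columns",
        call. = FALSE
      )
    }
    ev <- suppressWarnings(as.numeric(toks[3]))
    b <- suppressWarnings(as.numeric(toks[4]))
    if (is.na(ev) || is.na(b)) {
      stop("malformed similarity line ", lines$lineno[[i]], call. = FALSE)
    }
    if (ev < 0 || b < 0) {
      stop("negative E-value or bit score on line ", lines$lineno[[i]],
        call. = FALSE
      )
    }
    query <- c(query, toks[1])
    target <- c(target, toks[2])
    evalue <- c(evalue, ev)
    bits <- c(bits, b)
  }
  dedup_similarity(tibble::tibble(
    query = query, target = target, evalue = evalue, bits_raw = bits
  ))
}

# keep the higher-bit-score entry per ordered (query, target) pair
dedup_similarity <- function(tab) {
  tab |>
    dplyr::group_by(.data$query, .data$target) |>
    dplyr::slice_max(.data$bits_raw, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$query, .data$target)
}

#' Write a similarity table
#'
#' @param table tibble as returned by [read_similarity()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(table, path) {
  writeLines(
    sprintf(
      "%s\t%s\t%.10g\t%.10g",
      table$query, table$target, table$evalue, table$bits_raw
    ),
    path
  )
  invisible(path)
}

write_tsv_plain <- function(df, path) {
  con <- file(path, open = "wb") # fixed \n EOL for byte-identical output
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(x) {
      if (is.numeric(x)) sprintf("%.10g", x) else as.character(x)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Write the four alignment output tables
#'
#' Emits `aligned_nodes.tsv` (query id, target id, bit score, E-value),
#' `conserved_edges.tsv` (query edges whose endpoint images form a target
#' edge), `unaligned_query_edges.tsv` (the remaining query edges) and
#' `unaligned_target_edges.tsv` (target edges between images of aligned
#' nodes whose pre-images are non-adjacent in the query — the predicted
#' missing interactions). All files are tab-separated with a header row
#' and deterministic lexicographic row order.
#'
#' @param result an alignment result from [align_topology()],
#'   [align_sequence_only()] or [brute_force_align()].
#' @param out_dir output directory (created if needed).
#' @return character vector of the four file paths, invisibly.
#' @export
write_alignment_tables <- function(result, out_dir) {
  stopifnot(inherits(result, "netq_alignment"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  m <- dplyr::arrange(result$mapping, .data$query)
  aligned <- tibble::tibble(
    query = m$query, target = m$target,
    bit_score = m$bits_norm, evalue = m$evalue
  )
  cons <- dplyr::arrange(result$conserved_edges, .data$from, .data$to)
  qe <- result$query$edges
  un_q <- dplyr::anti_join(qe, cons, by = c("from", "to")) |>
    dplyr::arrange(.data$from, .data$to)
  un_t <- predicted_interactions(result) |>
    dplyr::arrange(.data$target_from, .data$target_to)
  paths <- file.path(out_dir, c(
    "aligned_nodes.tsv", "conserved_edges.tsv",
    "unaligned_query_edges.tsv", "unaligned_target_edges.tsv"
  ))
  write_tsv_plain(aligned, paths[1])
  write_tsv_plain(cons, paths[2])
  write_tsv_plain(un_q, paths[3])
  write_tsv_plain(un_t, paths[4])
  invisible(paths)
}

#' Write Cytoscape-compatible alignment files
#'
#' Emits `alignment.sif`, the union graph over query node identifiers
#' (every query edge, plus each target edge between images of mapped
#' query nodes drawn between the pre-images), with node
#' (`alignment.noa`) and edge (`alignment.eda`) attribute files marking
#' origin: `both` for conserved edges / aligned nodes, `query` for
#' query-only edges / unaligned nodes, `target` for matched target edges
#' with no query counterpart.
#'
#' @inheritParams write_alignment_tables
#' @return character vector of the three file paths, invisibly.
#' @export
write_cytoscape <- function(result, out_dir) {
  stopifnot(inherits(result, "netq_alignment"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  u <- union_graph(result)
  sif_path <- file.path(out_dir, "alignment.sif")
  writeLines(sprintf("%s pp %s", u$edges$from, u$edges$to), sif_path)
  noa <- file.path(out_dir, "alignment.noa")
  writeLines(c(
    "origin (class=java.lang.String)",
    sprintf("%s = %s", u$nodes$id, u$nodes$origin)
  ), noa)
  eda <- file.path(out_dir, "alignment.eda")
  writeLines(c(
    "origin (class=java.lang.String)",
    sprintf("%s (pp) %s = %s", u$edges$from, u$edges$to, u$edges$origin)
  ), eda)
  invisible(c(sif_path, noa, eda))
}

# union of query edges and matched target edges, expressed on query ids
union_graph <- function(result) {
  m <- result$mapping
  qe <- result$query$edges
  cons <- result$conserved_edges
  pred <- predicted_interactions(result)
  q_only <- dplyr::anti_join(qe, cons, by = c("from", "to"))
  edges <- dplyr::bind_rows(
    tibble::tibble(from = cons$from, to = cons$to, origin = "both"),
    tibble::tibble(from = q_only$from, to = q_only$to, origin = "query"),
    tibble::tibble(
      from = pmin(pred$query_from, pred$query_to),
      to = pmax(pred$query_from, pred$query_to), origin = "target"
    )
  ) |> dplyr::arrange(.data$from, .data$to)
  nodes <- tibble::tibble(
    id = result$query$nodes$id,
    origin = ifelse(result$query$nodes$id %in% m$query, "both", "query")
  )
  list(nodes = nodes, edges = edges)
}
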