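#' Normalize bit scores to \[0, 1\]
#'
#' Adds a `bits_norm` column: each raw bit score divided by the maximum
#' raw bit score over all stored pairs, so the best-scoring pair(s) get
#' exactly 1. The normalization is instance-intrinsic and
#' order-preserving; it only ever affects tiebreaks in the alignment
#' score, never the primary topology objective.
#'
#' @param table similarity tibble with columns `query`, `target`,
#'   `evalue`, `bits_raw`.
#' @return the table with `bits_norm` added.
#' @export
normalize_bits <- function(table) {
  stopifnot(nrow(table) > 0, all(c("bits_raw", "evalue") %in% names(table)))
  bmax <- max(table$bits_raw)
  if (bmax <= 0) {
    stop("all bit scores are zero: no informative similarity", call. = FALSE)
  }
  dplyr::mutate(table, bits_norm = .data$bits_raw / bmax)
}

#' The default E-value cutoff ladder
#'
#' @return the seven cutoffs `c(0, 1e-100, 1e-50, 1e-10, 1, 10, 100)` in
#'   ascending order. The exact-zero cutoff admits only pairs whose
#'   E-value is exactly 0.
#' @export
default_cutoffs <- function() c(0, 1e-100, 1e-50, 1e-10, 1, 10, 100)

#' Build the candidate pairings for an E-value cutoff
#'
#' A query node may only be aligned to target nodes whose E-value is at
#' most `e_max`; pairs absent from the similarity table are forbidden at
#' every cutoff. Candidate sets are therefore nested along the cutoff
#' ladder.
#'
#' @param table similarity tibble with `bits_norm` populated (see
#'   [normalize_bits()]).
#' @param e_max non-negative E-value cutoff.
#' @return a `candidate_set`: list with `e_max` and a `pairs` tibble
#'   (`query`, `target`, `evalue`, `bits_norm`).
#' @export
build_candidates <- function(table, e_max) {
  if (!is.numeric(e_max) || length(e_max) != 1 || is.na(e_max) || e_max < 0) {
    stop("e_max must be a single non-negative number", call. = FALSE)
  }
  if (!"bits_norm" %in% names(table)) {
    stop("bits_norm not populated; call normalize_bits() first", call. = FALSE)
  }
  pairs <- table |>
    dplyr::filter(.data$evalue <= e_max) |>
    dplyr::select("query", "target", "evalue", "bits_norm") |>
    dplyr::arrange(.data$query, .data$target)
  structure(list(e_max = e_max, pairs = pairs), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> e_max = ", format(x$e_max), ", ",
    nrow(x$pairs), " allowed pairs over ",
    length(unique(x$pairs$query)), " query nodes\n",
    sep = ""
  )
  invisible(x)
}

#' Run an external all-against-all protein aligner
#'
#' Optional convenience around a BLAST-like tool. The `executor` is an
#' injected adapter: a function taking the two FASTA paths and returning
#' tabular hit lines (12 tab-separated columns in the classic tabular
#' layout: query id and subject id first, E-value and bit score last).
#' The default adapter shells out to `blastp`. Duplicate hits for an
#' ordered pair keep the higher bit score. The core pipeline never
#' requires this: a precomputed similarity table is the supported input.
#'
#' @param query_fasta,target_fasta protein FASTA paths.
#' @param executor adapter function `(query_fasta, target_fasta) ->
#'   character vector of tabular hit lines`.
#' @return similarity tibble as from [read_similarity()].
#' @export
run_external_aligner <- function(query_fasta, target_fasta,
                                 executor = blastp_executor) {
  lines <- tryCatch(
    executor(query_fasta, target_fasta),
    error = function(e) {
      stop("external aligner failed (", conditionMessage(e),
        "); supply a precomputed similarity table instead",
        call. = FALSE
      )
    }
  )
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) {
    stop("external aligner produced no hits; ",
      "supply a precomputed similarity table instead",
      call. = FALSE
    )
  }
  rows <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(rows, length, 1L) < 12)
  if (length(bad)) {
    stop("unparseable aligner output line ", bad[1], call. = FALSE)
  }
  tab <- tibble::tibble(
    query = vapply(rows, `[[`, "", 1),
    target = vapply(rows, `[[`, "", 2),
    evalue = as.numeric(vapply(rows, `[[`, "", 11)),
    bits_raw = as.numeric(vapply(rows, `[[`, "", 12))
  )
  if (anyNA(tab$evalue) || anyNA(tab$bits_raw)) {
    stop("non-numeric E-value or bit score in aligner output", call. = FALSE)
  }
  dedup_similarity(tab)
}

# default adapter: all-against-all blastp in tabular output format
blastp_executor <- function(query_fasta, target_fasta) {
  if (Sys.which("blastp") == "") {
    stop("blastp not found on PATH")
  }
  out <- system2("blastp",
    c(
      "-query", shQuote(query_fasta), "-subject", shQuote(target_fasta),
      "-outfmt", "6"
    ),
    stdout = TRUE, stderr = FALSE
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) stop("blastp exited with status ", status)
  out
}
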