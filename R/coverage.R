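#' @title Term coverage of pathway collections
#'
#' @description
#' Measures how much of an annotation vocabulary (e.g. the three Gene
#' Ontology branches, or a metabolome) is reachable from two pathway
#' collections A and B: a term is covered by a collection iff at least one
#' of its annotated entities occurs in that collection's identifier set.
#' The report partitions terms into only-A, only-B, overlap and uncovered,
#' with the identities `only_A + only_B + overlap = combined` and
#' `combined + uncovered = total`.  Coverage is by direct annotation; no
#' ontology-graph ancestor propagation is performed.
#' @name coverage
NULL

#' Build an annotation map
#'
#' @param category category label (e.g. `"BP"`, `"MF"`, `"CC"`,
#'   `"metabolome"`).
#' @param terms named list: term id -> character vector of entity
#'   identifiers.
#' @export
annotation_map <- function(category, terms) {
  if (anyDuplicated(names(terms)))
    stop_pb("term ids must be unique within a category",
            "pathbridge_validation_error")
  structure(list(category = category,
                 terms = lapply(terms, function(v) unique(as.character(v)))),
            class = "pb_annotation_map")
}

#' Read an annotation map from two-column TSV or GMT
#'
#' TSV: one `term <TAB> entity` pair per line (GAF-like).  GMT: `term
#' <TAB> description <TAB> entity...` per line.
#'
#' @param path file path.
#' @param category category label recorded on the map.
#' @param format `"tsv"` or `"gmt"`; guessed from the extension by default.
#' @export
read_annotation_map <- function(path, category = "terms", format = NULL) {
  if (!file.exists(path))
    stop_pb(paste0("no such file: ", path), "pathbridge_io_error")
  if (is.null(format))
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  terms <- list()
  if (format == "gmt") {
    for (ln in lines) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3) next
      terms[[f[1]]] <- unique(c(terms[[f[1]]] %||% character(), f[-(1:2)]))
    }
  } else {
    for (ln in lines) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 2) next
      terms[[f[1]]] <- unique(c(terms[[f[1]]] %||% character(), f[2]))
    }
  }
  annotation_map(category, terms)
}

#' Collect distinct identifiers from pathway data nodes
#'
#' @param pathways list of `pb_gpml_pathway`.
#' @param node_types data-node types to include (complex placeholders are
#'   excluded by the default).
#' @param id_map optional named character vector mapping node identifiers
#'   to a canonical identifier space (e.g. probe/protein -> Ensembl);
#'   identifiers absent from the map pass through unchanged.
#' @return character vector of distinct (mapped) identifiers.
#' @export
collect_identifiers <- function(pathways,
                                node_types = c("GeneProduct", "Protein",
                                               "Rna"),
                                id_map = NULL) {
  ids <- character()
  for (p in pathways)
    for (n in p$data_nodes)
      if (n$node_type %in% node_types && !is.null(n$xref))
        ids <- c(ids, n$xref$identifier)
  if (!is.null(id_map)) {
    mapped <- id_map[ids]
    ids <- ifelse(is.na(mapped), ids, unname(mapped))
  }
  unique(ids)
}

#' Compute a term coverage report for two identifier sets
#'
#' @param A,B character vectors of identifiers (collection A and B).
#' @param ann a `pb_annotation_map`.
#' @param labels length-2 character vector naming the collections.
#' @return a `pb_coverage_report` list with `category`, `labels`, `total`,
#'   `only_A`, `only_B`, `overlap`, `combined`, `uncovered`.
#' @export
compute_coverage <- function(A, B, ann, labels = c("A", "B")) {
  A <- unique(as.character(A))
  B <- unique(as.character(B))
  in_A <- vapply(ann$terms, function(g) any(g %in% A), TRUE)
  in_B <- vapply(ann$terms, function(g) any(g %in% B), TRUE)
  total <- length(ann$terms)
  structure(list(category = ann$category, labels = labels,
                 total = total,
                 only_A = sum(in_A & !in_B),
                 only_B = sum(in_B & !in_A),
                 overlap = sum(in_A & in_B),
                 combined = sum(in_A | in_B),
                 uncovered = sum(!in_A & !in_B)),
            class = "pb_coverage_report")
}

#' @export
print.pb_coverage_report <- function(x, ...) {
  pct <- function(k) if (x$total == 0) "0%" else
    paste0(round(100 * k / x$total, 1), "%")
  cat("Coverage of ", x$total, " ", x$category, " terms (A = ", x$labels[1],
      ", B = ", x$labels[2], ")\n", sep = "")
  cat("  only A:   ", x$only_A, " (", pct(x$only_A), ")\n", sep = "")
  cat("  only B:   ", x$only_B, " (", pct(x$only_B), ")\n", sep = "")
  cat("  overlap:  ", x$overlap, " (", pct(x$overlap), ")\n", sep = "")
  cat("  combined: ", x$combined, " (", pct(x$combined), ")\n", sep = "")
  cat("  uncovered:", x$uncovered, " (", pct(x$uncovered), ")\n", sep = "")
  invisible(x)
}

#' Write coverage reports as TSV (one row per category)
#'
#' @param reports a `pb_coverage_report` or list of them.
#' @param path output path.
#' @param provenance optional `#` comment lines.
#' @export
write_coverage_tsv <- function(reports, path, provenance = NULL) {
  if (inherits(reports, "pb_coverage_report")) reports <- list(reports)
  hdr <- paste(c("category", "total", "only_A", "only_B", "overlap",
                 "combined", "uncovered"), collapse = "\t")
  body <- vapply(reports, function(x)
    paste(c(x$category, x$total, x$only_A, x$only_B, x$overlap, x$combined,
            x$uncovered), collapse = "\t"), "")
  write_atomic(c(if (!is.null(provenance)) paste0("# ", provenance),
                 hdr, body), path)
}
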