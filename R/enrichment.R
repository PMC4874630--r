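#' @title Criterion-based over-representation analysis
#'
#' @description
#' Ranks pathways by how strongly their members are over-represented among
#' the measurements that satisfy a user criterion.  With N measured
#' identifiers of which R qualify, a pathway containing n measured
#' identifiers of which r qualify gets the standardized score
#' \deqn{z = \frac{r - n R/N}{\sqrt{n (R/N)(1 - R/N)(1 - \frac{n-1}{N-1})}}}
#' i.e. r centred and scaled by its hypergeometric mean and variance under
#' random draws of n from the measured universe.  This is the classic
#' MAPPFinder/PathVisio pathway statistic.
#' @name enrichment
NULL

#' Over-representation z score
#'
#' @param r qualifying measured identifiers in the pathway.
#' @param n measured identifiers in the pathway.
#' @param R qualifying identifiers in the whole dataset.
#' @param N measured identifiers in the whole dataset.
#' @return the z score; `NA` when the variance is zero (`n = 0`, `R = 0`,
#'   `R = N` or `n = N`).  Vectorized over `r` and `n`.
#' @export
zscore <- function(r, n, R, N) {
  if (any(N < 2) || any(r < 0) || any(r > n) || any(n > N) ||
      any(r > R) || any(R > N))
    stop_pb("need 0 <= r <= n <= N, r <= R <= N, N >= 2",
            "pathbridge_domain_error")
  p <- R / N
  v <- n * p * (1 - p) * (1 - (n - 1) / (N - 1))
  ifelse(v <= 0, NA_real_, (r - n * p) / sqrt(v))
}

#' Read a delimited statistics table
#'
#' First column: measurement identifier; remaining columns numeric
#' statistics (e.g. `logFC`, `P.value`).  Lines starting with `#` are
#' provenance comments and are skipped.
#'
#' @param path file path.
#' @param sep field separator (tab by default).
#' @return data frame with the identifier column named as in the file.
#' @export
read_data_table <- function(path, sep = "\t") {
  if (!file.exists(path))
    stop_pb(paste0("no such file: ", path), "pathbridge_io_error")
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  if (ncol(df) < 2)
    stop_pb("table needs an identifier column plus at least one statistic",
            "pathbridge_validation_error")
  if (anyDuplicated(names(df)))
    stop_pb("duplicate column names in table", "pathbridge_validation_error")
  df[[1]] <- as.character(df[[1]])
  df
}

# identifiers carried by a pathway's data nodes; complex placeholders (type
# Complex) are skipped, flattened component nodes are ordinary nodes and
# count
pathway_identifiers <- function(p) {
  ids <- character()
  for (n in p$data_nodes) {
    if (n$node_type == "Complex") next
    if (!is.null(n$xref)) ids <- c(ids, n$xref$identifier)
  }
  unique(ids)
}

collection_tag <- function(p) {
  for (cm in p$comments)
    if (identical(cm$source, "DataSource")) return(cm$text)
  "unknown"
}

#' Run over-representation analysis across a pathway collection
#'
#' Identifiers are collapsed after mapping (several probes mapping to one
#' identifier count once and qualify if any probe qualifies).  Rows whose
#' criterion columns are missing do not qualify but remain measured.  A
#' pathway with no measured identifier gets an undefined z and ranks last.
#' Results are sorted by z descending, ties broken by pathway name.
#'
#' @param table data frame from [read_data_table()]; first column holds the
#'   measurement identifiers.
#' @param crit a `pb_criterion` or criterion string.
#' @param pathways list of `pb_gpml_pathway`.
#' @param id_mapper optional mapping from table identifiers to the
#'   identifier space of the pathway data nodes: a named character vector
#'   or a function; identity by default.
#' @param collections optional character vector of collection tags, one per
#'   pathway; defaults to each pathway's `DataSource` comment.
#' @return a `pb_enrichment` data frame with columns `pathway`, `source`,
#'   `r`, `n`, `R`, `N`, `z`.
#' @export
run_enrichment <- function(table, crit, pathways, id_mapper = identity,
                           collections = NULL) {
  if (is.null(table) || nrow(table) == 0)
    stop_pb("empty data table", "pathbridge_domain_error")
  if (is.character(crit)) crit <- parse_criterion(crit)

  raw_ids <- as.character(table[[1]])
  mapped <- if (is.function(id_mapper)) {
    vapply(raw_ids, function(x) as.character(id_mapper(x)), "",
           USE.NAMES = FALSE)
  } else {
    out <- id_mapper[raw_ids]
    ifelse(is.na(out), raw_ids, unname(out))
  }
  qual_rows <- criterion_matches(crit, table)
  qual_by_id <- tapply(qual_rows, mapped, any)
  universe <- names(qual_by_id)
  N <- length(universe)
  R <- sum(qual_by_id)

  if (is.null(collections))
    collections <- vapply(pathways, collection_tag, "")
  names_ <- vapply(pathways, `[[`, "", "name")

  n <- integer(length(pathways))
  r <- integer(length(pathways))
  for (k in seq_along(pathways)) {
    present <- intersect(pathway_identifiers(pathways[[k]]), universe)
    n[k] <- length(present)
    r[k] <- sum(qual_by_id[present])
  }
  z <- if (N >= 2) zscore(r, n, R, N) else rep(NA_real_, length(pathways))

  res <- data.frame(pathway = names_, source = collections,
                    r = r, n = n, R = R, N = N, z = z,
                    stringsAsFactors = FALSE)
  ord <- order(is.na(res$z), -ifelse(is.na(res$z), 0, res$z), res$pathway)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("pb_enrichment", "data.frame")
  res
}

#' @export
print.pb_enrichment <- function(x, n_show = 10L, ...) {
  cat("Over-representation analysis: N =", x$N[1], "measured, R =",
      x$R[1], "qualifying\n")
  print.data.frame(utils::head(x, n_show), digits = 4, row.names = TRUE)
  if (nrow(x) > n_show) cat("... and", nrow(x) - n_show, "more pathways\n")
  invisible(x)
}

#' Write an enrichment result table as TSV
#'
#' @param res a `pb_enrichment`.
#' @param path output path.
#' @param provenance optional character vector written as leading `#`
#'   comment lines.
#' @export
write_enrichment_tsv <- function(res, path, provenance = NULL) {
  hdr <- paste(c("pathway", "source", "r", "n", "R", "N", "z"),
               collapse = "\t")
  body <- vapply(seq_len(nrow(res)), function(k)
    paste(c(res$pathway[k], res$source[k], res$r[k], res$n[k], res$R[k],
            res$N[k],
            if (is.na(res$z[k])) "NA" else fmt_num(res$z[k])),
          collapse = "\t"), "")
  lines <- c(if (!is.null(provenance)) paste0("# ", provenance), hdr, body)
  write_atomic(lines, path)
}
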