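#' @title Complex percentage scoring and colour rules
#'
#' @description
#' Scores every complex/entity-set on a converted pathway by the percentage
#' of its component nodes (those with data) that satisfy a user criterion,
#' then maps scores to colours through ordered rules or a linear gradient
#' -- the workflow used to highlight affected complexes on a diagram (e.g.
#' percent > 25 marked orange, the rest dark grey).  Components without a
#' data row are excluded from numerator and denominator, mirroring the "not
#' measured" convention for gene nodes.
#' @name complex_scoring
NULL

#' Score complexes by the percentage of qualifying components
#'
#' @param p a `pb_gpml_pathway` produced by [convert_pathway()].
#' @param map complex-component map (named list: container placeholder
#'   graph_id -> component node graph_ids); defaults to
#'   [read_component_map()] on `p`.
#' @param table data frame; first column identifiers matching the component
#'   nodes' xref identifiers.
#' @param crit a `pb_criterion` or criterion string.
#' @return data frame of class `pb_complex_scores` with columns
#'   `complex_id`, `label`, `n_components` (components with data),
#'   `n_qualifying` and `percent` (`NA` when no component has data).
#' @export
score_complexes <- function(p, map = NULL, table, crit) {
  if (is.null(map)) map <- read_component_map(p)
  if (length(map) == 0)
    return(structure(data.frame(complex_id = character(),
                                label = character(),
                                n_components = integer(),
                                n_qualifying = integer(),
                                percent = numeric(),
                                stringsAsFactors = FALSE),
                     class = c("pb_complex_scores", "data.frame")))
  if (is.character(crit)) crit <- parse_criterion(crit)

  nodes <- stats::setNames(p$data_nodes,
                           vapply(p$data_nodes, `[[`, "", "graph_id"))
  for (cid in names(map))
    for (gid in map[[cid]])
      if (is.null(nodes[[gid]]))
        stop_pb(paste0("component node '", gid, "' not found in pathway"),
                "pathbridge_reference_error")

  ids <- as.character(table[[1]])
  qual_rows <- criterion_matches(crit, table)
  qual_by_id <- tapply(qual_rows, ids, any)

  rows <- lapply(names(map), function(cid) {
    comp_ids <- vapply(map[[cid]], function(gid) {
      x <- nodes[[gid]]$xref
      if (is.null(x)) NA_character_ else x$identifier
    }, "")
    with_data <- comp_ids[!is.na(comp_ids) & comp_ids %in% names(qual_by_id)]
    n_comp <- length(with_data)
    n_qual <- if (n_comp == 0) 0L else sum(qual_by_id[with_data])
    data.frame(complex_id = cid,
               label = nodes[[cid]]$text_label,
               n_components = n_comp,
               n_qualifying = as.integer(n_qual),
               percent = if (n_comp == 0) NA_real_ else 100 * n_qual / n_comp,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("pb_complex_scores", "data.frame")
  res
}

#' Colour rule
#'
#' Either a threshold rule (`op` + `threshold` + `color`) or a linear
#' gradient between two anchor scores.
#'
#' @param op one of `">"`, `">="`, `"<"`, `"<="`, `"="` for threshold
#'   rules, or `"gradient"`.
#' @param threshold threshold percent (threshold rules).
#' @param color target colour, hex `"#RRGGBB"` (threshold rules).
#' @param anchors numeric length-2 vector of gradient anchor percents.
#' @param colors character length-2 vector of gradient anchor colours.
#' @export
color_rule <- function(op, threshold = NULL, color = NULL,
                       anchors = NULL, colors = NULL) {
  if (op == "gradient") {
    if (length(anchors) != 2 || anchors[1] == anchors[2])
      stop_pb("gradient anchors must be two distinct values",
              "pathbridge_validation_error")
    if (length(colors) != 2)
      stop_pb("gradient needs two colours", "pathbridge_validation_error")
    structure(list(op = "gradient", anchors = as.numeric(anchors),
                   colors = colors), class = "pb_color_rule")
  } else {
    if (!(op %in% c("<", "<=", ">", ">=", "=")))
      stop_pb(paste0("unknown rule operator '", op, "'"),
              "pathbridge_validation_error")
    structure(list(op = op, threshold = as.numeric(threshold),
                   color = color), class = "pb_color_rule")
  }
}

hex_to_rgb <- function(h) as.numeric(grDevices::col2rgb(h))
rgb_to_hex <- function(v)
  grDevices::rgb(v[1], v[2], v[3], maxColorValue = 255)

#' Assign colours to complex scores
#'
#' Rules are evaluated in the supplied order; the first matching rule wins.
#' Threshold comparisons are exact (a strict `> 25` rule leaves a score of
#' exactly 25 to later rules or the default).  Gradient rules interpolate
#' linearly in RGB between the two anchors, clamping outside them.
#' Undefined scores always take the default colour.
#'
#' @param scores a `pb_complex_scores`.
#' @param rules list of [color_rule()] (a single rule is accepted).
#' @param default default colour for unmatched or undefined scores.
#' @return named character vector: complex graph_id -> hex colour.
#' @export
apply_color_rules <- function(scores, rules, default = "#404040") {
  if (inherits(rules, "pb_color_rule")) rules <- list(rules)
  if (length(rules) == 0 && is.null(default))
    stop_pb("need at least one rule or a default colour",
            "pathbridge_validation_error")
  one <- function(pct) {
    if (is.na(pct)) return(default)
    for (rl in rules) {
      if (rl$op == "gradient") {
        t <- (pct - rl$anchors[1]) / (rl$anchors[2] - rl$anchors[1])
        t <- min(max(t, 0), 1)
        lo <- hex_to_rgb(rl$colors[1])
        hi <- hex_to_rgb(rl$colors[2])
        return(rgb_to_hex(round(lo + t * (hi - lo))))
      }
      hit <- switch(rl$op,
                    ">" = pct > rl$threshold, ">=" = pct >= rl$threshold,
                    "<" = pct < rl$threshold, "<=" = pct <= rl$threshold,
                    "=" = pct == rl$threshold)
      if (hit) return(rl$color)
    }
    default
  }
  stats::setNames(vapply(scores$percent, one, ""), scores$complex_id)
}

#' Look up linked elements across the complex-component map
#'
#' For a complex placeholder id, returns its component node ids; for a
#' component node id, returns every complex containing it.  The relation is
#' symmetric: `y %in% complex_lookup(p, map, x)` iff
#' `x %in% complex_lookup(p, map, y)`.
#'
#' @param p a `pb_gpml_pathway`.
#' @param map complex-component map; defaults to [read_component_map()].
#' @param id a complex placeholder or component node graph_id.
#' @return character vector of linked graph_ids.
#' @export
complex_lookup <- function(p, map = NULL, id) {
  if (is.null(map)) map <- read_component_map(p)
  if (id %in% names(map)) return(map[[id]])
  containing <- names(map)[vapply(map, function(v) id %in% v, TRUE)]
  if (length(containing) == 0)
    stop_pb(paste0("'", id, "' is neither a complex nor a component node"),
            "pathbridge_lookup_error")
  containing
}

#' Write complex scores and colours as TSV
#'
#' @param scores a `pb_complex_scores`.
#' @param colors optional named colour vector from [apply_color_rules()].
#' @param path output path.
#' @param provenance optional `#` comment lines.
#' @export
write_complex_scores_tsv <- function(scores, colors = NULL, path,
                                     provenance = NULL) {
  cols <- c("complex_id", "label", "n_components", "n_qualifying", "percent")
  hdr <- paste(c(cols, if (!is.null(colors)) "color"), collapse = "\t")
  body <- vapply(seq_len(nrow(scores)), function(k) {
    pct <- scores$percent[k]
    paste(c(scores$complex_id[k], scores$label[k], scores$n_components[k],
            scores$n_qualifying[k], if (is.na(pct)) "NA" else fmt_num(pct),
            if (!is.null(colors)) colors[[scores$complex_id[k]]]),
          collapse = "\t")
  }, "")
  write_atomic(c(if (!is.null(provenance)) paste0("# ", provenance),
                 hdr, body), path)
}
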