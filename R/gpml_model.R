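#' @title GPML 2013a document model
#'
#' @description
#' In-memory model of a GPML (Graphical Pathway Markup Language) pathway as
#' used by WikiPathways and PathVisio, dialect 2013a (namespace
#' `http://pathvisio.org/GPML/2013a`): data nodes, interactions built from
#' ordered points that may attach to other elements or to anchors at
#' fractional positions along an interaction, groups (with the styles
#' "Complex" and "Group"), free labels and shapes.  Literature references are
#' encoded the GPML way: elements carry `BiopaxRef` children pointing at
#' `bp:PublicationXref` records collected in a trailing `Biopax` section.
#' @name gpml_model
NULL

GPML_NS <- "http://pathvisio.org/GPML/2013a"
NODE_TYPES <- c("GeneProduct", "Protein", "Rna", "Metabolite", "Pathway",
                "Complex", "Unknown")
ARROW_HEADS <- c("none", "arrow", "t_bar", "mim_catalysis",
                 "mim_stimulation", "mim_inhibition", "mim_conversion",
                 "mim_binding")
# model token -> GPML ArrowHead attribute
ARROW_ATTR <- c(none = "Line", arrow = "Arrow", t_bar = "TBar",
                mim_catalysis = "mim-catalysis",
                mim_stimulation = "mim-stimulation",
                mim_inhibition = "mim-inhibition",
                mim_conversion = "mim-conversion",
                mim_binding = "mim-binding")
GROUP_STYLES <- c("Complex", "Group", "None")

#' GPML data node
#' @param graph_id id unique within the document.
#' @param text_label node label.
#' @param node_type one of `GeneProduct`, `Protein`, `Rna`, `Metabolite`,
#'   `Pathway`, `Complex`, `Unknown`.
#' @param center,size numeric pairs in board units.
#' @param group_ref optional id of the group the node belongs to.
#' @param xref optional [xref()].
#' @param comments list of `list(source =, text =)`.
#' @param literature character vector of PubMed ids.
#' @export
gpml_data_node <- function(graph_id, text_label, node_type = "Unknown",
                           center = c(0, 0), size = c(80, 20),
                           group_ref = NULL, xref = NULL,
                           comments = list(), literature = character()) {
  structure(list(graph_id = graph_id, text_label = text_label,
                 node_type = node_type, center = as.numeric(center),
                 size = as.numeric(size), group_ref = group_ref,
                 xref = xref, comments = comments,
                 literature = as.character(literature)),
            class = "pb_gpml_data_node")
}

#' Anchor on an interaction
#' @param anchor_id id unique within the document.
#' @param position fraction in `[0, 1]` along the owning interaction.
#' @export
gpml_anchor <- function(anchor_id, position) {
  structure(list(anchor_id = anchor_id, position = as.numeric(position)),
            class = "pb_gpml_anchor")
}

#' Interaction way-point
#' @param coords numeric `c(x, y)`.
#' @param graph_ref optional id of a data node or anchor this point attaches
#'   to.
#' @param arrow_head one of `none`, `arrow`, `t_bar`, `mim_catalysis`,
#'   `mim_stimulation`, `mim_inhibition`, `mim_conversion`, `mim_binding`.
#' @export
gpml_point <- function(coords, graph_ref = NULL, arrow_head = "none") {
  structure(list(coords = as.numeric(coords), graph_ref = graph_ref,
                 arrow_head = arrow_head),
            class = "pb_gpml_point")
}

#' Interaction (edge, possibly carrying anchors)
#' @param graph_id document-unique id.
#' @param points list of [gpml_point()], length at least 2; first and last
#'   are the endpoints.
#' @param anchors list of [gpml_anchor()] owned by this interaction.
#' @param xref optional [xref()].
#' @param comments list of `list(source =, text =)`.
#' @param literature character vector of PubMed ids.
#' @export
gpml_interaction <- function(graph_id, points, anchors = list(),
                             xref = NULL, comments = list(),
                             literature = character()) {
  structure(list(graph_id = graph_id, points = points, anchors = anchors,
                 xref = xref, comments = comments,
                 literature = as.character(literature)),
            class = "pb_gpml_interaction")
}

#' Group (complex or plain grouping)
#' @param group_id document-unique id.
#' @param style `"Complex"`, `"Group"` or `"None"`.
#' @export
gpml_group <- function(group_id, style = "None") {
  structure(list(group_id = group_id, style = style),
            class = "pb_gpml_group")
}

#' Free text label
#' @param graph_id document-unique id.
#' @param text label text.
#' @param geometry numeric `c(center_x, center_y, width, height)`.
#' @export
gpml_label <- function(graph_id, text, geometry = c(0, 0, 90, 25)) {
  structure(list(graph_id = graph_id, text = text,
                 geometry = as.numeric(geometry)),
            class = "pb_gpml_label")
}

#' Graphical shape
#' @param graph_id document-unique id.
#' @param shape_kind e.g. `"Rectangle"`, `"RoundedRectangle"`, `"Oval"`.
#' @param geometry numeric `c(center_x, center_y, width, height)`.
#' @param text_label optional text drawn on the shape.
#' @param group_ref optional owning group id.
#' @param double_line draw with a double-line border (membranes).
#' @export
gpml_shape <- function(graph_id, shape_kind = "Rectangle",
                       geometry = c(0, 0, 100, 100), text_label = "",
                       group_ref = NULL, double_line = FALSE) {
  structure(list(graph_id = graph_id, shape_kind = shape_kind,
                 geometry = as.numeric(geometry), text_label = text_label,
                 group_ref = group_ref, double_line = isTRUE(double_line)),
            class = "pb_gpml_shape")
}

#' Assemble a GPML pathway document
#' @param name,organism pathway metadata.
#' @param comments list of `list(source =, text =)`; conversion output
#'   carries the data source and source version here.
#' @param authors character vector (written to the `Author` attribute).
#' @param maintainers character vector (written as comments with source
#'   `"Maintainer"`).
#' @param board numeric `c(width, height)`.
#' @param data_nodes,interactions,groups,labels,shapes element lists.
#' @export
gpml_pathway <- function(name, organism = "", comments = list(),
                         authors = character(), maintainers = character(),
                         board = c(500, 500), data_nodes = list(),
                         interactions = list(), groups = list(),
                         labels = list(), shapes = list()) {
  structure(list(name = name, organism = organism, comments = comments,
                 authors = as.character(authors),
                 maintainers = as.character(maintainers),
                 board = as.numeric(board), data_nodes = data_nodes,
                 interactions = interactions, groups = groups,
                 labels = labels, shapes = shapes),
            class = "pb_gpml_pathway")
}

#' @export
print.pb_gpml_pathway <- function(x, ...) {
  n_anchors <- sum(vapply(x$interactions, function(i) length(i$anchors), 0L))
  cat("GPML pathway: ", x$name,
      if (nzchar(x$organism)) paste0(" (", x$organism, ")"), "\n", sep = "")
  cat("  data nodes:   ", length(x$data_nodes), "\n")
  cat("  interactions: ", length(x$interactions),
      " (", n_anchors, " anchors)\n", sep = "")
  cat("  groups:       ", length(x$groups), "\n")
  cat("  labels/shapes:", length(x$labels), "/", length(x$shapes), "\n")
  invisible(x)
}

gpml_ids <- function(p) {
  list(
    nodes = vapply(p$data_nodes, `[[`, "", "graph_id"),
    anchors = unlist(lapply(p$interactions, function(i)
      vapply(i$anchors, `[[`, "", "anchor_id"))) %||% character(),
    groups = vapply(p$groups, `[[`, "", "group_id"))
}

#' Validate a GPML document model
#'
#' Checks id uniqueness, resolution of every `graph_ref`/`group_ref`,
#' anchor position range, point-list length, group reference counts, and
#' that the board encloses all element bounding boxes.
#' @param p a `pb_gpml_pathway`.
#' @return data frame of violations (`element`, `rule`); zero rows if valid.
#' @export
validate_gpml <- function(p) {
  v <- list()
  add <- function(el, rule) v[[length(v) + 1]] <<- violation(el, rule)
  ids <- gpml_ids(p)
  all_ids <- c(ids$nodes, ids$anchors)
  if (anyDuplicated(c(ids$nodes, ids$anchors, ids$groups)))
    add("<document>", "duplicate graph/group ids")

  grp_used <- character()
  for (n in p$data_nodes) {
    if (!(n$node_type %in% NODE_TYPES))
      add(n$graph_id, paste0("unknown node type '", n$node_type, "'"))
    if (any(n$size <= 0)) add(n$graph_id, "size must be positive")
    if (!is.null(n$group_ref)) {
      grp_used <- c(grp_used, n$group_ref)
      if (!(n$group_ref %in% ids$groups))
        add(n$graph_id, paste0("group_ref '", n$group_ref, "' does not resolve"))
    }
  }
  for (i in p$interactions) {
    if (length(i$points) < 2) add(i$graph_id, "needs at least 2 points")
    for (pt in i$points) {
      if (!is.null(pt$graph_ref) && !(pt$graph_ref %in% all_ids))
        add(i$graph_id,
            paste0("graph_ref '", pt$graph_ref, "' does not resolve"))
      if (!(pt$arrow_head %in% ARROW_HEADS))
        add(i$graph_id, paste0("unknown arrow head '", pt$arrow_head, "'"))
    }
    for (a in i$anchors)
      if (a$position < 0 || a$position > 1)
        add(a$anchor_id, "anchor position outside [0, 1]")
  }
  for (s in p$shapes)
    if (!is.null(s$group_ref)) {
      grp_used <- c(grp_used, s$group_ref)
      if (!(s$group_ref %in% ids$groups))
        add(s$graph_id, paste0("group_ref '", s$group_ref, "' does not resolve"))
    }
  for (g in p$groups) {
    if (!(g$style %in% GROUP_STYLES))
      add(g$group_id, paste0("unknown group style '", g$style, "'"))
    if (!(g$group_id %in% grp_used))
      add(g$group_id, "group referenced by no element")
  }

  bb <- element_bbox(p)
  if (!is.null(bb) && (bb[3] > p$board[1] + 1e-6 || bb[4] > p$board[2] + 1e-6))
    add("<document>", "board size does not enclose all elements")
  if (length(v) == 0)
    return(data.frame(element = character(), rule = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}

# overall (xmin, ymin, xmax, ymax) of drawn elements, NULL when empty
element_bbox <- function(p) {
  boxes <- list()
  for (n in p$data_nodes)
    boxes[[length(boxes) + 1]] <- c(n$center - n$size / 2, n$center + n$size / 2)
  for (l in p$labels)
    boxes[[length(boxes) + 1]] <-
      c(l$geometry[1:2] - l$geometry[3:4] / 2,
        l$geometry[1:2] + l$geometry[3:4] / 2)
  for (s in p$shapes)
    boxes[[length(boxes) + 1]] <-
      c(s$geometry[1:2] - s$geometry[3:4] / 2,
        s$geometry[1:2] + s$geometry[3:4] / 2)
  for (i in p$interactions)
    for (pt in i$points)
      boxes[[length(boxes) + 1]] <- c(pt$coords, pt$coords)
  if (length(boxes) == 0) return(NULL)
  m <- do.call(rbind, boxes)
  c(min(m[, 1]), min(m[, 2]), max(m[, 3]), max(m[, 4]))
}

collect_literature <- function(p) {
  lit <- character()
  for (n in p$data_nodes) lit <- c(lit, n$literature)
  for (i in p$interactions) lit <- c(lit, i$literature)
  unique(lit)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub('"', "&quot;", s, fixed = TRUE)
}

# ' Name="value"' attribute string; NULL values are dropped
xml_attrs_str <- function(...) {
  a <- list(...)
  a <- a[!vapply(a, is.null, TRUE)]
  if (length(a) == 0) return("")
  paste0(" ", names(a), '="', vapply(a, xml_escape, ""), '"',
         collapse = "")
}

#' Write a GPML 2013a XML file
#'
#' Emits elements in the canonical order (metadata comments, DataNodes,
#' Interactions, Labels, Shapes, Groups, InfoBox, Biopax), UTF-8, two-space
#' indentation, deterministic attribute order, so converting the same input
#' twice yields byte-identical files.
#'
#' @param p a valid `pb_gpml_pathway`.
#' @param path output path.
#' @export
write_gpml <- function(p, path) {
  viol <- validate_gpml(p)
  refv <- grepl("does not resolve", viol$rule)
  if (any(refv))
    stop_pb(paste0(viol$element[refv], ": ", viol$rule[refv], collapse = "; "),
            "pathbridge_reference_error")
  if (nrow(viol) > 0)
    stop_pb(paste0(viol$element, ": ", viol$rule, collapse = "; "),
            "pathbridge_validation_error")

  L <- vector("list", 64)
  nL <- 0L
  add <- function(...) {
    nL <<- nL + 1L
    L[[nL]] <<- paste0(...)
  }
  comment_lines <- function(ind, comments) {
    for (cm in comments)
      add(ind, "<Comment",
          if (!is.null(cm$source) && nzchar(cm$source))
            xml_attrs_str(Source = cm$source) else "",
          ">", xml_escape(cm$text), "</Comment>")
  }
  bpref_lines <- function(ind, literature) {
    for (pmid in literature)
      add(ind, "<BiopaxRef>pub_", pmid, "</BiopaxRef>")
  }
  xref_line <- function(ind, xref) {
    add(ind, "<Xref",
        xml_attrs_str(Database = if (is.null(xref)) "" else xref$data_source,
                      ID = if (is.null(xref)) "" else xref$identifier),
        "/>")
  }

  add('<?xml version="1.0" encoding="UTF-8"?>')
  add("<Pathway",
      xml_attrs_str(
        xmlns = GPML_NS,
        "xmlns:bp" = "http://www.biopax.org/release/biopax-level3.owl#",
        "xmlns:rdf" = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
        Name = p$name,
        Organism = if (nzchar(p$organism)) p$organism,
        Author = if (length(p$authors)) paste(p$authors, collapse = ", ")),
      ">")
  comment_lines("  ", p$comments)
  for (m in p$maintainers)
    add('  <Comment Source="Maintainer">', xml_escape(m), "</Comment>")
  add("  <Graphics", xml_attrs_str(BoardWidth = fmt_num(p$board[1]),
                                   BoardHeight = fmt_num(p$board[2])), "/>")

  for (n in p$data_nodes) {
    add("  <DataNode",
        xml_attrs_str(TextLabel = n$text_label, GraphId = n$graph_id,
                      Type = n$node_type, GroupRef = n$group_ref), ">")
    comment_lines("    ", n$comments)
    bpref_lines("    ", n$literature)
    add("    <Graphics", xml_attrs_str(CenterX = fmt_num(n$center[1]),
                                       CenterY = fmt_num(n$center[2]),
                                       Width = fmt_num(n$size[1]),
                                       Height = fmt_num(n$size[2])), "/>")
    xref_line("    ", n$xref)
    add("  </DataNode>")
  }

  for (i in p$interactions) {
    add("  <Interaction", xml_attrs_str(GraphId = i$graph_id), ">")
    comment_lines("    ", i$comments)
    bpref_lines("    ", i$literature)
    add("    <Graphics>")
    for (pt in i$points)
      add("      <Point",
          xml_attrs_str(X = fmt_num(pt$coords[1]),
                        Y = fmt_num(pt$coords[2]),
                        GraphRef = pt$graph_ref,
                        ArrowHead = if (pt$arrow_head != "none")
                          ARROW_ATTR[[pt$arrow_head]]), "/>")
    for (a in i$anchors)
      add("      <Anchor",
          xml_attrs_str(Position = fmt_num(a$position),
                        GraphId = a$anchor_id, Shape = "None"), "/>")
    add("    </Graphics>")
    xref_line("    ", i$xref)
    add("  </Interaction>")
  }

  for (l in p$labels) {
    add("  <Label", xml_attrs_str(TextLabel = l$text, GraphId = l$graph_id),
        ">")
    add("    <Graphics", xml_attrs_str(CenterX = fmt_num(l$geometry[1]),
                                       CenterY = fmt_num(l$geometry[2]),
                                       Width = fmt_num(l$geometry[3]),
                                       Height = fmt_num(l$geometry[4])), "/>")
    add("  </Label>")
  }

  for (s in p$shapes) {
    add("  <Shape",
        xml_attrs_str(TextLabel = if (nzchar(s$text_label)) s$text_label,
                      GraphId = s$graph_id, GroupRef = s$group_ref), ">")
    add("    <Graphics",
        xml_attrs_str(CenterX = fmt_num(s$geometry[1]),
                      CenterY = fmt_num(s$geometry[2]),
                      Width = fmt_num(s$geometry[3]),
                      Height = fmt_num(s$geometry[4]),
                      ShapeType = s$shape_kind,
                      LineStyle = if (s$double_line) "Double"), "/>")
    add("  </Shape>")
  }

  for (g in p$groups)
    add("  <Group", xml_attrs_str(GroupId = g$group_id, Style = g$style),
        "/>")
  add('  <InfoBox CenterX="0.0" CenterY="0.0"/>')

  lit <- collect_literature(p)
  if (length(lit) == 0) {
    add("  <Biopax/>")
  } else {
    add("  <Biopax>")
    for (pmid in lit) {
      add('    <bp:PublicationXref rdf:id="pub_', pmid, '">')
      add("      <bp:ID>", xml_escape(pmid), "</bp:ID>")
      add("      <bp:Database>PubMed</bp:Database>")
      add("    </bp:PublicationXref>")
    }
    add("  </Biopax>")
  }
  add("</Pathway>")
  write_atomic(unlist(L[seq_len(nL)]), path)
  invisible(path)
}

known_attrs <- function(node, known, ctx) {
  at <- names(xml2::xml_attrs(node))
  unknown <- setdiff(at, known)
  if (length(unknown))
    pb_log("ignoring unknown attribute(s) ", paste(unknown, collapse = ", "),
           " on ", ctx, level = "warn")
}

parse_xref_xml <- function(parent) {
  xn <- xml2::xml_find_first(parent, "./Xref")
  if (inherits(xn, "xml_missing")) return(NULL)
  db <- xml2::xml_attr(xn, "Database")
  id <- xml2::xml_attr(xn, "ID")
  if (is.na(db) || is.na(id) || !nzchar(db) || !nzchar(id)) return(NULL)
  xref(db, id)
}

parse_comments_xml <- function(parent) {
  out <- list()
  for (cn in xml2::xml_find_all(parent, "./Comment")) {
    src <- xml2::xml_attr(cn, "Source")
    out[[length(out) + 1]] <- list(source = if (is.na(src)) "" else src,
                                   text = xml2::xml_text(cn))
  }
  out
}

parse_bprefs_xml <- function(parent) {
  refs <- xml2::xml_text(xml2::xml_find_all(parent, "./BiopaxRef"))
  sub("^pub_", "", refs)
}

#' Read a GPML 2013a XML file
#'
#' Inverse of [write_gpml()] on documents this package writes.  Unknown
#' attributes are ignored with a logged warning.  A `GraphRef` pointing at a
#' nonexistent element is a referential-integrity error; a root outside the
#' GPML 2013a namespace is a format error.
#'
#' @param path path to a `.gpml` file.
#' @return a `pb_gpml_pathway`.
#' @export
read_gpml <- function(path) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_root(doc)
  ns <- xml2::xml_ns(doc)
  if (!(GPML_NS %in% unlist(ns)) ||
      xml2::xml_name(root) != "Pathway")
    stop_pb(paste0(path, " is not a GPML 2013a document"),
            "pathbridge_format_error")
  xml2::xml_ns_strip(doc)

  known_attrs(root, c("Name", "Organism", "Author", "xmlns", "xmlns:bp",
                      "xmlns:rdf"), "Pathway")
  name <- xml2::xml_attr(root, "Name")
  organism <- xml2::xml_attr(root, "Organism")
  author_at <- xml2::xml_attr(root, "Author")
  authors <- if (is.na(author_at)) character() else
    trimws(strsplit(author_at, ",")[[1]])

  comments_all <- parse_comments_xml(root)
  is_maint <- vapply(comments_all, function(cm)
    identical(cm$source, "Maintainer"), TRUE)
  maintainers <- vapply(comments_all[is_maint], `[[`, "", "text")
  comments <- comments_all[!is_maint]

  gnode <- xml2::xml_find_first(root, "./Graphics")
  board <- c(as.numeric(xml2::xml_attr(gnode, "BoardWidth")),
             as.numeric(xml2::xml_attr(gnode, "BoardHeight")))

  data_nodes <- lapply(xml2::xml_find_all(root, "./DataNode"), function(dn) {
    known_attrs(dn, c("TextLabel", "GraphId", "Type", "GroupRef"), "DataNode")
    g <- xml2::xml_find_first(dn, "./Graphics")
    gr <- xml2::xml_attr(dn, "GroupRef")
    gpml_data_node(
      graph_id = xml2::xml_attr(dn, "GraphId"),
      text_label = xml2::xml_attr(dn, "TextLabel"),
      node_type = xml2::xml_attr(dn, "Type"),
      center = c(as.numeric(xml2::xml_attr(g, "CenterX")),
                 as.numeric(xml2::xml_attr(g, "CenterY"))),
      size = c(as.numeric(xml2::xml_attr(g, "Width")),
               as.numeric(xml2::xml_attr(g, "Height"))),
      group_ref = if (is.na(gr)) NULL else gr,
      xref = parse_xref_xml(dn),
      comments = parse_comments_xml(dn),
      literature = parse_bprefs_xml(dn))
  })

  rev_arrow <- stats::setNames(names(ARROW_ATTR), ARROW_ATTR)
  interactions <- lapply(xml2::xml_find_all(root, "./Interaction"),
                         function(ia) {
    g <- xml2::xml_find_first(ia, "./Graphics")
    points <- lapply(xml2::xml_find_all(g, "./Point"), function(pn) {
      gr <- xml2::xml_attr(pn, "GraphRef")
      ah <- xml2::xml_attr(pn, "ArrowHead")
      gpml_point(
        coords = c(as.numeric(xml2::xml_attr(pn, "X")),
                   as.numeric(xml2::xml_attr(pn, "Y"))),
        graph_ref = if (is.na(gr)) NULL else gr,
        arrow_head = if (is.na(ah)) "none" else rev_arrow[[ah]])
    })
    anchors <- lapply(xml2::xml_find_all(g, "./Anchor"), function(an)
      gpml_anchor(anchor_id = xml2::xml_attr(an, "GraphId"),
                  position = as.numeric(xml2::xml_attr(an, "Position"))))
    gpml_interaction(graph_id = xml2::xml_attr(ia, "GraphId"),
                     points = points, anchors = anchors,
                     xref = parse_xref_xml(ia),
                     comments = parse_comments_xml(ia),
                     literature = parse_bprefs_xml(ia))
  })

  labels <- lapply(xml2::xml_find_all(root, "./Label"), function(lb) {
    g <- xml2::xml_find_first(lb, "./Graphics")
    gpml_label(graph_id = xml2::xml_attr(lb, "GraphId"),
               text = xml2::xml_attr(lb, "TextLabel"),
               geometry = as.numeric(c(xml2::xml_attr(g, "CenterX"),
                                       xml2::xml_attr(g, "CenterY"),
                                       xml2::xml_attr(g, "Width"),
                                       xml2::xml_attr(g, "Height"))))
  })

  shapes <- lapply(xml2::xml_find_all(root, "./Shape"), function(sh) {
    g <- xml2::xml_find_first(sh, "./Graphics")
    tl <- xml2::xml_attr(sh, "TextLabel")
    gr <- xml2::xml_attr(sh, "GroupRef")
    gpml_shape(graph_id = xml2::xml_attr(sh, "GraphId"),
               shape_kind = xml2::xml_attr(g, "ShapeType"),
               geometry = as.numeric(c(xml2::xml_attr(g, "CenterX"),
                                       xml2::xml_attr(g, "CenterY"),
                                       xml2::xml_attr(g, "Width"),
                                       xml2::xml_attr(g, "Height"))),
               text_label = if (is.na(tl)) "" else tl,
               group_ref = if (is.na(gr)) NULL else gr,
               double_line = identical(xml2::xml_attr(g, "LineStyle"),
                                       "Double"))
  })

  groups <- lapply(xml2::xml_find_all(root, "./Group"), function(gn)
    gpml_group(group_id = xml2::xml_attr(gn, "GroupId"),
               style = xml2::xml_attr(gn, "Style")))

  p <- gpml_pathway(name = name,
                    organism = if (is.na(organism)) "" else organism,
                    comments = comments, authors = authors,
                    maintainers = maintainers, board = board,
                    data_nodes = data_nodes, interactions = interactions,
                    groups = groups, labels = labels, shapes = shapes)

  ids <- gpml_ids(p)
  all_ids <- c(ids$nodes, ids$anchors)
  for (i in p$interactions)
    for (pt in i$points)
      if (!is.null(pt$graph_ref) && !(pt$graph_ref %in% all_ids))
        stop_pb(paste0("GraphRef '", pt$graph_ref,
                       "' does not resolve in ", path),
                "pathbridge_reference_error")
  p
}
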