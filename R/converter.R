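#' @title Reaction-centric to GPML conversion
#'
#' @description
#' Conversion proceeds in three steps: (i) create a GPML pathway and carry
#' over the metadata (data source, source version, organism, authors,
#' maintainers); (ii) convert the elements -- entities become data nodes,
#' complexes and entity sets become groups with an in-diagram placeholder
#' node and their components are flattened to a deduplicated grid at the
#' bottom of the diagram, compartments become groups with a labelled
#' rectangle, notes become labels, and each reaction hyperedge is decomposed
#' into a backbone interaction plus one anchored interaction per additional
#' branch; (iii) annotate everything -- proteins preferably with UniProt,
#' metabolites with ChEBI, falling back to Reactome identifiers, while
#' interactions, complexes and pathway links take Reactome identifiers only,
#' and all PubMed literature references are carried over.
#' @name converter
NULL

#' Conversion options
#'
#' @param draw_components draw flattened complex/entity-set components in a
#'   grid at the bottom of the diagram (default `TRUE`).
#' @param columns grid columns for the component area.
#' @param cell_width,cell_height grid cell size in board units.
#' @param top_margin vertical gap between the lowest diagram element and the
#'   component grid.
#' @param preferred_sources named list mapping an entity class to the
#'   ordered data-source preference used for annotation.
#' @return a `pb_conversion_options` list.
#' @export
conversion_options <- function(draw_components = TRUE, columns = 10L,
                               cell_width = 100, cell_height = 30,
                               top_margin = 60,
                               preferred_sources = NULL) {
  if (!is_count1(columns))
    stop_pb("columns must be a positive integer", "pathbridge_validation_error")
  defaults <- list(
    protein = c("UniProt", "Reactome"),
    small_molecule = c("ChEBI", "Reactome"),
    rna = c("Ensembl", "Reactome"),
    gene = c("Ensembl", "Reactome"),
    process_node = "Reactome",
    complex = "Reactome",
    entity_set = "Reactome",
    other = "Reactome")
  if (!is.null(preferred_sources))
    defaults[names(preferred_sources)] <- preferred_sources
  structure(list(draw_components = isTRUE(draw_components),
                 columns = as.integer(columns),
                 cell_width = cell_width, cell_height = cell_height,
                 top_margin = top_margin, preferred_sources = defaults),
            class = "pb_conversion_options")
}

#' Map an entity class to a GPML data-node type
#'
#' Proteins map to `Protein`, small molecules to `Metabolite`, RNAs to
#' `Rna`, genes to `GeneProduct`, process nodes (sub-pathways) to `Pathway`
#' and anything unrecognised to `Unknown`.  Complexes and entity sets are
#' not node types -- they become groups -- so passing one is a contract
#' error directing the caller to [convert_container()].
#'
#' @param entity_class a source entity class string.
#' @return a GPML node type string.
#' @export
map_entity_class <- function(entity_class) {
  if (entity_class %in% CONTAINER_CLASSES)
    stop_pb(paste0("'", entity_class,
                   "' becomes a Group, not a data node; use convert_container"),
            "pathbridge_contract_error")
  switch(entity_class,
         protein = "Protein",
         small_molecule = "Metabolite",
         rna = "Rna",
         gene = "GeneProduct",
         process_node = "Pathway",
         other = "Unknown",
         stop_pb(paste0("unknown entity class '", entity_class, "'"),
                 "pathbridge_validation_error"))
}

#' Choose the annotation xref for an element
#'
#' Walks the ordered data-source preference and returns the first matching
#' cross-reference; `NULL` (with a logged note) when none matches.
#'
#' @param xrefs list of [xref()] in document order.
#' @param preference character vector of data sources in preference order.
#' @param label element label used in the log message.
#' @return an [xref()] or `NULL`.
#' @export
annotate_element <- function(xrefs, preference, label = "<element>") {
  for (src in preference)
    for (x in xrefs)
      if (x$data_source == src) return(x)
  pb_log("no ", paste(preference, collapse = "/"),
         " annotation for ", label)
  NULL
}

# deterministic id factory: kind prefix + zero-padded counter
id_factory <- function() {
  counters <- new.env(parent = emptyenv())
  function(prefix) {
    n <- (get0(prefix, envir = counters) %||% 0L) + 1L
    assign(prefix, n, envir = counters)
    sprintf("%s_%04d", prefix, n)
  }
}

# recursive leaf expansion of a container: non-container entities reachable
# through complex/entity_set membership, in depth-first document order
expand_components <- function(entity_id, entity_index) {
  e <- entity_index[[entity_id]]
  out <- list()
  for (cm in e$components) {
    child <- entity_index[[cm$ref]]
    if (child$entity_class %in% CONTAINER_CLASSES)
      out <- c(out, expand_components(cm$ref, entity_index))
    else
      out <- c(out, list(list(entity_id = cm$ref,
                              stoichiometry = cm$stoichiometry %||% 1L,
                              via = entity_id)))
  }
  out
}

component_key <- function(e) {
  if (length(e$xrefs) > 0) xref_key(e$xrefs[[1]]) else e$display_name
}

#' Convert a complex or entity set to a GPML group and placeholder node
#'
#' A complex becomes a group with style `"Complex"`, an entity set a group
#' with style `"Group"`; both get one in-diagram placeholder data node of
#' type `Complex` carrying the container's label and Reactome annotation.
#' The component data nodes themselves are emitted by
#' [flatten_components()], not here.
#'
#' @param e a `pb_source_entity` with class `complex` or `entity_set`.
#' @param opts [conversion_options()].
#' @param new_id id factory (internal use); fresh ids are generated when
#'   omitted.
#' @return list with elements `group`, `placeholder`.
#' @export
convert_container <- function(e, opts = conversion_options(),
                              new_id = id_factory()) {
  if (!(e$entity_class %in% CONTAINER_CLASSES))
    stop_pb(paste0("'", e$entity_id, "' is not a complex or entity set"),
            "pathbridge_contract_error")
  if (length(e$components) == 0)
    stop_pb(paste0("container '", e$entity_id, "' has no components"),
            "pathbridge_validation_error")
  style <- if (e$entity_class == "complex") "Complex" else "Group"
  grp <- gpml_group(new_id("grp"), style = style)
  node <- gpml_data_node(
    graph_id = new_id("dn"),
    text_label = e$display_name,
    node_type = "Complex",
    center = e$geometry[1:2], size = e$geometry[3:4],
    group_ref = grp$group_id,
    xref = annotate_element(e$xrefs, opts$preferred_sources[[e$entity_class]],
                            e$display_name),
    literature = e$literature)
  list(group = grp, placeholder = node)
}

#' Decompose a reaction hyperedge into GPML interactions
#'
#' One backbone interaction follows the reaction's backbone polyline; its
#' end arrowhead encodes the reaction type (`mim_conversion` for
#' transitions, `mim_binding` for bindings, `arrow` otherwise).  When the
#' reaction has inputs/outputs, the first input and first output (document
#' order) attach directly to the backbone endpoints.  Every additional
#' input or output, and every catalyst, activator and inhibitor, becomes
#' its own interaction joined to a fresh anchor on the backbone; anchors
#' are evenly spaced at fractions k/(m+1).  Branch arrowheads: outputs get
#' `arrow` at the node end; catalysts `mim_catalysis`, activators
#' `mim_stimulation` and inhibitors `t_bar` at the anchor end; extra inputs
#' carry no arrowhead.
#'
#' @param r a `pb_source_reaction`.
#' @param node_index named character vector: entity_id -> data-node
#'   graph_id.
#' @param node_centers named list: entity_id -> numeric `c(x, y)`.
#' @param new_id id factory; fresh ids generated when omitted.
#' @return list with elements `backbone` (one `pb_gpml_interaction`) and
#'   `branches` (list of `pb_gpml_interaction`).
#' @export
convert_hyperedge <- function(r, node_index, node_centers,
                              new_id = id_factory()) {
  roles <- vapply(r$branches, `[[`, "", "role")
  for (b in r$branches)
    if (is.na(node_index[b$entity_id]))
      stop_pb(paste0("reaction '", r$reaction_id, "': branch entity '",
                     b$entity_id, "' has no data node"),
              "pathbridge_reference_error")

  first_of <- function(role) {
    k <- which(roles == role)
    if (length(k) == 0) NULL else r$branches[[k[1]]]
  }
  first_in <- first_of("input")
  first_out <- first_of("output")
  # anchored branches, in the fixed order: extra inputs, extra outputs,
  # catalysts, activators, inhibitors
  anchored <- list()
  for (role in c("input", "output", "catalyst", "activator", "inhibitor")) {
    ks <- which(roles == role)
    if (role %in% c("input", "output") && length(ks) > 0)
      ks <- ks[-1]                       # first one sits on the endpoint
    for (k in ks) anchored[[length(anchored) + 1]] <- r$branches[[k]]
  }

  m <- length(anchored)
  bb_pts <- r$backbone_points
  end_arrow <- switch(r$reaction_type,
                      transition = "mim_conversion",
                      binding = "mim_binding",
                      "arrow")
  points <- vector("list", length(bb_pts))
  for (k in seq_along(bb_pts))
    points[[k]] <- gpml_point(bb_pts[[k]])
  if (!is.null(first_in))
    points[[1]] <- gpml_point(bb_pts[[1]],
                              graph_ref = node_index[[first_in$entity_id]])
  last <- length(points)
  points[[last]] <- gpml_point(
    bb_pts[[last]],
    graph_ref = if (!is.null(first_out)) node_index[[first_out$entity_id]],
    arrow_head = end_arrow)

  anchors <- list()
  branch_edges <- list()
  if (m > 0) {
    pos <- seq_len(m) / (m + 1)
    for (k in seq_len(m)) {
      b <- anchored[[k]]
      a <- gpml_anchor(new_id("an"), pos[k])
      anchors[[k]] <- a
      axy <- polyline_point(bb_pts, pos[k])
      nid <- node_index[[b$entity_id]]
      nxy <- node_centers[[b$entity_id]]
      pts <- switch(b$role,
        output = list(gpml_point(axy, graph_ref = a$anchor_id),
                      gpml_point(nxy, graph_ref = nid, arrow_head = "arrow")),
        input = list(gpml_point(nxy, graph_ref = nid),
                     gpml_point(axy, graph_ref = a$anchor_id)),
        catalyst = list(gpml_point(nxy, graph_ref = nid),
                        gpml_point(axy, graph_ref = a$anchor_id,
                                   arrow_head = "mim_catalysis")),
        activator = list(gpml_point(nxy, graph_ref = nid),
                         gpml_point(axy, graph_ref = a$anchor_id,
                                    arrow_head = "mim_stimulation")),
        inhibitor = list(gpml_point(nxy, graph_ref = nid),
                         gpml_point(axy, graph_ref = a$anchor_id,
                                    arrow_head = "t_bar")))
      branch_edges[[k]] <- gpml_interaction(new_id("br"), pts)
    }
  }

  backbone <- gpml_interaction(
    new_id("bb"), points, anchors = anchors,
    xref = annotate_element(r$xrefs, "Reactome", r$reaction_id),
    literature = r$literature)
  list(backbone = backbone, branches = branch_edges)
}

# point at fraction t of the arc length of a polyline given as list of c(x,y)
polyline_point <- function(pts, t) {
  m <- do.call(rbind, pts)
  seg <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
  total <- sum(seg)
  if (total == 0) return(m[1, ])
  target <- t * total
  acc <- 0
  for (k in seq_along(seg)) {
    if (acc + seg[k] >= target) {
      f <- if (seg[k] == 0) 0 else (target - acc) / seg[k]
      return(m[k, ] + f * (m[k + 1, ] - m[k, ]))
    }
    acc <- acc + seg[k]
  }
  m[nrow(m), ]
}

#' Flatten complex/entity-set components into a bottom grid
#'
#' Recursively expands every container down to its non-container components
#' and lays the unique ones out left-to-right, top-to-bottom in a grid
#' below the lowest diagram element.  The deduplication key is the primary
#' (first) cross-reference when present, the display name otherwise.
#' Duplicate occurrences are not drawn but are preserved as hidden entries
#' (pathway comments).  Entity-set member stoichiometry is ignored (sets
#' are alternatives, not assemblies); complex member stoichiometry above 1
#' is recorded in a comment on the component node.
#'
#' @param p a `pb_source_pathway`.
#' @param opts [conversion_options()].
#' @param container_nodes named character vector: container entity_id ->
#'   placeholder graph_id (as produced by [convert_container()]).
#' @param diagram_bottom y coordinate below which the grid starts.
#' @param new_id id factory; fresh ids generated when omitted.
#' @return list with `nodes` (component data nodes), `component_map`
#'   (named list: placeholder graph_id -> component graph_ids),
#'   `hidden` (character vector of "<placeholder> <key>" duplicate records).
#' @export
flatten_components <- function(p, opts = conversion_options(),
                               container_nodes = NULL,
                               diagram_bottom = 0,
                               new_id = id_factory()) {
  entity_index <- stats::setNames(p$entities,
                                  vapply(p$entities, `[[`, "", "entity_id"))
  containers <- Filter(function(e) e$entity_class %in% CONTAINER_CLASSES,
                       p$entities)
  if (is.null(container_nodes)) {
    container_nodes <- stats::setNames(
      vapply(containers, `[[`, "", "entity_id"),
      vapply(containers, `[[`, "", "entity_id"))
  }
  key_to_node <- character()      # dedup key -> drawn graph_id
  nodes <- list()
  component_map <- list()
  hidden <- character()
  order_keys <- character()

  for (e in containers) {
    leaves <- expand_components(e$entity_id, entity_index)
    gid <- container_nodes[[e$entity_id]]
    ids_for_container <- character()
    for (lf in leaves) {
      ce <- entity_index[[lf$entity_id]]
      key <- component_key(ce)
      if (is.na(key_to_node[key] %||% NA_character_)) {
        node_id <- new_id("cmp")
        cmts <- list()
        if (lf$stoichiometry > 1 && e$entity_class == "complex")
          cmts <- list(list(source = "Stoichiometry",
                            text = paste0(lf$via, " x", lf$stoichiometry)))
        nodes[[length(nodes) + 1]] <- gpml_data_node(
          graph_id = node_id,
          text_label = ce$display_name,
          node_type = map_entity_class(ce$entity_class),
          center = c(0, 0), size = c(opts$cell_width - 10,
                                     opts$cell_height - 10),
          xref = annotate_element(ce$xrefs,
                                  opts$preferred_sources[[ce$entity_class]],
                                  ce$display_name),
          comments = cmts)
        key_to_node[key] <- node_id
        order_keys <- c(order_keys, key)
      } else {
        hidden <- c(hidden, paste(gid, key))
      }
      ids_for_container <- c(ids_for_container, key_to_node[[key]])
    }
    component_map[[gid]] <- unique(ids_for_container)
  }

  # grid placement in first-encounter order
  for (k in seq_along(nodes)) {
    col <- (k - 1L) %% opts$columns
    row <- (k - 1L) %/% opts$columns
    nodes[[k]]$center <- c(20 + col * opts$cell_width + opts$cell_width / 2,
                           diagram_bottom + opts$top_margin +
                             row * opts$cell_height + opts$cell_height / 2)
  }
  list(nodes = nodes, component_map = component_map, hidden = hidden)
}

#' Convert a source pathway to a GPML document
#'
#' Runs the full three-step conversion (see the package vignette): metadata,
#' element conversion with hyperedge decomposition and component
#' flattening, and annotation.  The output is deterministic: converting the
#' same pathway twice yields byte-identical GPML.
#'
#' The complex-component linkage is recorded twice: as a machine-readable
#' comment (source `"ComplexComponents"`) on every container placeholder
#' node, recoverable with [read_component_map()], and as a `"conversion"`
#' attribute on the returned object carrying the full entity/reaction to
#' graph-id mapping for programmatic use.
#'
#' @param p a valid `pb_source_pathway`.
#' @param opts [conversion_options()].
#' @return a `pb_gpml_pathway`; attribute `"conversion"` holds the mapping
#'   record (`entity_nodes`, `reaction_backbones`, `component_map`,
#'   `hidden`).
#' @export
convert_pathway <- function(p, opts = conversion_options()) {
  viol <- validate_source_pathway(p)
  if (nrow(viol) > 0)
    stop_pb(paste0(viol$element, ": ", viol$rule, collapse = "; "),
            "pathbridge_validation_error")
  new_id <- id_factory()

  comments <- list(list(source = "DataSource", text = "Reactome"),
                   list(source = "Version", text = p$source_version))
  maintainers <- vapply(p$maintainers, function(m)
    if (nzchar(m$email %||% "")) paste0(m$name, " <", m$email, ">")
    else m$name, "")

  data_nodes <- list()
  groups <- list()
  entity_nodes <- character()
  placeholder_of <- character()   # container entity_id -> placeholder gid

  for (e in p$entities) {
    if (e$entity_class %in% CONTAINER_CLASSES) {
      cc <- convert_container(e, opts, new_id)
      groups[[length(groups) + 1]] <- cc$group
      data_nodes[[length(data_nodes) + 1]] <- cc$placeholder
      entity_nodes[e$entity_id] <- cc$placeholder$graph_id
      placeholder_of[e$entity_id] <- cc$placeholder$graph_id
    } else {
      node <- gpml_data_node(
        graph_id = new_id("dn"),
        text_label = e$display_name,
        node_type = map_entity_class(e$entity_class),
        center = e$geometry[1:2], size = e$geometry[3:4],
        xref = annotate_element(e$xrefs,
                                opts$preferred_sources[[e$entity_class]],
                                e$display_name),
        literature = e$literature)
      data_nodes[[length(data_nodes) + 1]] <- node
      entity_nodes[e$entity_id] <- node$graph_id
    }
  }

  node_centers <- stats::setNames(
    lapply(p$entities, function(e) e$geometry[1:2]),
    vapply(p$entities, `[[`, "", "entity_id"))

  interactions <- list()
  reaction_backbones <- character()
  for (r in p$reactions) {
    he <- convert_hyperedge(r, entity_nodes, node_centers, new_id)
    interactions <- c(interactions, list(he$backbone), he$branches)
    reaction_backbones[r$reaction_id] <- he$backbone$graph_id
  }

  labels <- lapply(p$notes, function(nt)
    gpml_label(new_id("lab"), nt$text,
               geometry = c(nt$position, 90, 25)))

  # compartments: group + labelled rectangle; membership by geometric
  # containment of node centers (container-group membership wins)
  shapes <- list()
  for (cp in p$compartments) {
    grp <- gpml_group(new_id("grp"), style = "Group")
    sh <- gpml_shape(new_id("shp"), shape_kind = "Rectangle",
                     geometry = c(cp$geometry[1] + cp$geometry[3] / 2,
                                  cp$geometry[2] + cp$geometry[4] / 2,
                                  cp$geometry[3], cp$geometry[4]),
                     text_label = cp$name, group_ref = grp$group_id,
                     double_line = cp$membrane)
    members <- 0L
    for (k in seq_along(data_nodes)) {
      n <- data_nodes[[k]]
      if (!is.null(n$group_ref)) next
      inside <- n$center[1] >= cp$geometry[1] &&
        n$center[1] <= cp$geometry[1] + cp$geometry[3] &&
        n$center[2] >= cp$geometry[2] &&
        n$center[2] <= cp$geometry[2] + cp$geometry[4]
      if (inside) {
        data_nodes[[k]]$group_ref <- grp$group_id
        members <- members + 1L
      }
    }
    shapes[[length(shapes) + 1]] <- sh
    groups[[length(groups) + 1]] <- grp
  }

  draft <- gpml_pathway(name = p$name, organism = p$organism,
                        comments = comments, maintainers = maintainers,
                        authors = p$authors,
                        data_nodes = data_nodes,
                        interactions = interactions, groups = groups,
                        labels = labels, shapes = shapes)
  bb <- element_bbox(draft)
  diagram_bottom <- if (is.null(bb)) 0 else bb[4]

  component_map <- list()
  hidden <- character()
  if (opts$draw_components) {
    fl <- flatten_components(p, opts, container_nodes = placeholder_of,
                             diagram_bottom = diagram_bottom,
                             new_id = new_id)
    draft$data_nodes <- c(draft$data_nodes, fl$nodes)
    component_map <- fl$component_map
    hidden <- fl$hidden
    # persist the linkage in GPML comments
    for (k in seq_along(draft$data_nodes)) {
      gid <- draft$data_nodes[[k]]$graph_id
      if (!is.null(component_map[[gid]]))
        draft$data_nodes[[k]]$comments <- c(
          draft$data_nodes[[k]]$comments,
          list(list(source = "ComplexComponents",
                    text = paste(component_map[[gid]], collapse = " "))))
    }
    for (h in hidden)
      draft$comments <- c(draft$comments,
                          list(list(source = "HiddenComponent", text = h)))
  }

  bb <- element_bbox(draft)
  draft$board <- if (is.null(bb)) c(500, 500) else
    c(max(bb[3] + 20, 100), max(bb[4] + 20, 100))

  structure(draft, conversion = list(entity_nodes = entity_nodes,
                                     reaction_backbones = reaction_backbones,
                                     component_map = component_map,
                                     hidden = hidden))
}

#' Recover the complex-component linkage from a GPML document
#'
#' Reads the `"ComplexComponents"` comments written by [convert_pathway()].
#'
#' @param p a `pb_gpml_pathway`.
#' @return named list: container placeholder graph_id -> character vector
#'   of component data-node graph_ids.
#' @export
read_component_map <- function(p) {
  out <- list()
  for (n in p$data_nodes)
    for (cm in n$comments)
      if (identical(cm$source, "ComplexComponents"))
        out[[n$graph_id]] <- strsplit(cm$text, " ", fixed = TRUE)[[1]]
  out
}

#' Recover (interaction, role, participant) triples from converted GPML
#'
#' Structural inverse of the hyperedge decomposition: an interaction owning
#' anchors (or attached to no anchor) is a backbone; interactions whose
#' endpoint references an anchor are branches.  Roles are read back from
#' endpoint positions (backbone start = input, end = output) and branch
#' arrowheads.
#'
#' @param p a `pb_gpml_pathway`.
#' @return data frame with columns `backbone`, `role`, `node`.
#' @export
recover_participants <- function(p) {
  anchor_owner <- character()
  for (i in p$interactions)
    for (a in i$anchors) anchor_owner[a$anchor_id] <- i$graph_id
  node_ids <- vapply(p$data_nodes, `[[`, "", "graph_id")

  rows <- list()
  emit <- function(backbone, role, node)
    rows[[length(rows) + 1]] <<- data.frame(backbone = backbone, role = role,
                                            node = node,
                                            stringsAsFactors = FALSE)
  for (i in p$interactions) {
    first <- i$points[[1]]
    last <- i$points[[length(i$points)]]
    refs <- c(first$graph_ref %||% NA_character_,
              last$graph_ref %||% NA_character_)
    anchor_ref <- refs[!is.na(refs) & refs %in% names(anchor_owner)]
    if (length(anchor_ref) > 0) {
      # branch edge
      bb <- anchor_owner[[anchor_ref[1]]]
      node_ref <- refs[!is.na(refs) & refs %in% node_ids]
      if (length(node_ref) == 0) next
      heads <- c(first$arrow_head, last$arrow_head)
      role <-
        if ("mim_catalysis" %in% heads) "catalyst"
        else if ("mim_stimulation" %in% heads) "activator"
        else if ("t_bar" %in% heads) "inhibitor"
        else if (identical(last$graph_ref, node_ref[1]) &&
                 last$arrow_head == "arrow") "output"
        else "input"
      emit(bb, role, node_ref[1])
    } else {
      # backbone (or plain edge)
      if (!is.null(first$graph_ref) && first$graph_ref %in% node_ids)
        emit(i$graph_id, "input", first$graph_ref)
      if (!is.null(last$graph_ref) && last$graph_ref %in% node_ids)
        emit(i$graph_id, "output", last$graph_ref)
    }
  }
  if (length(rows) == 0)
    return(data.frame(backbone = character(), role = character(),
                      node = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
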