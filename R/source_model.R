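#' @title Reaction-centric source pathway model
#'
#' @description
#' The converter consumes pathways in a reaction-centric model mirroring how
#' pathway databases such as Reactome organise their content: entities
#' (proteins, small molecules, RNAs, genes, sub-pathway process nodes,
#' complexes and entity sets) participate in reactions through role-typed
#' branches (input, output, catalyst, activator, inhibitor), and a reaction
#' carries its own backbone polyline in diagram coordinates.  Complexes are
#' molecular assemblies; entity sets group alternative entities that play the
#' same role in a reaction.  The model is exchanged as a JSON document whose
#' schema ships with the package (`inst/extdata/source-pathway.schema.json`).
#'
#' Coordinates are diagram units, origin top-left, y increasing downward --
#' the same convention GPML uses, so conversion needs no axis flip.
#' @name source_model
NULL

ENTITY_CLASSES <- c("protein", "small_molecule", "rna", "gene",
                    "process_node", "complex", "entity_set", "other")
CONTAINER_CLASSES <- c("complex", "entity_set")
BRANCH_ROLES <- c("input", "output", "catalyst", "activator", "inhibitor")
REACTION_TYPES <- c("transition", "binding", "dissociation", "omitted",
                    "uncertain")
DATA_SOURCES <- c("UniProt", "ChEBI", "Reactome", "Ensembl", "HMDB",
                  "PubMed", "Other")

#' Cross-reference to an external database
#'
#' @param data_source one of `"UniProt"`, `"ChEBI"`, `"Reactome"`,
#'   `"Ensembl"`, `"HMDB"`, `"PubMed"`, `"Other"`.
#' @param identifier nonempty identifier string; surrounding whitespace is
#'   rejected.
#' @return an object of class `pb_xref`.
#' @export
xref <- function(data_source, identifier) {
  if (!is.character(data_source) || length(data_source) != 1 ||
      !(data_source %in% DATA_SOURCES))
    stop_pb(paste0("unknown data source '", data_source, "'"),
            "pathbridge_validation_error")
  if (!is.character(identifier) || length(identifier) != 1 ||
      !nzchar(identifier) || identifier != trimws(identifier))
    stop_pb("identifier must be a nonempty string without surrounding whitespace",
            "pathbridge_validation_error")
  structure(list(data_source = data_source, identifier = identifier),
            class = "pb_xref")
}

xref_key <- function(x) paste0(x$data_source, ":", x$identifier)

#' Pathway entity
#'
#' @param entity_id id unique within the pathway.
#' @param display_name label shown on the diagram.
#' @param entity_class one of `protein`, `small_molecule`, `rna`, `gene`,
#'   `process_node`, `complex`, `entity_set`, `other`.
#' @param geometry numeric `c(center_x, center_y, width, height)`.
#' @param compartment_id optional compartment id.
#' @param xrefs list of [xref()] in preference order.
#' @param components for complexes/entity sets: list of
#'   `list(ref = <entity_id>, stoichiometry = <positive integer>)`.
#' @param literature character vector of PubMed identifiers.
#' @return an object of class `pb_source_entity`.
#' @export
source_entity <- function(entity_id, display_name, entity_class,
                          geometry = c(0, 0, 80, 20), compartment_id = NULL,
                          xrefs = list(), components = list(),
                          literature = character()) {
  structure(list(entity_id = entity_id, display_name = display_name,
                 entity_class = entity_class,
                 compartment_id = compartment_id,
                 xrefs = xrefs, components = components,
                 geometry = as.numeric(geometry),
                 literature = as.character(literature)),
            class = "pb_source_entity")
}

#' Role-typed reaction branch
#' @param role one of `input`, `output`, `catalyst`, `activator`, `inhibitor`.
#' @param entity_id id of the participating entity.
#' @param stoichiometry positive integer, default 1.
#' @export
reaction_branch <- function(role, entity_id, stoichiometry = 1L) {
  structure(list(role = role, entity_id = entity_id,
                 stoichiometry = as.integer(stoichiometry)),
            class = "pb_reaction_branch")
}

#' Reaction (hyperedge)
#'
#' @param reaction_id id unique within the pathway.
#' @param branches list of [reaction_branch()].
#' @param backbone_points list of `c(x, y)` pairs, length at least 2.
#' @param reaction_type one of `transition`, `binding`, `dissociation`,
#'   `omitted`, `uncertain`.
#' @param xrefs,literature as for [source_entity()].
#' @export
source_reaction <- function(reaction_id, branches, backbone_points,
                            reaction_type = "transition", xrefs = list(),
                            literature = character()) {
  structure(list(reaction_id = reaction_id, reaction_type = reaction_type,
                 branches = branches,
                 backbone_points = lapply(backbone_points, as.numeric),
                 xrefs = xrefs, literature = as.character(literature)),
            class = "pb_source_reaction")
}

#' Compartment (cellular location rectangle)
#' @param compartment_id,name identifiers.
#' @param geometry numeric `c(x, y, width, height)` (top-left corner).
#' @param membrane whether drawn with a double-line membrane border.
#' @export
source_compartment <- function(compartment_id, name, geometry,
                               membrane = FALSE) {
  structure(list(compartment_id = compartment_id, name = name,
                 geometry = as.numeric(geometry),
                 membrane = isTRUE(membrane)),
            class = "pb_source_compartment")
}

#' Free-text note
#' @param text nonempty note text.
#' @param position numeric `c(x, y)`.
#' @export
source_note <- function(text, position = c(0, 0)) {
  structure(list(text = text, position = as.numeric(position)),
            class = "pb_source_note")
}

#' Assemble a source pathway
#'
#' @param name,organism,source_version pathway metadata.
#' @param authors character vector of author names.
#' @param maintainers list of `list(name =, email =)`.
#' @param entities,reactions,compartments,notes model element lists.
#' @param xref optional pathway-level [xref()].
#' @return an object of class `pb_source_pathway`.
#' @export
source_pathway <- function(name, organism = "Homo sapiens",
                           source_version = "0", authors = character(),
                           maintainers = list(), entities = list(),
                           reactions = list(), compartments = list(),
                           notes = list(), xref = NULL) {
  structure(list(name = name, organism = organism,
                 source_version = as.character(source_version),
                 authors = as.character(authors), maintainers = maintainers,
                 entities = entities, reactions = reactions,
                 compartments = compartments, notes = notes, xref = xref),
            class = "pb_source_pathway")
}

#' @export
print.pb_source_pathway <- function(x, ...) {
  cat("Source pathway: ", x$name, " (", x$organism, ")\n", sep = "")
  cat("  entities:     ", length(x$entities), "\n")
  cat("  reactions:    ", length(x$reactions), "\n")
  cat("  compartments: ", length(x$compartments), "\n")
  cat("  notes:        ", length(x$notes), "\n")
  invisible(x)
}

violation <- function(element, rule) {
  data.frame(element = element, rule = rule, stringsAsFactors = FALSE)
}

#' Validate a source pathway against the model invariants
#'
#' Checks id uniqueness, referential integrity of branch and component
#' references, positivity of geometry and stoichiometry, the restriction of
#' components to complexes/entity sets, backbone length, and branch role /
#' entity class constraints.  Violations are returned, never raised.
#'
#' @param p a `pb_source_pathway`.
#' @return a data frame with columns `element` and `rule`; zero rows when
#'   the pathway is valid.
#' @export
validate_source_pathway <- function(p) {
  v <- list()
  add <- function(el, rule) v[[length(v) + 1]] <<- violation(el, rule)

  ids <- vapply(p$entities, `[[`, "", "entity_id")
  if (anyDuplicated(ids))
    for (d in unique(ids[duplicated(ids)]))
      add(d, "duplicate entity_id")
  classes <- vapply(p$entities, `[[`, "", "entity_class")
  names(classes) <- ids

  for (e in p$entities) {
    if (!(e$entity_class %in% ENTITY_CLASSES))
      add(e$entity_id, paste0("unknown entity_class '", e$entity_class, "'"))
    g <- e$geometry
    if (length(g) != 4 || any(!is.finite(g)) || g[3] <= 0 || g[4] <= 0)
      add(e$entity_id, "geometry must be (cx, cy, width>0, height>0)")
    if (length(e$components) > 0 &&
        !(e$entity_class %in% CONTAINER_CLASSES))
      add(e$entity_id, "components only allowed on complex/entity_set")
    if (e$entity_class %in% CONTAINER_CLASSES &&
        length(e$components) == 0)
      add(e$entity_id, "complex/entity_set must have components")
    for (cm in e$components) {
      if (!(cm$ref %in% ids))
        add(e$entity_id,
            paste0("component reference '", cm$ref, "' does not resolve"))
      s <- cm$stoichiometry %||% 1L
      if (!is_count1(s))
        add(e$entity_id, "component stoichiometry must be a positive integer")
    }
    if (!is.null(e$compartment_id)) {
      cids <- vapply(p$compartments, `[[`, "", "compartment_id")
      if (!(e$compartment_id %in% cids))
        add(e$entity_id,
            paste0("compartment '", e$compartment_id, "' does not resolve"))
    }
    for (x in e$xrefs)
      if (!(x$data_source %in% DATA_SOURCES))
        add(e$entity_id, paste0("unknown xref data source '", x$data_source, "'"))
  }

  rids <- vapply(p$reactions, `[[`, "", "reaction_id")
  if (anyDuplicated(rids))
    for (d in unique(rids[duplicated(rids)]))
      add(d, "duplicate reaction_id")
  for (r in p$reactions) {
    if (!(r$reaction_type %in% REACTION_TYPES))
      add(r$reaction_id, paste0("unknown reaction_type '", r$reaction_type, "'"))
    roles <- vapply(r$branches, `[[`, "", "role")
    if (!any(roles %in% c("input", "output")))
      add(r$reaction_id, "reaction needs at least one input or output branch")
    for (b in r$branches) {
      if (!(b$role %in% BRANCH_ROLES))
        add(r$reaction_id, paste0("unknown branch role '", b$role, "'"))
      if (!(b$entity_id %in% ids))
        add(r$reaction_id,
            paste0("branch entity '", b$entity_id, "' does not resolve"))
      else if (classes[[b$entity_id]] == "process_node")
        add(r$reaction_id,
            paste0("branch entity '", b$entity_id, "' is a process_node"))
      if (!is_count1(b$stoichiometry %||% 1L))
        add(r$reaction_id, "branch stoichiometry must be a positive integer")
    }
    if (length(r$backbone_points) < 2)
      add(r$reaction_id, "backbone needs at least 2 points")
  }

  for (cp in p$compartments) {
    g <- cp$geometry
    if (length(g) != 4 || g[3] <= 0 || g[4] <= 0)
      add(cp$compartment_id, "geometry must be (x, y, width>0, height>0)")
  }
  for (nt in p$notes)
    if (!nzchar(trimws(nt$text)))
      add("<note>", "note text must be nonempty")

  if (length(v) == 0)
    return(data.frame(element = character(), rule = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}

parse_xref_json <- function(j) xref(j$dataSource, j$identifier)

#' Read a source pathway from its JSON document format
#'
#' The document format is described by the JSON schema shipped at
#' `system.file("extdata", "source-pathway.schema.json", package =
#' "pathbridge")`.  Stoichiometry defaults to 1 when omitted.
#'
#' @param path path to a JSON file.
#' @return a validated `pb_source_pathway`.
#' @export
read_source_pathway <- function(path) {
  if (!file.exists(path))
    stop_pb(paste0("no such file: ", path), "pathbridge_io_error")
  j <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop_pb(paste0("malformed JSON in ", path, ": ",
                                       conditionMessage(e)),
                                "pathbridge_parse_error"))
  p <- source_pathway_from_list(j)
  viol <- validate_source_pathway(p)
  if (nrow(viol) > 0) {
    ref <- grepl("does not resolve", viol$rule)
    msg <- paste0(viol$element, ": ", viol$rule, collapse = "; ")
    stop_pb(msg, if (any(ref)) "pathbridge_reference_error"
            else "pathbridge_validation_error")
  }
  p
}

source_pathway_from_list <- function(j) {
  req <- function(obj, field, ctx) {
    if (is.null(obj[[field]]))
      stop_pb(paste0("missing required field '", field, "' in ", ctx),
              "pathbridge_validation_error")
    obj[[field]]
  }
  ent <- lapply(j$entities %||% list(), function(e) {
    g <- req(e, "geometry", paste0("entity '", e$id %||% "?", "'"))
    source_entity(
      entity_id = req(e, "id", "entity"),
      display_name = req(e, "displayName", paste0("entity '", e$id, "'")),
      entity_class = req(e, "class", paste0("entity '", e$id, "'")),
      geometry = c(g$centerX, g$centerY, g$width, g$height),
      compartment_id = e$compartment,
      xrefs = lapply(e$xrefs %||% list(), parse_xref_json),
      components = lapply(e$components %||% list(), function(cm)
        list(ref = req(cm, "ref", "component"),
             stoichiometry = as.integer(cm$stoichiometry %||% 1L))),
      literature = unlist(e$literature %||% list()) %||% character())
  })
  rea <- lapply(j$reactions %||% list(), function(r) {
    source_reaction(
      reaction_id = req(r, "id", "reaction"),
      reaction_type = r$type %||% "transition",
      branches = lapply(req(r, "branches", paste0("reaction '", r$id, "'")),
                        function(b)
        reaction_branch(req(b, "role", "branch"),
                        req(b, "entityId", "branch"),
                        as.integer(b$stoichiometry %||% 1L))),
      backbone_points = lapply(
        req(r, "backbonePoints", paste0("reaction '", r$id, "'")),
        function(pt) c(pt[[1]], pt[[2]])),
      xrefs = lapply(r$xrefs %||% list(), parse_xref_json),
      literature = unlist(r$literature %||% list()) %||% character())
  })
  cmp <- lapply(j$compartments %||% list(), function(cp) {
    g <- req(cp, "geometry", paste0("compartment '", cp$id %||% "?", "'"))
    source_compartment(req(cp, "id", "compartment"),
                       req(cp, "name", "compartment"),
                       c(g$x, g$y, g$width, g$height),
                       isTRUE(cp$membrane))
  })
  nts <- lapply(j$notes %||% list(), function(nt)
    source_note(req(nt, "text", "note"),
                c(nt$position[[1]] %||% 0, nt$position[[2]] %||% 0)))
  source_pathway(
    name = req(j, "name", "pathway"),
    organism = j$organism %||% "Homo sapiens",
    source_version = as.character(j$sourceVersion %||% "0"),
    authors = unlist(j$authors %||% list()) %||% character(),
    maintainers = lapply(j$maintainers %||% list(), function(m)
      list(name = m$name, email = m$email %||% "")),
    entities = ent, reactions = rea, compartments = cmp, notes = nts,
    xref = if (!is.null(j$xref)) parse_xref_json(j$xref))
}

#' Write a source pathway to the JSON document format
#'
#' Inverse of [read_source_pathway()]; used to publish fixtures.  Output is
#' deterministic (fixed key order, no timestamps).
#'
#' @param p a `pb_source_pathway`.
#' @param path output path.
#' @export
write_source_pathway <- function(p, path) {
  xr <- function(x) list(dataSource = x$data_source, identifier = x$identifier)
  doc <- list(
    name = p$name, organism = p$organism, sourceVersion = p$source_version,
    authors = as.list(p$authors),
    maintainers = lapply(p$maintainers, function(m)
      list(name = m$name, email = m$email)),
    entities = lapply(p$entities, function(e) {
      o <- list(id = e$entity_id, displayName = e$display_name,
                class = e$entity_class,
                geometry = list(centerX = e$geometry[1],
                                centerY = e$geometry[2],
                                width = e$geometry[3],
                                height = e$geometry[4]))
      if (!is.null(e$compartment_id)) o$compartment <- e$compartment_id
      if (length(e$xrefs)) o$xrefs <- lapply(e$xrefs, xr)
      if (length(e$components))
        o$components <- lapply(e$components, function(cm)
          list(ref = cm$ref, stoichiometry = cm$stoichiometry %||% 1L))
      if (length(e$literature)) o$literature <- as.list(e$literature)
      o
    }),
    reactions = lapply(p$reactions, function(r) {
      o <- list(id = r$reaction_id, type = r$reaction_type,
                branches = lapply(r$branches, function(b)
                  list(role = b$role, entityId = b$entity_id,
                       stoichiometry = b$stoichiometry %||% 1L)),
                backbonePoints = lapply(r$backbone_points, as.list))
      if (length(r$xrefs)) o$xrefs <- lapply(r$xrefs, xr)
      if (length(r$literature)) o$literature <- as.list(r$literature)
      o
    }),
    compartments = lapply(p$compartments, function(cp)
      list(id = cp$compartment_id, name = cp$name,
           geometry = list(x = cp$geometry[1], y = cp$geometry[2],
                           width = cp$geometry[3], height = cp$geometry[4]),
           membrane = cp$membrane)),
    notes = lapply(p$notes, function(nt)
      list(text = nt$text, position = as.list(nt$position))))
  if (!is.null(p$xref)) doc$xref <- xr(p$xref)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA)
  write_atomic(json, path)
}
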