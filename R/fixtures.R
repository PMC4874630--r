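#' @title Seeded synthetic fixtures
#'
#' @description
#' Generators for reaction-centric pathways, expression tables with a
#' planted enrichment signal, and annotation maps.  Everything is
#' reproducible byte-for-byte from `(spec, seed)` and every generated
#' object carries a ground-truth record (attribute `"truth"`) sufficient to
#' recompute the counting, conservation and scoring oracles without
#' re-parsing any output.  The generators emulate the mechanics of curated
#' reaction-centric content -- role-typed hyperedges, nested complexes,
#' alternative-member entity sets, compartments -- not the content
#' distribution or aesthetics of any real database.
#' @name synthetic_fixtures
NULL

#' Fixture specification
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_entities non-container entities.
#' @param n_reactions reactions.
#' @param p_complex per-entity probability of adding a container
#'   (complex/entity set) on top of the base entities.
#' @param mean_components mean container size (Poisson, floored at 2).
#' @param n_compartments compartment rectangles.
#' @param expression list: `fraction_signal` (probability a planted-pathway
#'   gene carries signal), `background_signal` (same for background genes),
#'   `effect` (|logFC| location of signal genes), plus the fixed mixture --
#'   signal p-values uniform on (0, 0.05), background uniform on (0, 1),
#'   signal logFC `±N(effect, 0.25)`, background `N(0, 0.25)`.
#' @param annotation list: `n_terms`, `genes_per_term`,
#'   `p_uncovered` (probability a term is annotated only with identifiers
#'   absent from every collection).
#' @export
fixture_spec <- function(seed = 42L, n_entities = 30L, n_reactions = 10L,
                         p_complex = 0.2, mean_components = 3,
                         n_compartments = 2L,
                         expression = list(), annotation = list()) {
  ex <- utils::modifyList(list(fraction_signal = 0.8,
                               background_signal = 0.1, effect = 2),
                          expression)
  an <- utils::modifyList(list(n_terms = 50L, genes_per_term = 5L,
                               p_uncovered = 0.15), annotation)
  s <- structure(list(seed = as.integer(seed),
                      n_entities = as.integer(n_entities),
                      n_reactions = as.integer(n_reactions),
                      p_complex = p_complex,
                      mean_components = mean_components,
                      n_compartments = as.integer(n_compartments),
                      expression = ex, annotation = an),
                 class = "pb_fixture_spec")
  probs <- c(p_complex, ex$fraction_signal, ex$background_signal,
             an$p_uncovered)
  if (any(probs < 0 | probs > 1))
    stop_pb("probabilities must lie in [0, 1]", "pathbridge_spec_error")
  if (any(c(n_entities, n_reactions, n_compartments) < 0))
    stop_pb("counts must be nonnegative", "pathbridge_spec_error")
  if (p_complex > 0 && n_entities < 2)
    stop_pb("containers need at least 2 base entities",
            "pathbridge_spec_error")
  if (n_reactions > 0 && n_entities < 2)
    stop_pb("reactions need at least 2 base entities",
            "pathbridge_spec_error")
  s
}

rcoord <- function(n, lo, hi) round(stats::runif(n, lo, hi) * 2) / 2

#' Generate a reaction-centric source pathway
#'
#' Base entities get class-appropriate annotation (UniProt for proteins,
#' ChEBI for small molecules, Ensembl for RNAs/genes, plus a Reactome id;
#' a tenth carry only the Reactome fallback and one in twenty none at
#' all).  Containers draw 2+ members; a third of later containers nest one
#' earlier container (depth capped at 2).  Reactions draw 1-3 inputs, 1-3
#' outputs and 0-2 catalysts plus optional activator/inhibitor from the
#' non-process-node entities.
#'
#' @param spec a [fixture_spec()].
#' @param name,organism pathway metadata.
#' @return a validated `pb_source_pathway`; attribute `"truth"` records
#'   entity classes, recursive container membership and the branch
#'   multiset.
#' @export
gen_source_pathway <- function(spec, name = "Synthetic pathway",
                               organism = "Homo sapiens") {
  with_seed(spec$seed, {
    nb <- spec$n_entities
    classes <- sample(c("protein", "small_molecule", "rna", "gene",
                        "process_node", "other"),
                      nb, replace = TRUE,
                      prob = c(0.52, 0.25, 0.08, 0.05, 0.05, 0.05))
    ids <- sprintf("E%03d", seq_len(nb))
    cx <- rcoord(nb, 60, 900)
    cy <- rcoord(nb, 60, 600)
    pubmed_pool <- sprintf("%d", 20000000 + seq_len(40))

    entities <- vector("list", nb)
    for (k in seq_len(nb)) {
      cls <- classes[k]
      xrefs <- list()
      anno <- stats::runif(1)
      if (anno < 0.85) {
        primary <- switch(cls,
          protein = xref("UniProt", sprintf("P%05d", 10000 + k)),
          small_molecule = xref("ChEBI", sprintf("CHEBI:%d", 15000 + k)),
          rna = xref("Ensembl", sprintf("ENSG%011d", 100000 + k)),
          gene = xref("Ensembl", sprintf("ENSG%011d", 100000 + k)),
          NULL)
        if (!is.null(primary)) xrefs <- list(primary)
        xrefs <- c(xrefs, list(xref("Reactome", sprintf("R-HSA-%d", 5000 + k))))
      } else if (anno < 0.95) {
        xrefs <- list(xref("Reactome", sprintf("R-HSA-%d", 5000 + k)))
      }
      lit <- if (stats::runif(1) < 0.3)
        sample(pubmed_pool, sample(1:2, 1)) else character()
      entities[[k]] <- source_entity(
        entity_id = ids[k],
        display_name = paste0(toupper(substr(cls, 1, 3)), k),
        entity_class = cls,
        geometry = c(cx[k], cy[k], 80, 20),
        xrefs = xrefs, literature = lit)
    }

    eligible <- ids[classes != "process_node"]
    membered <- ids[!(classes %in% c("process_node"))]

    # containers on top of the base entities
    n_cont <- stats::rbinom(1, nb, spec$p_complex)
    cont_ids <- character()
    cont_depth <- integer()
    truth_members <- list()
    for (k in seq_len(n_cont)) {
      cid <- sprintf("C%03d", k)
      cls <- if (stats::runif(1) < 0.7) "complex" else "entity_set"
      size <- max(2L, stats::rpois(1, spec$mean_components))
      pool <- membered
      comps <- sample(pool, min(size, length(pool)))
      depth <- 1L
      # nest an earlier depth-1 container in a third of later containers
      shallow <- cont_ids[cont_depth == 1L]
      if (length(shallow) > 0 && stats::runif(1) < (1 / 3)) {
        comps <- c(comps[-1], sample(shallow, 1))
        depth <- 2L
      }
      stoich <- ifelse(stats::runif(length(comps)) < 0.2, 2L, 1L)
      entities[[length(entities) + 1]] <- source_entity(
        entity_id = cid,
        display_name = paste0(if (cls == "complex") "CPX" else "SET", k),
        entity_class = cls,
        geometry = c(rcoord(1, 60, 900), rcoord(1, 60, 600), 90, 30),
        xrefs = list(xref("Reactome", sprintf("R-HSA-%d", 7000 + k))),
        components = Map(function(ref, s) list(ref = ref, stoichiometry = s),
                         comps, stoich))
      cont_ids <- c(cont_ids, cid)
      cont_depth <- c(cont_depth, depth)
    }

    participants <- c(eligible, cont_ids)
    reactions <- vector("list", spec$n_reactions)
    truth_branches <- list()
    for (k in seq_len(spec$n_reactions)) {
      rid <- sprintf("R%03d", k)
      n_in <- sample(1:3, 1)
      n_out <- sample(1:3, 1)
      n_cat <- sample(0:2, 1)
      n_act <- stats::rbinom(1, 1, 0.2)
      n_inh <- stats::rbinom(1, 1, 0.2)
      pick <- function(m) sample(participants, m, replace = FALSE)
      branches <- c(
        lapply(pick(n_in), function(e) reaction_branch("input", e)),
        lapply(pick(n_out), function(e) reaction_branch("output", e)),
        lapply(if (n_cat) pick(n_cat) else character(),
               function(e) reaction_branch("catalyst", e)),
        lapply(if (n_act) pick(n_act) else character(),
               function(e) reaction_branch("activator", e)),
        lapply(if (n_inh) pick(n_inh) else character(),
               function(e) reaction_branch("inhibitor", e)))
      x1 <- rcoord(1, 100, 800); y1 <- rcoord(1, 100, 550)
      reactions[[k]] <- source_reaction(
        reaction_id = rid, branches = branches,
        backbone_points = list(c(x1, y1), c(x1 + 60, y1)),
        reaction_type = sample(c("transition", "binding", "dissociation",
                                 "omitted", "uncertain"), 1,
                               prob = c(0.6, 0.15, 0.1, 0.1, 0.05)),
        xrefs = list(xref("Reactome", sprintf("R-HSA-%d", 9000 + k))),
        literature = if (stats::runif(1) < 0.4)
          sample(pubmed_pool, 1) else character())
      for (b in branches)
        truth_branches[[length(truth_branches) + 1]] <-
          data.frame(reaction = rid, role = b$role, entity = b$entity_id,
                     stringsAsFactors = FALSE)
    }

    compartments <- lapply(seq_len(spec$n_compartments), function(k)
      source_compartment(sprintf("cpt%d", k),
                         paste0("compartment ", k),
                         c(30 + (k - 1) * 450, 30, 420, 620),
                         membrane = k %% 2 == 0))
    notes <- if (stats::runif(1) < 0.5)
      list(source_note("curator note", c(rcoord(1, 50, 900),
                                         rcoord(1, 50, 600))))
      else list()

    p <- source_pathway(
      name = name, organism = organism,
      source_version = "54",
      authors = c("A. Curator", "B. Biologist"),
      maintainers = list(list(name = "R. Editor",
                              email = "editor@example.org")),
      entities = entities, reactions = reactions,
      compartments = compartments, notes = notes,
      xref = xref("Reactome", "R-HSA-99999"))

    entity_index <- stats::setNames(entities,
                                    vapply(entities, `[[`, "", "entity_id"))
    for (cid in cont_ids) {
      leaves <- expand_components(cid, entity_index)
      truth_members[[cid]] <- vapply(leaves, `[[`, "", "entity_id")
    }
    all_classes <- vapply(entities, `[[`, "", "entity_class")
    names(all_classes) <- vapply(entities, `[[`, "", "entity_id")
    structure(p, truth = list(
      classes = all_classes,
      containers = truth_members,
      branches = if (length(truth_branches))
        do.call(rbind, truth_branches)
        else data.frame(reaction = character(), role = character(),
                        entity = character(), stringsAsFactors = FALSE)))
  })
}

#' Generate a converted pathway collection
#'
#' Convenience wrapper: `n_pathways` source pathways from consecutive
#' seeds, each converted to GPML.
#'
#' @param spec a [fixture_spec()]; pathway k uses seed `spec$seed + k`.
#' @param n_pathways number of pathways.
#' @param opts [conversion_options()].
#' @return list of `pb_gpml_pathway` (named by pathway name).
#' @export
gen_pathway_collection <- function(spec, n_pathways = 20L,
                                   opts = conversion_options()) {
  out <- vector("list", n_pathways)
  for (k in seq_len(n_pathways)) {
    sp <- spec
    sp$seed <- spec$seed + k
    src <- gen_source_pathway(sp, name = sprintf("Pathway %02d", k))
    out[[k]] <- convert_pathway(src, opts)
  }
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Generate an expression table with a planted enrichment signal
#'
#' The measurement universe is the union of gene-level identifiers across
#' the supplied converted pathways.  Genes of the planted pathway carry
#' signal with probability `fraction_signal`, background genes with
#' probability `background_signal`.  Signal genes draw `P.value ~ U(0,
#' 0.05)` and `logFC ~ ±N(effect, 0.25)` (random sign); background genes
#' `P.value ~ U(0, 1)`, `logFC ~ N(0, 0.25)` -- so signal genes all but
#' surely qualify under `abs([logFC]) > 1 AND [P.value] < 0.05` and
#' background genes all but surely do not.
#'
#' @param spec a [fixture_spec()].
#' @param pathways list of `pb_gpml_pathway`.
#' @param planted index or name of the planted pathway.
#' @return data frame with columns `id`, `logFC`, `P.value`; attribute
#'   `"truth"` records each gene's signal flag and actual qualification.
#' @export
gen_expression_table <- function(spec, pathways, planted = 1L) {
  if (is.character(planted))
    planted <- match(planted, vapply(pathways, `[[`, "", "name"))
  if (is.na(planted) || planted < 1 || planted > length(pathways))
    stop_pb("planted pathway not found", "pathbridge_spec_error")
  universe <- sort(unique(unlist(lapply(pathways, pathway_identifiers))))
  planted_ids <- pathway_identifiers(pathways[[planted]])
  ex <- spec$expression
  with_seed(spec$seed + 1000003L, {
    in_planted <- universe %in% planted_ids
    p_sig <- ifelse(in_planted, ex$fraction_signal, ex$background_signal)
    signal <- stats::runif(length(universe)) < p_sig
    pval <- ifelse(signal, stats::runif(length(universe), 0, 0.05),
                   stats::runif(length(universe), 0, 1))
    lfc <- ifelse(signal,
                  sample(c(-1, 1), length(universe), replace = TRUE) *
                    stats::rnorm(length(universe), ex$effect, 0.25),
                  stats::rnorm(length(universe), 0, 0.25))
    tab <- data.frame(id = universe, logFC = lfc, P.value = pval,
                      stringsAsFactors = FALSE)
    qualifies <- abs(lfc) > 1 & pval < 0.05
    structure(tab, truth = data.frame(id = universe, in_planted = in_planted,
                                      signal = signal, qualifies = qualifies,
                                      stringsAsFactors = FALSE))
  })
}

#' Generate a random annotation map
#'
#' @param spec a [fixture_spec()].
#' @param identifiers identifier pool terms annotate.
#' @param category category label.
#' @return a `pb_annotation_map`; terms flagged uncovered draw only
#'   identifiers outside the pool.
#' @export
gen_annotation_map <- function(spec, identifiers, category = "BP") {
  an <- spec$annotation
  with_seed(spec$seed + 2000003L, {
    terms <- list()
    for (k in seq_len(an$n_terms)) {
      tid <- sprintf("T%04d", k)
      if (stats::runif(1) < an$p_uncovered || length(identifiers) == 0) {
        terms[[tid]] <- sprintf("ORPHAN%04d_%d", k, seq_len(an$genes_per_term))
      } else {
        m <- min(an$genes_per_term, length(identifiers))
        terms[[tid]] <- sample(identifiers, m)
      }
    }
    annotation_map(category, terms)
  })
}

#' Write a data table as TSV
#'
#' @param table data frame.
#' @param path output path.
#' @param provenance optional `#` comment lines.
#' @export
write_data_table <- function(table, path, provenance = NULL) {
  hdr <- paste(names(table), collapse = "\t")
  body <- vapply(seq_len(nrow(table)), function(k)
    paste(vapply(table[k, ], function(v)
      if (is.numeric(v)) fmt_num(v) else as.character(v), ""),
      collapse = "\t"), "")
  write_atomic(c(if (!is.null(provenance)) paste0("# ", provenance),
                 hdr, body), path)
}
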