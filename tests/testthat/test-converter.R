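test_that("entity classes map to the corresponding GPML node types", {
  expect_equal(map_entity_class("protein"), "Protein")
  expect_equal(map_entity_class("small_molecule"), "Metabolite")
  expect_equal(map_entity_class("rna"), "Rna")
  expect_equal(map_entity_class("gene"), "GeneProduct")
  expect_equal(map_entity_class("process_node"), "Pathway")
  expect_equal(map_entity_class("other"), "Unknown")
  expect_error(map_entity_class("complex"),
               class = "pathbridge_contract_error")
  expect_error(map_entity_class("entity_set"),
               class = "pathbridge_contract_error")
})

test_that("complexes become Complex-style groups, entity sets Group-style", {
  e_cpx <- source_entity("C1", "AKT:MTOR", "complex", c(10, 10, 90, 30),
                         xrefs = list(xref("Reactome", "R-HSA-2")),
                         components = list(list(ref = "P1", stoichiometry = 1L),
                                           list(ref = "P2", stoichiometry = 1L),
                                           list(ref = "P3", stoichiometry = 1L)))
  cc <- convert_container(e_cpx)
  expect_equal(cc$group$style, "Complex")
  expect_equal(cc$placeholder$node_type, "Complex")
  expect_equal(cc$placeholder$group_ref, cc$group$group_id)
  expect_equal(cc$placeholder$xref$identifier, "R-HSA-2")

  e_set <- source_entity("S1", "kinases", "entity_set", c(0, 0, 90, 30),
                         components = list(list(ref = "P1", stoichiometry = 1L),
                                           list(ref = "P2", stoichiometry = 1L)))
  expect_equal(quiet(convert_container(e_set))$group$style, "Group")

  e_empty <- source_entity("S2", "empty", "entity_set", c(0, 0, 10, 10))
  expect_error(convert_container(e_empty),
               class = "pathbridge_validation_error")
  expect_error(convert_container(
    source_entity("P9", "prot", "protein", c(0, 0, 10, 10))),
    class = "pathbridge_contract_error")
})

test_that("hyperedge decomposition obeys the interaction and anchor counting law", {
  set.seed(404)
  ids <- sprintf("X%d", 1:12)
  node_index <- setNames(paste0("dn_", seq_along(ids)), ids)
  node_centers <- setNames(lapply(seq_along(ids), function(k) c(k * 10, 5)),
                           ids)
  for (case in 1:60) {
    n_in <- sample(0:3, 1)
    n_out <- if (n_in == 0) sample(1:3, 1) else sample(0:3, 1)
    n_cat <- sample(0:2, 1); n_act <- sample(0:2, 1); n_inh <- sample(0:2, 1)
    picks <- sample(ids, n_in + n_out + n_cat + n_act + n_inh, replace = FALSE)
    roles <- rep(c("input", "output", "catalyst", "activator", "inhibitor"),
                 c(n_in, n_out, n_cat, n_act, n_inh))
    r <- source_reaction("R1",
                         branches = Map(reaction_branch, roles, picks),
                         backbone_points = list(c(0, 0), c(100, 0)))
    he <- quiet(convert_hyperedge(r, node_index, node_centers))
    n_int <- 1L + length(he$branches)
    expect_equal(n_int,
                 expected_interactions(n_in, n_out, n_cat, n_act, n_inh))
    expect_equal(length(he$backbone$anchors), n_int - 1L)
    # anchors evenly spaced at k/(m+1)
    m <- length(he$backbone$anchors)
    if (m > 0)
      expect_equal(vapply(he$backbone$anchors, `[[`, 0, "position"),
                   seq_len(m) / (m + 1))
  }
})

test_that("a 1-input/1-output reaction degenerates to a single plain edge", {
  r <- source_reaction("R1",
                       branches = list(reaction_branch("input", "X1"),
                                       reaction_branch("output", "X2")),
                       backbone_points = list(c(0, 0), c(100, 0)))
  he <- quiet(convert_hyperedge(r, c(X1 = "dn_1", X2 = "dn_2"),
                                list(X1 = c(0, 0), X2 = c(100, 0))))
  expect_length(he$branches, 0)
  expect_length(he$backbone$anchors, 0)
  expect_equal(he$backbone$points[[1]]$graph_ref, "dn_1")
  expect_equal(he$backbone$points[[2]]$graph_ref, "dn_2")
  expect_equal(he$backbone$points[[2]]$arrow_head, "mim_conversion")
})

test_that("backbone arrowhead encodes the reaction type and branch arrowheads the roles", {
  node_index <- c(A = "dn_1", B = "dn_2", C = "dn_3", D = "dn_4", E = "dn_5")
  centers <- list(A = c(0, 0), B = c(10, 0), C = c(5, 5), D = c(5, -5),
                  E = c(8, 5))
  mk <- function(type) source_reaction("R1",
    branches = list(reaction_branch("input", "A"),
                    reaction_branch("output", "B"),
                    reaction_branch("catalyst", "C"),
                    reaction_branch("activator", "D"),
                    reaction_branch("inhibitor", "E")),
    backbone_points = list(c(0, 0), c(100, 0)), reaction_type = type)
  he <- quiet(convert_hyperedge(mk("binding"), node_index, centers))
  expect_equal(he$backbone$points[[2]]$arrow_head, "mim_binding")
  heads <- vapply(he$branches, function(b)
    b$points[[2]]$arrow_head, "")
  expect_setequal(heads, c("mim_catalysis", "mim_stimulation", "t_bar"))
  he2 <- quiet(convert_hyperedge(mk("dissociation"), node_index, centers))
  expect_equal(he2$backbone$points[[2]]$arrow_head, "arrow")
})

test_that("component flattening dedups shared members and lays out a grid", {
  # two complexes sharing P: P drawn once, listed under both
  mk_prot <- function(id, nm, up)
    source_entity(id, nm, "protein", c(10, 10, 80, 20),
                  xrefs = list(xref("UniProt", up)))
  p <- source_pathway("share", entities = list(
    mk_prot("P1", "P", "P00001"), mk_prot("P2", "Q", "P00002"),
    mk_prot("P3", "R", "P00003"),
    source_entity("C1", "cpx1", "complex", c(0, 0, 90, 30),
                  components = list(list(ref = "P1", stoichiometry = 1L),
                                    list(ref = "P2", stoichiometry = 1L))),
    source_entity("C2", "cpx2", "complex", c(0, 0, 90, 30),
                  components = list(list(ref = "P1", stoichiometry = 1L),
                                    list(ref = "P3", stoichiometry = 1L)))))
  fl <- quiet(flatten_components(p, container_nodes = c(C1 = "g1", C2 = "g2")))
  expect_length(fl$nodes, 3)                 # P, Q, R drawn once each
  p_node <- fl$nodes[[1]]$graph_id
  expect_true(p_node %in% fl$component_map$g1)
  expect_true(p_node %in% fl$component_map$g2)
  expect_length(fl$hidden, 1)                # the duplicate P occurrence

  # no containers -> nothing flattened
  p0 <- source_pathway("plain", entities = list(mk_prot("P1", "P", "P00001")))
  fl0 <- flatten_components(p0)
  expect_length(fl0$nodes, 0)
  expect_length(fl0$component_map, 0)

  # 12 unique components at 10 columns -> second row starts at node 11
  ents <- lapply(1:12, function(k)
    mk_prot(sprintf("P%02d", k), sprintf("prot%02d", k),
            sprintf("P%05d", k)))
  ents[[13]] <- source_entity("C1", "big", "complex", c(0, 0, 90, 30),
    components = lapply(1:12, function(k)
      list(ref = sprintf("P%02d", k), stoichiometry = 1L)))
  pg <- source_pathway("grid", entities = ents)
  opts <- conversion_options(columns = 10L)
  flg <- quiet(flatten_components(pg, opts,
                                  container_nodes = c(C1 = "g1"),
                                  diagram_bottom = 100))
  ys <- vapply(flg$nodes, function(n) n$center[2], 0)
  xs <- vapply(flg$nodes, function(n) n$center[1], 0)
  expect_length(unique(ys[1:10]), 1)         # first row
  expect_equal(unique(ys[11:12]), ys[1] + opts$cell_height)
  expect_equal(xs[11], xs[1])                # row 2 restarts at column 1
  expect_true(all(ys > 100))
})

test_that("nested complexes flatten recursively to their leaf members", {
  mk_prot <- function(id, up)
    source_entity(id, id, "protein", c(10, 10, 80, 20),
                  xrefs = list(xref("UniProt", up)))
  p <- source_pathway("nested", entities = list(
    mk_prot("P1", "P00001"), mk_prot("P2", "P00002"), mk_prot("P3", "P00003"),
    source_entity("Inner", "inner", "complex", c(0, 0, 90, 30),
                  components = list(list(ref = "P1", stoichiometry = 1L),
                                    list(ref = "P2", stoichiometry = 1L))),
    source_entity("Outer", "outer", "complex", c(0, 0, 90, 30),
                  components = list(list(ref = "Inner", stoichiometry = 1L),
                                    list(ref = "P3", stoichiometry = 1L)))))
  fl <- quiet(flatten_components(p, container_nodes = c(Inner = "gi",
                                                        Outer = "go")))
  labels_of <- function(gid) sort(vapply(fl$component_map[[gid]], function(id)
    Filter(function(n) n$graph_id == id, fl$nodes)[[1]]$text_label, ""))
  expect_equal(unname(labels_of("gi")), c("P1", "P2"))
  expect_equal(unname(labels_of("go")), c("P1", "P2", "P3"))
})

test_that("annotation prefers UniProt/ChEBI over Reactome and logs absences", {
  xs <- list(xref("Reactome", "R-HSA-1"), xref("UniProt", "P31749"))
  expect_equal(annotate_element(xs, c("UniProt", "Reactome"))$identifier,
               "P31749")
  only_r <- list(xref("Reactome", "R-ALL-2"))
  expect_equal(annotate_element(only_r, c("ChEBI", "Reactome"))$identifier,
               "R-ALL-2")
  expect_message(res <- annotate_element(list(), c("UniProt", "Reactome")),
                 class = "pathbridge_log")
  expect_null(res)
})

test_that("the transporter fixture converts to 3 data nodes, 2 interactions, 1 anchor", {
  src <- read_source_pathway(abacavir_path())
  gp <- quiet(convert_pathway(src))
  expect_length(gp$data_nodes, 3)
  expect_length(gp$interactions, 2)
  expect_equal(count_anchors(gp), 1)
  # the catalyst edge ends in a catalysis arrowhead at the anchor
  anchor_id <- gp$interactions[[1]]$anchors[[1]]$anchor_id
  cat_edge <- gp$interactions[[2]]
  last_pt <- cat_edge$points[[length(cat_edge$points)]]
  expect_equal(last_pt$graph_ref, anchor_id)
  expect_equal(last_pt$arrow_head, "mim_catalysis")
  # metabolites annotated ChEBI-first, catalyst protein UniProt-first
  types <- vapply(gp$data_nodes, `[[`, "", "node_type")
  expect_equal(sort(types), c("Metabolite", "Metabolite", "Protein"))
  prot <- gp$data_nodes[[which(types == "Protein")]]
  expect_equal(prot$xref$data_source, "UniProt")
})

test_that("full conversion carries metadata, compartments, notes and the counting oracle", {
  p <- source_pathway("meta", organism = "Homo sapiens",
                      source_version = "54",
                      authors = "A. Curator",
                      maintainers = list(list(name = "R. Editor",
                                              email = "ed@x.org")))
  gp <- convert_pathway(p)
  srcs <- vapply(gp$comments, `[[`, "", "source")
  txts <- vapply(gp$comments, `[[`, "", "text")
  expect_equal(txts[srcs == "DataSource"], "Reactome")
  expect_equal(txts[srcs == "Version"], "54")
  expect_equal(gp$maintainers, "R. Editor <ed@x.org>")
  expect_length(gp$data_nodes, 0)

  for (seed in c(2, 9, 23)) {
    src <- gen_source_pathway(fixture_spec(seed = seed))
    tr <- attr(src, "truth")
    gp <- quiet(convert_pathway(src))
    n_noncont <- sum(!(tr$classes %in% c("complex", "entity_set")))
    n_cont <- sum(tr$classes %in% c("complex", "entity_set"))
    # unique flattened components by the truth record, dedup key as spec'd
    ent_idx <- setNames(src$entities,
                        vapply(src$entities, `[[`, "", "entity_id"))
    keys <- unique(unlist(lapply(tr$containers, function(members)
      vapply(members, function(id) {
        e <- ent_idx[[id]]
        if (length(e$xrefs)) paste0(e$xrefs[[1]]$data_source, ":",
                                    e$xrefs[[1]]$identifier)
        else e$display_name
      }, ""))))
    expect_length(gp$data_nodes, n_noncont + n_cont + length(keys))
    # notes become labels, compartments become labelled rectangles
    expect_length(gp$labels, length(src$notes))
    expect_length(gp$shapes, length(src$compartments))
  }
})

test_that("participant triples are conserved through conversion", {
  for (seed in c(5, 17)) {
    src <- gen_source_pathway(fixture_spec(seed = seed))
    gp <- quiet(convert_pathway(src))
    got <- sort_triples(recovered_source_triples(gp))
    want <- sort_triples(attr(src, "truth")$branches)
    expect_equal(got, want)
  }
})

test_that("conversion output is byte-identical across runs", {
  src <- gen_source_pathway(fixture_spec(seed = 31))
  f1 <- withr::local_tempfile(fileext = ".gpml")
  f2 <- withr::local_tempfile(fileext = ".gpml")
  write_gpml(quiet(convert_pathway(src)), f1)
  write_gpml(quiet(convert_pathway(src)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every source literature identifier lands on exactly one output element", {
  src <- gen_source_pathway(fixture_spec(seed = 13))
  gp <- quiet(convert_pathway(src))
  src_lit <- c(unlist(lapply(src$entities, `[[`, "literature")),
               unlist(lapply(src$reactions, `[[`, "literature")))
  # per-element occurrences on the output, excluding flattened copies
  conv <- attr(gp, "conversion")
  main_nodes <- Filter(function(n) n$graph_id %in% conv$entity_nodes,
                       gp$data_nodes)
  out_lit <- c(unlist(lapply(main_nodes, `[[`, "literature")),
               unlist(lapply(gp$interactions, `[[`, "literature")))
  expect_equal(sort(out_lit), sort(src_lit))
})

test_that("the recorded component map is recoverable from the written GPML", {
  src <- gen_source_pathway(fixture_spec(seed = 19))
  gp <- quiet(convert_pathway(src))
  path <- withr::local_tempfile(fileext = ".gpml")
  write_gpml(gp, path)
  m1 <- attr(gp, "conversion")$component_map
  m2 <- read_component_map(read_gpml(path))
  expect_equal(m2[order(names(m2))], m1[order(names(m1))])
})
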