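# shared fixture builders and independent oracles

quiet <- function(expr) {
  withCallingHandlers(expr, pathbridge_log = function(c)
    invokeRestart("muffleMessage"))
}

abacavir_path <- function() {
  system.file("extdata", "abacavir-transport-synthetic.json",
              package = "pathbridge")
}

# tiny hand-built pathway: 2 proteins, 1 metabolite, 1 complex over P1+P2
tiny_pathway <- function() {
  source_pathway(
    name = "tiny", organism = "Homo sapiens", source_version = "54",
    entities = list(
      source_entity("P1", "AKT1", "protein", c(100, 100, 80, 20),
                    xrefs = list(xref("Reactome", "R-HSA-1"),
                                 xref("UniProt", "P31749"))),
      source_entity("P2", "MTOR", "protein", c(250, 100, 80, 20),
                    xrefs = list(xref("UniProt", "P42345"))),
      source_entity("M1", "ATP", "small_molecule", c(100, 220, 70, 20),
                    xrefs = list(xref("ChEBI", "CHEBI:15422"))),
      source_entity("C1", "AKT1:MTOR", "complex", c(250, 220, 90, 30),
                    xrefs = list(xref("Reactome", "R-HSA-2")),
                    components = list(list(ref = "P1", stoichiometry = 1L),
                                      list(ref = "P2", stoichiometry = 1L)))),
    reactions = list(
      source_reaction("R1",
                      branches = list(reaction_branch("input", "P1"),
                                      reaction_branch("input", "P2"),
                                      reaction_branch("output", "C1")),
                      backbone_points = list(c(150, 160), c(230, 160)),
                      reaction_type = "binding")))
}

# independent criterion evaluator built on R's own parser: translate the
# bracket syntax to an R expression and eval it column-wise
ref_eval_criterion <- function(expr, table) {
  e <- expr
  e <- gsub("\\[([^]]+)\\]", "table[['\\1']]", e)
  e <- gsub("<=", "\001", e)
  e <- gsub(">=", "\002", e)
  e <- gsub("(?<![<>=!])=(?!=)", "==", e, perl = TRUE)
  e <- gsub("\001", "<=", e, fixed = TRUE)
  e <- gsub("\002", ">=", e, fixed = TRUE)
  e <- gsub("\\bAND\\b", "&", e, ignore.case = TRUE)
  e <- gsub("\\bOR\\b", "|", e, ignore.case = TRUE)
  e <- gsub("\\bNOT\\b", "!", e, ignore.case = TRUE)
  res <- eval(parse(text = e))
  if (length(res) == 1) res <- rep(res, nrow(table))
  res & !is.na(res)
}

# counting oracle for hyperedge decomposition, from role counts alone
expected_interactions <- function(n_in, n_out, n_cat, n_act, n_inh) {
  1L + max(0L, n_in - 1L) + max(0L, n_out - 1L) + n_cat + n_act + n_inh
}

count_anchors <- function(p) {
  sum(vapply(p$interactions, function(i) length(i$anchors), 0L))
}

# map converted participant triples back to source entity/reaction ids via
# the deterministic conversion record
recovered_source_triples <- function(gp) {
  conv <- attr(gp, "conversion")
  rec <- recover_participants(gp)
  node_to_entity <- setNames(names(conv$entity_nodes), conv$entity_nodes)
  bb_to_reaction <- setNames(names(conv$reaction_backbones),
                             conv$reaction_backbones)
  data.frame(reaction = unname(bb_to_reaction[rec$backbone]),
             role = rec$role,
             entity = unname(node_to_entity[rec$node]),
             stringsAsFactors = FALSE)
}

sort_triples <- function(df) {
  df <- df[order(df$reaction, df$role, df$entity), , drop = FALSE]
  rownames(df) <- NULL
  df
}

gpml_schema <- function() {
  xml2::read_xml(system.file("extdata", "gpml2013a-subset.xsd",
                             package = "pathbridge"))
}
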