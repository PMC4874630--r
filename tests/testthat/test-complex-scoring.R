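scored_fixture <- function(seed = 7) {
  spec <- fixture_spec(seed = seed)
  src <- gen_source_pathway(spec)
  gp <- quiet(convert_pathway(src))
  ids <- pathbridge:::pathway_identifiers(gp)
  with_seed <- pathbridge:::with_seed
  tab <- with_seed(seed + 77L, data.frame(
    id = ids, P.value = round(runif(length(ids)), 3)))
  list(src = src, gp = gp, tab = tab)
}

test_that("percent is qualifying components over components with data", {
  # hand-built check: 4 components, exactly 1 qualifying -> 25
  mk_prot <- function(id, up)
    source_entity(id, id, "protein", c(30 * as.integer(substring(id, 2)),
                                       40, 80, 20),
                  xrefs = list(xref("UniProt", up)))
  ents <- c(lapply(1:4, function(k) mk_prot(paste0("E", k),
                                            sprintf("P%05d", k))),
            list(source_entity("C1", "cpx", "complex", c(300, 40, 90, 30),
                               components = lapply(1:4, function(k)
                                 list(ref = paste0("E", k),
                                      stoichiometry = 1L)))))
  gp <- quiet(convert_pathway(source_pathway("q", entities = ents)))
  tab <- data.frame(id = sprintf("P%05d", 1:4),
                    P.value = c(0.01, 0.5, 0.6, 0.7))
  sc <- score_complexes(gp, table = tab, crit = "[P.value] < 0.05")
  expect_equal(nrow(sc), 1)
  expect_equal(sc$n_components, 4)
  expect_equal(sc$n_qualifying, 1)
  expect_equal(sc$percent, 25)
})

test_that("components without data drop from numerator and denominator; none -> undefined", {
  mk_prot <- function(id, up)
    source_entity(id, id, "protein", c(30, 40, 80, 20),
                  xrefs = list(xref("UniProt", up)))
  ents <- list(mk_prot("E1", "P00001"), mk_prot("E2", "P00002"),
               source_entity("C1", "cpx", "complex", c(300, 40, 90, 30),
                             components = list(
                               list(ref = "E1", stoichiometry = 1L),
                               list(ref = "E2", stoichiometry = 1L))))
  gp <- quiet(convert_pathway(source_pathway("m", entities = ents)))
  # only E1 measured and it qualifies -> 100, not 50
  tab <- data.frame(id = "P00001", P.value = 0.01)
  sc <- score_complexes(gp, table = tab, crit = "[P.value] < 0.05")
  expect_equal(sc$n_components, 1)
  expect_equal(sc$percent, 100)
  # no component measured -> undefined
  tab0 <- data.frame(id = "P99999", P.value = 0.01)
  sc0 <- score_complexes(gp, table = tab0, crit = "[P.value] < 0.05")
  expect_true(is.na(sc0$percent))
})

test_that("scores equal a brute-force recount over the ground-truth membership", {
  for (seed in c(3, 7, 15)) {
    fx <- scored_fixture(seed)
    crit <- "[P.value] < 0.05"
    sc <- score_complexes(fx$gp, table = fx$tab, crit = crit)
    truth <- attr(fx$src, "truth")
    conv <- attr(fx$gp, "conversion")
    ent_idx <- setNames(fx$src$entities,
                        vapply(fx$src$entities, `[[`, "", "entity_id"))
    qual <- setNames(fx$tab$P.value < 0.05, fx$tab$id)
    for (cid in names(truth$containers)) {
      gid <- unname(conv$entity_nodes[cid])
      # recount from truth: distinct leaf identifiers with data
      keys <- unique(vapply(truth$containers[[cid]], function(eid) {
        e <- ent_idx[[eid]]
        if (length(e$xrefs)) e$xrefs[[1]]$identifier else e$display_name
      }, ""))
      with_data <- keys[keys %in% names(qual)]
      row <- sc[sc$complex_id == gid, ]
      expect_equal(row$n_components, length(with_data))
      if (length(with_data) > 0) {
        expect_equal(row$n_qualifying, sum(qual[with_data]))
        expect_equal(row$percent, 100 * sum(qual[with_data]) /
                       length(with_data))
      } else {
        expect_true(is.na(row$percent))
      }
    }
    # invariance under component order: permuting table rows changes nothing
    perm <- fx$tab[sample(nrow(fx$tab)), , drop = FALSE]
    sc2 <- score_complexes(fx$gp, table = perm, crit = crit)
    expect_equal(sc2[order(sc2$complex_id), ], sc[order(sc$complex_id), ])
  }
})

test_that("the strict >25 rule highlights only scores above the threshold", {
  sc <- data.frame(complex_id = c("a", "b", "c", "d"),
                   label = letters[1:4],
                   n_components = 4L, n_qualifying = 1L,
                   percent = c(30, 25, 24.9, NA))
  cols <- apply_color_rules(sc, color_rule(">", 25, "#FFA500"),
                            default = "#404040")
  expect_equal(unname(cols["a"]), "#FFA500")
  expect_equal(unname(cols["b"]), "#404040")   # boundary stays grey
  expect_equal(unname(cols["c"]), "#404040")
  expect_equal(unname(cols["d"]), "#404040")   # undefined -> default
})

test_that("gradient rules interpolate linearly in RGB", {
  sc <- data.frame(complex_id = "a", label = "a", n_components = 2L,
                   n_qualifying = 1L, percent = 50)
  g <- color_rule("gradient", anchors = c(0, 100),
                  colors = c("#0000FF", "#FFFF00"))
  col <- apply_color_rules(sc, g, default = "#404040")
  expect_equal(unname(col["a"]), "#808080")    # midpoint of blue..yellow
  expect_error(color_rule("gradient", anchors = c(50, 50),
                          colors = c("#000000", "#FFFFFF")),
               class = "pathbridge_validation_error")
})

test_that("first matching rule wins in user order", {
  sc <- data.frame(complex_id = "a", label = "a", n_components = 2L,
                   n_qualifying = 2L, percent = 80)
  rules <- list(color_rule(">", 50, "#FF0000"), color_rule(">", 25, "#FFA500"))
  expect_equal(unname(apply_color_rules(sc, rules, "#404040")["a"]),
               "#FF0000")
  rules_rev <- rev(rules)
  expect_equal(unname(apply_color_rules(sc, rules_rev, "#404040")["a"]),
               "#FFA500")
})

test_that("complex/component lookup is symmetric", {
  fx <- scored_fixture(9)
  map <- read_component_map(fx$gp)
  expect_gt(length(map), 0)
  for (cid in names(map)) {
    comps <- complex_lookup(fx$gp, map, cid)
    expect_setequal(comps, map[[cid]])
    for (co in comps)
      expect_true(cid %in% complex_lookup(fx$gp, map, co))
  }
  expect_error(complex_lookup(fx$gp, map, "does_not_exist"),
               class = "pathbridge_lookup_error")
})
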