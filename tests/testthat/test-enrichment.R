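test_that("z score matches its closed forms and undefined cases", {
  # centred case: r exactly at expectation
  expect_equal(zscore(6, 12, 25, 50), 0)
  # n = 1 reduces to a single Bernoulli standardisation
  p <- 10 / 40
  expect_equal(zscore(1, 1, 10, 40), (1 - p) / sqrt(p * (1 - p)))
  expect_equal(zscore(0, 1, 10, 40), (0 - p) / sqrt(p * (1 - p)))
  # degenerate variances
  expect_true(is.na(zscore(0, 0, 10, 40)))   # n = 0
  expect_true(is.na(zscore(0, 5, 0, 40)))    # R = 0
  expect_true(is.na(zscore(5, 5, 40, 40)))   # R = N
  expect_true(is.na(zscore(10, 40, 10, 40))) # n = N
  expect_error(zscore(5, 4, 10, 40), class = "pathbridge_domain_error")
})

test_that("z mean and variance match hypergeometric sampling", {
  set.seed(12)
  for (case in 1:5) {
    N <- sample(50:200, 1)
    R <- sample(5:(N - 5), 1)
    n <- sample(2:(N - 2), 1)
    draws <- rhyper(20000, R, N - R, n)
    mu <- n * R / N
    v <- n * (R / N) * (1 - R / N) * (1 - (n - 1) / (N - 1))
    se_mean <- sqrt(v / length(draws))
    expect_lt(abs(mean(draws) - mu), 4 * se_mean)
    # z of the empirical mean count is ~0
    zz <- zscore(round(mu), n, R, N)
    expect_lt(abs(zz), 1)
  }
})

test_that("z is strictly increasing in r for fixed n, R, N", {
  for (case in list(c(20, 60, 200), c(5, 10, 50), c(30, 100, 400))) {
    n <- case[1]; R <- case[2]; N <- case[3]
    zs <- zscore(0:min(n, R), rep(n, min(n, R) + 1), R, N)
    expect_true(all(diff(zs) > 0))
  }
})

make_collection <- function(seed = 7, n = 10) {
  spec <- fixture_spec(seed = seed, n_entities = 20L, n_reactions = 6L)
  quiet(gen_pathway_collection(spec, n))
}

test_that("a planted signal pathway ranks first", {
  spec <- fixture_spec(seed = 7, n_entities = 20L, n_reactions = 6L)
  pws <- make_collection(7, 10)
  tab <- gen_expression_table(spec, pws, planted = 3L)
  res <- run_enrichment(tab, "abs([logFC]) > 1 AND [P.value] < 0.05", pws)
  expect_s3_class(res, "pb_enrichment")
  expect_equal(res$pathway[1], names(pws)[3])
  zz <- res$z[!is.na(res$z)]
  expect_true(all(diff(zz) <= 1e-12))            # sorted descending
  expect_true(all(is.na(res$z[seq_along(res$z) > length(zz)])))  # NAs last
  # counts consistent with the generator's ground truth
  truth <- attr(tab, "truth")
  expect_equal(res$R[1], sum(truth$qualifies))
  expect_equal(res$N[1], nrow(truth))
})

test_that("edge cases: zero qualifiers, all-encompassing pathway, empty table", {
  pws <- make_collection(21, 4)
  ids <- sort(unique(unlist(lapply(pws, pathbridge:::pathway_identifiers))))
  tab <- data.frame(id = ids, logFC = 0, P.value = 0.9)
  res <- run_enrichment(tab, "abs([logFC]) > 1 AND [P.value] < 0.05", pws)
  expect_true(all(is.na(res$z)))             # R = 0
  expect_error(run_enrichment(tab[0, ], "[P.value] < 0.05", pws),
               class = "pathbridge_domain_error")
  # single pathway containing every measured id -> n = N -> undefined z
  one <- pws[1]
  ids1 <- pathbridge:::pathway_identifiers(one[[1]])
  tab1 <- data.frame(id = ids1, logFC = c(2, rep(0, length(ids1) - 1)),
                     P.value = c(0.01, rep(0.9, length(ids1) - 1)))
  res1 <- run_enrichment(tab1, "abs([logFC]) > 1 AND [P.value] < 0.05", one)
  expect_true(is.na(res1$z[1]))
  expect_equal(res1$n[1], res1$N[1])
})

test_that("multiple probes collapsing to one identifier count once and qualify if any does", {
  pws <- make_collection(33, 3)
  ids <- sort(unique(unlist(lapply(pws, pathbridge:::pathway_identifiers))))
  # two probes per identifier; only the second of each qualifies
  tab <- data.frame(id = paste0("probe", seq_len(2 * length(ids))),
                    logFC = rep(c(0, 2), length(ids)),
                    P.value = rep(c(0.9, 0.01), length(ids)))
  mapper <- setNames(rep(ids, each = 2), tab$id)
  res <- run_enrichment(tab, "abs([logFC]) > 1 AND [P.value] < 0.05", pws,
                        id_mapper = mapper)
  expect_equal(res$N[1], length(ids))
  expect_equal(res$R[1], length(ids))        # every id has a qualifying probe
})

test_that("pathway statistics count flattened complex components", {
  # pathway A: genes inside a complex; pathway B: same genes as plain nodes
  mk_prot <- function(id, up)
    source_entity(id, id, "protein", c(50 * as.integer(substring(id, 2)),
                                       50, 80, 20),
                  xrefs = list(xref("UniProt", up)))
  genes <- sprintf("P%05d", 1:4)
  entsA <- c(lapply(1:2, function(k) mk_prot(paste0("E", k), genes[k])),
             list(source_entity("C1", "cpx", "complex", c(300, 50, 90, 30),
                                components = list(
                                  list(ref = "E1", stoichiometry = 1L),
                                  list(ref = "E2", stoichiometry = 1L)))))
  pA <- quiet(convert_pathway(source_pathway("A", entities = entsA)))
  pB <- quiet(convert_pathway(source_pathway("B", entities =
    lapply(1:2, function(k) mk_prot(paste0("E", k), genes[k])))))
  tab <- data.frame(id = genes, logFC = c(2, 0, 2, 0),
                    P.value = c(0.01, 0.5, 0.01, 0.5))
  res <- run_enrichment(tab, "abs([logFC]) > 1 AND [P.value] < 0.05",
                        list(pA, pB))
  expect_equal(res$n[res$pathway == "A"], res$n[res$pathway == "B"])
  expect_equal(res$r[res$pathway == "A"], res$r[res$pathway == "B"])
  expect_equal(res$z[res$pathway == "A"], res$z[res$pathway == "B"])
})

test_that("permutation null gives per-pathway mean z near zero", {
  set.seed(5)
  pws <- make_collection(11, 8)
  ids <- sort(unique(unlist(lapply(pws, pathbridge:::pathway_identifiers))))
  N <- length(ids)
  R <- round(0.3 * N)
  membership <- lapply(pws, function(p)
    match(pathbridge:::pathway_identifiers(p), ids))
  n_perm <- 600
  zmat <- matrix(NA_real_, n_perm, length(pws))
  for (b in seq_len(n_perm)) {
    qual <- logical(N)
    qual[sample.int(N, R)] <- TRUE
    for (j in seq_along(membership)) {
      n_j <- length(membership[[j]])
      zmat[b, j] <- zscore(sum(qual[membership[[j]]]), n_j, R, N)
    }
  }
  for (j in seq_along(pws)) {
    zj <- zmat[, j][!is.na(zmat[, j])]
    se <- sd(zj) / sqrt(length(zj))
    expect_lt(abs(mean(zj)), 3 * se + 1e-12)
  }
})

test_that("enrichment TSV output matches the r/n/R/N/z table shape", {
  pws <- make_collection(3, 3)
  spec <- fixture_spec(seed = 3, n_entities = 20L, n_reactions = 6L)
  tab <- gen_expression_table(spec, pws, 1)
  res <- run_enrichment(tab, "abs([logFC]) > 1 AND [P.value] < 0.05", pws)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_tsv(res, path, provenance = "run 1")
  lines <- readLines(path)
  expect_true(startsWith(lines[1], "# "))
  expect_equal(strsplit(lines[2], "\t")[[1]],
               c("pathway", "source", "r", "n", "R", "N", "z"))
  back <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(back$r, res$r)
})
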