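test_that("hypergeom_p matches hand computation and enumeration", {
  # k=4, K=5, n=4, N=10 -> C(5,4)/C(10,4) = 5/210
  expect_equal(hypergeom_p(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_p(0, 5, 4, 10), 1)
  expect_equal(hypergeom_p(3, 6, 5, 20), hyper_oracle(3, 6, 5, 20),
               tolerance = 1e-12)
  # agreement with the distribution function
  expect_equal(hypergeom_p(3, 6, 5, 20),
               phyper(2, 6, 14, 5, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(hypergeom_p(5, 4, 6, 10), "inconsistent")
  expect_error(hypergeom_p(3, 5, 2, 10), "inconsistent")
})

test_that("enrich finds a planted over-represented term", {
  universe <- paste0("g", 1:1000)
  carriers <- paste0("g", 1:100)
  ann <- annotation_map(c(
    setNames(lapply(carriers, function(x) "T"), carriers),
    setNames(lapply(paste0("g", 101:1000), function(x) "other"),
             paste0("g", 101:1000))
  ))
  genes <- c(paste0("g", 1:15), paste0("g", 101:105))   # 15/20 carry T
  res <- enrich(genes, ann, universe, correction = "bonferroni")
  expect_identical(res$term[1], "T")
  expect_lt(res$p_corrected[1], 0.05)
  expect_equal(res$k[res$term == "T"], 15L)
  expect_equal(res$K[res$term == "T"], 100L)
  # hypergeometric oracle agreement
  expect_equal(res$p_value[res$term == "T"], hypergeom_p(15, 100, 20, 1000))
  # term carried by every gene has p = 1
  ann_all <- annotation_map(setNames(lapply(universe, function(x) "T"), universe))
  res_all <- enrich(genes, ann_all, universe)
  expect_equal(res_all$p_value[res_all$term == "T"], 1)
  # empty gene set -> empty result
  expect_equal(nrow(enrich(character(0), ann, universe)), 0)
  expect_error(enrich("not_there", ann, universe), "subset")
})

test_that("enrichment corrections and invariances", {
  universe <- paste0("g", 1:50)
  ann <- annotation_map(setNames(
    lapply(1:50, function(i) c(if (i <= 10) "A", if (i %% 2) "B")), universe))
  genes <- paste0("g", c(1:8, 11, 13))
  for (corr in c("bonferroni", "bh", "none")) {
    res <- enrich(genes, ann, universe, correction = corr)
    expect_true(all(res$p_corrected >= res$p_value - 1e-15))
    if (corr == "bonferroni")
      expect_equal(res$p_corrected, pmin(1, nrow(res) * res$p_value))
  }
  # invariant to permutation of gene order
  r1 <- enrich(genes, ann, universe)
  r2 <- enrich(rev(genes), ann, universe)
  expect_equal(r1[, setdiff(names(r1), "members")],
               r2[, setdiff(names(r2), "members")])
})

test_that("slim vocabulary maps terms to categories before testing", {
  universe <- paste0("g", 1:40)
  g2t <- setNames(lapply(1:40, function(i) {
    if (i <= 10) c("GO:1", "GO:2") else "GO:3"
  }), universe)
  slim <- c("GO:1" = "stress", "GO:2" = "stress", "GO:3" = "metabolism")
  ann <- annotation_map(g2t, slim = slim)
  res <- enrich(paste0("g", 1:8), ann, universe, vocabulary = "slim")
  expect_setequal(res$term, "stress")
  # the two GO terms collapse into one slim category counted once per gene
  expect_equal(res$k[res$term == "stress"], 8L)
  expect_equal(res$K[res$term == "stress"], 10L)
})

test_that("revealed_by_as returns SAS-only significant terms", {
  universe <- paste0("g", 1:200)
  # term T carried by the anti-sense-linked genes only
  carriers <- paste0("g", 1:20)
  g2t <- setNames(lapply(1:200, function(i)
    if (i <= 20) "T" else "bg"), universe)
  ann <- annotation_map(g2t)
  set_S <- paste0("g", 100:130)                 # no T carriers
  set_SAS <- c(set_S, paste0("g", 1:12))        # 12 T carriers join
  res <- revealed_by_as(set_S, set_SAS, ann, universe)
  expect_true("T" %in% res$term)
  # identical sets reveal nothing
  expect_equal(nrow(revealed_by_as(set_S, set_S, ann, universe)), 0)
  # empty AS contribution reveals nothing
  expect_equal(nrow(revealed_by_as(set_SAS, set_SAS, ann, universe)), 0)
})

test_that("propagate applies the true-path rule and detects cycles", {
  parents <- list(c = "b", b = "a")
  ann <- annotation_map(list(g1 = "c"), parents = parents)
  prop <- propagate(ann)
  expect_setequal(prop$gene2terms$g1, c("a", "b", "c"))
  # idempotent
  expect_equal(propagate(prop)$gene2terms, prop$gene2terms)
  # random DAGs agree with a transitive-closure oracle
  set.seed(50)
  for (rep in 1:10) {
    n <- 20
    terms <- paste0("t", 1:n)
    parents <- list()
    for (i in 2:n) {
      ps <- sample(terms[1:(i - 1)], sample(0:min(2, i - 1), 1))
      if (length(ps)) parents[[terms[i]]] <- ps
    }
    anc <- term_ancestors(parents)
    oracle <- closure_oracle(parents)
    for (t in names(parents))
      expect_setequal(anc[[t]], oracle[[t]])
  }
  # cycle detection
  expect_error(term_ancestors(list(a = "b", b = "a")), "cycle")
})

test_that("anti-sense transcripts inherit sense annotations", {
  ann <- annotation_map(list(g1 = c("T1", "T2")))
  ext <- annotate_antisense(ann, c("g1_AS", "g2", "g2_AS"))
  expect_setequal(ext$gene2terms$g1_AS, c("T1", "T2"))
  expect_identical(ext$gene2terms$g2, "unknown biological processes")
  expect_identical(ext$gene2terms$g2_AS, "unknown biological processes")
})

test_that("annotation and OBO readers parse their formats", {
  ann_path <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tterm\tslim",
               "g1\tGO:1\tstress",
               "g1\tGO:2\tmetabolism",
               "g2\tGO:1\tstress"), ann_path)
  ann <- read_annotation_tsv(ann_path)
  expect_setequal(ann$gene2terms$g1, c("GO:1", "GO:2"))
  expect_identical(unname(ann$slim["GO:1"]), "stress")

  obo_path <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:1", "name: root", "",
               "[Term]", "id: GO:2", "name: child", "is_a: GO:1 ! root", "",
               "[Term]", "id: GO:3", "name: dead", "is_obsolete: true", "",
               "[Typedef]", "id: part_of"), obo_path)
  obo <- read_obo(obo_path)
  expect_identical(obo$parents$`GO:2`, "GO:1")
  expect_false("GO:3" %in% names(obo$parents))
  expect_identical(unname(obo$names["GO:2"]), "child")

  # enrichment writer round-trip of the column layout
  universe <- paste0("g", 1:10)
  ann2 <- annotation_map(setNames(lapply(1:10, function(i)
    if (i <= 4) "GO:1" else "GO:2"), universe))
  res <- enrich(paste0("g", 1:4), ann2, universe)
  out <- tempfile(fileext = ".tsv")
  write_enrichment_tsv(res, out)
  back <- read.delim(out)
  expect_identical(names(back),
                   c("term", "p_value", "p_corrected", "k", "K", "n", "N", "members"))
})
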