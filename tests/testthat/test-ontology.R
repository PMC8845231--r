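# OBO parsing, DAG queries, count propagation and information content

minimal_obo <- c(
  "format-version: 1.2", "",
  "[Term]", "id: R", "name: root", "namespace: synthetic", "",
  "[Term]", "id: A", "name: alpha", "namespace: synthetic", "is_a: R ! root", "",
  "[Term]", "id: B", "name: beta", "namespace: synthetic",
  "relationship: part_of R ! root", ""
)

test_that("read_obo parses is_a and part_of edges into a rooted graph", {
  g <- read_obo(minimal_obo, text = TRUE)
  expect_s3_class(g, "ontology_graph")
  expect_setequal(g$terms$id, c("R", "A", "B"))
  expect_identical(unname(g$roots), "R")
  expect_identical(g$parents$A, "R")
  expect_identical(g$parents$B, "R")
  expect_identical(g$relations$B, "part_of")
})

test_that("is_a-only relation handling drops part_of edges", {
  obo <- c("[Term]", "id: R", "name: root", "namespace: synthetic", "",
           "[Term]", "id: A", "name: alpha", "namespace: synthetic",
           "is_a: R ! root", "",
           "[Term]", "id: B", "name: beta", "namespace: synthetic",
           "is_a: R ! root", "relationship: part_of A ! alpha", "")
  g <- read_obo(obo, text = TRUE)
  expect_setequal(g$parents$B, c("R", "A"))
  expect_warning(g2 <- read_obo(obo, relations = "is_a", text = TRUE),
                 "part_of")
  expect_identical(g2$parents$B, "R")
})

test_that("obsolete terms are excluded from traversal", {
  obo <- c(minimal_obo,
           "[Term]", "id: X", "name: gone", "namespace: synthetic",
           "is_a: R ! root", "is_obsolete: true", "")
  g <- read_obo(obo, text = TRUE)
  expect_true("X" %in% g$terms$id)
  expect_true(g$terms$obsolete[g$terms$id == "X"])
  expect_false("X" %in% names(g$children))
  expect_error(term_ancestors(g, "X"), "unknown term")
})

test_that("a go-basic style stanza with two is_a parents yields both edges", {
  obo <- c(
    "[Term]", "id: GO:0007411", "name: axon guidance",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0007409", "name: axonogenesis",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0008045", "name: motor neuron axon guidance",
    "namespace: biological_process",
    "is_a: GO:0007411 ! axon guidance",
    "is_a: GO:0007409 ! axonogenesis", ""
  )
  expect_error(read_obo(obo, text = TRUE), "multiple roots")
  obo_rooted <- c(
    "[Term]", "id: GO:0008150", "name: biological_process",
    "namespace: biological_process", "",
    sub("^$", "", obo))
  obo_rooted <- append(obo_rooted, "is_a: GO:0008150 ! biological_process",
                       after = which(obo_rooted == "name: axon guidance") + 1L)
  obo_rooted <- append(obo_rooted, "is_a: GO:0008150 ! biological_process",
                       after = which(obo_rooted == "name: axonogenesis") + 1L)
  g <- read_obo(obo_rooted, text = TRUE)
  expect_setequal(g$parents[["GO:0008045"]], c("GO:0007411", "GO:0007409"))
})

test_that("malformed stanzas and cycles are rejected with context", {
  expect_error(read_obo(c("[Term]", "name: no id here"), text = TRUE),
               "missing id")
  cyc <- c("[Term]", "id: P", "namespace: s", "is_a: Q", "",
           "[Term]", "id: Q", "namespace: s", "is_a: P", "")
  expect_error(read_obo(cyc, text = TRUE), "cycle")
})

test_that("unknown relationship types are ignored with a warning", {
  obo <- c(minimal_obo[1:7],
           "[Term]", "id: Z", "name: zeta", "namespace: synthetic",
           "is_a: R ! root", "relationship: regulates R ! root", "")
  expect_warning(g <- read_obo(obo, text = TRUE), "regulates")
  expect_identical(g$parents$Z, "R")
})

test_that("ancestors is the reflexive transitive closure", {
  toy <- make_toy_dag()
  expect_identical(term_ancestors(toy$graph, "C"), c("A", "C", "R"))
  expect_identical(term_ancestors(toy$graph, "R"), "R")
  # diamond: both paths contribute
  obo <- c("[Term]", "id: R", "namespace: s", "",
           "[Term]", "id: A", "namespace: s", "is_a: R", "",
           "[Term]", "id: B", "namespace: s", "is_a: R", "",
           "[Term]", "id: X", "namespace: s", "is_a: A", "is_a: B", "")
  g <- read_obo(obo, text = TRUE)
  expect_setequal(term_ancestors(g, "X"), c("X", "A", "B", "R"))
})

test_that("count propagation matches the hand-worked toy values", {
  toy <- make_toy_dag()
  pc <- toy$corpus$propagated_counts
  expect_equal(unname(pc[c("A", "B", "R", "C", "D", "E")]),
               c(4, 4, 8, 2, 1, 3))
  expect_equal(unname(toy$corpus$namespace_totals["synthetic"]), 8)
})

test_that("GAF propagation deduplicates per gene-product across diamonds", {
  toy <- make_toy_dag()
  # one gene annotated to both C and D contributes once to shared ancestor A
  ann <- data.frame(gene = c("g1", "g1"), term = c("C", "D"))
  corpus <- propagate_counts(toy$graph, ann)
  expect_equal(unname(corpus$propagated_counts["A"]), 1)
  expect_equal(unname(corpus$propagated_counts["R"]), 1)
  expect_equal(unname(corpus$direct_counts[c("C", "D")]), c(1, 1))
})

test_that("empty or unknown annotations are handled per policy", {
  toy <- make_toy_dag()
  expect_error(propagate_counts(toy$graph, numeric(0)), "empty corpus")
  expect_error(propagate_counts(toy$graph, c(NOPE = 3)), "unknown")
  expect_warning(
    corpus <- propagate_counts(toy$graph, c(C = 2, NOPE = 3), unknown = "skip"),
    "skipped")
  expect_equal(unname(corpus$propagated_counts["R"]), 2)
})

test_that("probability and IC follow the propagated counts", {
  toy <- make_toy_dag()
  expect_equal(term_probability(toy$corpus, "C"), 0.25)
  expect_equal(term_probability(toy$corpus, "R"), 1)
  expect_equal(term_ic(toy$corpus, "C"), -log(0.25))
  expect_equal(term_ic(toy$corpus, "C"), 1.3863, tolerance = 1e-4)
  expect_equal(term_ic(toy$corpus, "D"), 2.0794, tolerance = 1e-4)
  expect_identical(term_ic(toy$corpus, "R"), 0)
  expect_equal(term_ic(toy$corpus, "C", base = 2), 2)  # log2(1/4)
})

test_that("p = 0 terms error or return Inf as configured", {
  toy <- make_toy_dag()
  g2 <- read_obo(c(write_obo(toy$graph),
                   "[Term]", "id: F", "name: term F", "namespace: synthetic",
                   "is_a: B", ""), text = TRUE)
  corpus <- propagate_counts(g2, c(C = 2, D = 1, E = 3, B = 1, A = 1))
  expect_equal(term_probability(corpus, "F"), 0)
  expect_error(term_ic(corpus, "F"), "p = 0")
  expect_identical(term_ic(corpus, "F", zero = "inf"), Inf)
})

test_that("MICA picks the max-IC common ancestor with lexicographic ties", {
  toy <- make_toy_dag()
  m <- term_mica(toy$graph, toy$corpus, "C", "D")
  expect_identical(m$id, "A")
  expect_equal(m$ic, 0.6931, tolerance = 1e-4)
  expect_identical(term_mica(toy$graph, toy$corpus, "C", "E")$id, "R")
  expect_identical(term_mica(toy$graph, toy$corpus, "C", "E")$ic, 0)
  # reflexive: mica(a, a) = a
  self <- term_mica(toy$graph, toy$corpus, "C", "C")
  expect_identical(self$id, "C")
  expect_equal(self$ic, term_ic(toy$corpus, "C"))
  # symmetric
  expect_identical(term_mica(toy$graph, toy$corpus, "D", "C"), m)
})

test_that("GAF reader keeps DB object id and GO id, skipping NOT rows", {
  gaf <- c("!gaf-version: 2.2",
           paste(c("DB", "geneA", "geneA", "", "C", rep("", 12)), collapse = "\t"),
           paste(c("DB", "geneB", "geneB", "NOT", "D", rep("", 12)), collapse = "\t"),
           paste(c("DB", "geneC", "geneC", "NOT|contributes_to", "E",
                   rep("", 12)), collapse = "\t"),
           paste(c("DB", "geneD", "geneD", "involved_in", "E", rep("", 12)),
                 collapse = "\t"))
  ann <- read_gaf(gaf, text = TRUE)
  expect_identical(ann$gene, c("geneA", "geneD"))
  expect_identical(ann$term, c("C", "E"))
})

test_that("ancestors and MICA agree with igraph/enumeration oracles", {
  skip_if_not_installed("igraph")
  for (seed in 1:25) {
    inst <- random_instance(seed, n_terms = sample(4:15, 1))
    g <- inst$graph
    ids <- names(g$children)
    for (id in sample(ids, min(4, length(ids)))) {
      expect_identical(term_ancestors(g, id), oracle_ancestors(g, id))
    }
    pair <- sample(inst$result$terms$term_id, 2)
    got <- term_mica(g, inst$corpus, pair[1], pair[2])
    want <- oracle_mica(g, inst$corpus, pair[1], pair[2])
    expect_identical(got$id, want$id)
    expect_equal(got$ic, want$ic, tolerance = 1e-12)
  }
})

test_that("IC is monotone along every edge and root count totals the corpus", {
  for (seed in 1:20) {
    inst <- random_instance(seed)
    g <- inst$graph
    pc <- inst$corpus$propagated_counts
    for (child in names(g$parents)) {
      for (parent in g$parents[[child]]) {
        expect_gte(pc[[parent]], pc[[child]])
      }
    }
    # GAF mode: root propagated count = distinct gene-product x namespace pairs
    expect_equal(
      unname(inst$corpus$namespace_totals[["biological_process"]]),
      length(unique(inst$annotations$gene)))
  }
})
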