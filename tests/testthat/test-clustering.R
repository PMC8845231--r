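# Agglomerative clustering, threshold cuts, collapse/expand, leaf order

three_term_result <- function() {
  # pairwise jaccard: AB = 80 (8/10); AC small (1/18), BC = 0
  enrichment_result(
    term_id = c("GO:A", "GO:B", "GO:C"),
    term_name = c("term A", "term B", "term C"),
    p_value = c(1e-4, 1e-3, 1e-2),
    genes = list(paste0("g", 1:9),             # A: g1..g9
                 paste0("g", 2:10),            # B: g2..g10
                 c("g1", "x1", "x2", "x3", "x4", "x5", "x6", "x7", "x8", "x9")))
}

jaccard_ctx <- function(result) {
  similarity_context(result, similarity_config("jaccard"))
}

test_that("a single term yields a single-leaf dendrogram with no merges", {
  res <- enrichment_result("GO:X", "only", 0.01, list("g1"))
  d <- build_dendrogram(res, jaccard_ctx(res))
  expect_length(d$merges, 0L)
  expect_identical(d$roots, "GO:X")
  expect_identical(leaf_order(d), "GO:X")
})

test_that("three terms merge best pair first, then the merged cluster", {
  res <- three_term_result()
  ctx <- jaccard_ctx(res)
  expect_equal(cluster_similarity("GO:A", "GO:B", ctx), 80)
  d <- build_dendrogram(res, ctx)
  m1 <- d$nodes[[d$merges[1]]]
  expect_setequal(m1$leaves, c("GO:A", "GO:B"))
  expect_equal(m1$similarity, 80)
  m2 <- d$nodes[[d$merges[2]]]
  expect_setequal(m2$leaves, c("GO:A", "GO:B", "GO:C"))
  # second merge similarity = jaccard(union(A,B), C) recomputed on clusters
  expect_equal(m2$similarity,
               cluster_similarity(c("GO:A", "GO:B"), "GO:C", ctx))
})

test_that("all-equal similarities resolve by the lexicographic tie-break", {
  # four disjoint-ish terms engineered so every pairwise jaccard is equal
  res <- enrichment_result(
    term_id = c("GO:a1", "GO:a2", "GO:a3", "GO:a4"),
    term_name = paste("t", 1:4), p_value = rep(0.01, 4),
    genes = list(c("s", "p1"), c("s", "p2"), c("s", "p3"), c("s", "p4")))
  ctx <- jaccard_ctx(res)
  d <- build_dendrogram(res, ctx)
  # first merge must be the lexicographically smallest pair (a1, a2)
  expect_setequal(d$nodes[[d$merges[1]]]$leaves, c("GO:a1", "GO:a2"))
  want <- oracle_agglomerate(res$terms$term_id, ctx)
  expect_equal(dendro_merge_list(d), want)
})

test_that("zero/undefined similarities never merge, leaving a forest", {
  res <- enrichment_result(
    term_id = c("GO:u", "GO:v"), term_name = c("u", "v"),
    p_value = c(0.01, 0.02), genes = list("g1", "g2"))
  d <- build_dendrogram(res, jaccard_ctx(res))
  expect_length(d$merges, 0L)
  expect_identical(d$roots, c("GO:u", "GO:v"))
})

test_that("build_dendrogram equals the brute-force reference on random instances", {
  for (seed in 1:30) {
    inst <- random_instance(seed, n_terms = sample(4:13, 1))
    cfg <- random_config(seed)
    ctx <- random_context(inst, cfg)
    d <- build_dendrogram(inst$result, ctx)
    want <- oracle_agglomerate(inst$result$terms$term_id, ctx)
    expect_equal(dendro_merge_list(d), want,
                 info = paste("seed", seed, cfg$metric, cfg$aggregate))
  }
})

test_that("threshold cuts follow strictly-greater semantics", {
  res <- three_term_result()
  ctx <- jaccard_ctx(res)
  d <- build_dendrogram(res, ctx)
  sims <- vapply(d$merges, function(m) d$nodes[[m]]$similarity, numeric(1))
  # above every merge: all singletons
  v <- cut_dendrogram(d, max(sims))
  expect_setequal(v$active, res$terms$term_id)
  # below every merge: one cluster per root
  v <- cut_dendrogram(d, min(sims) - 1e-9)
  expect_identical(v$active, d$roots)
  # at 50: {A,B} stays merged iff the second merge sim <= 50
  v <- cut_dendrogram(d, 50)
  expect_setequal(v$active, c(d$merges[1], "GO:C"))
  expect_true(all(v$provenance == "systematic"))
})

test_that("raising the threshold only refines the partition", {
  partition_of <- function(view, dend) {
    lapply(view$active, function(v) dend$nodes[[v]]$leaves)
  }
  refines <- function(fine, coarse) {
    all(vapply(fine, function(f) {
      any(vapply(coarse, function(c) all(f %in% c), logical(1)))
    }, logical(1)))
  }
  for (seed in 1:20) {
    inst <- random_instance(seed)
    ctx <- random_context(inst, random_config(seed))
    d <- build_dendrogram(inst$result, ctx)
    sims <- vapply(d$merges, function(m) d$nodes[[m]]$similarity, numeric(1))
    grid <- sort(unique(c(-1, sims, sims / 2, max(c(sims, 1)) + 1)))
    views <- lapply(grid, function(t) cut_dendrogram(d, t))
    for (k in seq_along(grid)[-1]) {
      expect_true(refines(partition_of(views[[k]], d),
                          partition_of(views[[k - 1]], d)),
                  info = paste("seed", seed, "thresholds",
                               grid[k - 1], grid[k]))
    }
  }
})

test_that("collapse replaces covered clusters and expand restores them", {
  res <- three_term_result()
  ctx <- jaccard_ctx(res)
  d <- build_dendrogram(res, ctx)
  v0 <- cut_dendrogram(d, 100)          # all singletons
  v1 <- collapse_node(v0, d, d$merges[1])
  expect_length(v1$active, 2L)
  expect_identical(unname(v1$provenance[d$merges[1]]), "manual")
  # collapsing an already-active node is a no-op
  expect_identical(collapse_node(v1, d, d$merges[1]), v1)
  # expand is the exact inverse
  expect_identical(expand_node(v1, d, d$merges[1]), v0)
  # expanding a leaf fails
  expect_error(expand_node(v0, d, "GO:C"), "leaf")
  expect_error(expand_node(v0, d, d$merges[2]), "not active")
  # collapse across a coarser sibling fails the antichain check
  v3 <- collapse_node(v0, d, d$merges[2])  # everything in one cluster
  expect_error(collapse_node(v3, d, d$merges[1]), "outside")
})

test_that("expand-after-collapse is the identity on random views", {
  for (seed in 1:20) {
    set.seed(seed)
    inst <- random_instance(seed)
    ctx <- random_context(inst, random_config(seed))
    d <- build_dendrogram(inst$result, ctx)
    if (!length(d$merges)) next
    sims <- vapply(d$merges, function(m) d$nodes[[m]]$similarity, numeric(1))
    v <- cut_dendrogram(d, sample(c(-1, sims), 1))
    collapsible <- Filter(function(n) {
      !(n %in% v$active) &&
        !inherits(try(collapse_node(v, d, n), silent = TRUE), "try-error")
    }, d$merges)
    if (!length(collapsible)) next
    n <- sample(collapsible, 1)
    expect_identical(expand_node(collapse_node(v, d, n), d, n), v,
                     info = paste("seed", seed))
  }
})

test_that("the partition invariant survives arbitrary op sequences", {
  check_partition <- function(view, dend) {
    leaves <- unlist(lapply(view$active, function(v) dend$nodes[[v]]$leaves))
    !anyDuplicated(leaves) && setequal(leaves, sort(unlist(
      lapply(dend$roots, function(r) dend$nodes[[r]]$leaves))))
  }
  for (seed in 1:10) {
    set.seed(seed)
    inst <- random_instance(seed)
    ctx <- random_context(inst, random_config(seed))
    d <- build_dendrogram(inst$result, ctx)
    v <- cut_dendrogram(d, stats::runif(1, -1, 1))
    for (step in 1:20) {
      if (stats::runif(1) < 0.5) {
        cand <- Filter(function(n) {
          !(n %in% v$active) &&
            !inherits(try(collapse_node(v, d, n), silent = TRUE), "try-error")
        }, d$merges)
        if (length(cand)) v <- collapse_node(v, d, sample(cand, 1))
      } else {
        cand <- intersect(v$active, d$merges)
        if (length(cand)) v <- expand_node(v, d, sample(cand, 1))
      }
      expect_true(check_partition(v, d), info = paste("seed", seed, "step", step))
    }
  }
})

test_that("leaf order keeps merge partners adjacent, forests lexicographic", {
  res <- three_term_result()
  ctx <- jaccard_ctx(res)
  d <- build_dendrogram(res, ctx)
  ord <- leaf_order(d)
  expect_setequal(ord, res$terms$term_id)
  expect_equal(abs(diff(match(c("GO:A", "GO:B"), ord))), 1)  # AB adjacent
  expect_identical(ord[3], "GO:C")
  # children of every internal node span contiguous ranges
  for (seed in 1:10) {
    inst <- random_instance(seed)
    ctx <- random_context(inst, random_config(seed))
    d <- build_dendrogram(inst$result, ctx)
    ord <- match(leaf_order(d), inst$result$terms$term_id)
    expect_false(anyNA(ord))
    ordv <- leaf_order(d)
    for (m in d$merges) {
      pos <- match(d$nodes[[m]]$leaves, ordv)
      expect_equal(sort(pos), seq(min(pos), max(pos)),
                   info = paste("seed", seed, "node", m))
    }
  }
  # forest: trees concatenated by smallest leaf id
  res2 <- enrichment_result(c("GO:z", "GO:a"), c("z", "a"), c(0.01, 0.01),
                            list("g1", "g2"))
  d2 <- build_dendrogram(res2, jaccard_ctx(res2))
  expect_identical(leaf_order(d2), c("GO:a", "GO:z"))
})
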