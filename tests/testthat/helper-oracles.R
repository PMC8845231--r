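# Independent oracles used across the suite. They deliberately avoid the
# package's traversal/clustering code paths: ancestor closure goes through
# igraph, MICA/Resnik/SimRel through exhaustive enumeration, and the
# agglomerative reference recomputes every pairwise similarity from scratch
# at every step.

oracle_ancestors <- function(graph, id) {
  edges <- do.call(rbind, lapply(names(graph$parents), function(ch) {
    if (!length(graph$parents[[ch]])) return(NULL)
    cbind(ch, graph$parents[[ch]])
  }))
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(names(graph$children))
  if (!is.null(edges)) g <- g + igraph::edges(t(edges))
  sort(names(igraph::subcomponent(g, id, mode = "out")))
}

oracle_ic <- function(corpus, id) {
  p <- corpus$propagated_counts[[id]] /
    corpus$namespace_totals[[corpus$namespaces[[id]]]]
  -log(p) + 0
}

oracle_common_ancestors <- function(graph, a, b) {
  intersect(oracle_ancestors(graph, a), oracle_ancestors(graph, b))
}

oracle_mica <- function(graph, corpus, a, b) {
  common <- oracle_common_ancestors(graph, a, b)
  common <- common[vapply(common, function(t) corpus$propagated_counts[[t]] > 0,
                          logical(1))]
  ic <- vapply(common, function(t) oracle_ic(corpus, t), numeric(1))
  best <- max(ic)
  cand <- sort(common[ic == best])
  list(id = cand[[1]], ic = unname(best))
}

oracle_resnik <- function(graph, corpus, a, b) oracle_mica(graph, corpus, a, b)$ic

oracle_simrel <- function(graph, corpus, a, b) {
  ica <- oracle_ic(corpus, a)
  icb <- oracle_ic(corpus, b)
  if (ica + icb == 0) return(0)
  common <- oracle_common_ancestors(graph, a, b)
  vals <- vapply(common, function(c) {
    p <- corpus$propagated_counts[[c]] /
      corpus$namespace_totals[[corpus$namespaces[[c]]]]
    if (p <= 0) return(-Inf)
    (2 * (-log(p) + 0) / (ica + icb)) * (1 - p)
  }, numeric(1))
  max(vals) + 0
}

# Brute-force greedy agglomeration: at every step rescan all cluster pairs,
# recomputing SIM, and merge the best pair (ties by the (smaller, larger)
# smallest-leaf-id tuple). Returns the merge list in order, each merge as
# the sorted leaf sets of the two merged clusters plus the similarity.
oracle_agglomerate <- function(term_ids, context) {
  clusters <- as.list(term_ids)
  merges <- list()
  repeat {
    n <- length(clusters)
    if (n < 2L) break
    best <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        s <- cluster_similarity(clusters[[i]], clusters[[j]], context)
        if (is.na(s) || s <= 0) next
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || s > best$s ||
            (s == best$s && (key[1] < best$key[1] ||
                             (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, s = s, key = key)
        }
      }
    }
    if (is.null(best)) break
    a <- clusters[[best$i]]; b <- clusters[[best$j]]
    if (min(a) > min(b)) { tmp <- a; a <- b; b <- tmp }
    merges[[length(merges) + 1L]] <-
      list(left = sort(a), right = sort(b), similarity = best$s)
    clusters <- c(clusters[-c(best$i, best$j)], list(c(a, b)))
  }
  merges
}

# flatten a go_dendrogram into the same merge-list shape
dendro_merge_list <- function(dend) {
  lapply(dend$merges, function(m) {
    nd <- dend$nodes[[m]]
    list(left = sort(dend$nodes[[nd$left]]$leaves),
         right = sort(dend$nodes[[nd$right]]$leaves),
         similarity = nd$similarity)
  })
}

random_instance <- function(seed, n_terms = NULL, overlap_rate = NULL) {
  set.seed(seed)
  if (is.null(n_terms)) n_terms <- sample(4:13, 1)
  if (is.null(overlap_rate)) overlap_rate <- stats::runif(1, 0, 0.9)
  make_random_instance(fixture_spec(
    n_terms = n_terms,
    max_parents = sample(1:3, 1),
    n_genes = 40 + 12 * n_terms,
    genes_per_term = c(2, 5),
    overlap_rate = overlap_rate,
    seed = seed
  ))
}

random_config <- function(seed) {
  set.seed(seed + 999L)
  similarity_config(
    metric = sample(c("jaccard", "resnik", "simrel"), 1),
    aggregate = sample(c("average", "minimum", "maximum"), 1)
  )
}

random_context <- function(inst, config) {
  similarity_context(inst$result, config, inst$graph, inst$corpus)
}

# a random session from a random instance: dendrogram + random cut + a few
# random collapse/expand operations
random_session <- function(seed) {
  inst <- random_instance(seed)
  config <- random_config(seed)
  ctx <- random_context(inst, config)
  dend <- build_dendrogram(inst$result, ctx)
  sims <- vapply(dend$merges, function(m) dend$nodes[[m]]$similarity, numeric(1))
  thr <- if (length(sims)) sample(c(-1, stats::quantile(sims, stats::runif(1))), 1)
         else 0
  view <- cut_dendrogram(dend, thr)
  internal <- names(dend$nodes)[vapply(dend$nodes, function(n) n$type == "merge",
                                       logical(1))]
  for (k in seq_len(sample(0:3, 1))) {
    cand <- setdiff(internal, view$active)
    cand <- cand[vapply(cand, function(nd) {
      !inherits(try(collapse_node(view, dend, nd), silent = TRUE), "try-error")
    }, logical(1))]
    if (!length(cand)) break
    view <- collapse_node(view, dend, sample(cand, 1))
  }
  new_session(config, inst$result, dend, view, context = ctx)
}
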