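# -- pairwise term similarities ---------------------------------------------

normalize_genes <- function(genes) {
  g <- toupper(trimws(as.character(genes)))
  sort(unique(g[nzchar(g)]))
}

#' Percentage of common genes (Jaccard similarity)
#'
#' `100 * |A intersect B| / |A union B|`. Gene identifiers are trimmed and
#' compared case-insensitively.
#'
#' @param genes_a,genes_b Gene identifier vectors; at least one non-empty.
#' @return Percent in `[0, 100]`.
#' @examples
#' jaccard_percent(c("shha", "tbx5"), c("TBX5", "nkx2.5"))
#' @export
jaccard_percent <- function(genes_a, genes_b) {
  a <- normalize_genes(genes_a)
  b <- normalize_genes(genes_b)
  if (!length(a) && !length(b)) {
    stop("Jaccard similarity undefined: both gene sets are empty", call. = FALSE)
  }
  100 * length(intersect(a, b)) / length(union(a, b))
}

#' Resnik semantic similarity
#'
#' The information content of the most informative common ancestor of two
#' terms. Symmetric; `resnik_sim(a, a) = IC(a)`; 0 when the only common
#' ancestor is the namespace root.
#'
#' @inheritParams term_mica
#' @return Non-negative similarity in IC units (nats by default).
#' @export
resnik_sim <- function(graph, corpus, a, b, base = exp(1)) {
  term_mica(graph, corpus, a, b, base = base)$ic
}

#' SimRel (relevance) semantic similarity
#'
#' Schlicker's relevance score: the maximum over common ancestors `c` of
#' `(2 IC(c) / (IC(a) + IC(b))) * (1 - p(c))` — a Lin-style IC ratio
#' down-weighted by how common the ancestor is, so promiscuous ancestors
#' near the root contribute little. Defined as 0 when `IC(a) + IC(b) = 0`
#' (both terms are roots).
#'
#' @inheritParams term_mica
#' @return Similarity in `[0, 1)`.
#' @export
simrel_sim <- function(graph, corpus, a, b, base = exp(1)) {
  ica <- term_ic(corpus, a, base = base)
  icb <- term_ic(corpus, b, base = base)
  if (ica + icb == 0) return(0)
  common <- intersect(term_ancestors(graph, a), term_ancestors(graph, b))
  if (!length(common)) {
    stop("terms ", a, " and ", b, " have no common ancestor ",
         "(different namespaces?)", call. = FALSE)
  }
  p <- vapply(common, function(t) term_probability(corpus, t), numeric(1))
  p <- p[p > 0]
  if (!length(p)) {
    stop("no common ancestor of ", a, " and ", b, " is annotated", call. = FALSE)
  }
  ic <- -log(p, base = base) + 0  # -0 -> 0
  max(2 * ic / (ica + icb) * (1 - p)) + 0
}

# -- configuration and cluster-level SIM -------------------------------------

#' Similarity configuration
#'
#' Bundles the metric and (for semantic metrics) the aggregate used by the
#' cluster-level SIM function. `aggregate` is ignored for `"jaccard"`,
#' where clusters are compared by the overlap of their pooled gene sets.
#'
#' @param metric `"jaccard"` (percentage of common genes), `"resnik"` or
#'   `"simrel"`.
#' @param aggregate How pairwise term similarities combine across two
#'   clusters: `"average"`, `"minimum"` or `"maximum"`.
#' @param ic_base Logarithm base for information content (natural log,
#'   i.e. nats, by default).
#' @return A `similarity_config`.
#' @export
similarity_config <- function(metric = c("jaccard", "resnik", "simrel"),
                              aggregate = c("average", "minimum", "maximum"),
                              ic_base = exp(1)) {
  metric <- match.arg(metric)
  aggregate <- match.arg(aggregate)
  stopifnot(is.numeric(ic_base), length(ic_base) == 1L, ic_base > 1)
  structure(list(metric = metric, aggregate = aggregate, ic_base = ic_base),
            class = "similarity_config")
}

#' @export
print.similarity_config <- function(x, ...) {
  cat("similarity_config: metric =", x$metric,
      if (x$metric != "jaccard") paste0("(aggregate = ", x$aggregate, ")"),
      "\n")
  invisible(x)
}

#' Precomputed similarity context for an enrichment result
#'
#' Caches per-term normalized gene sets and, for semantic metrics, the full
#' pairwise term-similarity matrix, so clustering does not recompute
#' ancestor closures. Terms with `p = 0` (no annotation support) are
#' excluded from semantic similarity with a warning — their pairwise values
#' are `NA` and they can only merge under Jaccard. Cross-namespace pairs
#' score 0 with a warning.
#'
#' @param result An `enrichment_result`.
#' @param config A `similarity_config`.
#' @param graph,corpus Ontology and annotation corpus; required for
#'   semantic metrics, optional for Jaccard.
#' @return A `similarity_context`.
#' @export
similarity_context <- function(result, config, graph = NULL, corpus = NULL) {
  stopifnot(inherits(result, "enrichment_result"),
            inherits(config, "similarity_config"))
  ids <- result$terms$term_id
  gene_sets <- lapply(result$genes[ids], normalize_genes)
  names(gene_sets) <- ids
  term_sim <- NULL
  if (config$metric != "jaccard") {
    if (is.null(graph) || is.null(corpus)) {
      stop("semantic metric '", config$metric,
           "' requires an ontology graph and annotation corpus", call. = FALSE)
    }
    term_sim <- semantic_matrix(graph, corpus, ids, config)
  }
  structure(list(gene_sets = gene_sets, term_sim = term_sim, config = config),
            class = "similarity_context")
}

semantic_matrix <- function(graph, corpus, ids, config) {
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  ns <- vapply(ids, function(i) term_namespace(graph, i), character(1))
  p <- vapply(ids, function(i) term_probability(corpus, i), numeric(1))
  if (any(p == 0)) {
    warning("term(s) without annotation support excluded from semantic ",
            "similarity: ", paste(ids[p == 0], collapse = ", "), call. = FALSE)
  }
  cross_ns <- FALSE
  fn <- if (config$metric == "resnik") resnik_sim else simrel_sim
  for (i in seq_len(n)) {
    if (p[[i]] == 0) next
    for (j in i:n) {
      if (p[[j]] == 0) next
      if (ns[[i]] != ns[[j]]) {
        cross_ns <- TRUE
        m[i, j] <- m[j, i] <- 0
        next
      }
      v <- fn(graph, corpus, ids[[i]], ids[[j]], base = config$ic_base)
      m[i, j] <- m[j, i] <- v
    }
  }
  if (cross_ns) {
    warning("cross-namespace term pairs present; their semantic similarity ",
            "is defined as 0", call. = FALSE)
  }
  m
}

#' Cluster-level similarity (the SIM function)
#'
#' Similarity between two disjoint clusters of enriched terms. Under
#' Jaccard the pooled gene sets of the two clusters are compared and the
#' overlap returned as a percentage. Under a semantic metric the pairwise
#' term similarities over all cross-cluster combinations are combined by
#' the configured aggregate (arithmetic mean, minimum or maximum);
#' undefined pairs (unannotated terms) are left out, and the result is `NA`
#' when no pair is defined.
#'
#' @param a_terms,b_terms Character vectors of term ids (disjoint,
#'   non-empty).
#' @param context A `similarity_context`.
#' @return Numeric similarity, or `NA` when undefined.
#' @export
cluster_similarity <- function(a_terms, b_terms, context) {
  stopifnot(inherits(context, "similarity_context"))
  if (!length(a_terms) || !length(b_terms)) {
    stop("cluster similarity undefined for an empty cluster", call. = FALSE)
  }
  if (length(intersect(a_terms, b_terms))) {
    stop("clusters overlap: ", paste(intersect(a_terms, b_terms), collapse = ", "),
         call. = FALSE)
  }
  cfg <- context$config
  if (cfg$metric == "jaccard") {
    ga <- unique(unlist(context$gene_sets[a_terms], use.names = FALSE))
    gb <- unique(unlist(context$gene_sets[b_terms], use.names = FALSE))
    return(jaccard_percent(ga, gb))
  }
  vals <- context$term_sim[a_terms, b_terms, drop = FALSE]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  switch(cfg$aggregate,
         average = mean(vals),
         minimum = min(vals),
         maximum = max(vals))
}
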