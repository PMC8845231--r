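# -- MICA hierarchy subgraph -------------------------------------------------

#' Ontology subgraph joining two terms
#'
#' The induced DAG fragment on the union of the ancestor sets of `a` and
#' `b` (which must share a namespace), with each node flagged as a query
#' term, a common ancestor, and/or the most informative common ancestor —
#' the view shown when a user inspects why two enriched terms are
#' semantically similar.
#'
#' @inheritParams term_mica
#' @return A `go_subgraph`: node table (`id`, `name`, `is_query`,
#'   `is_common`, `is_mica`), edge table (`child`, `parent`, `relation`),
#'   the query pair and the MICA id with its IC.
#' @export
hierarchy_subgraph <- function(graph, corpus, a, b, base = exp(1)) {
  ns_a <- term_namespace(graph, a)
  ns_b <- term_namespace(graph, b)
  if (!identical(ns_a, ns_b)) {
    stop("terms ", a, " (", ns_a, ") and ", b, " (", ns_b,
         ") are in different namespaces", call. = FALSE)
  }
  anc_a <- term_ancestors(graph, a)
  anc_b <- term_ancestors(graph, b)
  ids <- sort(union(anc_a, anc_b))
  common <- intersect(anc_a, anc_b)
  mica <- term_mica(graph, corpus, a, b, base = base)

  nodes <- data.frame(
    id = ids,
    name = vapply(ids, function(i) term_name(graph, i), character(1)),
    is_query = ids %in% c(a, b),
    is_common = ids %in% common,
    is_mica = ids == mica$id,
    row.names = NULL, stringsAsFactors = FALSE
  )
  edges <- do.call(rbind, c(list(
    data.frame(child = character(0), parent = character(0),
               relation = character(0), stringsAsFactors = FALSE)),
    lapply(ids, function(i) {
      keep <- graph$parents[[i]] %in% ids
      data.frame(child = rep(i, sum(keep)), parent = graph$parents[[i]][keep],
                 relation = graph$relations[[i]][keep],
                 stringsAsFactors = FALSE)
    })))
  structure(list(nodes = nodes, edges = edges, query = c(a, b),
                 mica = mica$id, mica_ic = mica$ic),
            class = "go_subgraph")
}

#' @export
print.go_subgraph <- function(x, ...) {
  cat("go_subgraph:", nrow(x$nodes), "terms,", nrow(x$edges), "edges; MICA",
      x$mica, sprintf("(IC %.4f)\n", x$mica_ic))
  invisible(x)
}

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Render a hierarchy subgraph as DOT
#'
#' Graphviz DOT text: query terms are boxes, the MICA is filled, `part_of`
#' edges are dashed. Edges point child -> parent (specific to general).
#'
#' @param sub A `go_subgraph`.
#' @param file Optional output path.
#' @return The DOT lines, invisibly when written to file.
#' @export
subgraph_dot <- function(sub, file = NULL) {
  stopifnot(inherits(sub, "go_subgraph"))
  n <- sub$nodes
  node_lines <- vapply(seq_len(nrow(n)), function(i) {
    attrs <- c(
      paste0("label=", dot_quote(paste0(n$id[i], "\\n", n$name[i]))),
      if (n$is_query[i]) "shape=box" else "shape=ellipse",
      if (n$is_mica[i]) c("style=filled", "fillcolor=gold")
      else if (n$is_common[i]) c("style=filled", "fillcolor=lightgrey")
    )
    paste0("  ", dot_quote(n$id[i]), " [", paste(attrs, collapse = ", "), "];")
  }, character(1))
  e <- sub$edges
  edge_lines <- if (nrow(e)) vapply(seq_len(nrow(e)), function(i) {
    style <- if (e$relation[i] == "part_of") " [style=dashed, label=\"part_of\"]" else ""
    paste0("  ", dot_quote(e$child[i]), " -> ", dot_quote(e$parent[i]), style, ";")
  }, character(1)) else character(0)
  lines <- c("digraph go_hierarchy {", "  rankdir=BT;", node_lines, edge_lines, "}")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
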