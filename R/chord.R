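# -- chord-diagram model -----------------------------------------------------

#' p-value color bin
#'
#' Assigns each p-value to one of six ordinal significance bins used to
#' colour arcs: bin 1 for p >= 0.05 down to bin 6 for p < 1e-8, with cut
#' points at 0.05, 1e-2, 1e-4, 1e-6 and 1e-8.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Integer vector of bins in `1:6` (higher = more significant).
#' @export
p_value_bin <- function(p) {
  stopifnot(is.numeric(p), all(p > 0 & p <= 1))
  cuts <- c(0.05, 1e-2, 1e-4, 1e-6, 1e-8)
  vapply(p, function(x) 1L + sum(x < cuts), integer(1))
}

#' Build the chord-diagram model of a cluster view
#'
#' Translates the current partition into the serializable description the
#' chord diagram is drawn from:
#'
#' * one **arc** per active cluster, in leaf order, sized by the number of
#'   distinct genes-of-interest in the cluster (`arc_fraction` is the
#'   cluster's share of the summed gene counts) and coloured by the most
#'   significant (minimum) member p-value;
#' * a **link** for every cluster pair sharing at least one gene, carrying
#'   the shared gene list and the overlap percentage of the pooled sets;
#' * a **merge arc** between every pair of leaf-order-adjacent clusters,
#'   labelled with their cluster-level similarity — the merge candidates a
#'   user can click to collapse.
#'
#' @param view A `cluster_view`.
#' @param dend The `go_dendrogram` behind the view.
#' @param result The `enrichment_result` that was clustered.
#' @param context The `similarity_context` used for clustering.
#' @return A `chord_model` with elements `arcs`, `links` and `merge_arcs`.
#' @export
build_chord <- function(view, dend, result, context) {
  stopifnot(inherits(view, "cluster_view"), inherits(dend, "go_dendrogram"),
            inherits(result, "enrichment_result"),
            inherits(context, "similarity_context"))
  check_view(view, dend)
  if (!setequal(dendro_leaves(dend), result$terms$term_id)) {
    stop("view/dendrogram and enrichment result describe different term sets",
         call. = FALSE)
  }

  ord <- leaf_order(dend)
  first_pos <- vapply(view$active, function(v) {
    min(match(dend$nodes[[v]]$leaves, ord))
  }, numeric(1))
  clusters <- view$active[order(first_pos)]

  arcs <- lapply(clusters, function(v) {
    members <- dend$nodes[[v]]$leaves
    members <- ord[ord %in% members]           # members in display order
    genes <- sort(unique(unlist(context$gene_sets[members], use.names = FALSE)))
    idx <- match(members, result$terms$term_id)
    list(cluster_id = v,
         label = paste(result$terms$term_name[idx], collapse = "; "),
         gene_count = length(genes),
         arc_fraction = NA_real_,               # filled below
         p_value_bin = p_value_bin(min(result$terms$p_value[idx])),
         p_value = min(result$terms$p_value[idx]),
         member_terms = members,
         genes = genes)
  })
  total <- sum(vapply(arcs, `[[`, numeric(1), "gene_count"))
  if (total <= 0) stop("no genes in any cluster", call. = FALSE)
  arcs <- lapply(arcs, function(a) {
    a$arc_fraction <- a$gene_count / total
    a
  })
  names(arcs) <- NULL

  links <- list()
  if (length(arcs) > 1L) {
    for (i in seq_len(length(arcs) - 1L)) {
      for (j in seq(i + 1L, length(arcs))) {
        shared <- intersect(arcs[[i]]$genes, arcs[[j]]$genes)
        if (!length(shared)) next
        links[[length(links) + 1L]] <- list(
          cluster_a = arcs[[i]]$cluster_id,
          cluster_b = arcs[[j]]$cluster_id,
          shared_genes = sort(shared),
          shared_percent = jaccard_percent(arcs[[i]]$genes, arcs[[j]]$genes)
        )
      }
    }
  }

  merge_arcs <- list()
  if (length(arcs) > 1L) {
    for (i in seq_len(length(arcs) - 1L)) {
      a <- clusters[[i]]; b <- clusters[[i + 1L]]
      s <- cluster_similarity(dend$nodes[[a]]$leaves, dend$nodes[[b]]$leaves,
                              context)
      merge_arcs[[i]] <- list(cluster_a = a, cluster_b = b,
                              similarity = if (is.na(s)) 0 else s)
    }
  }

  structure(list(arcs = arcs, links = links, merge_arcs = merge_arcs),
            class = "chord_model")
}

#' @export
print.chord_model <- function(x, ...) {
  cat("chord_model:", length(x$arcs), "arcs,", length(x$links), "links,",
      length(x$merge_arcs), "merge arc(s)\n")
  invisible(x)
}

# -- free-text search --------------------------------------------------------

#' Search genes and terms in an enrichment result
#'
#' Case-insensitive substring search. A matching gene is reported together
#' with every enriched term whose gene set contains it; terms match on
#' accession or name.
#'
#' @param result An `enrichment_result`.
#' @param query Free-text query.
#' @return List with `genes` (named list gene -> annotating term ids) and
#'   `terms` (matching term ids); both may be empty.
#' @export
search_enrichment <- function(result, query) {
  stopifnot(inherits(result, "enrichment_result"), is.character(query))
  q <- toupper(trimws(query))
  if (!nzchar(q)) return(list(genes = list(), terms = character(0)))
  all_genes <- sort(unique(unlist(result$genes, use.names = FALSE)))
  hit_genes <- all_genes[grepl(q, all_genes, fixed = TRUE)]
  genes <- lapply(hit_genes, function(g) {
    sort(result$terms$term_id[vapply(result$genes[result$terms$term_id],
                                     function(gs) g %in% gs, logical(1))])
  })
  names(genes) <- hit_genes
  term_hit <- grepl(q, toupper(result$terms$term_id), fixed = TRUE) |
    grepl(q, toupper(result$terms$term_name), fixed = TRUE)
  list(genes = genes, terms = result$terms$term_id[term_hit])
}
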