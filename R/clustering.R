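# -- dendrogram construction -------------------------------------------------

# tie-break key for a candidate merge: the (smaller, larger) pair of the two
# clusters' smallest leaf ids, compared lexicographically
pair_key <- function(leaves_a, leaves_b) {
  k <- sort(c(min(leaves_a), min(leaves_b)))
  paste(k[1], k[2], sep = "\r")
}

#' Agglomeratively cluster enriched terms
#'
#' Greedy agglomeration: starting from one singleton cluster per enriched
#' term, repeatedly merge the pair of current clusters with the highest
#' cluster-level similarity (recomputed on the merged clusters, not by
#' linkage updates), recording the merge similarity, until a single cluster
#' remains or every remaining pair scores 0 or is undefined — in which case
#' the result is a forest. Ties are broken deterministically: among
#' equal-similarity pairs the one whose (smaller, larger) tuple of smallest
#' member leaf ids sorts first is merged.
#'
#' @param result An `enrichment_result`.
#' @param context A `similarity_context` built from `result` (see
#'   [similarity_context()]).
#' @return A `go_dendrogram`: a node table (leaves named by term id, merge
#'   nodes `M1`, `M2`, ... in merge order), the root node ids, and the merge
#'   order.
#' @export
build_dendrogram <- function(result, context) {
  stopifnot(inherits(result, "enrichment_result"),
            inherits(context, "similarity_context"))
  ids <- result$terms$term_id
  nodes <- lapply(ids, function(t) {
    list(id = t, type = "leaf", term = t, leaves = t)
  })
  names(nodes) <- ids

  active <- ids                      # node ids of current clusters
  members <- stats::setNames(as.list(ids), ids)  # node id -> term ids
  n <- length(active)
  sim <- matrix(NA_real_, n, n, dimnames = list(active, active))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        v <- cluster_similarity(members[[i]], members[[j]], context)
        sim[i, j] <- sim[j, i] <- v
      }
    }
  }

  merges <- character(0)
  k <- 0L
  while (length(active) > 1L) {
    cand <- which(upper.tri(sim) & !is.na(sim) & sim > 0, arr.ind = TRUE)
    if (!nrow(cand)) break
    vals <- sim[cand]
    best <- max(vals)
    top <- cand[vals == best, , drop = FALSE]
    if (nrow(top) > 1L) {
      keys <- vapply(seq_len(nrow(top)), function(r) {
        pair_key(nodes[[active[top[r, 1]]]]$leaves,
                 nodes[[active[top[r, 2]]]]$leaves)
      }, character(1))
      top <- top[order(keys)[1], , drop = FALSE]
    }
    ia <- top[1, 1]; ib <- top[1, 2]
    na_id <- active[ia]; nb_id <- active[ib]
    # left child = the one whose smallest leaf sorts first
    if (min(nodes[[na_id]]$leaves) > min(nodes[[nb_id]]$leaves)) {
      tmp <- na_id; na_id <- nb_id; nb_id <- tmp
    }
    k <- k + 1L
    new_id <- paste0("M", k)
    merged_terms <- c(members[[na_id]], members[[nb_id]])
    nodes[[new_id]] <- list(
      id = new_id, type = "merge", left = na_id, right = nb_id,
      similarity = best,
      leaves = sort(c(nodes[[na_id]]$leaves, nodes[[nb_id]]$leaves))
    )
    merges <- c(merges, new_id)

    drop_idx <- match(c(na_id, nb_id), active)
    keep <- setdiff(seq_along(active), drop_idx)
    active <- c(active[keep], new_id)
    members[[na_id]] <- NULL; members[[nb_id]] <- NULL
    members[[new_id]] <- merged_terms

    old <- sim[keep, keep, drop = FALSE]
    n2 <- length(active)
    sim <- matrix(NA_real_, n2, n2, dimnames = list(active, active))
    if (n2 > 1L) {
      sim[seq_len(n2 - 1L), seq_len(n2 - 1L)] <- old
      for (i in seq_len(n2 - 1L)) {
        sim[i, n2] <- sim[n2, i] <-
          cluster_similarity(members[[active[i]]], merged_terms, context)
      }
    }
  }

  structure(
    list(nodes = nodes, roots = sort_node_ids(nodes, active), merges = merges),
    class = "go_dendrogram"
  )
}

# order node ids by their smallest leaf id (lexicographic)
sort_node_ids <- function(nodes, ids) {
  if (!length(ids)) return(character(0))
  ids[order(vapply(ids, function(i) min(nodes[[i]]$leaves), character(1)))]
}

#' @export
print.go_dendrogram <- function(x, ...) {
  cat("go_dendrogram:", sum(vapply(x$nodes, function(n) n$type == "leaf", TRUE)),
      "leaves,", length(x$merges), "merges,", length(x$roots), "root(s)\n")
  invisible(x)
}

dendro_leaves <- function(dend) {
  sort(unlist(lapply(dend$roots, function(r) dend$nodes[[r]]$leaves),
              use.names = FALSE))
}

# minimum merge similarity over a node's internal subtree (Inf for leaves)
subtree_min_sim <- function(dend) {
  res <- stats::setNames(rep(Inf, length(dend$nodes)), names(dend$nodes))
  for (m in dend$merges) {   # merge order: children precede parents
    node <- dend$nodes[[m]]
    res[[m]] <- min(node$similarity, res[[node$left]], res[[node$right]])
  }
  res
}

# -- threshold cuts ----------------------------------------------------------

new_cluster_view <- function(active, provenance, stash = list()) {
  if (!length(stash)) stash <- list()   # drop names of an emptied stash
  structure(list(active = active, provenance = provenance, stash = stash),
            class = "cluster_view")
}

#' Cut a dendrogram at a similarity threshold
#'
#' Returns the coarsest partition in which every active internal node — and
#' every internal node below it — merged at a similarity strictly greater
#' than `threshold` ("similarity within the cluster is greater than the
#' threshold"). Leaves are always eligible, so raising the threshold can
#' only split clusters, never join them.
#'
#' @param dend A `go_dendrogram`.
#' @param threshold Similarity threshold in the metric's native units
#'   (percent for Jaccard).
#' @return A `cluster_view`: the active antichain plus per-node provenance
#'   (`"systematic"` for threshold cuts).
#' @export
cut_dendrogram <- function(dend, threshold) {
  stopifnot(inherits(dend, "go_dendrogram"), is.numeric(threshold))
  minsim <- subtree_min_sim(dend)
  active <- character(0)
  queue <- dend$roots
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    if (minsim[[v]] > threshold) {
      active <- c(active, v)
    } else {
      node <- dend$nodes[[v]]
      queue <- c(queue, node$left, node$right)
    }
  }
  active <- sort_node_ids(dend$nodes, active)
  new_cluster_view(active,
                   stats::setNames(rep("systematic", length(active)), active))
}

#' @export
print.cluster_view <- function(x, ...) {
  cat("cluster_view:", length(x$active), "active cluster(s) (",
      sum(x$provenance == "manual"), "manual )\n")
  invisible(x)
}

check_view <- function(view, dend) {
  leaves <- unlist(lapply(view$active, function(v) dend$nodes[[v]]$leaves),
                   use.names = FALSE)
  if (anyDuplicated(leaves) || !setequal(leaves, dendro_leaves(dend))) {
    stop("inconsistent cluster view: active nodes do not partition the leaves",
         call. = FALSE)
  }
  invisible(TRUE)
}

# -- manual collapse / expand ------------------------------------------------

#' Collapse active clusters into an ancestor node
#'
#' Replaces the active nodes lying under `node` by `node` itself (the
#' manual clustering gesture: clicking a merge-candidate arc). The replaced
#' sub-partition is stashed so a later [expand_node()] restores it exactly.
#'
#' @param view A `cluster_view`.
#' @param dend The `go_dendrogram` the view was cut from.
#' @param node Id of an internal dendrogram node.
#' @return The updated `cluster_view`; collapsing an already-active node is
#'   a no-op.
#' @export
collapse_node <- function(view, dend, node) {
  stopifnot(inherits(view, "cluster_view"), inherits(dend, "go_dendrogram"))
  if (!node %in% names(dend$nodes)) stop("unknown node id: ", node, call. = FALSE)
  if (node %in% view$active) return(view)
  target <- dend$nodes[[node]]$leaves
  under <- view$active[vapply(view$active, function(v) {
    all(dend$nodes[[v]]$leaves %in% target)
  }, logical(1))]
  covered <- unlist(lapply(under, function(v) dend$nodes[[v]]$leaves),
                    use.names = FALSE)
  if (!setequal(covered, target)) {
    stop("cannot collapse ", node,
         ": its leaves are partly covered by clusters outside the node",
         call. = FALSE)
  }
  stash <- view$stash
  stash[[node]] <- list(active = under, provenance = view$provenance[under])
  active <- sort_node_ids(dend$nodes, c(setdiff(view$active, under), node))
  prov <- view$provenance[setdiff(view$active, under)]
  prov[[node]] <- "manual"
  new_cluster_view(active, prov[active], stash)
}

#' Expand an active cluster back into its parts
#'
#' Inverse of [collapse_node()]: if the node was collapsed earlier its
#' stashed sub-partition (and provenance) is restored, so
#' `expand_node(collapse_node(v, d, n), d, n)` reproduces `v` exactly;
#' otherwise the node is replaced by its two children with manual
#' provenance.
#'
#' @inheritParams collapse_node
#' @param node Id of an *active internal* node.
#' @return The updated `cluster_view`.
#' @export
expand_node <- function(view, dend, node) {
  stopifnot(inherits(view, "cluster_view"), inherits(dend, "go_dendrogram"))
  if (!node %in% view$active) stop("node ", node, " is not active", call. = FALSE)
  nd <- dend$nodes[[node]]
  if (nd$type == "leaf") stop("cannot expand leaf ", node, call. = FALSE)
  stash <- view$stash
  if (!is.null(stash[[node]])) {
    restored <- stash[[node]]
    stash[[node]] <- NULL
  } else {
    kids <- c(nd$left, nd$right)
    restored <- list(active = kids,
                     provenance = stats::setNames(rep("manual", 2L), kids))
  }
  active <- sort_node_ids(dend$nodes,
                          c(setdiff(view$active, node), restored$active))
  prov <- c(view$provenance[setdiff(view$active, node)], restored$provenance)
  new_cluster_view(active, prov[active], stash)
}

# -- leaf ordering for the circular layout -----------------------------------

#' Leaf order for the chord layout
#'
#' In-order traversal of the dendrogram with, at every internal node, the
#' higher-merge-similarity subtree first (a leaf child counts as lowest);
#' ties fall back to the lexicographically smallest leaf id. Forest trees
#' are concatenated by smallest leaf id. The two children of every internal
#' node therefore occupy contiguous spans, keeping merge candidates
#' adjacent on the circle.
#'
#' @param dend A `go_dendrogram`.
#' @return Character vector of term ids in display order.
#' @export
leaf_order <- function(dend) {
  stopifnot(inherits(dend, "go_dendrogram"))
  walk <- function(id) {
    node <- dend$nodes[[id]]
    if (node$type == "leaf") return(node$term)
    kids <- c(node$left, node$right)
    score <- vapply(kids, function(k) {
      kn <- dend$nodes[[k]]
      if (kn$type == "leaf") -Inf else kn$similarity
    }, numeric(1))
    tie <- vapply(kids, function(k) min(dend$nodes[[k]]$leaves), character(1))
    kids <- kids[order(-score, tie)]
    c(walk(kids[[1]]), walk(kids[[2]]))
  }
  unlist(lapply(dend$roots, walk), use.names = FALSE)
}
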