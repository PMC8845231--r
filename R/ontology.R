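# -- ontology graph ----------------------------------------------------------

new_ontology_graph <- function(terms, parents, relations) {
  stopifnot(is.data.frame(terms), all(c("id", "name", "namespace", "obsolete") %in% names(terms)))
  active <- terms$id[!terms$obsolete]
  # obsolete terms never carry parent edges
  parents <- parents[intersect(names(parents), active)]
  relations <- relations[names(parents)]
  children <- invert_edges(parents, active)
  roots <- find_roots(terms, parents)
  g <- structure(
    list(terms = terms, parents = parents, relations = relations,
         children = children, roots = roots),
    class = "ontology_graph"
  )
  validate_dag(g)
  g
}

invert_edges <- function(parents, active) {
  ch <- lapply(stats::setNames(nm = active), function(i) character(0))
  for (id in names(parents)) {
    for (p in parents[[id]]) ch[[p]] <- c(ch[[p]], id)
  }
  lapply(ch, function(v) sort(unique(v)))
}

find_roots <- function(terms, parents) {
  active <- terms[!terms$obsolete, , drop = FALSE]
  n_par <- vapply(active$id, function(i) length(parents[[i]]), integer(1))
  roots <- active$id[n_par == 0L]
  ns <- active$namespace[match(roots, active$id)]
  if (anyDuplicated(ns)) {
    dup <- unique(ns[duplicated(ns)])
    stop("namespace '", dup[1], "' has multiple roots: ",
         paste(roots[ns == dup[1]], collapse = ", "), call. = FALSE)
  }
  stats::setNames(roots, ns)
}

validate_dag <- function(g) {
  ids <- names(g$children)
  indeg <- vapply(ids, function(i) length(g$parents[[i]]), integer(1))
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (c in g$children[[v]]) {
      indeg[[c]] <- indeg[[c]] - 1L
      if (indeg[[c]] == 0L) queue <- c(queue, c)
    }
  }
  if (seen < length(ids)) {
    stop("ontology relations contain a cycle: ",
         paste(find_cycle(g, ids[indeg > 0L]), collapse = " -> "), call. = FALSE)
  }
  invisible(g)
}

# one representative cycle among the residual (non-sorted) vertices
find_cycle <- function(g, residual) {
  res <- stats::setNames(rep(TRUE, length(residual)), residual)
  start <- residual[[1]]
  path <- character(0)
  v <- start
  repeat {
    if (v %in% path) return(c(path[which(path == v):length(path)], v))
    path <- c(path, v)
    nxt <- intersect(g$parents[[v]], names(res))
    v <- nxt[[1]]
  }
}

#' Parse an ontology in OBO format
#'
#' Reads `[Term]` stanzas of an OBO 1.2/1.4 file (the go-basic dialect:
#' `id`, `name`, `namespace`, `is_a`, `relationship: part_of`,
#' `is_obsolete`). Obsolete terms are retained in the term table but carry
#' no edges and are excluded from traversal. Unknown relationship types are
#' skipped with a warning.
#'
#' @param file Path to an OBO file, or a character vector of OBO lines when
#'   `text = TRUE`.
#' @param relations Which relations form parent edges. go-basic ships both
#'   `is_a` and `part_of`; restrict to `"is_a"` to ignore partonomy.
#' @param text If `TRUE`, `file` is the OBO content itself.
#' @return An `ontology_graph`: term table, parent/child adjacency and the
#'   per-namespace roots.
#' @examples
#' obo <- c("[Term]", "id: GO:0000001", "name: root",
#'          "namespace: biological_process")
#' g <- read_obo(obo, text = TRUE)
#' @export
read_obo <- function(file, relations = c("is_a", "part_of"), text = FALSE) {
  relations <- match.arg(relations, c("is_a", "part_of"), several.ok = TRUE)
  lines <- if (text) file else readLines(file)
  lines <- trimws(lines)

  stanza_starts <- which(lines == "[Term]")
  other_starts <- grep("^\\[.*\\]$", lines)
  bounds <- c(other_starts, length(lines) + 1L)

  recs <- list()
  unknown_rel <- character(0)
  for (s in stanza_starts) {
    end <- min(bounds[bounds > s]) - 1L
    body <- lines[seq(s + 1L, length.out = max(0L, end - s))]
    body <- body[nzchar(body) & !startsWith(body, "!")]
    tags <- sub(":.*$", "", body)
    vals <- trimws(sub("^[^:]+:", "", body))
    vals <- trimws(sub("!.*$", "", vals))  # trailing OBO comments

    id <- vals[tags == "id"]
    if (length(id) != 1L || !nzchar(id)) {
      stop("malformed [Term] stanza starting at line ", s, ": missing id", call. = FALSE)
    }
    obsolete <- any(tags == "is_obsolete" & vals == "true")
    par <- character(0); rel <- character(0)
    if ("is_a" %in% relations) {
      isa <- vals[tags == "is_a"]
      par <- c(par, isa); rel <- c(rel, rep("is_a", length(isa)))
    }
    for (rv in vals[tags == "relationship"]) {
      parts <- strsplit(rv, "\\s+")[[1]]
      if (length(parts) < 2L) next
      if (parts[1] %in% relations) {
        par <- c(par, parts[2]); rel <- c(rel, parts[1])
      } else {
        unknown_rel <- c(unknown_rel, parts[1])
      }
    }
    nm <- vals[tags == "name"]
    ns <- vals[tags == "namespace"]
    recs[[id]] <- list(
      id = id,
      name = if (length(nm)) nm[[1]] else id,
      namespace = if (length(ns)) ns[[1]] else "unknown",
      obsolete = obsolete,
      parents = par, relations = rel
    )
  }
  if (!length(recs)) stop("no [Term] stanzas found", call. = FALSE)
  if (length(unknown_rel)) {
    warning("ignoring unsupported relationship type(s): ",
            paste(sort(unique(unknown_rel)), collapse = ", "), call. = FALSE)
  }

  terms <- data.frame(
    id = vapply(recs, `[[`, "", "id"),
    name = vapply(recs, `[[`, "", "name"),
    namespace = vapply(recs, `[[`, "", "namespace"),
    obsolete = vapply(recs, `[[`, NA, "obsolete"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  parents <- lapply(recs, `[[`, "parents")
  rels <- lapply(recs, `[[`, "relations")
  known <- terms$id[!terms$obsolete]
  for (id in names(parents)) {
    keep <- parents[[id]] %in% known
    if (!all(keep)) {
      warning("term ", id, " references unknown/obsolete parent(s): ",
              paste(parents[[id]][!keep], collapse = ", "), call. = FALSE)
    }
    parents[[id]] <- parents[[id]][keep]
    rels[[id]] <- rels[[id]][keep]
  }
  new_ontology_graph(terms, parents, rels)
}

#' @export
print.ontology_graph <- function(x, ...) {
  n <- sum(!x$terms$obsolete)
  cat("ontology_graph:", n, "active terms (", sum(x$terms$obsolete),
      "obsolete ),", length(x$roots), "namespace root(s)\n")
  for (ns in names(x$roots)) cat("  ", ns, "-> root", x$roots[[ns]], "\n")
  invisible(x)
}

graph_ids <- function(graph) names(graph$children)

term_namespace <- function(graph, id) {
  i <- match(id, graph$terms$id)
  if (is.na(i)) stop("unknown term id: ", id, call. = FALSE)
  graph$terms$namespace[[i]]
}

term_name <- function(graph, id) {
  i <- match(id, graph$terms$id)
  if (is.na(i)) id else graph$terms$name[[i]]
}

#' Ancestors of a term
#'
#' Reflexive-transitive closure over parent edges: a term is its own
#' ancestor (needed so the most informative common ancestor of a term with
#' itself is the term).
#'
#' @param graph An `ontology_graph`.
#' @param id Term accession.
#' @return Sorted character vector of ancestor ids, including `id`.
#' @export
term_ancestors <- function(graph, id) {
  if (!id %in% graph_ids(graph)) stop("unknown term id: ", id, call. = FALSE)
  seen <- character(0)
  queue <- id
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    queue <- c(queue, setdiff(graph$parents[[v]], seen))
  }
  sort(seen)
}

# all-terms ancestor closure, computed once in topological order
all_ancestors <- function(graph) {
  ids <- graph_ids(graph)
  indeg <- vapply(ids, function(i) length(graph$parents[[i]]), integer(1))
  queue <- ids[indeg == 0L]
  anc <- vector("list", length(ids))
  names(anc) <- ids
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    anc[[v]] <- sort(unique(c(v, unlist(anc[graph$parents[[v]]], use.names = FALSE))))
    for (c in graph$children[[v]]) {
      indeg[[c]] <- indeg[[c]] - 1L
      if (indeg[[c]] == 0L) queue <- c(queue, c)
    }
  }
  anc
}

# -- annotation corpus -------------------------------------------------------

#' Propagate annotation counts up the ontology
#'
#' Builds an annotation corpus whose per-term counts include everything
#' annotated at or below the term. Two input modes:
#'
#' * **GAF mode** — a data frame with `gene` and `term` columns (as returned
#'   by [read_gaf()]). Each distinct gene-product contributes 1 to every
#'   ancestor of every term it is annotated to, deduplicated per
#'   gene-product and ancestor, so diamond paths never double count.
#' * **Count mode** — a named numeric vector (or two-column data frame
#'   `term`,`count`) of direct counts; counts propagate additively over each
#'   term's unique ancestor set.
#'
#' @param graph An `ontology_graph`.
#' @param annotations GAF data frame or direct-count table.
#' @param unknown What to do with annotations to ids absent from the graph
#'   (or obsolete): `"error"` or `"skip"` (with a warning).
#' @return An `annotation_corpus` with direct counts, propagated counts,
#'   per-term namespaces and per-namespace totals (the propagated count at
#'   each namespace root).
#' @export
propagate_counts <- function(graph, annotations, unknown = c("error", "skip")) {
  unknown <- match.arg(unknown)
  ids <- graph_ids(graph)
  anc <- all_ancestors(graph)
  direct <- stats::setNames(numeric(length(ids)), ids)
  propagated <- direct

  if (is.data.frame(annotations) && all(c("gene", "term") %in% names(annotations))) {
    ann <- unique(annotations[, c("gene", "term")])
    if (!nrow(ann)) stop("empty corpus: no annotations supplied", call. = FALSE)
    bad <- !(ann$term %in% ids)
    if (any(bad)) {
      msg <- paste0("annotation(s) to unknown or obsolete term(s): ",
                    paste(sort(unique(ann$term[bad])), collapse = ", "))
      if (unknown == "error") stop(msg, call. = FALSE)
      warning(msg, " (skipped)", call. = FALSE)
      ann <- ann[!bad, , drop = FALSE]
      if (!nrow(ann)) stop("empty corpus: no annotations supplied", call. = FALSE)
    }
    dtab <- table(ann$term[!duplicated(ann[, c("gene", "term")])])
    direct[names(dtab)] <- as.numeric(dtab)
    hits <- unlist(lapply(split(ann$term, ann$gene), function(ts) {
      unique(unlist(anc[unique(ts)], use.names = FALSE))
    }), use.names = FALSE)
    ptab <- table(hits)
    propagated[names(ptab)] <- as.numeric(ptab)
  } else {
    if (is.data.frame(annotations)) {
      annotations <- stats::setNames(annotations[[2]], annotations[[1]])
    }
    counts <- annotations[annotations > 0]
    if (!length(counts)) stop("empty corpus: no annotations supplied", call. = FALSE)
    bad <- !(names(counts) %in% ids)
    if (any(bad)) {
      msg <- paste0("counts for unknown or obsolete term(s): ",
                    paste(sort(names(counts)[bad]), collapse = ", "))
      if (unknown == "error") stop(msg, call. = FALSE)
      warning(msg, " (skipped)", call. = FALSE)
      counts <- counts[!bad]
      if (!length(counts)) stop("empty corpus: no annotations supplied", call. = FALSE)
    }
    direct[names(counts)] <- as.numeric(counts)
    for (t in names(counts)) {
      propagated[anc[[t]]] <- propagated[anc[[t]]] + counts[[t]]
    }
  }

  namespaces <- stats::setNames(graph$terms$namespace[match(ids, graph$terms$id)], ids)
  totals <- stats::setNames(propagated[graph$roots], names(graph$roots))
  structure(
    list(direct_counts = direct, propagated_counts = propagated,
         namespaces = namespaces, namespace_totals = totals),
    class = "annotation_corpus"
  )
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat("annotation_corpus:", sum(x$direct_counts > 0), "directly annotated terms\n")
  for (ns in names(x$namespace_totals)) {
    cat("  ", ns, "total:", x$namespace_totals[[ns]], "\n")
  }
  invisible(x)
}

#' Annotation probability of a term
#'
#' `p(t)` = propagated count of `t` divided by the propagated count of its
#' namespace root, so `p(root) = 1` and unannotated terms have `p = 0`.
#'
#' @param corpus An `annotation_corpus`.
#' @param id Term accession.
#' @return Probability in `[0, 1]`.
#' @export
term_probability <- function(corpus, id) {
  if (!id %in% names(corpus$propagated_counts)) {
    stop("unknown term id: ", id, call. = FALSE)
  }
  ns <- corpus$namespaces[[id]]
  total <- corpus$namespace_totals[[ns]]
  if (is.null(total) || is.na(total) || total <= 0) {
    stop("namespace '", ns, "' has zero annotation total", call. = FALSE)
  }
  unname(corpus$propagated_counts[[id]] / total)
}

#' Information content of a term
#'
#' `IC(t) = -log p(t)` in the chosen base (natural log by default, i.e.
#' nats), so `IC(root) = 0` and rarer terms are more informative.
#'
#' @inheritParams term_probability
#' @param base Logarithm base; `exp(1)` gives nats, `2` bits.
#' @param zero Handling of `p = 0` terms: `"error"` (default) or `"inf"`
#'   to return `Inf`.
#' @return Non-negative IC value.
#' @export
term_ic <- function(corpus, id, base = exp(1), zero = c("error", "inf")) {
  zero <- match.arg(zero)
  p <- term_probability(corpus, id)
  if (p <= 0) {
    if (zero == "error") {
      stop("IC undefined for unannotated term ", id, " (p = 0)", call. = FALSE)
    }
    return(Inf)
  }
  -log(p, base = base) + 0  # + 0 normalizes -log(1) = -0 to 0
}

#' Most informative common ancestor (MICA)
#'
#' Among the common ancestors of `a` and `b` (both in the same namespace),
#' returns the one with maximal information content; ties are broken by the
#' lexicographically smallest accession. Ancestors with `p = 0` are skipped
#' (their IC is undefined); the namespace root (`p = 1`, `IC = 0`) is always
#' a fallback.
#'
#' @param graph An `ontology_graph`.
#' @param corpus An `annotation_corpus` on the same graph.
#' @param a,b Term accessions in the same namespace.
#' @param base Logarithm base for IC.
#' @return List with elements `id` (the MICA accession) and `ic`.
#' @export
term_mica <- function(graph, corpus, a, b, base = exp(1)) {
  common <- intersect(term_ancestors(graph, a), term_ancestors(graph, b))
  if (!length(common)) {
    stop("terms ", a, " and ", b, " have no common ancestor ",
         "(different namespaces?)", call. = FALSE)
  }
  p <- vapply(common, function(t) term_probability(corpus, t), numeric(1))
  common <- common[p > 0]
  p <- p[p > 0]
  if (!length(common)) {
    stop("no common ancestor of ", a, " and ", b, " is annotated", call. = FALSE)
  }
  ic <- -log(p, base = base) + 0  # -0 -> 0
  best <- max(ic)
  cand <- sort(common[ic == best])
  list(id = cand[[1]], ic = unname(best))
}

# -- annotation readers ------------------------------------------------------

#' Read a Gene Association File (GAF 2.1/2.2)
#'
#' Keeps columns 2 (DB object id) and 5 (GO id); rows whose qualifier
#' (column 4) contains `NOT` and comment lines starting with `!` are
#' skipped.
#'
#' @param file Path to a GAF file, or GAF lines when `text = TRUE`.
#' @param text If `TRUE`, `file` is the content itself.
#' @return Data frame with columns `gene` and `term`.
#' @export
read_gaf <- function(file, text = FALSE) {
  lines <- if (text) file else readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) stop("empty corpus: GAF contains no annotation rows", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 5L
  if (any(short)) {
    stop("malformed GAF row (fewer than 5 columns) at data line ",
         which(short)[1], call. = FALSE)
  }
  gene <- vapply(fields, `[[`, "", 2L)
  qualifier <- vapply(fields, `[[`, "", 4L)
  term <- vapply(fields, `[[`, "", 5L)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier)
  data.frame(gene = gene[keep], term = term[keep], stringsAsFactors = FALSE)
}

#' Read a two-column term/count table
#'
#' Tab-separated `term_id<TAB>count` rows; `#` comments and blank lines are
#' skipped.
#'
#' @param file Path, or lines when `text = TRUE`.
#' @param text If `TRUE`, `file` is the content itself.
#' @return Named numeric vector of direct counts.
#' @export
read_term_counts <- function(file, text = FALSE) {
  lines <- if (text) file else readLines(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("empty corpus: count table has no rows", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  cnt <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(cnt)) {
    stop("non-numeric count at line ", which(is.na(cnt))[1], call. = FALSE)
  }
  stats::setNames(cnt, vapply(fields, `[[`, "", 1L))
}
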