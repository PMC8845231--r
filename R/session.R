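# -- session container -------------------------------------------------------

SESSION_FORMAT_VERSION <- 1L

#' Bundle an analysis state into a session
#'
#' A session captures everything needed to restore the current chord
#' diagram: the similarity configuration, the enrichment result, the full
#' merge tree, the active partition (with manual-operation provenance and
#' collapse stashes) and the rendered chord model.
#'
#' @param config A `similarity_config`.
#' @param result An `enrichment_result`.
#' @param dend A `go_dendrogram`.
#' @param view A `cluster_view`.
#' @param model A `chord_model` (rebuilt from the other parts if omitted);
#'   pass an existing model to keep exports cheap.
#' @param context Optional `similarity_context`; required when `model` is
#'   omitted.
#' @param term_sim Optional pairwise term-similarity matrix; taken from
#'   `context` when available. Stored in the session so semantic metrics
#'   can be re-cut without the ontology.
#' @return A `go_session`.
#' @export
new_session <- function(config, result, dend, view, model = NULL,
                        context = NULL, term_sim = NULL) {
  if (is.null(model)) {
    if (is.null(context)) stop("either model or context must be supplied",
                               call. = FALSE)
    model <- build_chord(view, dend, result, context)
  }
  if (is.null(term_sim) && !is.null(context)) term_sim <- context$term_sim
  structure(
    list(format_version = SESSION_FORMAT_VERSION, config = config,
         enrichment = result, dendrogram = dend, view = view, model = model,
         term_sim = term_sim),
    class = "go_session"
  )
}

#' @export
print.go_session <- function(x, ...) {
  cat("go_session (format", x$format_version, "):",
      nrow(x$enrichment$terms), "terms,",
      length(x$view$active), "active cluster(s), metric", x$config$metric, "\n")
  invisible(x)
}

# -- payload conversion (R objects <-> plain lists for JSON) -----------------

# Recursively sort object keys so exports are byte-deterministic.
sort_keys <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, sort_keys)
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
  }
  x
}

# named character/numeric vector -> {name: value} object (sorted), {} if empty
map_payload <- function(v) {
  if (!length(v)) return(stats::setNames(list(), character(0)))
  as.list(v[order(names(v))])
}

session_payload <- function(s) {
  dend <- s$dendrogram
  nodes <- lapply(dend$nodes, function(n) {
    if (n$type == "leaf") {
      list(type = "leaf", term = n$term)
    } else {
      list(type = "merge", left = n$left, right = n$right,
           similarity = n$similarity)
    }
  })
  res <- s$enrichment
  entries <- lapply(seq_len(nrow(res$terms)), function(i) {
    list(term_id = res$terms$term_id[[i]],
         term_name = res$terms$term_name[[i]],
         p_value = res$terms$p_value[[i]],
         genes = as.list(res$genes[[res$terms$term_id[[i]]]]))
  })
  stash <- lapply(s$view$stash, function(st) {
    list(active = as.list(st$active), provenance = map_payload(st$provenance))
  })
  model <- list(
    arcs = lapply(s$model$arcs, function(a) {
      list(cluster_id = a$cluster_id, label = a$label,
           gene_count = a$gene_count, arc_fraction = a$arc_fraction,
           p_value_bin = a$p_value_bin, p_value = a$p_value,
           member_terms = as.list(a$member_terms), genes = as.list(a$genes))
    }),
    links = lapply(s$model$links, function(l) {
      list(cluster_a = l$cluster_a, cluster_b = l$cluster_b,
           shared_genes = as.list(l$shared_genes),
           shared_percent = l$shared_percent)
    }),
    merge_arcs = lapply(s$model$merge_arcs, function(m) {
      list(cluster_a = m$cluster_a, cluster_b = m$cluster_b,
           similarity = m$similarity)
    })
  )
  term_sim <- NULL
  if (!is.null(s$term_sim)) {
    ids <- sort(rownames(s$term_sim))
    term_sim <- list(ids = as.list(ids),
                     values = as.list(as.numeric(s$term_sim[ids, ids])))
  }
  sort_keys(list(
    format_version = s$format_version,
    config = list(metric = s$config$metric, aggregate = s$config$aggregate,
                  ic_base = s$config$ic_base),
    term_sim = term_sim,
    enrichment = list(source = res$source,
                      namespace = if (is.na(res$namespace)) NULL else res$namespace,
                      entries = entries),
    dendrogram = list(nodes = nodes[order(names(nodes))],
                      roots = as.list(dend$roots),
                      merges = as.list(dend$merges)),
    view = list(active = as.list(s$view$active),
                provenance = map_payload(s$view$provenance),
                stash = if (length(stash)) stash[order(names(stash))] else
                  stats::setNames(list(), character(0))),
    model = model
  ))
}

#' Export a session as JSON
#'
#' Serialization is canonical: object keys are sorted and numbers written
#' at full (round-trippable) precision, so exporting the same session twice
#' yields byte-identical text and `import_session()` reproduces the model
#' exactly.
#'
#' @param session A `go_session`.
#' @param file Optional output path.
#' @return The JSON text (a single string), invisibly when written to file.
#' @export
export_session <- function(session, file = NULL) {
  stopifnot(inherits(session, "go_session"))
  json <- jsonlite::toJSON(session_payload(session), auto_unbox = TRUE,
                           digits = I(17), null = "null", na = "null",
                           pretty = TRUE)
  json <- paste0(as.character(json), "\n")
  if (!is.null(file)) {
    # write bytes directly: identical on every platform
    con <- file(file, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(json), con)
    return(invisible(json))
  }
  json
}

chr <- function(x) as.character(unlist(x, use.names = FALSE))

need <- function(payload, key, path) {
  if (is.null(payload[[key]])) {
    stop("invalid session JSON: missing ", path, ".", key, call. = FALSE)
  }
  payload[[key]]
}

#' Import a session from JSON
#'
#' Restores a session written by [export_session()]. Unknown format
#' versions and missing required fields are rejected with an explicit
#' error naming the JSON path.
#'
#' @param file Path to a session JSON file, or the JSON text itself when
#'   `text = TRUE`.
#' @param text If `TRUE`, `file` is the JSON string.
#' @return A `go_session`.
#' @export
import_session <- function(file, text = FALSE) {
  json <- if (text) paste(file, collapse = "\n") else
    paste(readLines(file, warn = FALSE), collapse = "\n")
  payload <- tryCatch(
    jsonlite::fromJSON(json, simplifyVector = FALSE),
    error = function(e) stop("invalid session JSON: ", conditionMessage(e),
                             call. = FALSE)
  )
  ver <- need(payload, "format_version", "$")
  if (!identical(as.integer(ver), SESSION_FORMAT_VERSION)) {
    stop("unsupported session format version: ", ver,
         " (supported: ", SESSION_FORMAT_VERSION, ")", call. = FALSE)
  }
  cfgp <- need(payload, "config", "$")
  config <- similarity_config(metric = need(cfgp, "metric", "$.config"),
                              aggregate = need(cfgp, "aggregate", "$.config"),
                              ic_base = need(cfgp, "ic_base", "$.config"))

  enr <- need(payload, "enrichment", "$")
  entries <- need(enr, "entries", "$.enrichment")
  result <- new_enrichment_result(
    term_id = vapply(entries, function(e) chr(need(e, "term_id", "$.enrichment.entries[]")), ""),
    term_name = vapply(entries, function(e) chr(e$term_name), ""),
    p_value = vapply(entries, function(e) as.numeric(e$p_value), numeric(1)),
    genes = lapply(entries, function(e) chr(e$genes)),
    source = if (is.null(enr$source)) "session" else chr(enr$source),
    namespace = if (is.null(enr$namespace)) NA_character_ else chr(enr$namespace)
  )

  dd <- need(payload, "dendrogram", "$")
  nodesp <- need(dd, "nodes", "$.dendrogram")
  nodes <- lapply(names(nodesp), function(id) {
    n <- nodesp[[id]]
    if (identical(n$type, "leaf")) {
      list(id = id, type = "leaf", term = chr(n$term), leaves = chr(n$term))
    } else {
      list(id = id, type = "merge", left = chr(n$left), right = chr(n$right),
           similarity = as.numeric(n$similarity), leaves = NULL)
    }
  })
  names(nodes) <- names(nodesp)
  merges <- chr(dd$merges)
  for (m in merges) {   # children precede parents in merge order
    nd <- nodes[[m]]
    nodes[[m]]$leaves <- sort(c(nodes[[nd$left]]$leaves,
                                nodes[[nd$right]]$leaves))
  }
  dend <- structure(list(nodes = nodes, roots = chr(dd$roots), merges = merges),
                    class = "go_dendrogram")

  vw <- need(payload, "view", "$")
  provp <- need(vw, "provenance", "$.view")
  stash <- lapply(vw$stash, function(st) {
    list(active = chr(st$active),
         provenance = stats::setNames(
           vapply(st$provenance, function(x) chr(x), ""), names(st$provenance)))
  })
  active <- chr(need(vw, "active", "$.view"))
  view <- new_cluster_view(
    active,
    stats::setNames(vapply(provp, function(x) chr(x), ""), names(provp))[active],
    if (length(stash)) stash else list()
  )
  check_view(view, dend)

  mp <- need(payload, "model", "$")
  model <- structure(list(
    arcs = lapply(mp$arcs, function(a) {
      list(cluster_id = chr(a$cluster_id), label = chr(a$label),
           gene_count = as.integer(a$gene_count),
           arc_fraction = as.numeric(a$arc_fraction),
           p_value_bin = as.integer(a$p_value_bin),
           p_value = as.numeric(a$p_value),
           member_terms = chr(a$member_terms), genes = chr(a$genes))
    }),
    links = lapply(mp$links, function(l) {
      list(cluster_a = chr(l$cluster_a), cluster_b = chr(l$cluster_b),
           shared_genes = chr(l$shared_genes),
           shared_percent = as.numeric(l$shared_percent))
    }),
    merge_arcs = lapply(mp$merge_arcs, function(m) {
      list(cluster_a = chr(m$cluster_a), cluster_b = chr(m$cluster_b),
           similarity = as.numeric(m$similarity))
    })
  ), class = "chord_model")

  term_sim <- NULL
  if (!is.null(payload$term_sim)) {
    ts <- payload$term_sim
    ids <- chr(need(ts, "ids", "$.term_sim"))
    vals <- vapply(need(ts, "values", "$.term_sim"),
                   function(v) if (is.null(v)) NA_real_ else as.numeric(v),
                   numeric(1))
    if (length(vals) != length(ids)^2) {
      stop("invalid session JSON: $.term_sim.values has wrong length",
           call. = FALSE)
    }
    term_sim <- matrix(vals, length(ids), length(ids),
                       dimnames = list(ids, ids))
  }

  new_session(config, result, dend, view, model, term_sim = term_sim)
}

# Rebuild a similarity context from a restored session: per-term gene sets
# always; for semantic metrics the pairwise matrix stored in the session.
session_context <- function(s) {
  ids <- s$enrichment$terms$term_id
  gene_sets <- lapply(s$enrichment$genes[ids], normalize_genes)
  names(gene_sets) <- ids
  term_sim <- NULL
  if (s$config$metric != "jaccard") {
    if (is.null(s$term_sim)) {
      stop("session lacks the pairwise similarity matrix; rebuild it from ",
           "the ontology with similarity_context()", call. = FALSE)
    }
    term_sim <- s$term_sim[ids, ids]
  }
  structure(list(gene_sets = gene_sets, term_sim = term_sim,
                 config = s$config),
            class = "similarity_context")
}
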