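# -- synthetic fixtures ------------------------------------------------------

build_graph <- function(ids, names, namespaces, parents, relations,
                        obsolete = rep(FALSE, length(ids))) {
  terms <- data.frame(id = ids, name = names, namespace = namespaces,
                      obsolete = obsolete, row.names = NULL,
                      stringsAsFactors = FALSE)
  miss <- setdiff(ids, names(parents))
  parents[miss] <- list(character(0))
  relations[miss] <- list(character(0))
  new_ontology_graph(terms, parents[ids], relations[ids])
}

#' The canonical six-term toy DAG
#'
#' A fixed miniature ontology used throughout the documentation and tests:
#' root `R`; `A`, `B` children of `R`; `C`, `D` children of `A`; `E` child
#' of `B`; direct annotation counts `C:2, D:1, E:3, B:1, A:1`. Propagation
#' gives `A = 4`, `B = 4`, `R = 8`, so e.g. `p(C) = 0.25`,
#' `IC(C) = -ln(0.25)` and the MICA of `C` and `D` is `A`.
#'
#' @return List with elements `graph` (an `ontology_graph`) and `corpus`
#'   (an `annotation_corpus`).
#' @examples
#' toy <- make_toy_dag()
#' term_ic(toy$corpus, "C")
#' @export
make_toy_dag <- function() {
  ids <- c("R", "A", "B", "C", "D", "E")
  parents <- list(A = "R", B = "R", C = "A", D = "A", E = "B")
  relations <- list(A = "is_a", B = "is_a", C = "is_a", D = "is_a", E = "is_a")
  graph <- build_graph(ids, names = paste0("term ", ids),
                       namespaces = rep("synthetic", 6L),
                       parents = parents, relations = relations)
  corpus <- propagate_counts(graph, c(C = 2, D = 1, E = 3, B = 1, A = 1))
  list(graph = graph, corpus = corpus)
}

#' Specification for a random synthetic instance
#'
#' @param n_terms Number of ontology terms including the root (>= 2).
#' @param max_parents Maximum parents drawn for each non-root term.
#' @param n_genes Size of the gene universe.
#' @param genes_per_term Two-element range for per-term gene-set sizes.
#' @param overlap_rate Fraction of each gene set drawn from a pool shared
#'   by all terms: 0 gives pairwise-disjoint sets, 1 (with equal sizes)
#'   identical sets.
#' @param p_value_range Range for log-uniform p-values.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(n_terms = 12, max_parents = 2, n_genes = 150,
                         genes_per_term = c(3, 6), overlap_rate = 0.3,
                         p_value_range = c(1e-8, 0.05), seed = 1) {
  stopifnot(n_terms >= 2, max_parents >= 1, n_genes >= 1,
            length(genes_per_term) == 2, genes_per_term[1] >= 1,
            genes_per_term[1] <= genes_per_term[2],
            overlap_rate >= 0, overlap_rate <= 1,
            length(p_value_range) == 2, p_value_range[1] > 0,
            p_value_range[2] <= 1, p_value_range[1] <= p_value_range[2])
  if (genes_per_term[2] > n_genes) {
    stop("infeasible fixture spec: genes_per_term exceeds n_genes", call. = FALSE)
  }
  structure(list(n_terms = as.integer(n_terms),
                 max_parents = as.integer(max_parents),
                 n_genes = as.integer(n_genes),
                 genes_per_term = as.integer(genes_per_term),
                 overlap_rate = overlap_rate,
                 p_value_range = p_value_range,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a random ontology / corpus / enrichment instance
#'
#' Grows a rooted DAG term by term (each new term attaches to 1 to
#' `max_parents` earlier terms with `is_a` or `part_of` edges), assigns
#' every non-root term a gene set whose pairwise overlap is controlled by
#' `overlap_rate`, draws log-uniform p-values, and derives the annotation
#' corpus from the gene sets in GAF fashion (one annotation per gene and
#' term). Given the same spec the output is identical, byte-for-byte when
#' written.
#'
#' @param spec A `fixture_spec`.
#' @param dir Optional directory; when given, `instance.obo`,
#'   `instance.gaf` and `instance.tsv` are written there so the file
#'   readers can be exercised end-to-end.
#' @return List with `graph`, `corpus`, `result`, the raw `annotations`
#'   data frame and, when `dir` is given, the file `paths`.
#' @export
make_random_instance <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, make_instance_impl(spec, dir))
}

make_instance_impl <- function(spec, dir) {
  n <- spec$n_terms
  ids <- sprintf("GO:%07d", seq_len(n))
  parents <- list(); relations <- list()
  for (i in seq(2L, n)) {
    k <- sample.int(min(spec$max_parents, i - 1L), 1L)
    pa <- sort(sample(ids[seq_len(i - 1L)], k))
    parents[[ids[i]]] <- pa
    relations[[ids[i]]] <- sample(c("is_a", "part_of"), k, replace = TRUE,
                                  prob = c(0.8, 0.2))
  }
  graph <- build_graph(ids, names = sprintf("synthetic process %d", seq_len(n)),
                       namespaces = rep("biological_process", n),
                       parents = parents, relations = relations)

  enriched <- ids[-1L]
  m <- length(enriched)
  sizes <- if (spec$overlap_rate >= 1) {
    rep(sample(seq(spec$genes_per_term[1], spec$genes_per_term[2]), 1L), m)
  } else {
    sample(seq(spec$genes_per_term[1], spec$genes_per_term[2]), m, replace = TRUE)
  }
  universe <- sprintf("G%05d", sample.int(spec$n_genes))
  shared_k <- round(spec$overlap_rate * sizes)
  pool_size <- max(shared_k)
  pool <- universe[seq_len(pool_size)]
  private_need <- sizes - shared_k
  if (pool_size + sum(private_need) > spec$n_genes) {
    stop("infeasible fixture spec: gene universe too small for ",
         "the requested set sizes and overlap_rate", call. = FALSE)
  }
  rest <- if (pool_size > 0) universe[-seq_len(pool_size)] else universe
  offs <- cumsum(c(0L, private_need))
  gene_sets <- lapply(seq_len(m), function(i) {
    priv <- if (private_need[i] > 0)
      rest[seq(offs[i] + 1L, offs[i] + private_need[i])] else character(0)
    sort(c(pool[seq_len(shared_k[i])], priv))
  })
  names(gene_sets) <- enriched

  lp <- log(spec$p_value_range)
  p <- exp(stats::runif(m, lp[1], lp[2]))
  result <- new_enrichment_result(enriched,
                                  sprintf("synthetic process %d", match(enriched, ids)),
                                  p, gene_sets, source = "synthetic")

  annotations <- data.frame(
    gene = unlist(gene_sets, use.names = FALSE),
    term = rep(enriched, vapply(gene_sets, length, integer(1))),
    stringsAsFactors = FALSE
  )
  corpus <- propagate_counts(graph, annotations)

  out <- list(graph = graph, corpus = corpus, result = result,
              annotations = annotations, spec = spec)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(obo = file.path(dir, "instance.obo"),
                  gaf = file.path(dir, "instance.gaf"),
                  tsv = file.path(dir, "instance.tsv"))
    write_obo(graph, paths$obo)
    write_gaf(annotations, paths$gaf)
    write_enrichment(result, paths$tsv)
    out$paths <- paths
  }
  out
}

# -- writers -----------------------------------------------------------------

#' Write an ontology graph as OBO
#'
#' Emits `[Term]` stanzas (sorted by id) that [read_obo()] parses back into
#' an equal graph.
#'
#' @param graph An `ontology_graph`.
#' @param file Output path; omit to return the lines.
#' @return The OBO lines, invisibly when written to file.
#' @export
write_obo <- function(graph, file = NULL) {
  stopifnot(inherits(graph, "ontology_graph"))
  t <- graph$terms[order(graph$terms$id), , drop = FALSE]
  stanzas <- lapply(seq_len(nrow(t)), function(i) {
    id <- t$id[i]
    lines <- c("[Term]", paste0("id: ", id), paste0("name: ", t$name[i]),
               paste0("namespace: ", t$namespace[i]))
    if (t$obsolete[i]) return(c(lines, "is_obsolete: true", ""))
    pa <- graph$parents[[id]]
    re <- graph$relations[[id]]
    for (j in seq_along(pa)) {
      lines <- c(lines, if (re[j] == "is_a") {
        paste0("is_a: ", pa[j], " ! ", term_name(graph, pa[j]))
      } else {
        paste0("relationship: ", re[j], " ", pa[j], " ! ", term_name(graph, pa[j]))
      })
    }
    c(lines, "")
  })
  lines <- c("format-version: 1.2", "ontology: synthetic", "",
             unlist(stanzas, use.names = FALSE))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Write annotations as GAF 2.2
#'
#' One 17-column row per gene/term pair; [read_gaf()] recovers the same
#' pairs.
#'
#' @param annotations Data frame with `gene` and `term` columns.
#' @param file Output path; omit to return the lines.
#' @param taxon NCBI taxon tag written in column 13.
#' @return The GAF lines, invisibly when written to file.
#' @export
write_gaf <- function(annotations, file = NULL, taxon = "taxon:0000") {
  stopifnot(is.data.frame(annotations),
            all(c("gene", "term") %in% names(annotations)))
  ann <- annotations[order(annotations$gene, annotations$term), , drop = FALSE]
  rows <- vapply(seq_len(nrow(ann)), function(i) {
    paste(c("SYNDB", ann$gene[i], ann$gene[i], "", ann$term[i], "SYN:0001",
            "IEA", "", "P", "", "", "protein", taxon, "20260101", "gochord",
            "", ""), collapse = "\t")
  }, character(1))
  lines <- c("!gaf-version: 2.2", "!generated-by: gochord", rows)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
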