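# -- enrichment result container ---------------------------------------------

new_enrichment_result <- function(term_id, term_name, p_value, genes,
                                  source = "generic", namespace = NA_character_) {
  if (!length(term_id)) stop("enrichment result has no entries", call. = FALSE)
  if (anyDuplicated(term_id)) {
    stop("duplicate term id(s): ",
         paste(unique(term_id[duplicated(term_id)]), collapse = ", "),
         call. = FALSE)
  }
  p_value <- as.numeric(p_value)
  if (any(!is.finite(p_value) | p_value <= 0 | p_value > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  genes <- lapply(genes, normalize_genes)
  empty <- vapply(genes, length, integer(1)) == 0L
  if (any(empty)) {
    stop("term(s) with empty gene list: ",
         paste(term_id[empty], collapse = ", "), call. = FALSE)
  }
  names(genes) <- term_id
  structure(
    list(terms = data.frame(term_id = term_id, term_name = term_name,
                            p_value = p_value, stringsAsFactors = FALSE),
         genes = genes, source = source, namespace = namespace),
    class = "enrichment_result"
  )
}

#' Construct an enrichment result in memory
#'
#' @param term_id,term_name,p_value Parallel vectors describing each
#'   enriched term; p-values in `(0, 1]`.
#' @param genes List of gene identifier vectors, one per term (non-empty;
#'   identifiers are trimmed and upper-cased).
#' @param source Free-text provenance label.
#' @param namespace Optional namespace label for the whole result.
#' @return An `enrichment_result`.
#' @export
enrichment_result <- function(term_id, term_name, p_value, genes,
                              source = "generic", namespace = NA_character_) {
  new_enrichment_result(term_id, term_name, p_value, genes, source, namespace)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result:", nrow(x$terms), "terms,",
      length(unique(unlist(x$genes, use.names = FALSE))), "distinct genes",
      paste0("(source: ", x$source, ")"), "\n")
  invisible(x)
}

#' Number of enriched terms
#' @param x An `enrichment_result`.
#' @export
length.enrichment_result <- function(x) nrow(x$terms)

# -- readers -----------------------------------------------------------------

#' Read a DAVID functional annotation chart
#'
#' Consumes DAVID's exported chart TSV. Rows whose `Category` matches
#' `GOTERM_*` (any of DAVID's GO category sets) are retained; the `Term`
#' cell is split on DAVID's tilde convention `GO:NNNNNNN~name`; `Genes`
#' cells are split on commas.
#'
#' @param file Path to the chart TSV, or its lines when `text = TRUE`.
#' @param p_column Which DAVID column supplies the p-value: the unadjusted
#'   `"PValue"` (default) or the `"Benjamini"` adjusted column.
#' @param text If `TRUE`, `file` is the content itself.
#' @return An `enrichment_result`.
#' @export
read_david_chart <- function(file, p_column = c("PValue", "Benjamini"),
                             text = FALSE) {
  p_column <- match.arg(p_column)
  lines <- if (text) file else readLines(file)
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("Category", "Term", p_column, "Genes")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("DAVID chart is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab <- tab[grepl("^GOTERM_", tab$Category), , drop = FALSE]
  if (!nrow(tab)) stop("no GOTERM_* rows in DAVID chart", call. = FALSE)
  has_tilde <- grepl("~", tab$Term, fixed = TRUE)
  term_id <- ifelse(has_tilde, sub("~.*$", "", tab$Term), tab$Term)
  term_name <- ifelse(has_tilde, sub("^[^~]*~", "", tab$Term), tab$Term)
  genes <- strsplit(tab$Genes, ",")
  ns <- unique(sub("^GOTERM_([A-Z]+)_.*$", "\\1", tab$Category))
  new_enrichment_result(term_id, term_name, as.numeric(tab[[p_column]]), genes,
                        source = "david_chart",
                        namespace = if (length(ns) == 1L) ns else NA_character_)
}

#' Read a generic 4-column enrichment TSV
#'
#' Tab-separated rows `term_id, term_name, p_value, comma-separated genes`
#' with no header; blank lines and `#` comments are skipped.
#'
#' @param file Path, or lines when `text = TRUE`.
#' @param text If `TRUE`, `file` is the content itself.
#' @return An `enrichment_result`.
#' @export
read_enrichment <- function(file, text = FALSE) {
  lines <- if (text) file else readLines(file)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("enrichment table has no rows", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- vapply(fields, length, integer(1))
  if (any(nfield < 4L)) {
    stop("line ", lineno[which(nfield < 4L)[1]],
         ": expected 4 tab-separated columns", call. = FALSE)
  }
  p <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(p)) {
    stop("line ", lineno[which(is.na(p))[1]], ": non-numeric p-value '",
         vapply(fields, `[[`, "", 3L)[which(is.na(p))[1]], "'", call. = FALSE)
  }
  genes <- lapply(fields, function(f) strsplit(f[[4]], ",")[[1]])
  empty <- vapply(lapply(genes, normalize_genes), length, integer(1)) == 0L
  if (any(empty)) {
    stop("line ", lineno[which(empty)[1]], ": empty gene list", call. = FALSE)
  }
  new_enrichment_result(vapply(fields, `[[`, "", 1L),
                        vapply(fields, `[[`, "", 2L), p, genes,
                        source = "generic")
}

#' Write the generic 4-column enrichment TSV
#'
#' Inverse of [read_enrichment()]: the written file re-parses to an
#' equivalent result.
#'
#' @param result An `enrichment_result`.
#' @param file Output path; omit to return the lines invisibly.
#' @return The written lines, invisibly.
#' @export
write_enrichment <- function(result, file = NULL) {
  stopifnot(inherits(result, "enrichment_result"))
  lines <- vapply(seq_len(nrow(result$terms)), function(i) {
    paste(result$terms$term_id[[i]], result$terms$term_name[[i]],
          format(result$terms$p_value[[i]], digits = 15, scientific = NA,
                 trim = TRUE),
          paste(result$genes[[result$terms$term_id[[i]]]], collapse = ","),
          sep = "\t")
  }, character(1))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

# -- validation --------------------------------------------------------------

#' Validate an enrichment result against an ontology
#'
#' Reports term ids absent from (or obsolete in) the graph. With
#' `action = "drop"` the offending entries are removed; with `"error"`
#' any unknown id aborts.
#'
#' @param result An `enrichment_result`.
#' @param graph An `ontology_graph`.
#' @param action `"drop"` (default) or `"error"`.
#' @return List with `result` (possibly shrunk) and `unknown` (the ids
#'   reported).
#' @export
validate_terms <- function(result, graph, action = c("drop", "error")) {
  action <- match.arg(action)
  known <- graph_ids(graph)
  unknown <- setdiff(result$terms$term_id, known)
  if (length(unknown) && action == "error") {
    stop("enriched term(s) absent from ontology: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(unknown)) {
    keep <- !(result$terms$term_id %in% unknown)
    if (!any(keep)) stop("no enriched term is present in the ontology", call. = FALSE)
    result <- new_enrichment_result(
      result$terms$term_id[keep], result$terms$term_name[keep],
      result$terms$p_value[keep], result$genes[result$terms$term_id[keep]],
      source = result$source, namespace = result$namespace
    )
  }
  list(result = result, unknown = unknown)
}
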