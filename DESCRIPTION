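Package: gochord
Title: Hierarchical Clustering and Chord-Diagram Models for Gene
    Ontology Enrichment Results
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A headless analytical engine for reducing redundancy in Gene
    Ontology (GO) enrichment results. Parses ontologies in OBO format and
    annotation corpora in GAF or term-count form, computes annotation-based
    information content and semantic similarities (Resnik, SimRel) as well
    as gene-overlap (Jaccard) similarity, clusters enriched terms by greedy
    agglomeration with deterministic tie-breaking, and supports
    threshold-based cuts plus manual collapse/expand of the cluster tree.
    The current partition is rendered into a serializable chord-diagram
    model (arcs sized by gene counts, links carrying shared genes,
    merge-candidate arcs between neighbours) with lossless, byte-
    deterministic JSON session export/import, free-text search, MICA
    hierarchy subgraphs in DOT, a synthetic fixture generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
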