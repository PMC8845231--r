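# gochord

**Hierarchical clustering and chord-diagram models for Gene Ontology
enrichment results.**

GO enrichment analyses routinely return dozens to hundreds of
over-represented terms, many of them near-duplicates because the ontology is
a hierarchy: "axonogenesis" and "axon guidance" may be reported side by side
with almost the same supporting genes. Biologists then either truncate the
list ("top 5 by p-value") or hand-pick "representative" terms — both
introduce selection bias. `gochord` is a headless analytical engine for
reducing that redundancy reproducibly: it clusters enriched terms by how
similar they are, lets the user cut or manually adjust the cluster tree, and
emits a serializable chord-diagram model (arcs, shared-gene links, merge
candidates) that any front end — or the bundled static SVG renderer — can
draw.

## What it computes

For an annotation corpus propagated over the GO DAG (each gene counted once
per ancestor, so diamond paths never double-count), a term's annotation
probability and information content are

> p(t) = n(t) / N_ns,  IC(t) = −ln p(t)

with n(t) the propagated count and N_ns the count at the namespace root.
Three similarity metrics are supported between enriched terms and clusters
of terms:

- **Percentage of common genes (Jaccard)** — 100·|A∩B| / |A∪B| over the
  pooled gene sets of two clusters;
- **Resnik** — IC of the most informative common ancestor (MICA) of two
  terms;
- **SimRel** — Schlicker's relevance measure,
  max over common ancestors c of [2·IC(c) / (IC(a)+IC(b))] · (1 − p(c)),
  which discounts promiscuous ancestors near the root.

For the semantic metrics, cluster-to-cluster similarity aggregates all
cross-cluster term pairs by the *average*, *minimum* or *maximum*. Enriched
terms are clustered by greedy agglomeration — always merging the currently
most similar pair, recomputing similarities on merged clusters — with a
deterministic lexicographic tie-break, producing a binary merge tree (a
forest when some pairs share nothing). A threshold cut keeps every cluster
whose internal merges are all *strictly greater* than the threshold; manual
collapse/expand operations refine any cut and are exact inverses of one
another. Sessions (config + enrichment + tree + view + chord model)
round-trip through canonical JSON byte-identically.

## Worked example

```r
library(gochord)

chart <- system.file("extdata", "david_chart_example.tsv", package = "gochord")
res   <- read_david_chart(chart)        # keeps the GOTERM_* rows
cfg   <- similarity_config("jaccard")
ctx   <- similarity_context(res, cfg)
dend  <- build_dendrogram(res, ctx)
view  <- cut_dendrogram(dend, 60)       # only merges > 60% survive
model <- build_chord(view, dend, res, ctx)
model
#> chord_model: 3 arcs, 1 links, 2 merge arc(s)
str(model$links[[1]])
#> List of 4
#>  $ cluster_a     : chr "GO:0007409"
#>  $ cluster_b     : chr "GO:0007411"
#>  $ shared_genes  : chr [1:3] "DCC" "ROBO1" "SHHA"
#>  $ shared_percent: num 50
```

The three enriched terms become three arcs; "axonogenesis" and "axon
guidance" share DCC, ROBO1 and SHHA — 50 % of their pooled genes — so a
link connects them and the merge arc between the neighbours is labelled 50.
Arc sizes are gene-count proportional (5, 4 and 3 genes → fractions 0.417,
0.333, 0.250) and arcs are coloured by p-value bin. Collapsing that merge
candidate manually reduces the diagram to two arcs:

```r
v2 <- collapse_node(view, dend, dend$merges[1])
build_chord(v2, dend, res, ctx)
#> chord_model: 2 arcs, 0 links, 1 merge arc(s)
```

`expand_node(v2, dend, dend$merges[1])` restores the previous view exactly.
For semantic clustering, supply an ontology and annotation corpus:

```r
g      <- read_obo("go-basic.obo")
corpus <- propagate_counts(g, read_gaf("annotations.gaf"))
cfg    <- similarity_config("resnik", "average")
ctx    <- similarity_context(res, cfg, g, corpus)
```

and `hierarchy_subgraph(g, corpus, a, b)` / `subgraph_dot()` emit the
ancestor DAG joining two terms with their MICA highlighted.

## Command line

A launcher is installed at `system.file("scripts", "gochord", package =
"gochord")`:

```sh
gochord cluster --enrichment res.tsv --metric jaccard --threshold 50 --out run
gochord recut   --session run.session.json --threshold 75 --out run75
gochord collapse --session run.session.json --node M3 --out run.collapsed
gochord subgraph --obo go-basic.obo --gaf ann.gaf --terms GO:0007409,GO:0007411 --out sg
gochord render  --session run.session.json --out chord.svg
gochord simulate --seed 1 --n-terms 12 --out fixtures/
```

All analysis subcommands are deterministic; randomness is confined to
`simulate --seed`.

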