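---
title: "Clustering GO enrichment results: models and methods"
author: "gochord authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering GO enrichment results: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gochord)
```

## The problem

A GO enrichment result is a list of terms, each with a p-value and the
genes-of-interest it annotates. Because GO is a hierarchy, such lists are
redundant: sibling or parent/child terms often carry almost identical gene
sets. `gochord` reduces this redundancy by clustering the enriched terms
under a user-chosen similarity, and renders the current partition as a
chord-diagram model. This vignette documents the models, the tunable
parameters, and the design choices made where more than one reasonable
definition exists.

## Annotation probability and information content

Annotations are propagated up the ontology DAG before anything else. In GAF
mode every distinct gene-product contributes **once** to each ancestor of
each term it is annotated to: the ancestor set is unioned per gene before
counting, so diamond-shaped paths cannot double-count. In count mode a raw
per-term table propagates additively over each term's unique ancestor set.
The propagated count at a namespace root is the namespace total \(N\), and

\[ p(t) = n(t)/N, \qquad \mathrm{IC}(t) = -\log p(t). \]

Two consequences the code relies on: \(p(\text{root}) = 1\), and IC is
monotone non-increasing along child-to-parent edges (a parent's propagated
count is at least each child's). Both are enforced by property tests.

**Logarithm base.** The IC base is a genuine free choice; natural log
(nats) is the default throughout, and every IC-consuming function accepts a
`base` argument (`similarity_config(ic_base = )` for the pipeline). Note
that SimRel is a ratio of ICs, so it is base-invariant; only Resnik values
change scale.

**Counting unit.** Corpus counts are per *distinct gene-product per term*,
not per annotation line — the same gene annotated twice to one term (e.g.
with two evidence codes) counts once. This matches the deduplication used
for propagation.

**Relations.** `is_a` and `part_of` both count as ancestry by default,
matching the edge set go-basic ships; `read_obo(relations = "is_a")`
restricts to the subsumption hierarchy alone.

**Reflexivity.** A term is its own ancestor. This makes
`term_mica(a, a) = a`, so self-similarity behaves sensibly for both Resnik
(`IC(a)`) and SimRel.

## Similarity metrics

* **Jaccard percent** operates on gene sets:
  \(100\,|A \cap B|/|A \cup B|\). Gene identifiers are trimmed and
  upper-cased before comparison; no alias resolution is attempted. The
  *union* denominator is used — consistent with two identical 11-gene sets
  sharing 100 % of their genes, the package's canonical worked example.
* **Resnik** is \(\mathrm{IC}\) of the most informative common ancestor.
  MICA ties (equal IC) are broken by the lexicographically smallest
  accession so every downstream result is deterministic.
* **SimRel** maximizes
  \(\frac{2\,\mathrm{IC}(c)}{\mathrm{IC}(a)+\mathrm{IC}(b)}(1-p(c))\) over
  common ancestors \(c\), and is defined as 0 when
  \(\mathrm{IC}(a)+\mathrm{IC}(b)=0\). The implementation scans all common
  ancestors, but it is worth recording that with IC derived from a single
  corpus the scanned score is strictly decreasing in \(p(c)\), so its
  maximum always falls on the minimum-\(p\) (maximum-IC) ancestor — the
  Resnik MICA. The two routes cannot disagree; a property test asserts the
  equality.

**Terms without annotation support** (\(p = 0\), IC undefined) are excluded
from semantic similarity with a warning; their pairwise values are `NA`,
they never merge under a semantic metric, and they remain fully clusterable
under Jaccard. **Cross-namespace pairs** score 0 with a warning — an
enrichment result normally lives in one namespace, and 0 keeps foreign
terms unmerged rather than aborting the run.

## Cluster-level similarity and agglomeration

Between two clusters of terms, Jaccard pools each cluster's gene sets and
compares the unions; the semantic metrics evaluate all \(|A|\times|B|\)
cross pairs and combine them with the configured aggregate — arithmetic
mean (including duplicate values), minimum, or maximum. Minimum is the most
conservative (the farthest pair governs), maximum the most permissive.
Pairs with undefined similarity are left out of the aggregate; a fully
undefined block yields `NA`.

Clustering is greedy agglomeration: repeatedly merge the pair of current
clusters with the highest similarity, *recomputing* similarities against
the merged cluster rather than applying Lance–Williams updates — the
cluster-level function is not a linkage in that sense (Jaccard on pooled
unions is not expressible as an update rule). The cost is \(O(n^3)\)
pairwise evaluations, comfortably cheap at enrichment scale (hundreds of
terms), with the semantic term-pair matrix computed once up front.

Determinism matters more than speed here: among equal-similarity candidate
pairs, the pair whose (smaller, larger) tuple of smallest member leaf ids
sorts first is merged, and the left child of every merge node is the one
with the smaller leading leaf id. An exact brute-force reference — rescan
every pair at every step — reproduces the package's merge trees on hundreds
of random instances in the acceptance suite.

Pairs with similarity 0 or `NA` are never merged. The result is then a
*forest*, rendered as separate top-level clusters; this is deliberate —
merging disjoint terms at similarity 0 would manufacture structure the data
does not support.

## Threshold cuts and manual operations

A cut keeps the coarsest antichain in which every active internal node, and
every internal node beneath it, merged at similarity **strictly greater**
than the threshold — equality splits. Since eligibility is monotone down
the tree, raising the threshold can only refine the partition, a property
verified on threshold grids that include the exact merge values and values
just below them.

`collapse_node()` replaces the active nodes under a merge node with that
node; `expand_node()` is its exact inverse. Exactness is achieved by
stashing the replaced sub-partition (node set and provenance) inside the
view when collapsing and restoring it on expand; expanding a node that was
never collapsed exposes its two children with `manual` provenance. The
stash is serialized with the session, so the inverse survives a round trip
through disk.

## The chord model

One arc per active cluster, ordered by an in-order traversal in which the
higher-similarity subtree precedes (leaves rank lowest, ties by smallest
leaf id) — this keeps the two children of every merge node contiguous on
the circle, so merge candidates are always neighbours. Arc length is
proportional to the cluster's distinct gene count; links carry the shared
gene list and the Jaccard percent of the pooled sets for every intersecting
cluster pair; merge arcs annotate each adjacent pair with its cluster
similarity. The cluster p-value is the minimum (most significant) of its
members.

Arcs are coloured by one of **six** significance bins with cut points 0.05,
1e−2, 1e−4, 1e−6 and 1e−8 (bin 1: \(p \ge 0.05\); bin 6: \(p < 10^{-8}\)),
a log-decade scheme chosen to spread typical enrichment p-values across the
palette.

## Sessions

A session bundles config, enrichment result, the full merge tree, the view
(with stashes), the chord model and — for semantic metrics — the pairwise
term-similarity matrix, so a restored session can be re-cut or manually
edited without re-reading the ontology. Serialization is canonical: keys
sorted, doubles written with 17 significant digits. Full-precision output
was chosen over fixed decimal places deliberately: fixed 6-decimal floats
would collapse small p-values to zero and break the invariant that
`import(export(s))` reproduces the model exactly and that repeated exports
are byte-identical. Version and schema violations are rejected with the
offending JSON path named.

## The synthetic generator

`make_random_instance()` emulates the shape of the real inputs: a rooted
DAG grown term by term (each new term takes 1–`max_parents` earlier parents,
`is_a`:`part_of` drawn 4:1), per-term gene sets of 3–6 genes from a universe
of ~150 (defaults), pairwise overlap controlled by drawing a fraction
`overlap_rate` of each set from a common pool, log-uniform p-values in
\([10^{-8}, 0.05]\), and a GAF-style corpus derived from the gene sets. It
does **not** reproduce real GO topology statistics (depth distribution,
fan-out, term counts) or species nomenclature, so passing property suites
demonstrate algorithmic correctness — propagation, similarity, clustering,
round trips — not biological calibration on any specific GO release.
Generation is a pure function of the `fixture_spec` (seeded via `withr`, no
global RNG state), so written OBO/GAF/TSV files are byte-reproducible.

## Validation scale and degenerate inputs

The test and acceptance suites run: 200 random instances (≤ 13 terms)
against the brute-force clustering reference with exact merge-tree
equality; 200 random DAGs (≤ 15 terms) against exhaustive common-ancestor
enumeration for Resnik/SimRel at 1e−9; 100 dendrograms × threshold grids
for refinement; 100 collapse/expand inversions plus 20-step random op
sequences; 50 session round trips; and 25 file-format round trips — a few
tens of seconds on one CPU, sized so the whole suite stays quick while
every code path is exercised many times.

Degenerate inputs are errors, not silent defaults: empty corpora (IC would
divide by zero), empty gene sets, p-values outside \((0,1]\), cyclic
ontologies (one witness cycle is reported), duplicate enriched term ids,
and expanding a leaf all fail loudly. Obsolete terms are parsed but carry
no edges and are invisible to traversal.

## Known limitations

- Only `is_a` and `part_of` are ontology relations; `regulates`-type edges
  are ignored with a warning, and alt_id resolution is out of scope.
- Gene identifiers are matched after trim/upper-case normalization only; no
  symbol-alias mapping.
- Lin, Wang, graph-based (GraSM) and best-match-average similarities are
  not implemented.
- Leaf ordering is the deterministic dendrogram traversal, not optimal leaf
  ordering; it guarantees merge-candidate adjacency, not globally minimal
  crossing.
- The SVG renderer is a static convenience; byte-exact reproducibility is
  promised for session JSON only.
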