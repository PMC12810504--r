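---
title: "Methods: network pharmacology with netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network pharmacology with netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The analysis chain

`netpharm` implements the inference chain used in network-pharmacology
studies that ask which disease processes a set of drugs converges on. The
chain is: (1) assemble a disease gene set by fusing several evidence
databases under a k-of-n retention rule; (2) build per-drug target sets by
requiring agreement between several target-prediction tools; (3) intersect
the drug consensus sets with the disease set; (4) build a protein-protein
interaction (PPI) network on the shared genes and read hubs off its
topology; (5) test how fragile the network is to the targeted removal of
those hubs; (6) characterize the shared genes functionally by
over-representation analysis with redundancy-reducing term clustering; and
(7) ask which transcription factors regulate the key hubs.

Every step consumes plain-text tables (gene lists, TSV edge lists or SIF,
GMT annotations, TRRUST-dialect TF tables), so the whole chain runs offline
and deterministically. The packaged worked example is a 14-gene
disease-drug network in major depressive disorder (MDD), whose hubs are the
mu-opioid receptor gene *OPRM1*, the epidermal growth factor receptor
*EGFR*, and glycogen synthase kinase 3 beta *GSK3B*, with the
transcription factor NFKB as the single regulator covering all three.

## Evidence fusion and consensus

`multi_evidence_intersect()` keeps genes supported by at least
`min_sources` of the supplied per-database lists (default 2, the common
2-of-3 design across e.g. CTD, MalaCards and Open Targets). Symbol
normalization is deliberately minimal — uppercase plus whitespace trimming —
and aliases merge only through an explicit synonym table passed to
`unify_identifiers()`. Automatic ortholog or identifier conversion would
require live database access and make runs irreproducible; an explicit
table keeps the mapping auditable. Venn-region accounting is reported for
up to 5 sources (32 regions); beyond that only the support histogram is
kept, since a 2^n region table stops being readable.

`consensus_targets()` applies the same k-of-n rule to per-predictor
drug-target lists (default: 2 of 3 tools). `disease_overlap()` then
intersects the per-drug consensus sets with the disease set. Two policies
are provided because published Venn figures are ambiguous on this point:
`"all_drugs"` (default) takes genes common to every drug — the reading
implied when a shared-gene set is described as regulated by all compounds —
while `"any_drug"` takes the union. The worked example's 14 shared genes
are shipped as a fixture rather than recomputed, because the upstream
per-database lists depend on database versions.

## The topology panel

`metric_panel()` reproduces the Cytoscape NetworkAnalyzer conventions so
its output is directly comparable with published PPI tables:

* **degree, betweenness, closeness** — betweenness is exact shortest-path
  betweenness with endpoints excluded, normalized by `(n-1)(n-2)/2`;
  closeness is the reciprocal of the *mean* distance to reachable nodes
  (an isolated node scores 0).
* **distance statistics** (diameter, radius, characteristic path length)
  are taken over connected pairs only, so the panel remains defined when a
  hub removal disconnects the network; the component count is reported
  alongside.
* **clustering coefficient** is the mean of local coefficients with
  degree-<2 nodes contributing 0.
* **heterogeneity** is the coefficient of variation of the degree sequence
  with population (divide-by-n) variance — this is the variant that
  reproduces the published value 0.338 for the worked example's degree
  sequence.
* **centralization** is `(n/(n-2)) * (max_degree/(n-1) - density)`: 0 for a
  regular graph, 1 for a star.

Four panel cells (density, average neighbors, heterogeneity,
centralization) are pure functions of the degree sequence, which gives a
strong internal consistency check: any realization of a published degree
sequence must reproduce them, and the test suite verifies this on 100
configuration-model graphs per run. Distance- and triangle-based cells
depend on the wiring. The worked example's edge list was never published —
only its degree sequence and per-node centralities — so the package ships
one frozen realization of the degree sequence (`fixture_network()`);
wiring-dependent statistics are reproducible for that fixture but are not
claims about the unpublished network. A constraint search that reconstructs
a wiring consistent with all printed per-node centralities is possible in
principle (the printed tables over-determine the graph) and is left as
future work.

Reports round to 3 decimals, matching published tables; all internal
computation keeps full precision.

## MCODE

`find_complexes()` implements the MCODE molecular-complex detection
algorithm: each vertex is weighted by the density of the highest k-core of
its closed neighborhood times that core's k; complexes grow greedily from
the highest-weight unassigned seed, recruiting neighbors whose weight
exceeds `seed_weight * (1 - node_score_cutoff)`; the haircut step trims a
complex to its 2-core; complexes without a k-core of the configured order
are dropped. Parameters default to the published MCODE defaults (node score
cutoff 0.2, k-core 2, haircut on, fluff off) since network-pharmacology
studies typically run the Cytoscape plugin at defaults. All ties (seed
choice, output order) are broken by symbol order, so output is fully
deterministic. The complex score is density times size, `2e/(n-1)`; a
clique of size n scores n, and an 11-node, 24-edge complex scores 4.8.

## Fragility analysis

`fragility_analysis()` removes each designated hub *independently* from the
baseline network — not cumulatively — and recomputes the full panel. The
independent-removal reading follows directly from the arithmetic of
published robustness tables, where every post-removal column has exactly
one node fewer than baseline. Two delta groups matter scientifically:
communication efficiency (diameter and characteristic path length increase
when a hub is removed) and cohesion (clustering coefficient and density
drop). Edge conservation (`edges_after = edges - degree(removed)`) is an
exact invariant and is tested as such.

## Enrichment and term clustering

`enrich()` computes the exact upper-tail hypergeometric probability
(one-sided Fisher test) for each annotation term, with fold enrichment
`(k/n)/(K/N)` and Benjamini-Hochberg FDR adjusted within each annotation
category independently (the behavior of DAVID-style tools). We use the
plain hypergeometric rather than DAVID's EASE-modified score: EASE's
backend is proprietary and version-bound, so published fold-enrichment
values from DAVID are context for interpretation, not quantities this
package reproduces. Terms with fewer than `min_hits = 2` hits are not
tested.

`cluster_terms()` reduces redundancy the way Metascape-style meta-analyses
do: Cohen's kappa between the binary membership vectors of each term pair,
an edge when kappa >= 0.3 (the conventional threshold), and single-linkage
clusters as the connected components of that graph, each represented by its
most significant member. The kappa domain defaults to the hit list —
agreement is measured on the genes actually tested — and can be switched to
the full universe. Single-linkage was chosen as the simplest faithful
reading of similarity-graph term clustering; multi-stage merge heuristics
of specific platforms are out of scope. Raising the threshold can only
refine clusters (a property the tests check), and kappa handles its
degenerate case (both vectors all-ones) as perfect agreement.

## TF overlay

`tf_coverage()` ranks regulators by how many of the key hubs they target,
with an upper-tail hypergeometric overlap p-value computed against an
*explicit, user-supplied universe*. Published TRRUST p-values are computed
against that database's internal background, which is not distributed, so
numerical p-values differ by construction; the coverage ranking (which TF
targets all key hubs) is the reproducible quantity.

## Synthetic data: what it emulates and what it does not

The generators produce every input type the pipeline consumes, with the
planted structure recorded in a truth object:

* `gen_source_lists()` — gene lists with exact counts per support level,
  emulating multi-database evidence with controlled overlap.
* `gen_degree_sequence_graph()` — a simple graph realizing a degree
  sequence exactly (deterministic realization followed by degree-preserving
  edge swaps), used both for the worked example's 14-gene sequence
  `[7,6,6,6,5,5,5,4,4,4,3,3,2,2]` and for property tests.
* `gen_planted_cluster_graph()` — an Erdős–Rényi background (default
  benchmark: n = 40, p = 0.05) with a planted clique (size 6), the standard
  planted-clique benchmark for dense-module detection.
* `gen_annotation()` — uniform background terms plus one planted term whose
  genes are drawn with odds `effect` (benchmark: 5) in favor of a
  designated 50-gene hit list in a 1000-gene universe, term sizes 50–150.
* `gen_tf_table()` — random regulons plus one planted TF covering all key
  genes; background regulons are capped below full key coverage so the
  planted regulator is the unique full-coverage answer.

These benchmark sizes are desk-scale on purpose: large enough that recovery
is a meaningful signal (the planted term's expected hit count, about 21 of
100, is far above the background's 5), small enough that the full suite
runs in minutes on one CPU. What the generators do **not** emulate: the
heavy-tailed term-size and degree distributions of real GO/STRING data,
literature-curation bias in TF tables, correlated annotation structure, and
identifier noise beyond simple case/whitespace/alias variation. Passing the
planted-recovery tests therefore demonstrates algorithmic correctness, not
field performance on live database snapshots.

## Numerical and degenerate-input choices

* Hypergeometric tails use `stats::phyper(k-1, ...)`; enumeration oracles
  in the tests confirm exactness for universes up to 25 genes.
* Kappa returns 1 when observed and chance agreement are both 1.
* Betweenness/closeness of graphs with fewer than 3 nodes are 0/defined
  trivially; `metric_panel()` refuses single-node graphs.
* Disconnected graphs: unreachable pairs simply drop out of distance
  statistics (and closeness averages over reachable nodes only), matching
  NetworkAnalyzer.
* Degree sequences are checked for graphicality (Erdős–Gallai, via igraph)
  before realization; odd-sum sequences are rejected with a clear error.
* All list-valued outputs are sorted deterministically (score, then size,
  then symbol), so identical inputs yield byte-identical reports.

## Problem sizes used in the shipped checks

The test suite and the acceptance script use: 100 random graphs (n <= 10)
for oracle equivalence of centralities and path lengths; 100
configuration-model graphs for degree-sequence identities; 20 evidence
scenarios, 50 planted-clique graphs, 100 planted-term runs and 20
planted-TF runs for recovery rates. These sizes give stable rates while
keeping a full run within a few minutes on a single core.

## Worked example

```{r example}
net <- fixture_network()
head(node_metrics(net), 4)

frag <- fragility_analysis(net, c("OPRM1", "EGFR", "GSK3B"))
fragility_table(frag)[c(1, 2, 3, 8), ]

regs <- fixture_tf_table()
uni <- unique(c(fixture_shared_genes(), unlist(lapply(regs, `[[`, "targets"))))
tf_coverage(regs, c("OPRM1", "EGFR", "GSK3B"), fixture_shared_genes(), uni)[1:3, ]
```

## Known limitations

* The edge list of the published worked example is unavailable; the frozen
  fixture realizes its degree sequence, so wiring-dependent cells
  (diameter, path length, clustering, radius, post-removal heterogeneity
  and centralization) are fixture-specific.
* No identifier mapping beyond an explicit synonym table.
* MCODE is the non-overlapping variant; fluff is available but off by
  default and complexes never share nodes.
* Enrichment assumes annotation gene sets are subsets of the declared
  universe after intersection; genes outside the universe are ignored.
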