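---
title: "Biodomain network reconstruction and weighted key-driver analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biodomain network reconstruction and weighted key-driver analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wkdanet)
```

## The problem

Complex neurodegenerative disease risk is spread across hundreds of genes and
many loosely defined biological processes ("biodomains": curated collections
of GO terms such as Synapse, Endolysosome or Lipid Metabolism). A gene-level
risk score — here a Target Risk Score (TRS) bounded in [0, 5] — summarises
genetic and multi-omic evidence per gene, but a flat ranked list says nothing
about mechanism. `wkdanet` turns an annotated protein-interaction network
plus per-gene risk scores into *domain-specific* interaction graphs and then
asks which hub proteins plausibly *drive* risk-associated processes, within
and across domains.

The pipeline has seven stages:

1. **filter** — keep nodes with any evidence of brain expression and edges
   supported by at least two distinct publications;
2. **seed** — preranked gene-set enrichment on the TRS ranking; the
   leading-edge genes of each domain's significant terms become that domain's
   seeds;
3. **reconstruct** — a domain graph is the union of risk-weighted Dijkstra
   shortest paths between all seed pairs;
4. **kda** — weighted key-driver analysis on each domain graph at two edge
   weightings (topology-only and risk-weighted);
5. **join/filter** — ΔFDR between the two weightings; retention thresholds;
6. **integrate** — consensus ranking of driver–term pairs across graphs;
7. **domains** — a directed graph over biodomains counting cross-domain
   driver relationships.

## Models and statistics

### Edge costs for reconstruction

For an edge $(u, v)$ and a target domain $D$,

$$w_{uv} = (5 - \mathrm{TRS}_u) + (5 - \mathrm{TRS}_v) + \pi_{uv}, \qquad
\pi_{uv} = \begin{cases} 0 & u, v \in D \\ 3 & \text{exactly one of } u,v \in D \\ 5 & u, v \notin D \end{cases}$$

so $w_{uv} \in [0, 15]$: cheap routes run through high-risk, in-domain
proteins. Zero-cost edges (two TRS-5 in-domain nodes) are legal. One
minimum-cost path is kept per unordered seed pair; among co-optimal paths the
lexicographically smallest node sequence is chosen, which makes the
reconstructed graph deterministic and independent of seed ordering (an
`all_shortest = TRUE` flag retains every co-optimal path instead). Seeds
unreachable from all other seeds stay in the graph as isolated nodes. Nodes
are labelled `input`, `added_in_domain` or `added_out_domain`, with the hop
distance to the nearest seed recorded per node.

### Weighted key-driver analysis

For hub $h$ and module $M$ at search depth 1, the statistic is
$S(h, M) = \sum_{v \in N(h) \cap M} (\mathrm{TRS}_h + \mathrm{TRS}_v)^{f}$
with edge factor $f \in \{0, 1\}$ and $0^0 := 1$ — at $f = 0$ this is the
plain neighborhood-overlap count. The null permutes module membership
uniformly over graph nodes, preserving module size; $p = (1 + \#\{S^* \ge
S\}) / (n_\mathrm{perm} + 1)$ and FDR is Benjamini–Hochberg across all tested
(hub, module) pairs in the run. Candidate hubs are nodes with a depth-1
neighborhood of at least the minimum module size (5); modules with fewer
than 5 genes in the graph are skipped. This is a self-contained
approximation of the Mergeomics wKDA contract; the parameters (edge factor,
depth 1, 2000 permutations, minimum module size 5, undirected analysis) map
one-to-one, but the exact internal enrichment statistic of that package is
not reproduced.

A deliberate design point: **for a given module the permutation stream is
shared across hubs and, given the same seed, across edge factors**. This
removes Monte-Carlo noise from the weighted-vs-unweighted comparison
$\Delta\mathrm{FDR} = -\log_{10}\mathrm{FDR}_{f=1} +
\log_{10}\mathrm{FDR}_{f=0}$ (FDRs floored at $1/(n_\mathrm{perm}+1)$ before
the log) and makes ΔFDR *exactly* zero on a constant-risk graph, which the
acceptance suite asserts. Comparisons $S^* \ge S$ are exact (no numeric
tolerance): at both edge factors the statistics are sums of identical
summands under constant risk, so equality is bit-reproducible.

Driver–term pairs are retained when the term's coverage in the graph is at
least 0.25 and the risk-weighted FDR is at most 0.05 (both boundaries
inclusive, following the quoted rules). The top driver per (graph, term) is
the retained record with the smallest weighted FDR; ties are broken by
larger ΔFDR, then lexicographically smallest hub. Ties at the permutation
floor do occur, and the ΔFDR tie-break deliberately prefers drivers whose
significance *depends* on risk weighting.

### Integration and the domain map

Within each graph, retained pairs are ranked ascending (average ranks on
ties) on $-\log_{10}$ weighted FDR and on ΔFDR; non-top candidates' ranks
are multiplied by 0.33; both ranks are multiplied by the term's coverage in
that graph; the scaled ranks are summed per (hub, term) across graphs. Raw
ranks are summed by default — the spec leaves open whether ranks should be
normalized per graph, so a `rank_normalize` flag divides ranks by the number
of retained pairs in the graph for users who want size-free sums. The raw
summed ΔFDR is emitted alongside for Table-1-style reporting.

The domain-interaction graph counts retained driver–term pairs from source
graph to the term's domain(s); multi-domain terms contribute one count per
mapped domain (counts are not split, so totals are contributions, not
records). A `unique_drivers` flag counts distinct hubs per cell instead,
since "number of key drivers" is ambiguous between pairs and nodes.
Out-degree fractions count self-edges on both sides.

## The synthetic world

`generate_benchmark()` emulates the statistical structure of the real
inputs at desk scale (defaults: 500 genes, 40 terms, 4 domains, seed 7):

* **Topology**: preferential-attachment growth (3 edges per node) gives the
  heavy-tailed degree distribution and near-zero assortativity reported for
  the real graphs; term wiring is layered on top.
* **Two term archetypes.** Non-planted terms are *complex-like*: member
  pairs are additionally wired with probability 0.3, emulating the elevated
  internal connectivity of curated gene sets inside interaction networks.
  This matters statistically: the BH family of a wKDA run contains thousands
  of (hub, module) tests, and with 2000 permutations the smallest possible
  p-value is ~5×10⁻⁴; unless a few hundred tests carry genuine signal, no
  test can reach FDR ≤ 0.05 after correction. A world of purely random gene
  sets is therefore *untestable* for driver recovery — not an artifact of
  this implementation but of permutation FDR itself. The three *planted*
  terms are dispersed pathways: scattered members plus an external regulator
  hub wired to 10 of them; the hub, not the members, is the unambiguous
  driver.
* **Cross-domain planting.** Planted terms are annotated to every domain, so
  their signal is visible from every domain graph — this is what the
  consensus integration rewards, mirroring the reported behaviour of
  consistent drivers being found independently in many graphs.
* **Risk scores**: Beta(2, 5) scaled to [0, 5] (right-skewed; most genes low
  risk); members of six risk-enriched terms (the three planted ones plus
  three domain-specific ones) and the planted hubs get +2.0, capped at 5.
* **Filters**: exactly 10% of nodes have all expression flags false and
  exactly 20% of edges carry a single PubMed ID; planted hubs, their term
  members and their star edges are excluded from these violation pools so
  the planted structure survives filtering (the truth manifest records all
  of it).

What a green test does **not** establish: the generator produces clean
Bernoulli expression flags rather than raw IHC/single-cell evidence tables,
the PubMed counts are exchangeable across edges (no literature bias toward
hubs), and gene sets are not nested the way GO terms are. Results on real
resources (Pathway Commons scale, 19k nodes, 7k+ GO terms) will differ in
BH-family size and coverage structure.

## Numerical and procedural choices

* **GSEA**: weighted Kolmogorov–Smirnov running sum with weight exponent 1
  and a gene-permutation null of 1000 draws (the reference tool's settings
  are unpublished; these are the documented assumptions). NES divides ES by
  the mean same-sign permuted ES; p-values are one-sided by ES sign with the
  +1 correction; ties in the ranking statistic are broken by input order
  with a warning. With these settings the padj ≤ 0.01 seed threshold is
  near the permutation resolution: a genuinely enriched term that suffers a
  single permutation exceedance (p ≈ 0.002) can fail BH at rank ~6/40. The
  suite's sensitivity check documents this honestly (observed 5/6 on the
  default world) rather than inflating the permutation count beyond the
  stated default.
* **Single-cell expression thresholds** default to p90 ≥ 1 expression unit
  and ≥ 10% of cells expressing; the reference analysis derived its
  threshold from data and never states it, so these are config-exposed
  placeholders.
* **Merge-then-filter**: parallel edges are merged (union of PubMed IDs and
  contributing type/class labels) *before* node/edge filtering; the source
  describes both operations without fixing an order, and merging first
  guarantees the literature filter sees the union of support.
* **Calibration accounting**: within a module all hubs share one permutation
  stream, so permutation-calibration standard errors are computed across
  modules (the independent Monte-Carlo units), not across (hub, module)
  pairs.
* **Determinism**: one global pipeline seed derives per-stage substreams;
  module iteration is in sorted name order; identical configuration and seed
  reproduce byte-identical artifacts.

## Known limitations

* Depth > 1 neighborhoods use the product of effective weights along one
  shortest-hop path; only depth 1 (the reference setting) is exercised by
  default.
* The wKDA statistic is an approximation of the cited tool's internals (see
  above); absolute FDR values are not comparable across implementations,
  only the contract (parameters, permutation scheme, thresholds) is.
* Greedy lexicographic path reconstruction excludes already-visited nodes,
  which on all-zero-weight plateaus can fail to certify the lexicographic
  minimum; the engine then falls back to a valid (still deterministic)
  shortest path. Random-weight graphs never hit this.
* No GO DAG semantics: terms are flat sets; ancestor propagation and
  redundancy collapsing are out of scope.
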