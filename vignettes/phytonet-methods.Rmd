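---
title: "Methods: from Q-TOF peaks to a compound–target–pathway network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from Q-TOF peaks to a compound-target-pathway network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytonet)
```

# The problem

Multi-compound herbal preparations act through many constituents hitting
many protein targets at once. Network pharmacology makes that tractable by
chaining together a small number of well-understood steps: identify the
constituents by high-resolution mass spectrometry, predict their protein
targets, intersect those with disease-associated genes, and study the
resulting compound–target, protein–protein interaction (PPI) and
compound–target–pathway networks topologically. phytonet implements that
chain as composable, tested functions, plus a synthetic-study generator
with planted ground truth so every screen in the chain can be validated
without touching any external database.

# Mass annotation

## Constants and conventions

All mass arithmetic is exact arithmetic over fixed constants.

* Monoisotopic masses (Da): C 12 (exact, defines the dalton),
  H 1.00782503207, N 14.0030740048, O 15.99491461956, Na 22.9897692809,
  Cl 34.96885268, S 31.97207100, P 30.97376163.
* Supported quasi-molecular ions, all singly charged, with
  electron-corrected mass deltas: [M+H]+ (+1.00727646),
  [M+Na]+ (+22.98922142), [M−H]− (−1.00727646), [M+Cl]− (+34.96940126),
  [M+COOH]− (+44.99820285). A protonated cation is one electron lighter
  than M+H; anions are one electron heavier.
* ppm error is signed: `(observed − theoretical) / theoretical × 1e6`,
  reported rounded to one decimal place, matching the convention of
  published compound identification tables.
* Rings-plus-double-bond equivalents (RDBE):
  `C + 1 + (N + P)/2 − (H + Cl + Na)/2`. Oxygen and sulfur (divalent)
  contribute nothing; the monovalent Na and Cl count like hydrogen.

## Candidate-formula enumeration

`fit_formulas()` enumerates *every* elemental composition within
per-element bounds whose adduct m/z lies within the ppm tolerance (default
5 ppm, a typical Q-TOF accuracy specification), keeps candidates with
RDBE ≥ 0, and ranks by absolute ppm error with ties broken by fewer
heteroatoms, then by formula string. The search is complete by
construction: a depth-first walk over the low-count elements (heaviest
first, with branch-and-bound on the attainable remaining mass), a
vectorized sweep over the widest-range element (carbon under the default
bounds), and a closed-form solve for hydrogen — the tolerance window at
any mass below ~1000 Da is far narrower than one hydrogen mass, so at
most a handful of hydrogen counts can fit a given partial composition.
Completeness is tested against an independent brute-force grid enumerator.

The default bounds (C ≤ 50, H ≤ 100, N ≤ 10, O ≤ 20, S ≤ 3, P ≤ 3,
Na ≤ 1, Cl ≤ 1) cover small-molecule phytochemistry below ~700 Da while
keeping the space tractable. The nitrogen rule is deliberately *not*
enforced: even-electron adduct ions make it unreliable, so RDBE ≥ 0 is
the only plausibility filter.

Two numerical facts matter when interpreting ranked candidates:

* **Formate degeneracy.** The [M+COOH]− delta exceeds the [M−H]− delta by
  exactly the mass of CH2O2. Consequently the formate adduct of a formula
  that is CH2O2 poorer is *exactly* mass-degenerate with the deprotonated
  ion of the original formula, and no mass accuracy can separate them.
  When the adduct hypothesis is fixed, a noise-free peak is always
  recovered at rank 1; across the full negative adduct list the
  degenerate alias may outrank the truth through the fewer-heteroatoms
  tie-break. This is a property of electrospray chemistry, not of the
  implementation.
* **Printed-table round-off.** `annotate_peaks()` recomputes ppm errors
  for peaks with known formulas, inferring the adduct by best absolute
  fit (adducts differ by ≥ 22 Da, so the inference is unambiguous at
  Q-TOF accuracy). For the bundled 41-compound identification table, 27
  rows reproduce the printed 1-d.p. error exactly from the printed
  4-decimal m/z; the remainder were evidently computed from unrounded
  instrument values (a few rows even carry formula/mass pairs
  inconsistent by integer mass units) and are flagged rather than
  reconciled.

# Target assembly

Four screening rules, each intentionally simple:

* Compound–target predictions keep rows with probability **strictly**
  greater than 0 (configurable), then deduplicate per compound and across
  compounds.
* Disease sources are screened **independently per source** — their score
  scales (relevance scores, association scores, curation flags) are not
  comparable — keeping genes with score ≥ the source's arithmetic mean.
  Duplicate genes within a source collapse to their maximum score *before*
  the mean is computed; this is this package's documented choice where
  the convention is otherwise unstated. Because the maximum is always at
  least the mean, every source keeps at least one gene.
* Sources without scores (small curated databases) keep all genes.
* The therapeutic target set is the intersection of the compound-target
  union with the merged disease union. Gene symbols are treated as opaque
  identifiers canonicalized to uppercase; alias resolution is out of
  scope.

# Network topology

Graphs are simple, undirected and role-typed (compound / target /
pathway). Degree is the incident edge count. Betweenness centrality is
computed by Brandes' dependency-accumulation algorithm over unweighted
shortest paths, endpoints excluded, normalized by `2/((n−1)(n−2))` with
`n` the node count of the **whole graph** — the convention of the common
network-visualization tools, also applied per connected component on
disconnected graphs (so values in a small component are discounted by the
whole-graph size). Graphs with fewer than three nodes have betweenness 0.
The implementation is verified against an independent walk-counting
oracle (powers of the adjacency matrix) and against igraph.

The main-ingredient screen computes the degree and betweenness means over
**compound nodes only** and keeps compounds exceeding both means
**strictly** ("greater than the mean"; `strict = FALSE` relaxes to ≥). The
PPI screen keeps edges with combined score ≥ 0.9 (inclusive — a score of
exactly 0.9 passes) and removes "free" genes left without edges. Hub
ranking sorts by degree descending with alphabetical tie-break and
reports any nodes tied with the k-th degree beyond the cut explicitly
rather than silently dropping them; published hub lists frequently end in
a tie at exactly the cut.

The compound–target–pathway network keeps the targets annotated to the
selected pathways, the compounds that retain at least one edge to those
targets, and the pathway nodes, with compound–target and target–pathway
edges.

# Over-representation analysis

For a query of `n` genes against a term of `K` genes in a background of
`N`, the p-value is the upper hypergeometric tail
`P(X ≥ k) = Σ_{i≥k} C(K,i) C(N−K,n−i) / C(N,n)` (evaluated via
`stats::phyper`; an enumeration oracle over all `C(N,n)` draws verifies it
exactly for N ≤ 15). Terms with zero overlap are never reported, rows
with `p < α` (default 0.01, on the **raw** p-value — matching common
practice in this analysis style) are returned sorted by p; Benjamini–
Hochberg adjustment is available behind a flag but is not applied by
default. The background defaults to all genes in the annotation table;
query genes outside the background are excluded from `n` and counted in
the run report. Pathway selection for visualization and the
compound–target–pathway network takes, per category, the top terms by
enriched gene **count** (ties by p, then term id), default 20.

# The synthetic-study generator

`generate_study()` emits the five pipeline inputs with planted ground
truth. Defaults are fixed once to emulate a realistic study of this kind:
41 compounds; per-compound target counts uniform on 15–40 over a 471-gene
compound pool; 7 planted main ingredients whose therapeutic links are
boosted 5-fold; four disease sources of 4000 / 900 / 1100 / 3 genes with
lognormal, lognormal, uniform and score-less families (exercising every
branch of the score screen); a planted therapeutic intersection of
exactly 262 genes; a PPI layer with exactly 222 connected genes, 1205
super-threshold edges drawn with 10-fold weight on 10 planted hubs, plus
600 sub-threshold noise edges so the 0.9 filter is non-trivial; and an
annotation base of 120 terms over a universe of 8000 genes with one
planted term per category at 60% overlap with the therapeutic set and
half of the remaining terms mildly enriched (20% overlap) so that
top-pathway selection has real competition.

Construction gives hard guarantees rather than expectations: planted
disease genes are placed at twice their source's background maximum (so
the score ≥ mean screen provably keeps them), no compound-pool gene
outside the planted intersection ever appears in a disease source (so the
intersection is exact), every connected PPI gene receives at least one
super-threshold edge and the super-threshold edge count is exact.
Randomness is driven by one master seed through per-table sub-streams, so
generating one table never perturbs another and studies are byte-identical
across runs.

What the generator does **not** emulate: real chemistry (formulas are
drawn from the bundled identification table, not from structures),
scale-free PPI topology beyond planted-degree construction, correlated
annotation terms (no ontology DAG), or gene-identifier noise. Passing
recovery tests therefore demonstrate that the screens isolate planted
signal under controlled overlap and noise — not that any particular real
preparation has those properties.

# Problem sizes and runtimes

The test suite exercises the oracles at the sizes where exhaustive
computation is exact and fast: all-pairs path enumeration on 200 random
graphs of ≤ 10 nodes, full hypergeometric enumeration for backgrounds of
≤ 15 genes, brute-force formula grids of ~10^5 compositions, and
100-seed recovery sweeps at the full default study size. The acceptance
script re-runs the mass-accuracy anchors, the published network-count
arithmetic, and a 20-seed recovery sweep; it completes in well under a
minute on one core.

# Known limitations

* Formula fitting targets singly charged ions below ~1000 Da; multiply
  charged species and isotope-pattern scoring are out of scope.
* Gene symbols are not resolved against any nomenclature authority.
* Betweenness means depend on the normalization convention; comparisons
  against values computed by other software are only meaningful under the
  same convention (documented above).
* The enrichment background should ideally be the assay universe; the
  default (all annotated genes) inherits that caveat from the tools this
  analysis style is built on.
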