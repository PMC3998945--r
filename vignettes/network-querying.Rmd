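---
title: "Topology-based PPI network querying: model, solver and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-based PPI network querying}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netquery)
```

## The problem

A biologist has a small, curated protein–protein interaction (PPI)
network — a pathway of interest — and wants to find its counterpart in
a large species-specific interactome. Matching proteins by sequence
similarity alone ignores the very thing the query encodes: which
proteins interact. netquery aligns the query to the target *globally
and by topology*: it searches for the partial injective node mapping
that conserves as many query interactions as possible, using sequence
bit scores only to break ties. The conserved part of the alignment
supports transfer of functional annotation; target edges between
aligned proteins that have no counterpart in the query are hypotheses
for interactions missing from the query species.

## Model

Both networks are undirected simple graphs with per-edge confidences in
[0, 1]; before alignment, edges with confidence at or below the
threshold `c_min` are discarded (strictly "above" is kept, so
`c_min = 0` retains every positive-confidence edge). The default
`c_min = 0.1` is a permissive value suited to STRING-style combined
scores, where low-confidence edges are noisy but wholesale removal
would disconnect pathways.

An alignment is a partial injective map $a : V_1 \to V_2$ restricted to
candidate pairs: $a(v_1)$ must satisfy $E(v_1, a(v_1)) \le E_{\max}$
for the current E-value cutoff (non-strict, so the cutoff $E_{\max}=0$
meaningfully admits exact-zero E-values, which BLAST does report for
near-identical sequences). Pairs absent from the similarity table are
forbidden at every cutoff — the alignment is only defined over pairs
for which an E-value was computed. The topology score is the edge
correctness

$$ t(a) = \frac{1}{\min\{|E_1|, |E_2|\}}
   \sum_{uv \in E_1} w(u, a(u), v, a(v)), $$

with $w = 1$ exactly when both endpoints are mapped and their images
form a target edge. The total score adds a sequence term,

$$ s(a) = t(a) + \frac{\sum_{u \in V_1} b(u, a(u))}
   {(1 + \min\{|E_1|, |E_2|\}) \cdot \min\{|V_1|, |V_2|\}}, $$

where $b \in [0,1]$ is the normalized bit score. Since the bit-score
sum is at most $\min\{|V_1|, |V_2|\}$, the sequence term is *always*
strictly smaller than $1/\min\{|E_1|,|E_2|\}$ — the value of one
conserved edge — so the optimum of $s$ is the lexicographic optimum
(most conserved edges, then highest bit-score sum). The test suite
verifies this subordination and the lexicographic equivalence by
exhaustive enumeration on small random instances.

Edge and node counts in both formulas refer to the
*confidence-filtered* networks, which are the networks the alignment is
actually computed on.

### Bit-score normalization

Raw bit scores are divided by the instance-wide maximum, so the best
pair scores exactly 1 and ordering is preserved. This choice is
instance-intrinsic (no external self-score reference is needed) and
scale-invariant; an alternative — dividing each pair by the query
protein's self-alignment score — would need self-hits that tabular
input does not guarantee. Because the sequence term only breaks ties,
the normalization never changes which alignments maximize conserved
edges; it can only reorder alignments that conserve equally many.

## Solver

The optimization is a quadratic-assignment-style problem: the edge term
couples pairs of node assignments. `align_topology()` solves it exactly
with a depth-first branch-and-bound over partial injective maps. Query
nodes are processed in lexicographic order; at each node the search
branches over the allowed free candidates (lexicographic) and finally
over leaving the node unmapped. The bound at a search node is an
assignment relaxation solved by the Hungarian algorithm
(`clue::solve_LSAP`): each remaining query node is given a per-candidate
profit consisting of its sequence term, the full value of query edges
into the already-fixed part that would be conserved, and *half* the
potential value of each still-open query edge (counted at both
endpoints, ignoring the partner's injectivity), so the LSAP optimum
dominates every feasible completion. Completed search proves the
incumbent optimal (`gap = 0`); if the per-cutoff time limit (default
300 s) expires, the incumbent is returned with the best bound among
abandoned subproblems and `optimal = FALSE`. With `b \ge 0`, mapping an
extra node never hurts, so optima are effectively maximal mappings;
zero-bit candidates remain mappable.

Determinism: the search order is fixed, an incumbent is replaced only
by a strictly better score (tolerance 1e-12), and the LSAP solver is
deterministic — two runs on the same input produce identical output,
which the suite checks byte-for-byte on written result files.

`align_sequence_only()` drops the topology term entirely and solves the
maximum-weight injective assignment over normalized bit scores — a
linear assignment problem solved exactly, so its gap is always 0.
`brute_force_align()` enumerates every feasible partial injective map
(guarded at $10^7$ maps) and serves as the independent oracle: on 30
seeded random instances both solver modes must equal it exactly.

## The E-value cutoff ladder

`run_pipeline()` repeats the alignment over the ascending cutoff ladder
`c(0, 1e-100, 1e-50, 1e-10, 1, 10, 100)`. Candidate sets are nested
along the ladder, so the optimal total score is non-decreasing in
$E_{\max}$; the per-cutoff overview (`run_summary()`, or `tidy()` on
the report) lets the user pick, say, the lowest cutoff that reaches the
best topology score. Per-run wall-clock seconds are reported but never
asserted in tests.

## Input and output formats

Network files may be plain edge lists (2–3 whitespace-separated
columns, numeric third column read as confidence), Cytoscape SIF
(`node type node ...`, including multi-target lines and single-token
isolated nodes), IntAct MITAB (≥ 15 tab-separated columns; identifiers
from columns 1–2 with database prefixes stripped; confidence from a
`score:x` entry in column 15 when parseable) and STRING protein-links
text (integer `combined_score`, normalized by division by 1000). The
format is autodetected from structure, never from the extension. Lines
starting with `#` and blank lines are skipped in every dialect — the
edge-list dialect is not standardized on this point, so the permissive
reading was chosen and is documented here. Duplicate edges merge
keeping the maximum confidence; self-loops are dropped with a warning;
unconfidenced edges (SIF, and MITAB without a score) default to 1.
Node identifiers are case-sensitive exact strings; no identifier
cross-referencing is performed.

Sequence similarity enters as a precomputed tab-separated table (query
id, target id, E-value, bit score); an optional adapter
(`run_external_aligner()`) can produce it from two FASTA files via a
BLAST-like tool, but no test or pipeline path requires an external
binary. Results are written as four tab-separated tables (aligned
nodes, conserved edges, unaligned query edges, unaligned target edges
between aligned nodes) plus Cytoscape-compatible SIF/attribute files of
the union graph.

## The synthetic benchmark

`generate_planted()` builds instances with known ground truth: an
Erdős–Rényi-style query (edge probability 0.3, comparable to the
density of the packaged Wnt pathway, 17 edges over 11 nodes), embedded
into the target under a hidden injective map with each embedded edge
deleted independently with probability `p_rewire`, plus background
nodes and edges (probability 0.15, never between two embedded images,
so the planted subgraph differs from the query by exactly the deleted
edges). Confidences are Uniform(0.5, 1), comfortably above the default
`c_min` so filtering is exercised without destroying the instance.
True pairs get bit score 100 perturbed with standard deviation
`sigma * 100`; `k_decoys` decoy pairs per query node get
Uniform(20, 50); E-values follow the fixed monotone map
$E = 10^{-\mathrm{bits}/5}$ (arbitrary, chosen so the default cutoff
ladder actually separates candidate sets). Setting `n_inflated > 0`
gives that many query nodes one decoy at 1.5× their true bit score,
pointing at a *non-image* target — the situation where the
sequence-wise best partner is topologically wrong, which is exactly
where topology scoring should win.

At the benchmark settings (`n_query = 8`, `n_target = 20`,
`p_rewire = 0.1`, `k_decoys = 3`, `sigma = 0.1`, 20 seeded
replicates) topology mode recovers over 90% of planted pairs on
average, and with two inflated decoys per instance it conserves
strictly more edges than the sequence-only baseline on every
replicate — both are asserted by the acceptance suite.

What the generator does *not* emulate: realistic PPI degree
distributions (hubs, duplication–divergence), correlated noise between
edge confidence and sequence similarity, and many-to-many homology
(paralog families). Passing the planted benchmark therefore shows the
solver and scoring behave correctly under controlled perturbation, not
that recovery rates transfer to real interactomes.

## The Wnt fixture

The packaged query network covers the canonical Wnt signaling cascade
with 11 proteins (WNT1, A2MR, FZD1, DVL1, AXIN1, GSK3B, CTNNB1, APC,
TCF7, TLE1, MYC) and 17 interactions: ligand–receptor binding,
Dishevelled activation, inhibition of the GSK-3β/axin/APC/β-catenin
degradation complex, β-catenin–TCF complex formation displacing
Groucho, and induction of c-myc. The node and edge counts are the
authoritative facts; the individual edges are a reconstruction of the
pathway description, and tests deliberately assert only the counts and
the protein names. Self-alignment of this fixture under identity
similarity must conserve all 17 interactions with a closed gap at every
cutoff — the package's standing sanity check.

```{r wnt}
wnt <- wnt_fixture()
res <- align_topology(
  wnt$network, wnt$network,
  build_candidates(normalize_bits(wnt$similarity), 1)
)
glance(res)
```

## Numerical choices and degenerate inputs

* Score comparisons use tolerance 1e-12; the subordination guarantee is
  structural, so double precision suffices and rational arithmetic is
  unnecessary.
* `optimal` means gap ≤ 1e-6 (the gap is exactly 0 whenever the search
  completes).
* A cutoff admitting no candidate pair yields an empty-alignment run
  with score and bound 0 and a warning status — not an error — so a
  ladder run never aborts halfway.
* Networks left without edges by confidence filtering make edge
  correctness undefined; scoring then fails with an explicit message.
* All-zero bit scores are rejected at normalization (no informative
  similarity).
* Output tables are sorted lexicographically and written with fixed
  number formatting and `\n` line endings, so repeated runs are
  byte-identical.

## Problem sizes

The test and acceptance suites run at query scale: oracle comparisons
on 30 instances with up to 7 query and 9 target nodes and ≤ 4
candidates per node, exhaustive property checks on instances small
enough to enumerate completely, and the planted benchmark at 8×20
nodes over 20 replicates. These sizes keep every exhaustive oracle
exact while covering the regimes (ties, empty candidate sets, heavy
rewiring) where the solver logic can actually fail. Full
interactome-versus-interactome alignment is out of scope.

## Known limitations

* The branch-and-bound targets query-scale instances (tens of nodes);
  aligning two large interactomes would need the Lagrangian machinery
  of dedicated large-scale aligners. The solver backend is isolated
  behind `align_topology()`'s interface, so such an engine could be
  substituted.
* MITAB support is minimal by design: identifier columns and the
  column-15 score; the full PSI-MI vocabulary is ignored.
* No identifier mapping: query and target must use consistent protein
  identifiers, matching how the similarity table was computed.
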