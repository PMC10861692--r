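---
title: "Deriving and analysing adverse outcome pathway networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and analysing adverse outcome pathway networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aopnet)
```

## The problem

An adverse outcome pathway (AOP) is a linear chain of causally linked
biological events: a molecular initiating event (MIE) triggered by a stressor,
a sequence of intermediate key events (KE), and a regulatory-relevant adverse
outcome (AO). Each link is a key event relationship (KER) annotated by its
developers with an adjacency flag (adjacent = direct, nonadjacent = indirect)
and a qualitative weight of evidence (WoE: high, medium, low, or left
unspecified). Single AOPs are deliberately narrow; real toxicological
processes — nephrotoxicity among them — are covered only by a *collection* of
AOPs that share events. Merging the collection on shared KEs and KERs yields a
directed network in which graph statistics identify the events most central to
the adverse-outcome domain, and hence the most informative targets for in
vitro or in silico assay batteries.

`aopnet` implements that derivation and analysis as a reusable pipeline:

1. **Ingest** a curated relationship table (one KER per row) from CSV or XLSX,
   with a configurable column mapping.
2. **Harmonise** synonymous key-event titles with an explicit, curated map.
3. **Validate** (missing endpoint annotations, contradictory duplicates,
   self-loops, unused map keys).
4. **Build** the merged network under documented node-drop,
   nonadjacency-reconciliation and edge-collapse rules.
5. **Analyse**: degrees and convergence classes, directed eccentricity with
   positional bands, betweenness, the normalised MIE→AO simple-path
   occurrence score, AOP-sharing counts, WoE distribution.
6. **Export** for Cytoscape (GraphML, SIF) and for downstream analysis (JSON,
   TSV, Markdown).

## The merge model

Nodes are key events identified solely by their canonical title after Unicode
NFC normalisation and whitespace collapsing. There is no fuzzy matching:
pooling two wiki entries that describe the same biology is a curation
decision, expressed as a `harmonisation_map()` (two-column CSV: raw title →
canonical title). The map must be idempotent — canonical titles may not
themselves be remapped — which makes `apply_harmonisation()` idempotent and
guarantees the KER multiset is preserved up to title rewriting. A map that
would collapse both endpoints of one KER is rejected, because it would
manufacture a self-loop out of curation noise.

Edges are collapsed to at most one per ordered node pair:

* **Provenance** — the set of AOP ids reporting the pair is unioned and kept
  per edge (and per node), so the simple graph used for metrics never loses
  the per-AOP multiplicity.
* **WoE merge** — the collapsed edge carries the *highest* contributor level
  (high > medium > low > unspecified). The per-AOP levels are retained in
  `woe_by_aop`; nothing is discarded. Taking the maximum reflects that a
  relationship's evidentiary support is at least as strong as its
  best-documented report.
* **Adjacency** — under the default `nonadjacent_policy = "reconcile"`, a pair
  flagged nonadjacent in one AOP but adjacent in another is stored as
  adjacent: the direct report supersedes the shortcut annotation. Pairs
  nonadjacent in *every* contributor keep the flag. `"keep_flagged"` and
  `"exclude"` are provided for sensitivity analysis, since nonadjacent
  shortcuts inflate degree and path counts and deflate eccentricity.
* **Node drops** — `drop_titles` defaults to `"Unknown, MIE"`, the wiki
  placeholder for an uncharacterised initiating event; it contributes no
  mechanistic information and is removed with its incident edges after the
  merge. Nodes left isolated by a drop are retained (they still count in
  sharing statistics, with degree 0) and logged.

Every applied rule is appended to `build_log`, so a derived network is
auditable against its input row by row. Node and edge tables are stored in
locale-independent (radix) sorted order, making builds bit-reproducible and
invariant to input row order.

## The statistics

For each node: in-degree, out-degree, total degree over the collapsed edge
set. A node is **convergent** when in > out (pathways meet there),
**divergent** when out > in (a fork point), and balanced otherwise; the three
classes always partition the node set.

**Directed eccentricity** defaults to the *incoming* orientation:
`ecc(v)` is the longest shortest directed path from any node that can reach
`v`, with unreachable pairs ignored and ancestor-free nodes scoring 0. This
orientation is what makes the conventional positional reading work — events
with no upstream causes (MIEs) score low, terminal outcomes score high — so
the bands are **upstream** (`ecc < 3`), **middle** (`3–6`), **downstream**
(`ecc > 6`). The outgoing orientation is available for sensitivity analysis;
the banding thresholds are the conventional ones for networks of this scale
(a few dozen events, chains of 3–8).

**Betweenness** is standard directed shortest-path betweenness normalised by
$(n-1)(n-2)$, computed with igraph (graphs with fewer than three nodes score
zero by convention).

**Simple-path occurrence** is the statistic that adapts betweenness to the
AOP setting: enumerate *all* simple directed paths from any annotated MIE to
any annotated AO, and score each node by the fraction of those paths that
contain it,

$$\mathrm{occ}(v) \;=\; \frac{\#\{\,P \in \mathcal{P}_{\mathrm{MIE}\to\mathrm{AO}} : v \in P\,\}}{|\mathcal{P}_{\mathrm{MIE}\to\mathrm{AO}}|} \in [0,1].$$

Three choices here are deliberate:

* **Endpoints are annotation-driven, not degree-driven.** An event recorded as
  the MIE of one pathway remains an enumeration source even when other
  pathways give it upstream causes (cytotoxicity is the canonical case), and
  an AO with outgoing edges remains a sink. Inferring endpoints from degree
  would silently change the statistic on exactly the most interesting nodes.
* **Cycle safety by construction.** The enumerator is a depth-first search
  that forbids revisiting a node within a path, so feedback loops (e.g.
  oxidative stress ↔ mitochondrial dysfunction) terminate naturally. Because
  simple-path counts are worst-case exponential, a `max_paths` guard
  (default $10^6$, far above anything a curated collection of this size
  produces) aborts with a resource error instead of exhausting memory.
* **Normalisation by the total path count**, the only reading that puts
  scores in $[0,1]$ with interior nodes scoring below endpoints that lie on
  every path. Single-node "paths" at a node annotated both MIE and AO are
  excluded: a zero-length path carries no relationship and would only inflate
  that node's own score.

Path emission order is lexicographic in the node sequence and therefore
deterministic.

**Sharing and WoE summaries.** Each node's `aop_share_count` is the number of
source AOPs reporting it; the histogram over counts quantifies the
interconnectivity of the collection. The WoE distribution is reported over
collapsed edges using the merged level. Integer percentages throughout use
**round half away from zero**, the convention under which the shares of a
45-node network render self-consistently (26/45 → 58%, 11/45 → 24%,
7/45 → 16%, 27/45 → 60%); raw fractions are always reported alongside, and a
percentage vector that does not sum to 100 after rounding is flagged rather
than silently rescaled. For the in/out-degree histograms the natural
denominator is ambiguous (all nodes, or only nodes with nonzero respective
degree), so `summarise_network()` emits both.

Ranked outputs are ordered by path occurrence (desc), then degree (desc),
then title — a fully deterministic tie-break.

## The synthetic generator

`generate_collection()` produces collections with the structural features the
analysis assumes, so the whole pipeline is testable without any download:

| parameter | default | meaning |
|---|---|---|
| `n_aops` | 13 | pathways per collection |
| `chain_length_range` | 3–8 | events per pathway (MIE, ≥1 KE, AO) |
| `p_share_ke` | 0.25 | chance a new event reuses an existing one |
| `p_share_ker` | 0.05 | chance a step reuses a whole relationship |
| `p_feedback` | 0.10 | chance of one feedback back-edge per pathway |
| `p_nonadjacent` | 0.04 | chance a KER is flagged nonadjacent |
| `woe_weights` | .23/.13/0/.64 | high/medium/low/unspecified mix |

The defaults describe the regime of curated nephrotoxicity collections: a
13-pathway inventory, limited interconnectivity (most events in one pathway
only), roughly a fifth of relationships with high and an eighth with medium
evidence and the rest unspecified, a handful of nonadjacent flags, and about
one feedback loop per collection. Feedback back-edges never run from a
pathway's AO to its own MIE, so every pathway keeps at least one MIE→AO path.
Reused events are drawn uniformly from the pool of previously created ones —
the simplest model with the required sharing structure.

Seeding: pathway `i` draws from a substream derived deterministically from
`(seed, i)`, so identical configs give byte-identical CSVs and appending a
pathway never reshuffles earlier ones.

What the generator does **not** emulate: real key-event title semantics (so
harmonisation exercises use synthetic synonym maps), hub-like preferential
sharing (reuse is uniform, whereas real collections concentrate on a few
events such as cytotoxicity), correlated WoE within a pathway, and
per-pathway endpoint reuse patterns (shared AOs across pathways arise only
through random reuse). Passing property tests on synthetic collections
therefore demonstrates correctness of the graph machinery and the curation
rules, not fidelity to any particular curated network; reproducing published
statistics requires the corresponding curated table.

The packaged fixtures follow an anti-fabrication rule: the 13-pathway
nephrotoxicity inventory fixture (`table1_fixture()`) contains the real
endpoint titles but clearly namespaced `placeholder:` interior events, because
the interiors are not part of the public inventory, and the convergence
reference fixture (`table2_fixture()`) carries only the published
classification lists, with no invented edges.

## Numerical and degenerate-input behaviour

* Empty collections, collections failing validation, and self-loops are build
  errors (self-loops name the AOP and relationship, since they can only arise
  from over-aggressive harmonisation).
* Networks with no annotated MIE or no annotated AO refuse path enumeration.
* An empty enumerated path list makes `path_occurrence()` error rather than
  return 0/0.
* Eccentricity on disconnected graphs maximises over finite distances only;
  isolated nodes score 0 and band as upstream.
* All orderings (node tables, edge tables, path emission, rankings) are
  radix-sorted, hence identical across locales and platforms.

## Validation strategy and problem sizes

The test suite checks the enumerator and the betweenness wrapper against
independent brute-force oracles (igraph's simple-path enumerator, and a
from-first-principles BFS shortest-path-counting implementation) exhaustively
over every labelled digraph on 2–4 nodes plus seeded random samples of 5- and
6-node digraphs; analytic diamond/chain cases are asserted exactly; and 200
seeded collections with a feedback loop forced into every pathway verify
termination and score ranges. These sizes keep the default test run fast
while covering the structures — cycles, multi-source/multi-sink overlap,
disconnected components — that the curated networks exhibit.

## Known limitations

* The curated nephrotoxicity relationship table itself is not
  redistributable here; the acceptance check that reproduces its published
  statistics runs only when that table is supplied at
  `inst/extdata/si1_nephrotoxicity_kers.csv`.
* Harmonisation is exact-match by design; no ontology mapping or synonym
  detection is attempted.
* The pipeline is qualitative: no dose–response or response–response
  modelling of relationships, no stressor chemistry, and no layout/rendering
  of network figures (exports target Cytoscape for that).
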