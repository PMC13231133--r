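---
title: "Linking curated toxicogenomic relations to adverse outcome pathways: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking curated toxicogenomic relations to adverse outcome pathways: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoplink)
```

## The problem

Adverse outcome pathways (AOPs) describe disease processes as a chain of
typed biological events — a molecular initiating event (MIE), intermediate
key events (KE) and an adverse outcome (AO) — connected by key event
relationships (KER). AOPs are deliberately chemical-agnostic. Curated
toxicogenomic knowledge bases, on the other hand, hold millions of
literature-curated statements relating chemicals to genes, phenotypes and
diseases. `aoplink` joins the two worlds offline: given a snapshot of five
curated relation tables (chemical–gene, chemical–phenotype,
chemical–disease, gene–phenotype, gene–disease), three controlled
vocabularies (a GO-style phenotype ontology, a MEDIC-style disease
poly-hierarchy, a chemical hierarchy) and an AOP event graph, it finds the
environmental chemicals that intersect each pathway event, prioritizes
them, enumerates mechanistic CGPD-tetramers, and builds candidate pathway
and disease networks from the shared intermediates.

## Data model and subsumption semantics

All identifiers are normalized to `NAMESPACE:ID` form (`MESH:D001321`,
`GO:0006979`, `GENE:2099`). Relation rows identical up to their supporting
articles are merged with the article sets unioned; rows differing in
direct-evidence class (`marker_mechanism` vs `therapeutic`) are kept
separate because the evidence class changes retrieval semantics — the
adverse-outcome event only counts chemicals curated as marker/mechanism to
the outcome disease. No organism filter is applied by default (curated
content is cross-species); an allow-list can be supplied.

Hierarchical queries use *descendant closure*: a query on a term returns
data annotated to the term or any transitive descendant, mirroring how
curated databases subsume descendant annotations under the parent. Closure
follows `is_a` links by default; `part_of` can be enabled when parsing OBO
input. Whether `regulates`-type links should also be traversed is left off
by default — it is the conservative core of subsumption, and the option can
be revisited without touching callers. Gene wildcards are prefix-only
patterns (`"GRIN*"`), matched case-insensitively against gene symbols; the
manual vetting of wildcard hits is reproduced as a declarative exclusion
list, never an interactive step, so runs are reproducible. A lone `*` is
rejected.

## Event coverage and the 1..E score

Each AOP event maps to an ordered list of vocabulary terms (genes, gene
patterns, phenotypes, or a disease with an optional evidence filter). A
chemical is *incident* to an event if at least one of the event's terms
retrieves it; duplicate hits from multiple terms of the same event count
once. The coverage score of a chemical is its incidence row-sum, an integer
between 1 and the number of events (six for the packaged autism pathway).
Chemicals touching no event never appear. Ranking orders by descending
score, then ascending chemical id — the tie-break is a determinism choice;
no ordering within a score tier is scientifically meaningful. Any curated
chemical–gene relation counts as an interaction regardless of direction or
action, matching the expansive "any aspect of gene modulation" reading of
the initiating event.

The packaged `autism_event_mapping()` carries the curated translation of
the six autism-pathway events into 19 mechanistic terms plus the
outcome disease (with marker/mechanism filter). One GO accession appears
with different digit counts in different places upstream; the fixture uses
the 7-digit form that is valid GO syntax (`GO:0098989`), and likewise
`GO:0050877` where an inconsistent variant circulates.

## CGPD-tetramers

A tetramer (chemical, gene, phenotype, disease) exists only when five
directly curated relations all exist: C–G, C–P, C–D, G–P and G–D.
Enumeration is implemented as indexed joins over the relation tables —
(C,G) × (G,P) filtered by existing (C,P), then × (G,D) filtered by existing
(C,D) — never as a materialized cross-product; a brute-force quadruple loop
exists only as a test oracle and the two are compared exactly on 100 seeded
random snapshots. The disease slot of a query is closure-expanded
(querying a parent disease also retrieves tetramers for its descendants)
and the resulting tuples are deduplicated on the full 4-tuple, so
overlapping descendant expansion cannot double-count. By default the C–D
edge must carry marker/mechanism evidence (consistent with the
adverse-outcome retrieval rule) while the G–D edge accepts any direct
evidence; both are arguments, since upstream documentation names no classes
for the tetramer tool itself.

Each tetramer carries its five per-edge article sets. The default
*evidence-strength score* is the number of distinct articles in the union
of the five sets — transparent, recomputable, and strictly monotone
non-decreasing in each edge's support. The weighting used by the upstream
database is not public; the score is therefore pluggable (`strategy`
argument) and the default documented as this package's own definition.

Projecting tetramers to their (gene, phenotype) pairs gives *GP-dimers*;
intersecting the dimer projections of several queries yields the shared
mechanistic intermediates, with per-gene and per-phenotype tallies. The
tetramers restricted to the shared dimers can be exported as chord-diagram
data (nodes in four roles; ribbon weight between two nodes = number of
tetramers containing both). Rendering is out of scope — the export is the
contract.

## Candidate pathway construction

For designated phenotypes, the distinct genes of their tetramers form
per-phenotype gene sets; every unordered phenotype pair with a non-empty
gene-set intersection becomes an edge carrying that intersection. Edges are
computed between *all* pairs, not only adjacent levels: the four levels of
biological organization (molecular < cellular < system < behavioral) are
presentation metadata assigned by the analyst, never inferred. The
assembled object verifies that each edge's genes are exactly the
intersection of its endpoints' sets, serializes to a sectioned text format
whose round trip preserves node and edge sets, and exports GraphML (via
igraph) with stressor→phenotype→outcome scaffold edges alongside the
shared-gene arcs.

## Disease networks

For each mechanistic event, the tetramers retrieved with each of the
event's gene/pattern/phenotype terms fixed are projected to their diseases
and unioned; an event mapped only to disease terms is rejected as circular.
Disease identity is the canonical id — parent and descendant diseases
remain distinct set elements (no closure collapsing), matching the
treatment of the spectrum disorder and its descendant as separate tetramer
outcomes. The k-way intersection is computed exactly: for k ≤ 6 labeled
sets, every non-empty label subset gets the count of elements belonging to
exactly those sets; regions are disjoint and sum to the union size
(asserted on every call path in the tests). Leave-one-out expansion drops
one label and reports `additional = expanded \ core`, with
`|additional| = |expanded| − |core|` by construction. Cross-pathway event
sharing lists, for each queried event, every pathway containing it with
that pathway's AO-typed events.

## The synthetic generator: what it emulates, and what it does not

`synthetic_config()` generates seeded snapshots whose *planted* structure
is machine-checkable against a ground-truth manifest. Its defaults are the
study conditions the pipeline is meant to reproduce:

* coverage tiers of 12 six-event and 64 five-event chemicals (76 at five or
  more), with lower tiers {4: 222, 3: 450, 2: 900, 1: 1995} chosen once so
  that, together with the five per-event block chemicals, the distinct
  intersecting chemicals total 3,648 — the split across the unreported
  lower tiers is a realism choice, not a reported quantity;
* three tetramer query chemicals totalling 2,021 / 2,161 / 1,373 tetramers
  against one outcome disease, sharing exactly 291 GP-dimers over 136 genes
  and 53 phenotypes, of which six designated phenotypes cover a 93-gene
  union (with planted gene overlap between consecutive selected phenotypes
  so the candidate pathway has shared-gene edges to carry);
* per-event disease sets of 149/619/55/471/842 with a 17-disease core and
  108 additional diseases when the smallest event is left out;
* near-miss decoys: tuples missing exactly one of the five required edges,
  cycling through the edge kinds — enumeration must never emit them, and
  any background edge that would complete one is recorded as a promotion;
* per-edge article counts of `1 + geometric(p = 0.5)` — no distribution is
  reported upstream; this one exercises evidence-score monotonicity with
  realistic small counts.

Tier chemicals annotate to random *descendants* of each event's anchor
term, so recovery genuinely exercises subsumption; hierarchies are random
trees with a configurable extra-parent probability (GO is a DAG, the
disease vocabulary a poly-hierarchy). A single integer seed drives one
explicit stream and the caller's RNG state is restored afterwards;
identical configurations serialize byte-identically.

What the generator does **not** emulate: the degree distributions, term
names or absolute per-term counts of the real curated database. Passing the
planted-recovery suite therefore shows the *algorithms* are exact, not that
real-data results would match any particular revision — live-database
quantities (per-term chemical counts, the identities of the shared
diseases, the 23-gene wildcard expansion) change monthly and are covered by
oracle-equivalence and planted-recovery properties instead. Reproducing the
deposited supplementary analyses requires downloading the four extended-data
workbooks and pointing `reproduce_supplementary()` (or the option
`aoplink.supplementary_dir`) at them.

## Numerical and testing choices

Degenerate inputs are defined, not accidental: empty relation files load as
empty tables; an empty vocabulary file is an empty hierarchy; an empty
ranking result is valid; a phenotype absent from all tetramers yields an
empty, flagged gene set. Validation errors (`aoplink_validation_error`),
format errors (`aoplink_format_error`) and lookup errors
(`aoplink_lookup_error`) are distinct condition classes.

Problem sizes in the test suite are chosen so the whole suite runs in well
under a minute while keeping the oracle comparisons exhaustive where they
matter: 100 seeded random snapshots of at most 8 chemicals × 6 genes × 6
phenotypes × 4 diseases for the tetramer quadruple-loop oracle, 100 random
DAGs of up to 200 nodes for the closure/BFS oracle, 25 snapshots of 50
chemicals for the per-triple coverage oracle, and 100 random 5-set
instances for the intersection algebra. The full-scale synthetic pipeline
(3,648 chemicals, ~5,500 tetramers) runs end-to-end in a few seconds and is
exercised by the acceptance script.

## Limitations

The artifact operates on local files only; it does not query live web
services, render chord diagrams or Venn figures, score KER weight of
evidence per regulatory guidance, or compute inference-network statistics.
The event→term mapping is consumed, not learned: translating pathway event
titles into vocabulary terms remains an expert judgment, and the packaged
mapping records one such judgment. Tetramers are a restrictive subset of
mechanistic hypotheses — if any one of the five curated statements is
missing, the tetramer does not exist, so absence of a tetramer is weak
evidence of absence.
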