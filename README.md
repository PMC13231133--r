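# aoplink

Offline linkage of curated toxicogenomic relations to adverse outcome
pathways (AOPs).

Chronic diseases arise from an interplay of genetics and environmental
exposure, and two kinds of public resources describe the two halves:
curated toxicogenomic databases hold literature-curated chemical–gene,
chemical–phenotype, chemical–disease, gene–phenotype and gene–disease
statements under controlled vocabularies (GO phenotypes, a MEDIC-style
disease poly-hierarchy, a chemical hierarchy), while AOP repositories hold
chemical-agnostic event graphs — a molecular initiating event (MIE), key
events (KE) and an adverse outcome (AO) joined by key event relationships
(KER). `aoplink` is for toxicologists and systems biologists who want to
join the two *offline*, on local snapshot files, and get reproducible
tables rather than web-tool sessions.

## What it computes

Given a knowledge snapshot, a pathway and an event→term mapping:

1. **Chemical–event intersection and prioritization.** For an AOP with
   events $e_1, \dots, e_E$, a chemical $c$ is incident to $e_j$ if any of
   the event's mapped terms retrieves it (gene interaction, prefix-wildcard
   gene family, phenotype or disease with descendant-closure subsumption,
   optionally filtered to marker/mechanism evidence). The coverage score
   $s(c) = \sum_j \mathbb{1}[c \in e_j] \in \{1,\dots,E\}$ ranks chemicals
   by the breadth of their intersection with the pathway.
2. **CGPD-tetramer enumeration.** A tetramer $(C, G, P, D)$ exists iff all
   five curated relations exist: C–G, C–P, C–D, G–P, G–D. Enumeration is by
   indexed joins; each tetramer carries its five per-edge article sets, and
   its evidence strength is the number of distinct supporting articles.
3. **Shared GP-dimers.** Intersecting the (gene, phenotype) projections of
   several tetramer queries yields the mechanistic intermediates common to
   all of them, with gene/phenotype frequency tallies and chord-diagram
   export.
4. **Candidate AOP construction.** Per-phenotype tetramer gene sets,
   shared-gene edges between every phenotype pair, levels of biological
   organization (molecular < cellular < system < behavioral) as
   presentation metadata, GraphML export.
5. **Disease networks.** Per-event tetramer-derived disease sets, exact
   Venn/UpSet region counts for up to six sets, leave-one-out core
   expansion, and cross-AOP event-sharing tables.

A seeded synthetic-snapshot generator (`synthetic_config()`,
`generate_snapshot()`) plants coverage tiers, tetramers, near-miss decoys
(tuples missing exactly one of the five edges) and shared-dimer blocks, all
recorded in a ground-truth manifest, so every stage is testable with no
download. The packaged fixtures include the autism pathway (six events,
bifurcated at the NMDAR event) and its curated 19-term event mapping.

## Worked example

```r
library(aoplink)

gen <- generate_snapshot(synthetic_config(seed = 1))
cov <- event_coverage(gen$snapshot, gen$mapping, gen$aop)
cov
#> <coverage_matrix> 3648 chemicals x 6 events
#>   score 6: 12
#>   score 5: 64
#>   score 4: 222
#>   score 3: 450
#>   score 2: 900
#>   score 1: 2000

head(rank_chemicals(cov, min_score = 6L)[, 1:4], 3)
#>    chemical_id score MIE:101 KE:102
#> 1 MESH:C000001     6    TRUE   TRUE
#> 2 MESH:C000002     6    TRUE   TRUE
#> 3 MESH:C000003     6    TRUE   TRUE

plan <- gen$manifest$dimer_plan
sets <- lapply(plan$chemicals, function(ch)
  enumerate_tetramers(gen$snapshot, chemical = ch, disease = plan$disease))
sapply(sets, nrow)
#> [1] 2021 2161 1373
sh <- shared_dimers(sets)
nrow(sh$dimers)
#> [1] 291
head(sh$phenotype_tally, 3)
#>           id n_dimers
#> 1 GO:0000088       18
#> 2 GO:0000089       18
#> 3 GO:0000090       18
```

3,648 distinct chemicals intersect the six events; 12 reach all six and 76
reach five or more — the prioritized stressor tier. The three tetramer
queries share 291 gene–phenotype dimers, and the tally shows which
phenotypes recur most among the shared mechanisms.

To rerun the published supplementary analyses on the deposited workbooks
(Tables S1–S4 of the extended data, not bundled here), download them and
point the package at the directory:

```r
options(aoplink.supplementary_dir = "/path/to/supplementary")
reproduce_supplementary(supplementary_dir())
```

## Layout

- `R/` — package code: loaders and snapshot assembly (`kb_io`), hierarchy
  algebra, event intersection, tetramer engine, pathway construction,
  disease networks, synthetic generator, pipeline runner.
- `inst/extdata/` — plain-text fixtures: the autism pathway, its event
  mapping, a related-pathways fixture, the autism disease branch.
- `analysis/` — numbered stage drivers; `scripts/acceptance.R` — the
  reproduction script; `vignettes/aop-linking-methods.Rmd` — the methods
  notes.
- `tests/testthat/` — unit, property and acceptance suites with naive
  oracles (BFS reachability, quadruple-loop enumeration, per-triple
  coverage) kept independent of the implementations they check.
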