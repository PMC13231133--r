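Package: aoplink
Title: Linking Curated Toxicogenomic Relations to Adverse Outcome Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An offline pipeline that joins curated chemical-gene,
    chemical-phenotype, chemical-disease, gene-phenotype and gene-disease
    relation tables (Comparative Toxicogenomics Database bulk-file dialect)
    with adverse outcome pathway (AOP) event graphs (AOP-Wiki dialect).
    Supports ontology descendant-closure queries over GO, MEDIC and chemical
    hierarchies, chemical-event intersection and 1..E coverage scoring,
    CGPD-tetramer enumeration under the five-curated-edge constraint,
    gene-phenotype dimer intersection and chord-diagram export, data-driven
    candidate AOP graph construction, and multi-set disease-network
    discovery (Venn/UpSet region counts, leave-one-out core expansion,
    cross-AOP event sharing). Includes a seeded synthetic snapshot generator
    with planted coverage tiers, tetramers and near-miss decoys so every
    stage is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    readxl,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
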