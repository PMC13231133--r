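#!/usr/bin/env Rscript

# Stage 4 — candidate-pathway construction.
#
# Collects the tetramer gene set of each designated phenotype (from the
# shared-dimer restricted tetramers), links every phenotype pair sharing
# genes, assigns the four levels of biological organization, and exports
# the leveled candidate pathway as structured text and GraphML.

library(aoplink)
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args)) args[[1]] else 1L)
dir.create("results", showWarnings = FALSE)

gen <- generate_snapshot(synthetic_config(seed = seed))
plan <- gen$manifest$dimer_plan
sets <- lapply(plan$chemicals, function(ch)
  enumerate_tetramers(gen$snapshot, chemical = ch, disease = plan$disease))
shared <- shared_dimers(sets)
restricted <- do.call(rbind, lapply(sets, restrict_to_dimers, dimers = shared$dimers))

sel <- plan$selected_phenotypes
gs <- phenotype_gene_sets(restricted, sel)
cat("selected phenotypes:", length(sel),
    " gene-set union:", length(unique(unlist(gs$gene_sets))), "\n")

candidate <- assemble_aop_graph(
  stressors = plan$chemicals,
  phenotypes = data.frame(
    phenotype_id = sel,
    level = rep_len(c("molecular", "cellular", "system", "behavioral"), length(sel))),
  gene_sets = gs$gene_sets,
  outcome = plan$disease)
print(candidate)
write_aop_candidate(candidate, file.path("results", "aop_candidate.txt"))
write_aop_graphml(candidate, file.path("results", "aop_candidate.graphml"))
cat("shared-gene edges between phenotype pairs:", nrow(candidate$edges), "\n")
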