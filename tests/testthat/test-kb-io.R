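# Loaders for the curated-relation, vocabulary, pathway and tetramer-export
# dialects, and the canonical snapshot round trip.

write_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("relation tables parse with comment headers and collapse duplicates", {
  path <- write_tmp(c(
    "# bulk download commentary",
    "# more commentary",
    "ChemicalID\tGeneID\tPubMedIDs",
    "C000001\t2099\ta1",
    "C000002\t2099\ta2",
    "C000003\t5594\ta3"
  ))
  cmap <- c(subject_id = "ChemicalID", object_id = "GeneID",
            support_articles = "PubMedIDs")
  rec <- load_relation_table(path, "chem_gene", cmap)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$subject_id, sprintf("MESH:C%06d", 1:3))
  expect_equal(rec$object_id, c("GENE:2099", "GENE:2099", "GENE:5594"))

  dup <- write_tmp(c("ChemicalID\tGeneID\tPubMedIDs",
                     "C000001\t2099\ta1", "C000001\t2099\ta2"))
  rec <- load_relation_table(dup, "chem_gene", cmap)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$support_articles[[1]], c("A1", "A2"))

  expect_error(
    load_relation_table(path, "chem_gene",
                        c(subject_id = "NoSuchColumn", object_id = "GeneID")),
    "NoSuchColumn", class = "aoplink_format_error")
})

test_that("relation rows differing only in evidence class stay separate", {
  path <- write_tmp(c("chem\tdis\tev",
                      "C000001\tD000001\tmarker/mechanism",
                      "C000001\tD000001\ttherapeutic"))
  rec <- load_relation_table(path, "chem_disease",
                             c(subject_id = "chem", object_id = "dis",
                               direct_evidence = "ev"))
  expect_equal(nrow(rec), 2L)
  expect_setequal(rec$direct_evidence, c("marker_mechanism", "therapeutic"))
})

test_that("gzip input is detected by magic bytes regardless of extension", {
  path <- withr::local_tempfile(fileext = ".tsv")  # no .gz extension
  con <- gzfile(path, "wt")
  writeLines(c("s\to", "C000001\t2099"), con)
  close(con)
  rec <- load_relation_table(path, "chem_gene", c(subject_id = "s", object_id = "o"))
  expect_equal(rec$object_id, "GENE:2099")
})

test_that("OBO parsing builds chains, drops obsolete terms, rejects dangling is_a", {
  obo <- write_tmp(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: A", "",
    "[Term]", "id: GO:0000002", "name: B", "is_a: GO:0000001 ! A", "",
    "[Term]", "id: GO:0000003", "name: C", "is_a: GO:0000002", ""
  ), ext = ".obo")
  h <- parse_obo(obo)
  expect_equal(nrow(h$nodes), 3L)
  expect_equal(descendant_closure(h, "GO:0000001"),
               c("GO:0000001", "GO:0000002", "GO:0000003"))

  obs <- write_tmp(c("[Term]", "id: GO:0000001", "name: A", "",
                     "[Term]", "id: GO:0000009", "name: gone",
                     "is_obsolete: true", ""), ext = ".obo")
  h <- parse_obo(obs)
  expect_equal(h$nodes$id, "GO:0000001")

  dangling <- write_tmp(c("[Term]", "id: GO:0000001", "name: A",
                          "is_a: GO:0999999", ""), ext = ".obo")
  expect_error(parse_obo(dangling), "GO:0999999", class = "aoplink_validation_error")
})

test_that("part_of links are honored only when enabled", {
  obo <- write_tmp(c("[Term]", "id: GO:0000001", "name: whole", "",
                     "[Term]", "id: GO:0000002", "name: part",
                     "relationship: part_of GO:0000001", ""), ext = ".obo")
  expect_equal(descendant_closure(parse_obo(obo), "GO:0000001"), "GO:0000001")
  expect_equal(descendant_closure(parse_obo(obo, part_of = TRUE), "GO:0000001"),
               c("GO:0000001", "GO:0000002"))
})

test_that("tree vocabularies parse the autism branch, multi-parents, empty files", {
  h <- parse_tree_vocab(system.file("extdata", "medic_autism.tsv", package = "aoplink"),
                        "disease")
  expect_equal(nrow(h$nodes), 4L)
  expect_setequal(
    setdiff(descendant_closure(h, "MESH:D000067877"), "MESH:D000067877"),
    c("MESH:D001321", "MESH:D020817", "MESH:C538235"))

  multi <- write_tmp(c("id\tname\tparent_ids\ttree_numbers",
                       "D000001\tA\t\tC01",
                       "D000002\tB\t\tC02",
                       "D000003\tX\t\tC01.100|C02.200"))
  h2 <- parse_tree_vocab(multi, "disease")
  expect_setequal(ancestors(h2, "MESH:D000003"), c("MESH:D000001", "MESH:D000002"))

  h3 <- parse_tree_vocab(write_tmp(character()), "disease")
  expect_equal(nrow(h3$nodes), 0L)
})

test_that("AOP files load typed events and KERs, sharing events across AOPs", {
  aop <- autism_aop()
  def <- aop$aops[["AOP:522"]]
  expect_equal(nrow(def$events), 6L)
  expect_equal(nrow(def$kers), 5L)
  # the pathway bifurcates: the NMDAR event feeds the synaptic event
  expect_equal(def$kers$to[def$kers$from == "KE:195"], "KE:2208")
  expect_equal(def$events$event_type[def$events$event_id == "AO:2209"], "AO")

  shared <- write_tmp(c(
    "aop_id\tevent_id\tevent_type\tevent_title\tdownstream_event_ids",
    "AOP:1\tKE:9\tKE\tshared event\t",
    "AOP:2\tKE:9\tKE\tshared event\t"))
  two <- load_aop_definitions(shared)
  expect_equal(length(two$aops), 2L)
  expect_equal(nrow(two$events), 1L)

  bad <- write_tmp(c(
    "aop_id\tevent_id\tevent_type\tevent_title\tdownstream_event_ids",
    "AOP:1\tKE:9\tKE\tevent\tKE:404"))
  expect_error(load_aop_definitions(bad), "KE:404", class = "aoplink_validation_error")
})

test_that("tetramer exports parse verbatim and reject incomplete rows", {
  csv <- write_tmp(c("chemical_id,gene_id,phenotype_id,disease_id",
                     "C006780,2099,GO:0006979,D000067877",
                     "C006780,2099,GO:0006979,D000067877",
                     "D014635,348,GO:0006629,D001321"), ext = ".csv")
  rows <- load_tetramer_export(csv)
  expect_equal(nrow(rows), 3L)  # duplicates preserved at load
  expect_equal(rows$disease_id[3], "MESH:D001321")

  incomplete <- write_tmp(c("chemical_id,gene_id,phenotype_id,disease_id",
                            "C006780,2099,GO:0006979,"), ext = ".csv")
  expect_error(load_tetramer_export(incomplete), "disease_id",
               class = "aoplink_format_error")
})

test_that("snapshot serialization round-trips and assembly is idempotent", {
  gen <- generate_snapshot(synthetic_config(
    seed = 3, n_chemicals = 30, coverage_tiers = c(`6` = 2, `3` = 3, `1` = 4),
    n_planted_tetramers = 4, n_decoys = 4, dimer_plan = NULL,
    event_disease_plan = NULL,
    background_density = c(chem_gene = 0.05, chem_phenotype = 0.05,
                           chem_disease = 0.05, gene_phenotype = 0.05,
                           gene_disease = 0.05)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_snapshot(gen$snapshot, d1)
  back <- read_snapshot(d1)
  for (k in names(gen$snapshot$relations)) {
    expect_equal(back$relations[[k]], gen$snapshot$relations[[k]],
                 ignore_attr = "row.names")
  }
  expect_equal(back$gene_universe, gen$snapshot$gene_universe)
  expect_setequal(back$phenotype_hierarchy$nodes$id,
                  gen$snapshot$phenotype_hierarchy$nodes$id)
  # byte-identical re-serialization
  write_snapshot(back, d2)
  for (f in list.files(d1)) {
    if (f == "manifest.tsv") next
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)),
                     label = f)
  }
})

test_that("the integrity report names exactly the unresolvable identifiers", {
  snap <- make_snapshot(cg = rel_edges("MESH:C000001", "GENE:1"))
  expect_equal(nrow(snap$integrity_report), 0L)
  # gene_phenotype referencing a gene outside the universe
  rel <- snap$relations
  rel$gene_phenotype <- rel_edges("GENE:404", "GO:0000404")
  flagged <- knowledge_snapshot(
    relations = rel,
    phenotype_hierarchy = snap$phenotype_hierarchy,
    disease_hierarchy = snap$disease_hierarchy,
    chemical_hierarchy = snap$chemical_hierarchy,
    gene_universe = snap$gene_universe)
  expect_setequal(flagged$integrity_report$id, c("GENE:404", "GO:0000404"))
  expect_error(
    knowledge_snapshot(
      relations = rel,
      phenotype_hierarchy = snap$phenotype_hierarchy,
      disease_hierarchy = snap$disease_hierarchy,
      chemical_hierarchy = snap$chemical_hierarchy,
      gene_universe = snap$gene_universe, strict = TRUE),
    class = "aoplink_validation_error")
})
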