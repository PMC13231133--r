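# Chemical-event intersection: per-term retrieval, the coverage matrix and
# its 1..E score, ranking, categorization, and the brute-force oracle.

test_that("per-term retrieval honors lookup, subsumption and evidence filters", {
  snap <- make_snapshot(
    cg = rel_edges(c("MESH:C000001", "MESH:C000002"), c("GENE:1", "GENE:1")),
    cp = rel_edges("MESH:C000003", "GO:0000002"),
    cd = rel_edges(c("MESH:C000004", "MESH:C000005"),
                   c("MESH:D000001", "MESH:D000001"),
                   evidence = c("therapeutic", "marker_mechanism")),
    phen_parents = data.frame(child = "GO:0000002", parent = "GO:0000001"),
    extra_phenotypes = "GO:0000001")
  expect_equal(chemicals_for_term(snap, "gene", "GENE:1"),
               c("MESH:C000001", "MESH:C000002"))
  # annotation to a child is subsumed by the parent phenotype
  expect_equal(chemicals_for_term(snap, "phenotype", "GO:0000001"), "MESH:C000003")
  expect_equal(chemicals_for_term(snap, "disease", "MESH:D000001",
                                  evidence_filter = "marker_mechanism"),
               "MESH:C000005")
  expect_equal(chemicals_for_term(snap, "disease", "MESH:D000001"),
               c("MESH:C000004", "MESH:C000005"))
  expect_error(chemicals_for_term(snap, "gene", "GENE:404"),
               class = "aoplink_lookup_error")
})

two_event_fixture <- function() {
  snap <- make_snapshot(
    cg = rel_edges("MESH:C000001", "GENE:1"),
    cp = rel_edges(c("MESH:C000001", "MESH:C000001", "MESH:C000002"),
                   c("GO:0000001", "GO:0000002", "GO:0000002")),
    extra_phenotypes = c("GO:0000001", "GO:0000002"))
  mapping <- as_event_mapping(data.frame(
    event_id = c("MIE:1", "MIE:1", "KE:2"),
    term_kind = c("gene", "phenotype", "phenotype"),
    term = c("GENE:1", "GO:0000001", "GO:0000002"),
    evidence_filter = ""))
  p <- tempfile(fileext = ".tsv")
  writeLines(c("aop_id\tevent_id\tevent_type\tevent_title\tdownstream_event_ids",
               "AOP:1\tMIE:1\tMIE\ta\tKE:2", "AOP:1\tKE:2\tKE\tb\t"), p)
  aop <- load_aop_definitions(p)
  unlink(p)
  list(snap = snap, mapping = mapping, aop = aop)
}

test_that("coverage counts each event once however many terms matched", {
  fx <- two_event_fixture()
  cov <- event_coverage(fx$snap, fx$mapping, fx$aop)
  # C1 matched MIE:1 by both a gene and a phenotype term: still one event
  expect_equal(unname(cov$score[c("MESH:C000001", "MESH:C000002")]), c(2L, 1L))
  expect_equal(cov$chemicals, c("MESH:C000001", "MESH:C000002"))
  expect_true(all(rowSums(cov$incidence) == cov$score))
  expect_error(event_coverage(fx$snap, fx$mapping[0, ], fx$aop),
               class = "aoplink_validation_error")
})

test_that("ranking applies the score-then-id tie-break and min_score boundary", {
  fx <- two_event_fixture()
  cov <- event_coverage(fx$snap, fx$mapping, fx$aop)
  r <- rank_chemicals(cov, 1L)
  expect_equal(r$chemical_id, c("MESH:C000001", "MESH:C000002"))
  expect_equal(nrow(rank_chemicals(cov, 2L)), 1L)
  expect_error(rank_chemicals(cov, 3L), class = "aoplink_validation_error")
  # ties broken by ascending chemical id
  snap <- make_snapshot(
    cp = rel_edges(c("MESH:C000009", "MESH:C000002"), c("GO:0000001", "GO:0000001")))
  cov2 <- event_coverage(snap, fx$mapping[2, , drop = FALSE], fx$aop)
  expect_equal(cov2$chemicals, c("MESH:C000002", "MESH:C000009"))
})

test_that("planted coverage tiers are recovered exactly at zero background", {
  gen <- generate_snapshot(synthetic_config(
    seed = 21, n_chemicals = 600,
    coverage_tiers = c(`6` = 12, `5` = 64, `1` = 500),
    n_planted_tetramers = 0, n_decoys = 0,
    dimer_plan = NULL, event_disease_plan = NULL))
  cov <- event_coverage(gen$snapshot, gen$mapping, gen$aop)
  man <- gen$manifest$tiers
  expect_equal(length(cov$chemicals), nrow(man))
  top <- names(cov$score)[cov$score == 6L]
  expect_setequal(top, man$chemical_id[man$score == 6L])
  expect_equal(length(top), 12L)
  expect_equal(sum(cov$score >= 5L), 76L)
  # per-chemical event incidence matches the manifest exactly
  got <- apply(cov$incidence, 1L, function(r) paste(colnames(cov$incidence)[r],
                                                    collapse = "|"))
  expect_equal(unname(got[man$chemical_id]), man$events)
})

test_that("coverage equals the per-triple brute force on random snapshots", {
  mapping <- NULL
  for (seed in 1:20) {
    snap <- random_snapshot(seed, n_chem = 12, n_gene = 5, n_phen = 6, n_dis = 4,
                            density = 0.25)
    mapping <- as_event_mapping(data.frame(
      event_id = c("MIE:1", "MIE:1", "KE:2", "KE:3", "AO:4"),
      term_kind = c("gene", "gene_pattern", "phenotype", "phenotype", "disease"),
      term = c("GENE:1", "G*", "GO:0000001", "GO:0000003", "MESH:D000001"),
      evidence_filter = c("", "", "", "", "marker_mechanism")))
    events <- c("MIE:1", "KE:2", "KE:3", "AO:4")
    aop <- aoplink:::aop_from_frames("AOP:1", data.frame(
      event_id = events, event_type = c("MIE", "KE", "KE", "AO"),
      event_title = events), data.frame(from = character(), to = character()))
    cov <- event_coverage(snap, mapping, aop)
    oracle <- brute_coverage(snap, mapping, events)
    expect_setequal(cov$chemicals, rownames(oracle))
    expect_equal(cov$incidence[order(rownames(cov$incidence)), , drop = FALSE],
                 oracle[order(rownames(oracle)), , drop = FALSE],
                 label = paste("seed", seed))
  }
})

test_that("adding a relation never decreases a score; dropping a term never raises one", {
  fx <- two_event_fixture()
  before <- event_coverage(fx$snap, fx$mapping, fx$aop)$score
  rel <- fx$snap$relations
  extra <- rel_edges("MESH:C000002", "GO:0000001")
  extra$relation_kind <- "chem_phenotype"
  rel$chem_phenotype <- rbind(rel$chem_phenotype, extra[names(rel$chem_phenotype)])
  bigger <- knowledge_snapshot(
    relations = rel, phenotype_hierarchy = fx$snap$phenotype_hierarchy,
    disease_hierarchy = fx$snap$disease_hierarchy,
    chemical_hierarchy = fx$snap$chemical_hierarchy,
    gene_universe = fx$snap$gene_universe)
  after <- event_coverage(bigger, fx$mapping, fx$aop)$score
  expect_true(all(after[names(before)] >= before))
  fewer <- event_coverage(fx$snap, fx$mapping[-2, ], fx$aop)$score
  common <- intersect(names(fewer), names(before))
  expect_true(all(fewer[common] <= before[common]))
})

test_that("chemicals join every category whose closure contains them", {
  h <- ontology_hierarchy(
    data.frame(id = c("MESH:C000001", "MESH:C000002", "MESH:C000003",
                      "MESH:C000010", "MESH:C000011"),
               name = c("root", "metals", "pollutants", "cadmium", "phthalate")),
    data.frame(child = c("MESH:C000002", "MESH:C000003", "MESH:C000010",
                         "MESH:C000010", "MESH:C000011"),
               parent = c("MESH:C000001", "MESH:C000001", "MESH:C000002",
                          "MESH:C000003", "MESH:C000003"),
               relation = "is_a"))
  groups <- categorize_chemicals(h, c("MESH:C000010", "MESH:C000011"),
                                 c("MESH:C000002", "MESH:C000003"))
  expect_equal(groups[["MESH:C000002"]], "MESH:C000010")  # cadmium under metals
  expect_setequal(groups[["MESH:C000003"]], c("MESH:C000010", "MESH:C000011"))
  expect_equal(groups$uncategorized, character())
  none <- categorize_chemicals(h, c("MESH:C000010"), character())
  expect_equal(none$uncategorized, "MESH:C000010")
  expect_error(categorize_chemicals(h, "MESH:C000010", "MESH:C000404"),
               class = "aoplink_lookup_error")
})

test_that("coverage tables reload from the chemical-by-event layout", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Chemical,MIE:1,KE:2,KE:3",
               "MESH:C000001,x,x,x",
               "MESH:C000002,x,,x",
               "MESH:C000003,,,x"), path)
  cov <- read_coverage_table(path, chemical_col = "Chemical")
  expect_equal(unname(cov$score), c(3L, 2L, 1L))
  expect_equal(nrow(rank_chemicals(cov, 3L)), 1L)
})
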