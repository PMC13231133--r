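# Per-event disease sets, exact Venn region counts, leave-one-out core
# expansion, and cross-AOP event sharing.

test_that("event disease sets union tetramer diseases over mapped terms", {
  snap <- make_snapshot(
    cg = rel_edges(c("MESH:C000001", "MESH:C000002"), c("GENE:1", "GENE:2")),
    cp = rel_edges(c("MESH:C000001", "MESH:C000002"), c("GO:0000001", "GO:0000002")),
    cd = rel_edges(c("MESH:C000001", "MESH:C000002"),
                   c("MESH:D000001", "MESH:D000002"),
                   evidence = "marker_mechanism"),
    gp = rel_edges(c("GENE:1", "GENE:2"), c("GO:0000001", "GO:0000002")),
    gd = rel_edges(c("GENE:1", "GENE:2"), c("MESH:D000001", "MESH:D000002")),
    symbols = c(`GENE:1` = "AAA1", `GENE:2` = "AAB2"))
  mapping <- as_event_mapping(data.frame(
    event_id = c("KE:1", "KE:2", "KE:2", "AO:9"),
    term_kind = c("gene", "gene", "phenotype", "disease"),
    term = c("GENE:1", "GENE:2", "GO:0000001", "MESH:D000001"),
    evidence_filter = c("", "", "", "marker_mechanism")))
  expect_equal(diseases_for_event(snap, mapping, "KE:1"), "MESH:D000001")
  # union across a gene term and a phenotype term
  expect_equal(diseases_for_event(snap, mapping, "KE:2"),
               c("MESH:D000001", "MESH:D000002"))
  # disease-only events are circular
  expect_error(diseases_for_event(snap, mapping, "AO:9"),
               class = "aoplink_validation_error")
  # gene patterns union over their expansion
  pat <- as_event_mapping(data.frame(event_id = "KE:3", term_kind = "gene_pattern",
                                     term = "AA*", evidence_filter = ""))
  expect_equal(diseases_for_event(snap, pat, "KE:3"),
               c("MESH:D000001", "MESH:D000002"))
})

test_that("event disease sets equal brute-force tetramer projection", {
  for (seed in 1:10) {
    snap <- random_snapshot(seed, density = 0.4)
    mapping <- as_event_mapping(data.frame(
      event_id = c("KE:1", "KE:1"), term_kind = c("gene", "phenotype"),
      term = c("GENE:1", "GO:0000002"), evidence_filter = ""))
    got <- diseases_for_event(snap, mapping, "KE:1")
    want <- sort(unique(c(brute_tetramers(snap, gene = "GENE:1")$disease_id,
                          brute_tetramers(snap, phenotype = "GO:0000002")$disease_id)))
    expect_equal(got, want, label = paste("seed", seed))
  }
})

test_that("venn regions enumerate exactly and conserve the union", {
  v <- venn_cells(list(A = c("1", "2"), B = c("2", "3")))
  counts <- stats::setNames(v$regions$count, v$regions$region)
  expect_equal(counts[["A"]], 1L)
  expect_equal(counts[["B"]], 1L)
  expect_equal(counts[["A&B"]], 1L)
  expect_equal(v$core, "2")

  same <- replicate(5, sprintf("MESH:D%06d", 1:17), simplify = FALSE)
  names(same) <- paste0("S", 1:5)
  v5 <- venn_cells(same)
  expect_equal(length(v5$core), 17L)
  expect_equal(sum(v5$regions$count), 17L)
  expect_equal(v5$regions$count[v5$regions$region != "S1&S2&S3&S4&S5"],
               rep(0L, 2^5 - 2))

  expect_error(venn_cells(list(A = "1")), class = "aoplink_validation_error")
  expect_error(venn_cells(stats::setNames(replicate(7, "x", simplify = FALSE),
                                          paste0("S", 1:7))),
               class = "aoplink_validation_error")

  # conservation on random 5-set instances
  for (seed in 1:100) {
    sets <- withr::with_seed(seed, stats::setNames(
      lapply(1:5, function(i) as.character(sample.int(40, sample.int(25, 1)))),
      paste0("S", 1:5)))
    v <- venn_cells(sets)
    expect_equal(sum(v$regions$count), length(unique(unlist(sets))),
                 label = paste("seed", seed))
  }
})

test_that("leave-one-out expansion obeys the core/expanded/additional algebra", {
  sets <- list(A = c("x", "y"), B = c("x"), C = c("x", "y"))
  r <- core_and_loo(sets, "B")
  expect_equal(r$core, "x")
  expect_equal(r$expanded, c("x", "y"))
  expect_equal(r$additional, "y")
  # dropping a superset of the others adds nothing
  sup <- list(A = c("x", "y", "z"), B = c("x"), C = c("x", "z"))
  expect_equal(core_and_loo(sup, "A")$additional, character())
  expect_error(core_and_loo(sets, "Z"), class = "aoplink_lookup_error")
  expect_error(core_and_loo(sets[1:2], "A"), class = "aoplink_validation_error")
  # algebra holds on random instances
  for (seed in 1:100) {
    sets <- withr::with_seed(seed, stats::setNames(
      lapply(1:5, function(i) as.character(sample.int(30, sample.int(20, 1)))),
      paste0("S", 1:5)))
    r <- core_and_loo(sets, "S3")
    expect_true(all(r$core %in% r$expanded))
    expect_equal(length(r$additional), length(r$expanded) - length(r$core))
    expect_equal(intersect(r$additional, r$core), character())
  }
})

test_that("a constructed 17-core fixture yields 108 additional diseases", {
  sets <- synthetic_event_disease_sets(
    sizes = c(`MIE:112` = 149, `KE:2207` = 619, `KE:195` = 55,
              `KE:2208` = 471, `KE:386` = 842),
    core_size = 17, loo_extra = 108, loo_label = "KE:195")
  expect_equal(lengths(sets),
               c(`MIE:112` = 149L, `KE:2207` = 619L, `KE:195` = 55L,
                 `KE:2208` = 471L, `KE:386` = 842L))
  v <- venn_cells(sets)
  expect_equal(length(v$core), 17L)
  r <- core_and_loo(sets, "KE:195")
  expect_equal(length(r$expanded), 125L)
  expect_equal(length(r$additional), 108L)
  expect_error(synthetic_event_disease_sets(c(A = 5, B = 5, C = 5), 10, 0, "A"),
               class = "aoplink_validation_error")
})

test_that("related AOPs list every pathway containing a queried event", {
  other <- load_aop_definitions(system.file("extdata", "related_aops_fixture.tsv",
                                            package = "aoplink"))
  r <- related_aops(other, "MIE:112")
  expect_equal(r[order(r$aop_id), c("event_id", "aop_id", "ao_event_id")],
               data.frame(event_id = "MIE:112", aop_id = c("AOP:443", "AOP:595"),
                          ao_event_id = c("AO:1982", "AO:520")),
               ignore_attr = "row.names")
  # events in no pathway yield no rows
  expect_equal(nrow(related_aops(other, "KE:404")), 0L)
  # reflexivity: each event of one AOP returns that AOP
  aop <- autism_aop()
  self <- related_aops(aop, aop$aops[[1]]$events$event_id)
  expect_true(all(self$aop_id == "AOP:522"))
  expect_equal(unique(self$event_id), aop$aops[[1]]$events$event_id)
  # and the pathway under study can be excluded
  expect_equal(nrow(related_aops(aop, "MIE:112", exclude_aop = "AOP:522")), 0L)
})
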