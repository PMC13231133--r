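# Tetramer enumeration under the five-edge constraint, evidence scoring,
# dimer projection/intersection, chord export, and the quadruple-loop oracle.

full_block <- function(drop = NULL) {
  edges <- list(
    cg = rel_edges("MESH:C000001", "GENE:1", articles = list("A1")),
    cp = rel_edges("MESH:C000001", "GO:0000001", articles = list("A2")),
    cd = rel_edges("MESH:C000001", "MESH:D000001", evidence = "marker_mechanism",
                   articles = list("A3")),
    gp = rel_edges("GENE:1", "GO:0000001", articles = list("A4")),
    gd = rel_edges("GENE:1", "MESH:D000001", articles = list("A5")))
  if (!is.null(drop)) edges[[drop]] <- NULL
  make_snapshot(cg = edges$cg, cp = edges$cp, cd = edges$cd,
                gp = edges$gp, gd = edges$gd,
                extra_phenotypes = "GO:0000001", extra_diseases = "MESH:D000001",
                extra_genes = "GENE:1")
}

test_that("a planted five-edge block yields exactly one tetramer", {
  t <- enumerate_tetramers(full_block(), chemical = "MESH:C000001")
  expect_equal(nrow(t), 1L)
  expect_equal(tetramer_tuples(t),
               data.frame(chemical_id = "MESH:C000001", gene_id = "GENE:1",
                          phenotype_id = "GO:0000001", disease_id = "MESH:D000001"))
  expect_equal(t$evidence_score, 5)  # five disjoint single-article edges
})

test_that("removing any one of the five edges suppresses the tetramer", {
  for (drop in c("cg", "cp", "cd", "gp", "gd")) {
    t <- enumerate_tetramers(full_block(drop = drop), chemical = "MESH:C000001")
    expect_equal(nrow(t), 0L, label = paste("missing", drop))
  }
})

test_that("the chemical-disease edge requires the configured evidence class", {
  snap <- full_block()
  snap$relations$chem_disease$direct_evidence <- "therapeutic"
  expect_equal(nrow(enumerate_tetramers(snap, chemical = "MESH:C000001")), 0L)
  expect_equal(nrow(enumerate_tetramers(snap, chemical = "MESH:C000001",
                                        chem_disease_evidence = NULL)), 1L)
})

test_that("querying a parent disease retrieves descendant tetramers (and supersets)", {
  snap <- make_snapshot(
    cg = rel_edges("MESH:C000001", "GENE:1"),
    cp = rel_edges("MESH:C000001", "GO:0000001"),
    cd = rel_edges("MESH:C000001", "MESH:D000002", evidence = "marker_mechanism"),
    gp = rel_edges("GENE:1", "GO:0000001"),
    gd = rel_edges("GENE:1", "MESH:D000002"),
    dis_parents = data.frame(child = "MESH:D000002", parent = "MESH:D000001"),
    extra_diseases = "MESH:D000001")
  parent_q <- enumerate_tetramers(snap, disease = "MESH:D000001")
  child_q <- enumerate_tetramers(snap, disease = "MESH:D000002")
  expect_equal(nrow(parent_q), 1L)
  expect_equal(tetramer_tuples(parent_q), tetramer_tuples(child_q))
  expect_error(enumerate_tetramers(snap), class = "aoplink_validation_error")
  expect_error(enumerate_tetramers(snap, gene = "GENE:404"),
               class = "aoplink_lookup_error")
})

test_that("enumeration equals the quadruple-loop oracle on random snapshots", {
  for (seed in 1:100) {
    snap <- random_snapshot(seed)
    got <- tetramer_tuples(enumerate_tetramers(snap, chemical = unique(
      c(snap$relations$chem_gene$subject_id, snap$relations$chem_phenotype$subject_id,
        snap$relations$chem_disease$subject_id))))
    expect_equal(got, brute_tetramers(snap), label = paste("seed", seed))
  }
})

test_that("slot queries agree with the oracle and fixing slots never enlarges results", {
  snap <- random_snapshot(3, density = 0.45)
  all_t <- enumerate_tetramers(snap, disease = "MESH:D000001")
  expect_equal(tetramer_tuples(all_t),
               brute_tetramers(snap, disease = "MESH:D000001"))
  if (nrow(all_t)) {
    one <- all_t[1, ]
    narrowed <- enumerate_tetramers(snap, disease = "MESH:D000001",
                                    chemical = one$chemical_id)
    expect_lte(nrow(narrowed), nrow(all_t))
    narrower <- enumerate_tetramers(snap, disease = "MESH:D000001",
                                    chemical = one$chemical_id,
                                    gene = one$gene_id,
                                    phenotype = one$phenotype_id)
    expect_lte(nrow(narrower), nrow(narrowed))
    expect_gte(nrow(narrower), 1L)
  }
})

test_that("evidence score is the distinct-article union and is monotone", {
  snap <- full_block()
  # all five edges citing one article collapse to score 1
  snap$relations <- lapply(snap$relations, function(r) {
    if (nrow(r)) r$support_articles <- rep(list("A1"), nrow(r))
    r
  })
  t <- enumerate_tetramers(snap, chemical = "MESH:C000001")
  expect_equal(t$evidence_score, 1)
  # adding an article to any edge never decreases the score
  for (seed in 1:20) {
    sets <- withr::with_seed(seed, lapply(1:5, function(i)
      sprintf("A%d", sample.int(20, sample.int(4, 1)))))
    base <- length(unique(unlist(sets)))
    grow <- withr::with_seed(seed + 99, {
      j <- sample.int(5, 1)
      sets[[j]] <- c(sets[[j]], sprintf("A%d", sample.int(40, 1)))
      sets
    })
    expect_gte(length(unique(unlist(grow))), base)
  }
})

test_that("dimer projection distinctness and the pigeonhole bound", {
  t3 <- data.frame(chemical_id = c("C1", "C2", "C3"),
                   gene_id = "GENE:1", phenotype_id = "GO:0000001")
  expect_equal(nrow(dimer_projection(t3)), 1L)
  expect_equal(nrow(dimer_projection(t3[0, ])), 0L)
  for (seed in 1:10) {
    snap <- random_snapshot(seed)
    t <- enumerate_tetramers(snap, disease = "MESH:D000001")
    expect_lte(nrow(dimer_projection(t)), max(nrow(t), 0L))
  }
})

test_that("shared dimers are the naive intersection of projections", {
  a <- data.frame(gene_id = c("G1", "G2"), phenotype_id = c("P1", "P1"))
  b <- data.frame(gene_id = "G1", phenotype_id = "P1")
  sh <- shared_dimers(list(a, b))
  expect_equal(sh$dimers, data.frame(gene_id = "G1", phenotype_id = "P1"))
  expect_equal(sh$gene_tally$id, "G1")
  # idempotence: intersecting a set with itself returns its projection
  self <- shared_dimers(list(a, a))
  expect_equal(self$dimers, dimer_projection(a))
  expect_error(shared_dimers(list(a)), class = "aoplink_validation_error")
  # oracle identity on random inputs
  for (seed in 1:10) {
    snaps <- lapply(seed + 0:2, random_snapshot, n_chem = 5)
    sets <- lapply(snaps, function(s) enumerate_tetramers(s, disease = "MESH:D000001"))
    got <- shared_dimers(sets)$dimers
    proj <- lapply(sets, function(s) {
      p <- dimer_projection(s); paste(p$gene_id, p$phenotype_id, sep = "|")
    })
    want <- sort(Reduce(intersect, proj))
    expect_equal(paste(got$gene_id, got$phenotype_id, sep = "|"), want,
                 label = paste("seed", seed))
  }
})

test_that("chord ribbons count tetramer co-occurrence symmetrically", {
  one <- enumerate_tetramers(full_block(), chemical = "MESH:C000001")
  ch <- chord_data(one)
  expect_equal(nrow(ch$nodes), 4L)
  expect_equal(nrow(ch$links), 6L)   # all pairwise ribbons
  expect_true(all(ch$links$weight == 1L))
  # two tetramers sharing only the chemical: cross ribbons stay at weight 1
  two <- data.frame(chemical_id = "C1", gene_id = c("G1", "G2"),
                    phenotype_id = c("P1", "P2"), disease_id = c("D1", "D2"))
  ch2 <- chord_data(two)
  expect_equal(sum(ch2$links$from == "C1" | ch2$links$to == "C1"), 6L)
  expect_true(all(ch2$links$weight == 1L))
  # combinatorial identity: total ribbon weight = 6 pairs per tetramer
  for (seed in 1:10) {
    snap <- random_snapshot(seed)
    t <- enumerate_tetramers(snap, disease = "MESH:D000001")
    if (!nrow(t)) next
    expect_equal(sum(chord_data(t)$links$weight), 6L * nrow(t))
  }
  expect_error(chord_data(one[0, ]), class = "aoplink_validation_error")
})

test_that("planted decoys are never emitted and planted tetramers always are", {
  gen <- generate_snapshot(synthetic_config(
    seed = 13, n_chemicals = 20, coverage_tiers = c(`2` = 3),
    n_planted_tetramers = 50, n_decoys = 50,
    dimer_plan = NULL, event_disease_plan = NULL))
  man <- gen$manifest
  all_t <- enumerate_tetramers(gen$snapshot,
                               chemical = unique(c(man$tetramers$chemical_id,
                                                   man$decoys$chemical_id)))
  expect_equal(tetramer_tuples(all_t), man$tetramers)
  # per-decoy: exactly one of the five required relations is absent
  rel <- gen$snapshot$relations
  has <- function(kind, s, o) any(rel[[kind]]$subject_id == s & rel[[kind]]$object_id == o)
  for (i in seq_len(nrow(man$decoys))) {
    d <- man$decoys[i, ]
    present <- c(
      chem_gene = has("chem_gene", d$chemical_id, d$gene_id),
      chem_phenotype = has("chem_phenotype", d$chemical_id, d$phenotype_id),
      chem_disease = has("chem_disease", d$chemical_id, d$disease_id),
      gene_phenotype = has("gene_phenotype", d$gene_id, d$phenotype_id),
      gene_disease = has("gene_disease", d$gene_id, d$disease_id))
    expect_equal(names(which(!present)), d$missing_edge)
  }
})
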