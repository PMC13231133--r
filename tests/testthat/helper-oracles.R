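# Shared fixtures and independent oracles. The oracles deliberately use
# naive algorithms (breadth-first reachability, quadruple loops, per-triple
# brute force) so they stay independent of the indexed implementations they
# cross-check.

rel_edges <- function(subject, object, evidence = NA_character_, articles = NULL) {
  df <- data.frame(subject_id = subject, object_id = object,
                   direct_evidence = rep_len(evidence, length(subject)),
                   organism_id = NA_character_, stringsAsFactors = FALSE)
  df$support_articles <- if (is.null(articles)) {
    rep(list(character()), nrow(df))
  } else articles
  df
}

# assemble a snapshot from bare edge frames; hierarchies contain every
# referenced id plus any declared parent links (child, parent)
make_snapshot <- function(cg = NULL, cp = NULL, cd = NULL, gp = NULL, gd = NULL,
                          phen_parents = NULL, dis_parents = NULL,
                          chem_parents = NULL, symbols = NULL,
                          extra_phenotypes = character(),
                          extra_diseases = character(),
                          extra_genes = character()) {
  rels <- list(chem_gene = cg, chem_phenotype = cp, chem_disease = cd,
               gene_phenotype = gp, gene_disease = gd)
  col <- function(kinds, side) {
    unique(unlist(lapply(rels[kinds], function(r) if (is.null(r)) NULL else r[[side]])))
  }
  hier <- function(ids, links) {
    ids <- unique(c(ids, if (!is.null(links)) c(links$child, links$parent)))
    if (!length(ids)) ids <- "ROOT:0"
    ontology_hierarchy(
      data.frame(id = ids, name = ids),
      if (is.null(links)) data.frame(child = character(), parent = character(),
                                     relation = character())
      else data.frame(child = links$child, parent = links$parent, relation = "is_a")
    )
  }
  genes <- unique(c(col("chem_gene", "object_id"),
                    col(c("gene_phenotype", "gene_disease"), "subject_id"),
                    extra_genes))
  uni <- data.frame(gene_id = genes,
                    gene_symbol = if (is.null(symbols)) sub("GENE:", "G", genes)
                    else unname(symbols[genes]),
                    stringsAsFactors = FALSE)
  knowledge_snapshot(
    relations = Filter(Negate(is.null), rels),
    phenotype_hierarchy = hier(c(col(c("chem_phenotype", "gene_phenotype"), "object_id"),
                                 extra_phenotypes), phen_parents),
    disease_hierarchy = hier(c(col(c("chem_disease", "gene_disease"), "object_id"),
                               extra_diseases), dis_parents),
    chemical_hierarchy = hier(col(c("chem_gene", "chem_phenotype", "chem_disease"),
                                  "subject_id"), chem_parents),
    gene_universe = uni
  )
}

# naive breadth-first reachability over child links (descendants incl. self)
naive_closure <- function(parents_df, term) {
  seen <- term
  repeat {
    nxt <- setdiff(parents_df$child[parents_df$parent %in% seen], seen)
    if (!length(nxt)) break
    seen <- c(seen, nxt)
  }
  sort(seen)
}

# quadruple-loop tetramer oracle: test every (C, G, P, D) against the five
# required edges, honoring evidence classes and disease-closure expansion
brute_tetramers <- function(snapshot, chemical = NULL, gene = NULL,
                            phenotype = NULL, disease = NULL,
                            chem_disease_evidence = "marker_mechanism") {
  rel <- snapshot$relations
  has <- function(r, s, o, ev = NULL) {
    hit <- r$subject_id == s & r$object_id == o
    if (!is.null(ev)) hit <- hit & !is.na(r$direct_evidence) & r$direct_evidence == ev
    any(hit)
  }
  chems <- unique(c(rel$chem_gene$subject_id, rel$chem_phenotype$subject_id,
                    rel$chem_disease$subject_id))
  genes <- snapshot$gene_universe$gene_id
  phens <- snapshot$phenotype_hierarchy$nodes$id
  dis <- snapshot$disease_hierarchy$nodes$id
  if (!is.null(chemical)) chems <- intersect(chems, chemical)
  if (!is.null(gene)) genes <- intersect(genes, gene)
  if (!is.null(phenotype)) phens <- intersect(phens, phenotype)
  if (!is.null(disease)) {
    dis <- intersect(dis, unique(unlist(
      lapply(disease, function(d) naive_closure(snapshot$disease_hierarchy$parents, d)))))
  }
  out <- list()
  for (C in chems) for (G in genes) for (P in phens) for (D in dis) {
    if (has(rel$chem_gene, C, G) && has(rel$chem_phenotype, C, P) &&
        has(rel$chem_disease, C, D, chem_disease_evidence) &&
        has(rel$gene_phenotype, G, P) && has(rel$gene_disease, G, D)) {
      out[[length(out) + 1L]] <- data.frame(chemical_id = C, gene_id = G,
                                            phenotype_id = P, disease_id = D)
    }
  }
  if (!length(out)) {
    return(data.frame(chemical_id = character(), gene_id = character(),
                      phenotype_id = character(), disease_id = character()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chemical_id, res$gene_id, res$phenotype_id, res$disease_id), ]
  rownames(res) <- NULL
  res
}

tetramer_tuples <- function(ts) {
  df <- as.data.frame(ts)[, c("chemical_id", "gene_id", "phenotype_id", "disease_id")]
  rownames(df) <- NULL
  df
}

# per-triple brute-force coverage oracle: test every (chemical, event, term)
# independently
brute_coverage <- function(snapshot, mapping, events) {
  rel <- snapshot$relations
  chems <- unique(c(rel$chem_gene$subject_id, rel$chem_phenotype$subject_id,
                    rel$chem_disease$subject_id))
  hit <- function(C, i) {
    kind <- mapping$term_kind[i]; term <- mapping$term[i]
    if (kind == "gene") {
      any(rel$chem_gene$subject_id == C & rel$chem_gene$object_id == term)
    } else if (kind == "gene_pattern") {
      genes <- expand_gene_pattern(term, snapshot$gene_universe)
      any(rel$chem_gene$subject_id == C & rel$chem_gene$object_id %in% genes)
    } else if (kind == "phenotype") {
      cl <- naive_closure(snapshot$phenotype_hierarchy$parents, term)
      any(rel$chem_phenotype$subject_id == C & rel$chem_phenotype$object_id %in% cl)
    } else {
      cl <- naive_closure(snapshot$disease_hierarchy$parents, term)
      ok <- rel$chem_disease$subject_id == C & rel$chem_disease$object_id %in% cl
      ev <- mapping$evidence_filter[i]
      if (!is.na(ev)) {
        ok <- ok & !is.na(rel$chem_disease$direct_evidence) &
          rel$chem_disease$direct_evidence == ev
      }
      any(ok)
    }
  }
  inc <- sapply(events, function(ev) {
    rows <- which(mapping$event_id == ev)
    vapply(chems, function(C) any(vapply(rows, function(i) hit(C, i), logical(1))),
           logical(1))
  })
  if (length(chems) == 1L) inc <- matrix(inc, nrow = 1L, dimnames = list(chems, events))
  rownames(inc) <- chems
  inc[rowSums(inc) > 0L, , drop = FALSE]
}

# random rooted DAG with edges pointing child -> earlier parent (acyclic by
# construction), for the closure-vs-BFS oracle
random_dag <- function(seed, n_max = 200) {
  withr::with_seed(seed, {
    n <- sample(2:n_max, 1)
    ids <- sprintf("N%03d", seq_len(n))
    parents <- do.call(rbind, lapply(2:n, function(i) {
      k <- sample(0:min(2, i - 1), 1)
      if (!k) return(NULL)
      data.frame(child = ids[i], parent = ids[sample.int(i - 1, k)])
    }))
    if (is.null(parents)) parents <- data.frame(child = character(),
                                                parent = character())
    list(ids = ids,
         h = ontology_hierarchy(data.frame(id = ids, name = ids),
                                data.frame(child = parents$child,
                                           parent = parents$parent,
                                           relation = rep("is_a", nrow(parents)))),
         parents = parents)
  })
}

# random relation snapshot over small entity pools (tetramer/coverage oracles)
random_snapshot <- function(seed, n_chem = 8, n_gene = 6, n_phen = 6, n_dis = 4,
                            density = 0.35) {
  withr::with_seed(seed, {
    chems <- sprintf("MESH:C%06d", seq_len(n_chem))
    genes <- sprintf("GENE:%d", seq_len(n_gene))
    phens <- sprintf("GO:%07d", seq_len(n_phen))
    dis <- sprintf("MESH:D%06d", seq_len(n_dis))
    pick <- function(a, b, ev = FALSE) {
      grid <- expand.grid(s = a, o = b, stringsAsFactors = FALSE)
      keep <- runif(nrow(grid)) < density
      g <- grid[keep, , drop = FALSE]
      if (!nrow(g)) return(NULL)
      rel_edges(g$s, g$o,
                evidence = if (ev) sample(c("marker_mechanism", "therapeutic"),
                                          nrow(g), replace = TRUE)
                else NA_character_,
                articles = lapply(seq_len(nrow(g)),
                                  function(i) sprintf("A%d", sample.int(50, sample.int(3, 1)))))
    }
    # random parent chains so closure expansion is exercised
    chain_links <- function(ids) {
      if (length(ids) < 2) return(NULL)
      data.frame(child = ids[-1],
                 parent = vapply(seq_along(ids[-1]),
                                 function(i) ids[sample.int(i, 1)], character(1)))
    }
    make_snapshot(cg = pick(chems, genes), cp = pick(chems, phens),
                  cd = pick(chems, dis, ev = TRUE), gp = pick(genes, phens),
                  gd = pick(genes, dis),
                  phen_parents = chain_links(phens),
                  dis_parents = chain_links(dis),
                  extra_phenotypes = phens, extra_diseases = dis,
                  extra_genes = genes)
  })
}
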