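# CGPD-tetramer enumeration under the five-curated-edge constraint, evidence
# scoring, gene-phenotype dimer projection/intersection, and chord-diagram
# data export.
#
# A tetramer (C, G, P, D) exists iff all five directly curated relations
# exist in the snapshot: C-G, C-P, C-D, G-P, G-D. Enumeration works by
# indexed joins over the relation tables (never a materialized
# cross-product); the brute-force quadruple loop exists only as a test
# oracle.

#' Enumerate CGPD-tetramers matching a query
#'
#' Any non-empty subset of the four slots may be fixed; the disease slot is
#' expanded by descendant closure over the disease hierarchy (querying a
#' parent disease also retrieves tetramers for its descendants). By default
#' the chemical-disease edge must carry `marker_mechanism` direct evidence
#' (consistent with adverse-outcome retrieval) while the gene-disease edge
#' may carry any; both are configurable. Duplicate tetramers arising from
#' overlapping closure expansion are deduplicated on the full 4-tuple.
#'
#' @param snapshot A `knowledge_snapshot`.
#' @param chemical,gene,phenotype,disease Optional canonical ids fixing the
#'   corresponding slot (each may be a vector; `disease` is
#'   closure-expanded).
#' @param chem_disease_evidence Direct-evidence class required on the C-D
#'   edge (`"marker_mechanism"` by default; `NULL` accepts any).
#' @param gene_disease_evidence Direct-evidence class required on the G-D
#'   edge (`NULL`, the default, accepts any).
#' @return Object of class `tetramer_set`: data frame with columns
#'   `chemical_id`, `gene_id`, `phenotype_id`, `disease_id`, five
#'   list-columns `support_cg` .. `support_gd` holding the per-edge article
#'   sets, and `evidence_score`.
#' @export
enumerate_tetramers <- function(snapshot, chemical = NULL, gene = NULL,
                                phenotype = NULL, disease = NULL,
                                chem_disease_evidence = "marker_mechanism",
                                gene_disease_evidence = NULL) {
  if (is.null(chemical) && is.null(gene) && is.null(phenotype) && is.null(disease)) {
    stop_validation("tetramer query must fix at least one of the four slots")
  }
  check_known <- function(ids, pool, what) {
    unknown <- setdiff(ids, pool)
    if (length(unknown)) stop_lookup("unknown ", what, ": ",
                                     paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (!is.null(chemical)) {
    pool <- unique(c(snapshot$chemical_hierarchy$nodes$id,
                     snapshot$relations$chem_gene$subject_id,
                     snapshot$relations$chem_phenotype$subject_id,
                     snapshot$relations$chem_disease$subject_id))
    check_known(chemical, pool, "chemical")
  }
  if (!is.null(gene)) check_known(gene, snapshot$gene_universe$gene_id, "gene")
  if (!is.null(phenotype)) check_known(phenotype, snapshot$phenotype_hierarchy$nodes$id, "phenotype")
  disease_set <- NULL
  if (!is.null(disease)) {
    check_known(disease, snapshot$disease_hierarchy$nodes$id, "disease")
    disease_set <- unique(unlist(lapply(disease, descendant_closure,
                                        hierarchy = snapshot$disease_hierarchy)))
  }

  rel <- snapshot$relations
  filt_ev <- function(r, klass) {
    if (is.null(klass)) r else r[!is.na(r$direct_evidence) & r$direct_evidence == klass, , drop = FALSE]
  }
  cg <- rel$chem_gene
  cp <- rel$chem_phenotype
  cd <- filt_ev(rel$chem_disease, chem_disease_evidence)
  gp <- rel$gene_phenotype
  gd <- filt_ev(rel$gene_disease, gene_disease_evidence)

  if (!is.null(chemical)) {
    cg <- cg[cg$subject_id %in% chemical, , drop = FALSE]
    cp <- cp[cp$subject_id %in% chemical, , drop = FALSE]
    cd <- cd[cd$subject_id %in% chemical, , drop = FALSE]
  }
  if (!is.null(gene)) {
    cg <- cg[cg$object_id %in% gene, , drop = FALSE]
    gp <- gp[gp$subject_id %in% gene, , drop = FALSE]
    gd <- gd[gd$subject_id %in% gene, , drop = FALSE]
  }
  if (!is.null(phenotype)) {
    cp <- cp[cp$object_id %in% phenotype, , drop = FALSE]
    gp <- gp[gp$object_id %in% phenotype, , drop = FALSE]
  }
  if (!is.null(disease_set)) {
    cd <- cd[cd$object_id %in% disease_set, , drop = FALSE]
    gd <- gd[gd$object_id %in% disease_set, , drop = FALSE]
  }

  empty <- function() {
    out <- data.frame(chemical_id = character(), gene_id = character(),
                      phenotype_id = character(), disease_id = character(),
                      stringsAsFactors = FALSE)
    for (s in c("support_cg", "support_cp", "support_cd", "support_gp", "support_gd")) {
      out[[s]] <- list()
    }
    out$evidence_score <- numeric()
    class(out) <- c("tetramer_set", "data.frame")
    out
  }
  if (!nrow(cg) || !nrow(cp) || !nrow(cd) || !nrow(gp) || !nrow(gd)) return(empty())

  # indexed joins: (C,G) x (G,P) restricted to existing (C,P), then x (G,D)
  # restricted to existing (C,D)
  cgp <- merge(data.frame(chemical_id = cg$subject_id, gene_id = cg$object_id),
               data.frame(gene_id = gp$subject_id, phenotype_id = gp$object_id),
               by = "gene_id")
  cp_key <- unique(paste(cp$subject_id, cp$object_id))
  cgp <- cgp[paste(cgp$chemical_id, cgp$phenotype_id) %in% cp_key, , drop = FALSE]
  if (!nrow(cgp)) return(empty())
  full <- merge(cgp,
                data.frame(gene_id = gd$subject_id, disease_id = gd$object_id),
                by = "gene_id")
  cd_key <- unique(paste(cd$subject_id, cd$object_id))
  full <- full[paste(full$chemical_id, full$disease_id) %in% cd_key, , drop = FALSE]
  if (!nrow(full)) return(empty())
  full <- full[, c("chemical_id", "gene_id", "phenotype_id", "disease_id")]
  full <- unique(full)
  full <- full[order(full$chemical_id, full$gene_id, full$phenotype_id, full$disease_id), ,
               drop = FALSE]
  rownames(full) <- NULL

  support_for <- function(r, s, o) {
    key <- paste(r$subject_id, r$object_id)
    grp <- split(r$support_articles, key)
    pooled <- lapply(grp, function(lst) sort(unique(unlist(lst, use.names = FALSE))))
    got <- pooled[paste(s, o)]
    lapply(got, function(v) if (is.null(v)) character() else v)
  }
  full$support_cg <- support_for(cg, full$chemical_id, full$gene_id)
  full$support_cp <- support_for(cp, full$chemical_id, full$phenotype_id)
  full$support_cd <- support_for(cd, full$chemical_id, full$disease_id)
  full$support_gp <- support_for(gp, full$gene_id, full$phenotype_id)
  full$support_gd <- support_for(gd, full$gene_id, full$disease_id)
  class(full) <- c("tetramer_set", "data.frame")
  full$evidence_score <- evidence_score(full)
  full
}

#' @export
print.tetramer_set <- function(x, ...) {
  cat("<tetramer_set> ", nrow(x), " tetramers over ",
      length(unique(x$chemical_id)), " chemicals, ",
      length(unique(x$gene_id)), " genes, ",
      length(unique(x$phenotype_id)), " phenotypes, ",
      length(unique(x$disease_id)), " diseases\n", sep = "")
  invisible(x)
}

#' Evidence-strength score of tetramers
#'
#' The default strategy counts the distinct articles across the union of the
#' five per-edge support sets — the number of underlying publications from
#' which the constituent curated statements derive. It is strictly monotone
#' non-decreasing in each support set. Alternative weightings can be passed
#' as `strategy`.
#'
#' @param tetramers A `tetramer_set` (support columns populated).
#' @param strategy Function taking a list of five character vectors (the
#'   per-edge article sets of one tetramer) and returning one number.
#' @return Numeric vector, one score per tetramer.
#' @export
evidence_score <- function(tetramers,
                           strategy = function(sets) length(unique(unlist(sets)))) {
  if (nrow(tetramers) == 0L) return(numeric())
  vapply(seq_len(nrow(tetramers)), function(i) {
    strategy(list(tetramers$support_cg[[i]], tetramers$support_cp[[i]],
                  tetramers$support_cd[[i]], tetramers$support_gp[[i]],
                  tetramers$support_gd[[i]]))
  }, numeric(1))
}

#' Gene-phenotype dimer projection
#'
#' @param tetramers A `tetramer_set` or any data frame with `gene_id` and
#'   `phenotype_id` columns.
#' @return Data frame of distinct `(gene_id, phenotype_id)` pairs, sorted.
#' @export
dimer_projection <- function(tetramers) {
  if (nrow(tetramers) == 0L) {
    return(data.frame(gene_id = character(), phenotype_id = character(),
                      stringsAsFactors = FALSE))
  }
  out <- unique(data.frame(gene_id = tetramers$gene_id,
                           phenotype_id = tetramers$phenotype_id,
                           stringsAsFactors = FALSE))
  out <- out[order(out$gene_id, out$phenotype_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-phenotype dimers shared across tetramer sets
#'
#' Intersects the dimer projections of two or more tetramer sets (e.g. the
#' outputs of independent chemical-disease queries) and tallies, per gene
#' and per phenotype, how many shared dimers contain it.
#'
#' @param tetramer_sets List of two or more `tetramer_set`s (or dimer data
#'   frames).
#' @return List with `dimers` (shared pairs, sorted), `gene_tally` and
#'   `phenotype_tally` (data frames `id`, `n_dimers`, descending).
#' @export
shared_dimers <- function(tetramer_sets) {
  if (!is.list(tetramer_sets) || length(tetramer_sets) < 2L) {
    stop_validation("shared_dimers needs at least two tetramer sets")
  }
  projections <- lapply(tetramer_sets, dimer_projection)
  keys <- lapply(projections, function(p) paste(p$gene_id, p$phenotype_id, sep = "\r"))
  shared_key <- Reduce(intersect, keys)
  parts <- strsplit(sort(shared_key), "\r", fixed = TRUE)
  dimers <- data.frame(
    gene_id = vapply(parts, `[`, character(1), 1L),
    phenotype_id = vapply(parts, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  tally <- function(ids) {
    if (!length(ids)) return(data.frame(id = character(), n_dimers = integer()))
    tb <- sort(table(ids), decreasing = TRUE)
    data.frame(id = names(tb), n_dimers = as.integer(tb), stringsAsFactors = FALSE)
  }
  list(dimers = dimers,
       gene_tally = tally(dimers$gene_id),
       phenotype_tally = tally(dimers$phenotype_id))
}

#' Restrict a tetramer set to a dimer set
#'
#' Keeps the tetramers whose (gene, phenotype) pair appears in `dimers` —
#' the subset visualized in chord form and fed into candidate-pathway
#' construction.
#'
#' @param tetramers A `tetramer_set`.
#' @param dimers Data frame with `gene_id`, `phenotype_id`.
#' @return The restricted `tetramer_set`.
#' @export
restrict_to_dimers <- function(tetramers, dimers) {
  key <- paste(dimers$gene_id, dimers$phenotype_id, sep = "\r")
  keep <- paste(tetramers$gene_id, tetramers$phenotype_id, sep = "\r") %in% key
  out <- tetramers[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chord-diagram data for a tetramer set
#'
#' Partitions the identifiers of a tetramer set into the four roles
#' (chemical, gene, phenotype, disease) and computes ribbon weights: the
#' weight between two nodes is the number of tetramers containing both
#' (symmetric by construction). Every tetramer contributes its six unordered
#' node pairs.
#'
#' @param tetramers A non-empty `tetramer_set`.
#' @return Object of class `chord_data`: list with `nodes` (`id`, `role`)
#'   and `links` (`from`, `to`, `weight`; `from < to` lexicographically).
#' @export
chord_data <- function(tetramers) {
  if (nrow(tetramers) == 0L) stop_validation("chord_data needs a non-empty tetramer set")
  nodes <- rbind(
    data.frame(id = unique(tetramers$chemical_id), role = "chemical"),
    data.frame(id = unique(tetramers$gene_id), role = "gene"),
    data.frame(id = unique(tetramers$phenotype_id), role = "phenotype"),
    data.frame(id = unique(tetramers$disease_id), role = "disease")
  )
  nodes <- nodes[order(nodes$role, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  slots <- c("chemical_id", "gene_id", "phenotype_id", "disease_id")
  combos <- utils::combn(slots, 2L)
  pair_list <- lapply(seq_len(ncol(combos)), function(j) {
    a <- tetramers[[combos[1L, j]]]
    b <- tetramers[[combos[2L, j]]]
    swap <- a > b
    data.frame(from = ifelse(swap, b, a), to = ifelse(swap, a, b),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pair_list)
  key <- paste(pairs$from, pairs$to, sep = "\r")
  tb <- table(key)
  parts <- strsplit(names(tb), "\r", fixed = TRUE)
  links <- data.frame(
    from = vapply(parts, `[`, character(1), 1L),
    to = vapply(parts, `[`, character(1), 2L),
    weight = as.integer(tb),
    stringsAsFactors = FALSE
  )
  links <- links[order(links$from, links$to), , drop = FALSE]
  rownames(links) <- NULL
  structure(list(nodes = nodes, links = links), class = "chord_data")
}

#' @export
print.chord_data <- function(x, ...) {
  cat("<chord_data> ", nrow(x$nodes), " nodes (",
      paste(names(table(x$nodes$role)), as.integer(table(x$nodes$role)),
            sep = ":", collapse = ", "),
      "), ", nrow(x$links), " ribbons\n", sep = "")
  invisible(x)
}

#' Write chord data as a structured text file
#'
#' Two TSV sections separated by `# nodes` / `# links` markers, consumable
#' by external plotting code.
#' @param chord A `chord_data` object.
#' @param path Output path.
#' @export
write_chord <- function(chord, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("# nodes", con)
  utils::write.table(chord$nodes, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("# links", con)
  utils::write.table(chord$links, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tetramer set as CSV
#'
#' Matches the export dialect read by [load_tetramer_export()], with the
#' per-edge support article sets pipe-joined in extra columns and the
#' evidence score last.
#' @param tetramers A `tetramer_set`.
#' @param path Output path.
#' @export
write_tetramers <- function(tetramers, path) {
  flat <- data.frame(
    chemical_id = tetramers$chemical_id, gene_id = tetramers$gene_id,
    phenotype_id = tetramers$phenotype_id, disease_id = tetramers$disease_id,
    support_cg = join_multi(tetramers$support_cg),
    support_cp = join_multi(tetramers$support_cp),
    support_cd = join_multi(tetramers$support_cd),
    support_gp = join_multi(tetramers$support_gp),
    support_gd = join_multi(tetramers$support_gd),
    evidence_score = tetramers$evidence_score,
    stringsAsFactors = FALSE
  )
  utils::write.csv(flat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
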