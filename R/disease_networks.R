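# Disease-network discovery: per-event tetramer-derived disease sets, exact
# k-way intersection (Venn/UpSet) region counts, leave-one-out core
# expansion, and a constructor for synthetic disease-set fixtures with a
# prescribed intersection structure.

#' Tetramer-derived diseases for one mapped event
#'
#' Unions, over the event's mapped gene / gene-pattern / phenotype terms,
#' the distinct diseases of the tetramers retrieved with that term fixed
#' (gene slot for genes and expanded patterns, phenotype slot for
#' phenotypes). An event mapped only to disease terms is rejected: querying
#' diseases to derive diseases is circular.
#'
#' @param snapshot A `knowledge_snapshot`.
#' @param mapping An `event_mapping`.
#' @param event_id Event to query.
#' @param chem_disease_evidence,gene_disease_evidence Passed to
#'   [enumerate_tetramers()].
#' @param pattern_exclude Gene-pattern vetting exclusion list.
#' @return Sorted character vector of disease ids.
#' @export
diseases_for_event <- function(snapshot, mapping, event_id,
                               chem_disease_evidence = "marker_mechanism",
                               gene_disease_evidence = NULL,
                               pattern_exclude = character()) {
  terms <- mapping[mapping$event_id == event_id, , drop = FALSE]
  if (nrow(terms) == 0L) stop_validation("event has no mapped terms: ", event_id)
  mech <- terms[terms$term_kind %in% c("gene", "gene_pattern", "phenotype"), , drop = FALSE]
  if (nrow(mech) == 0L) {
    stop_validation("event ", event_id,
                    " maps only to disease terms; disease-set retrieval would be circular")
  }
  out <- character()
  for (i in seq_len(nrow(mech))) {
    kind <- mech$term_kind[i]
    term <- mech$term[i]
    tt <- switch(kind,
      gene = enumerate_tetramers(snapshot, gene = term,
                                 chem_disease_evidence = chem_disease_evidence,
                                 gene_disease_evidence = gene_disease_evidence),
      gene_pattern = {
        genes <- expand_gene_pattern(term, snapshot$gene_universe,
                                     exclude = pattern_exclude)
        if (!length(genes)) NULL else
          enumerate_tetramers(snapshot, gene = genes,
                              chem_disease_evidence = chem_disease_evidence,
                              gene_disease_evidence = gene_disease_evidence)
      },
      phenotype = enumerate_tetramers(snapshot, phenotype = term,
                                      chem_disease_evidence = chem_disease_evidence,
                                      gene_disease_evidence = gene_disease_evidence)
    )
    if (!is.null(tt)) out <- c(out, tt$disease_id)
  }
  sort(unique(out))
}

#' Exact Venn/UpSet region counts for labeled sets
#'
#' For k labeled sets (2 <= k <= 6) computes, for every non-empty subset of
#' labels, the number of elements belonging to exactly those sets. Regions
#' are disjoint by construction and sum to the size of the union. The core
#' (elements common to all sets) is returned explicitly.
#'
#' @param sets Named list of 2..6 character vectors.
#' @return Object of class `venn_result`: list with `regions` (data frame
#'   `region` — labels joined by `&` — and `count`, covering all 2^k - 1
#'   subsets) and `core`.
#' @export
venn_cells <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 6L) stop_validation("venn_cells needs between 2 and 6 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_validation("sets must be named")
  }
  labels <- names(sets)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  # every non-empty label subset, in size-then-lexicographic order
  subsets <- unlist(lapply(seq_len(k), function(m) {
    cmb <- utils::combn(labels, m, simplify = FALSE)
    cmb
  }), recursive = FALSE)
  region_of <- apply(membership, 1L, function(row) paste(labels[row], collapse = "&"))
  counts <- vapply(subsets, function(sub) {
    sum(region_of == paste(sub, collapse = "&"))
  }, integer(1))
  regions <- data.frame(
    region = vapply(subsets, paste, character(1), collapse = "&"),
    count = counts,
    stringsAsFactors = FALSE
  )
  core <- sort(Reduce(intersect, sets))
  structure(list(regions = regions, core = core, labels = labels,
                 n_union = length(universe)),
            class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat("<venn_result> ", length(x$labels), " sets, union ", x$n_union,
      ", core ", length(x$core), "\n", sep = "")
  nz <- x$regions[x$regions$count > 0L, , drop = FALSE]
  for (i in seq_len(min(nrow(nz), 10L))) {
    cat("  ", nz$region[i], ": ", nz$count[i], "\n", sep = "")
  }
  invisible(x)
}

#' Core and leave-one-out expansion of labeled sets
#'
#' The core is the intersection of all sets; dropping one label yields an
#' expanded core, and the additional elements are those gained by the drop:
#' `additional = expanded \ core`, so
#' `|additional| = |expanded| - |core| >= 0`.
#'
#' @param sets Named list of >= 3 character vectors.
#' @param drop_label Label of the set to leave out.
#' @return List with `core`, `expanded` and `additional` (sorted vectors).
#' @export
core_and_loo <- function(sets, drop_label) {
  if (length(sets) < 3L) stop_validation("core_and_loo needs at least three sets")
  if (!drop_label %in% names(sets)) stop_lookup("unknown label: ", drop_label)
  sets <- lapply(sets, unique)
  core <- Reduce(intersect, sets)
  expanded <- Reduce(intersect, sets[setdiff(names(sets), drop_label)])
  list(core = sort(core),
       expanded = sort(expanded),
       additional = sort(setdiff(expanded, core)))
}

#' Write Venn region counts as TSV
#' @param venn A `venn_result`.
#' @param path Output path.
#' @export
write_venn <- function(venn, path) {
  utils::write.table(venn$regions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct synthetic disease sets with a prescribed intersection structure
#'
#' Builds labeled sets of synthetic disease identifiers such that a chosen
#' core is shared by all sets, a chosen block is shared by all sets except
#' one (`loo_label`), and each set is padded with private elements to its
#' prescribed size. Useful for exercising the Venn and leave-one-out algebra
#' at a realistic scale without any external data; all identifiers are
#' synthetic.
#'
#' @param sizes Named integer vector: final size of each set.
#' @param core_size Number of elements common to all sets.
#' @param loo_extra Number of elements common to all sets except
#'   `loo_label`.
#' @param loo_label The left-out label (must name an entry of `sizes`).
#' @return Named list of disease-id vectors.
#' @export
synthetic_event_disease_sets <- function(sizes, core_size, loo_extra, loo_label) {
  if (!loo_label %in% names(sizes)) stop_lookup("unknown label: ", loo_label)
  others <- setdiff(names(sizes), loo_label)
  private <- ifelse(names(sizes) == loo_label,
                    sizes - core_size,
                    sizes - core_size - loo_extra)
  names(private) <- names(sizes)
  if (any(private < 0L)) {
    stop_validation("infeasible sizes: core/loo blocks exceed a set size")
  }
  mk <- function(n, offset) sprintf("MESH:D9%06d", offset + seq_len(n))
  core <- mk(core_size, 0L)
  loo <- mk(loo_extra, core_size)
  offset <- core_size + loo_extra
  out <- list()
  for (lab in names(sizes)) {
    priv <- mk(private[[lab]], offset)
    offset <- offset + private[[lab]]
    out[[lab]] <- c(core, if (lab %in% others) loo, priv)
  }
  out
}
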