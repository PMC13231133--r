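# Chemical-event intersection: map AOP events to vocabulary terms, retrieve
# the chemical set intersecting each event, score chemicals 1..E by event
# coverage, rank, and group into chemical-hierarchy categories.

.term_kinds <- c("gene", "gene_pattern", "phenotype", "disease")

#' Load an event -> term mapping
#'
#' A mapping is a data frame with columns `event_id`, `term_kind` (one of
#' `gene`, `gene_pattern`, `phenotype`, `disease`), `term` (a canonical
#' identifier, or a symbol prefix ending `*` for `gene_pattern`), and
#' optionally `evidence_filter` (only meaningful for disease terms; value
#' `marker_mechanism` restricts retrieval to that direct-evidence class).
#'
#' @param path TSV with those columns.
#' @return Validated mapping data frame (class `event_mapping`).
#' @export
load_event_mapping <- function(path) {
  df <- read_delim_commented(path)
  miss <- setdiff(c("event_id", "term_kind", "term"), names(df))
  if (length(miss)) stop_format("missing column(s) in event mapping: ",
                                paste(miss, collapse = ", "))
  if (!"evidence_filter" %in% names(df)) df$evidence_filter <- ""
  as_event_mapping(df)
}

#' @rdname load_event_mapping
#' @param df Data frame with the mapping columns.
#' @export
as_event_mapping <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  bad <- !df$term_kind %in% .term_kinds
  if (any(bad)) stop_validation("unknown term_kind: ",
                                paste(unique(df$term_kind[bad]), collapse = ", "))
  ev <- trimws(ifelse(is.na(df$evidence_filter), "", df$evidence_filter))
  ev[!nzchar(ev)] <- NA_character_
  if (any(!is.na(ev) & df$term_kind != "disease")) {
    stop_validation("evidence_filter is only valid for disease terms")
  }
  if (any(!is.na(ev) & !ev %in% .evidence_levels)) {
    stop_validation("unknown evidence_filter value(s)")
  }
  df$evidence_filter <- ev
  out <- df[, c("event_id", "term_kind", "term", "evidence_filter")]
  rownames(out) <- NULL
  class(out) <- c("event_mapping", "data.frame")
  out
}

#' Packaged event mapping for the autism AOP
#'
#' The curated term translation of the six autism AOP events into genes,
#' gene patterns, phenotypes and the autism-spectrum disease term (with the
#' marker/mechanism evidence filter on the adverse-outcome retrieval).
#' @return An `event_mapping` data frame.
#' @export
autism_event_mapping <- function() {
  load_event_mapping(system.file("extdata", "aop522_event_mapping.tsv",
                                 package = "aoplink"))
}

#' Chemicals intersecting one mapped term
#'
#' Retrieval semantics per term kind: a gene returns every chemical with any
#' curated chemical-gene relation to it (any interaction direction counts);
#' a gene pattern unions over its expanded genes; a phenotype returns
#' chemicals with chemical-phenotype relations to the term or any transitive
#' descendant (subsumption); a disease likewise uses descendant closure over
#' the disease hierarchy, restricted to the requested direct-evidence class
#' when `evidence_filter` is set.
#'
#' @param snapshot A `knowledge_snapshot`.
#' @param term_kind One of `gene`, `gene_pattern`, `phenotype`, `disease`.
#' @param term Canonical identifier (or symbol prefix pattern).
#' @param evidence_filter Optional direct-evidence class (disease only).
#' @param pattern_exclude Exclusion list for gene-pattern vetting.
#' @return Sorted character vector of chemical ids.
#' @export
chemicals_for_term <- function(snapshot, term_kind, term,
                               evidence_filter = NULL,
                               pattern_exclude = character()) {
  term_kind <- match.arg(term_kind, .term_kinds)
  rel <- snapshot$relations
  chems <- switch(term_kind,
    gene = {
      if (!term %in% snapshot$gene_universe$gene_id) stop_lookup("unknown gene: ", term)
      r <- rel$chem_gene
      r$subject_id[r$object_id == term]
    },
    gene_pattern = {
      genes <- expand_gene_pattern(term, snapshot$gene_universe, exclude = pattern_exclude)
      r <- rel$chem_gene
      r$subject_id[r$object_id %in% genes]
    },
    phenotype = {
      terms <- descendant_closure(snapshot$phenotype_hierarchy, term)
      r <- rel$chem_phenotype
      r$subject_id[r$object_id %in% terms]
    },
    disease = {
      terms <- descendant_closure(snapshot$disease_hierarchy, term)
      r <- rel$chem_disease
      keep <- r$object_id %in% terms
      if (!is.null(evidence_filter) && !is.na(evidence_filter)) {
        keep <- keep & !is.na(r$direct_evidence) & r$direct_evidence == evidence_filter
      }
      r$subject_id[keep]
    }
  )
  sort(unique(chems))
}

#' Chemical x event coverage matrix
#'
#' A chemical is incident to an event iff at least one of that event's
#' mapped terms returns it — counted once per event however many terms
#' matched (duplicate listings from multiple queries are removed). A
#' chemical's score is the number of events it touches (its incidence
#' row-sum, 1..E); chemicals touching no event are absent. Rows are ordered
#' by descending score, ties broken by ascending chemical id.
#'
#' @param snapshot A `knowledge_snapshot`.
#' @param mapping An `event_mapping`.
#' @param aop An `aop_definition` (or `aop_set` holding exactly one AOP);
#'   fixes the event set and order.
#' @param pattern_exclude Gene-pattern vetting exclusion list.
#' @return Object of class `coverage_matrix`: list with `chemicals`,
#'   `events`, logical `incidence` matrix and integer `score`.
#' @export
event_coverage <- function(snapshot, mapping, aop, pattern_exclude = character()) {
  if (inherits(aop, "aop_set")) {
    if (length(aop$aops) != 1L) stop_validation("aop_set must hold exactly one AOP here")
    aop <- aop$aops[[1]]
  }
  events <- aop$events$event_id
  mapping <- mapping[mapping$event_id %in% events, , drop = FALSE]
  if (nrow(mapping) == 0L) stop_validation("empty event mapping for this AOP")
  per_event <- lapply(events, function(ev) {
    rows <- which(mapping$event_id == ev)
    out <- character()
    for (i in rows) {
      out <- c(out, chemicals_for_term(snapshot, mapping$term_kind[i],
                                       mapping$term[i], mapping$evidence_filter[i],
                                       pattern_exclude = pattern_exclude))
    }
    unique(out)
  })
  names(per_event) <- events
  chems <- sort(unique(unlist(per_event, use.names = FALSE)))
  inc <- vapply(per_event, function(s) chems %in% s, logical(length(chems)))
  if (length(chems) == 1L) inc <- matrix(inc, nrow = 1L, dimnames = list(chems, events))
  if (length(chems) == 0L) inc <- matrix(logical(), nrow = 0L, ncol = length(events),
                                         dimnames = list(NULL, events))
  rownames(inc) <- chems
  score <- as.integer(rowSums(inc))
  ord <- order(-score, chems)
  structure(
    list(chemicals = chems[ord], events = events,
         incidence = inc[ord, , drop = FALSE],
         score = stats::setNames(score[ord], chems[ord])),
    class = "coverage_matrix"
  )
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat("<coverage_matrix> ", length(x$chemicals), " chemicals x ",
      length(x$events), " events\n", sep = "")
  if (length(x$score)) {
    tb <- table(factor(x$score, levels = rev(seq_along(x$events))))
    for (s in names(tb)) if (tb[[s]] > 0) cat("  score ", s, ": ", tb[[s]], "\n", sep = "")
  }
  invisible(x)
}

#' Rank chemicals by event coverage
#'
#' @param coverage A `coverage_matrix`.
#' @param min_score Minimum score to report (1..number of events).
#' @return Data frame `chemical_id`, `score`, plus one logical column per
#'   event, ordered by descending score then ascending chemical id. Empty
#'   when nothing reaches `min_score`.
#' @export
rank_chemicals <- function(coverage, min_score = 1L) {
  n_ev <- length(coverage$events)
  if (min_score < 1L || min_score > n_ev) {
    stop_validation("min_score must be in 1..", n_ev)
  }
  keep <- coverage$score >= min_score
  out <- data.frame(chemical_id = coverage$chemicals[keep],
                    score = as.integer(coverage$score[keep]),
                    stringsAsFactors = FALSE)
  inc <- coverage$incidence[keep, , drop = FALSE]
  for (ev in coverage$events) out[[ev]] <- inc[, ev]
  rownames(out) <- NULL
  out
}

#' Group chemicals by shared parentage in the chemical hierarchy
#'
#' A chemical is assigned to every listed category whose descendant closure
#' contains it (multi-membership allowed); chemicals matching no listed
#' category fall into `"uncategorized"`.
#'
#' @param chemical_hierarchy An `ontology_hierarchy`.
#' @param chemicals Character vector of chemical ids.
#' @param category_parents Character vector of hierarchy term ids.
#' @return Named list of sorted chemical-id vectors, one per category plus
#'   `uncategorized`.
#' @export
categorize_chemicals <- function(chemical_hierarchy, chemicals, category_parents) {
  groups <- stats::setNames(lapply(category_parents, function(p) {
    members <- descendant_closure(chemical_hierarchy, p)  # errors on unknown parent
    sort(intersect(chemicals, members))
  }), category_parents)
  assigned <- unique(unlist(groups, use.names = FALSE))
  groups$uncategorized <- sort(setdiff(chemicals, assigned))
  groups
}

#' Read a coverage workbook (chemical rows x event columns)
#'
#' Accepts the supplementary-table layout in which each row is a chemical
#' and each event column holds a non-empty marker when the chemical
#' intersects that event. Builds a `coverage_matrix` directly, so scores and
#' tiers can be recomputed from a deposited workbook.
#'
#' @param path `.xlsx` (requires readxl), CSV or TSV file.
#' @param chemical_col Name of the chemical identifier column.
#' @param event_cols Character vector naming the event columns, in pathway
#'   order; defaults to every column after `chemical_col`.
#' @param sheet Sheet (xlsx only).
#' @return A `coverage_matrix`.
#' @export
read_coverage_table <- function(path, chemical_col = 1L, event_cols = NULL, sheet = 1L) {
  if (grepl("\\.xlsx$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop_format("reading xlsx requires the 'readxl' package")
    }
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet, col_types = "text"))
  } else {
    df <- read_delim_commented(path)
  }
  if (is.numeric(chemical_col)) chemical_col <- names(df)[chemical_col]
  if (is.null(event_cols)) {
    event_cols <- setdiff(names(df), chemical_col)
  }
  miss <- setdiff(c(chemical_col, event_cols), names(df))
  if (length(miss)) stop_format("missing column(s): ", paste(miss, collapse = ", "))
  chems <- trimws(df[[chemical_col]])
  keep <- !is.na(chems) & nzchar(chems)
  df <- df[keep, , drop = FALSE]; chems <- chems[keep]
  inc <- vapply(event_cols, function(cn) {
    v <- trimws(ifelse(is.na(df[[cn]]), "", df[[cn]]))
    nzchar(v) & !tolower(v) %in% c("0", "false", "no")
  }, logical(nrow(df)))
  if (nrow(df) == 1L) inc <- matrix(inc, nrow = 1L)
  rownames(inc) <- chems
  colnames(inc) <- event_cols
  # collapse duplicated chemical rows by logical-or
  if (anyDuplicated(chems)) {
    inc <- rowsum(inc + 0L, chems) > 0L
    chems <- rownames(inc)
  }
  score <- as.integer(rowSums(inc))
  keep <- score > 0L
  inc <- inc[keep, , drop = FALSE]; chems <- chems[keep]; score <- score[keep]
  ord <- order(-score, chems)
  structure(
    list(chemicals = chems[ord], events = event_cols,
         incidence = inc[ord, , drop = FALSE],
         score = stats::setNames(score[ord], chems[ord])),
    class = "coverage_matrix"
  )
}

#' Write a coverage matrix / ranking report as TSV
#' @param coverage A `coverage_matrix`.
#' @param path Output path.
#' @param min_score Passed to [rank_chemicals()].
#' @export
write_coverage <- function(coverage, path, min_score = 1L) {
  utils::write.table(rank_chemicals(coverage, min_score), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
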