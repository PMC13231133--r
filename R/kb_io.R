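# Reading, validating and assembling the knowledge snapshot: five curated
# relation tables (chemical-gene, chemical-phenotype, chemical-disease,
# gene-phenotype, gene-disease) plus three vocabularies and a gene universe.

.relation_kinds <- c("chem_gene", "chem_phenotype", "chem_disease",
                     "gene_phenotype", "gene_disease")

# subject/object namespace per relation kind
.kind_ns <- list(
  chem_gene      = c("chemical", "gene"),
  chem_phenotype = c("chemical", "phenotype"),
  chem_disease   = c("chemical", "disease"),
  gene_phenotype = c("gene", "phenotype"),
  gene_disease   = c("gene", "disease")
)

.evidence_levels <- c("marker_mechanism", "therapeutic")

#' Load one curated relation table
#'
#' Reads a TSV/CSV (optionally gzip-compressed, `#` comment headers allowed)
#' in the bulk-download dialect and returns canonical relation records.
#' Identifiers are normalized to the namespaces implied by `relation_kind`;
#' rows lacking a subject or object are rejected; rows identical up to their
#' supporting articles are merged with the article sets unioned. Rows that
#' differ in `direct_evidence` are kept separate, because the evidence class
#' changes query semantics downstream (adverse-outcome retrieval filters on
#' marker/mechanism).
#'
#' @param path File path.
#' @param relation_kind One of `r paste0('\x60', .relation_kinds, '\x60', collapse=", ")`.
#' @param column_map Named character vector mapping canonical fields
#'   (`subject_id`, `object_id`, and optionally `direct_evidence`,
#'   `organism_id`, `support_articles`) to the file's column names.
#' @return Data frame with columns `subject_id`, `object_id`,
#'   `relation_kind`, `direct_evidence`, `organism_id`, and list-column
#'   `support_articles` (character vectors of article ids, no duplicates).
#' @export
load_relation_table <- function(path, relation_kind,
                                column_map = c(subject_id = "subject_id",
                                               object_id = "object_id",
                                               direct_evidence = "direct_evidence",
                                               organism_id = "organism_id",
                                               support_articles = "support_articles")) {
  relation_kind <- match.arg(relation_kind, .relation_kinds)
  if (!file.exists(path)) stop_format("no such file: ", path)
  df <- read_delim_commented(path)
  for (f in c("subject_id", "object_id")) {
    col <- column_map[[f]]
    if (is.null(col) || is.na(col) || !col %in% names(df)) {
      stop_format("missing mapped column for '", f, "': ",
                  if (is.null(col) || is.na(col)) "<unmapped>" else col)
    }
  }
  getcol <- function(f, default = NA_character_) {
    col <- column_map[f]
    if (!is.na(col) && col %in% names(df)) df[[col]] else rep(default, nrow(df))
  }
  subject <- getcol("subject_id")
  object <- getcol("object_id")
  bad <- is.na(subject) | !nzchar(trimws(subject)) |
    is.na(object) | !nzchar(trimws(object))
  if (any(bad)) {
    df <- df[!bad, , drop = FALSE]
    subject <- subject[!bad]; object <- object[!bad]
  }
  ns <- .kind_ns[[relation_kind]]
  rec <- data.frame(
    subject_id = if (length(subject)) normalize_identifier(subject, ns[1]) else character(),
    object_id = if (length(object)) normalize_identifier(object, ns[2]) else character(),
    relation_kind = rep(relation_kind, length(subject)),
    direct_evidence = {
      ev <- trimws(getcol("direct_evidence"))
      ev[!nzchar(ev) | is.na(ev)] <- NA_character_
      ev <- gsub("[ /]", "_", tolower(ev))
      bad_ev <- !is.na(ev) & !ev %in% .evidence_levels
      if (any(bad_ev)) {
        stop_validation("unknown direct_evidence value(s) at row(s) ",
                        paste(utils::head(which(bad_ev), 5), collapse = ", "))
      }
      ev
    },
    organism_id = {
      org <- trimws(getcol("organism_id"))
      org[!nzchar(org) | is.na(org)] <- NA_character_
      org
    },
    stringsAsFactors = FALSE
  )
  rec$support_articles <- lapply(split_multi(getcol("support_articles", "")),
                                 function(v) sort(unique(toupper(trimws(v)))))
  dedup_relations(rec)
}

# Merge rows identical up to support_articles, unioning the article sets.
#' @keywords internal
dedup_relations <- function(rec, relation_kind = NULL) {
  if (!is.null(relation_kind)) rec$relation_kind <- rep(relation_kind, nrow(rec))
  if (is.null(rec$direct_evidence)) rec$direct_evidence <- rep(NA_character_, nrow(rec))
  if (is.null(rec$organism_id)) rec$organism_id <- rep(NA_character_, nrow(rec))
  if (is.null(rec$support_articles)) rec$support_articles <- rep(list(character()), nrow(rec))
  if (nrow(rec) == 0L) return(empty_relations(rec$relation_kind[0]))
  key <- paste(rec$subject_id, rec$object_id, rec$relation_kind,
               ifelse(is.na(rec$direct_evidence), "", rec$direct_evidence),
               ifelse(is.na(rec$organism_id), "", rec$organism_id),
               sep = "\r")
  grp <- match(key, unique(key))
  first <- !duplicated(grp)
  out <- rec[first, , drop = FALSE]
  arts <- split(rec$support_articles, grp)
  out$support_articles <- lapply(arts, function(lst) sort(unique(unlist(lst, use.names = FALSE))))
  ord <- order(out$subject_id, out$object_id,
               ifelse(is.na(out$direct_evidence), "", out$direct_evidence))
  out <- out[ord, c("subject_id", "object_id", "relation_kind", "direct_evidence",
                    "organism_id", "support_articles"), drop = FALSE]
  names(out$support_articles) <- NULL
  rownames(out) <- NULL
  out
}

#' @keywords internal
empty_relations <- function(kind) {
  out <- data.frame(subject_id = character(), object_id = character(),
                    relation_kind = character(), direct_evidence = character(),
                    organism_id = character(), stringsAsFactors = FALSE)
  out$support_articles <- list()
  out
}

#' Assemble a knowledge snapshot
#'
#' Bundles the five relation tables, the three vocabularies and the gene
#' universe into one referentially consistent object. Referential problems
#' (genes missing from the universe, terms outside their hierarchy) are
#' collected into an integrity report; with `strict = TRUE` any problem is an
#' error, otherwise offending identifiers are flagged but retained.
#'
#' @param relations Named list of relation data frames (names from
#'   `chem_gene`, `chem_phenotype`, `chem_disease`, `gene_phenotype`,
#'   `gene_disease`); missing kinds default to empty tables.
#' @param phenotype_hierarchy,disease_hierarchy,chemical_hierarchy
#'   `ontology_hierarchy` objects.
#' @param gene_universe Data frame with columns `gene_id`, `gene_symbol`.
#' @param snapshot_label Free-text revision tag.
#' @param organism_allow Optional character vector; when given, relation rows
#'   whose `organism_id` is absent from the list are dropped (rows with no
#'   organism are kept). No organism filter is applied by default.
#' @param strict Error on referential problems instead of flagging.
#' @return An object of class `knowledge_snapshot` with an
#'   `integrity_report` data frame (`id`, `problem`) attached.
#' @export
knowledge_snapshot <- function(relations = list(),
                               phenotype_hierarchy,
                               disease_hierarchy,
                               chemical_hierarchy,
                               gene_universe,
                               snapshot_label = "unlabelled",
                               organism_allow = NULL,
                               strict = FALSE) {
  rel <- stats::setNames(lapply(.relation_kinds, function(k) {
    r <- relations[[k]]
    if (is.null(r)) empty_relations(k) else dedup_relations(r, relation_kind = k)
  }), .relation_kinds)
  if (!is.null(organism_allow)) {
    rel <- lapply(rel, function(r) {
      keep <- is.na(r$organism_id) | r$organism_id %in% organism_allow
      r[keep, , drop = FALSE]
    })
  }
  gene_universe <- data.frame(gene_id = as.character(gene_universe$gene_id),
                              gene_symbol = as.character(gene_universe$gene_symbol),
                              stringsAsFactors = FALSE)
  gene_universe <- gene_universe[order(gene_universe$gene_id), , drop = FALSE]
  gene_universe <- gene_universe[!duplicated(gene_universe$gene_id), , drop = FALSE]
  rownames(gene_universe) <- NULL

  report <- list()
  used <- function(kind, side) {
    ids <- unlist(lapply(rel[kind], function(r) r[[side]]), use.names = FALSE)
    unique(ids)
  }
  miss_gene <- setdiff(c(used(c("gene_phenotype", "gene_disease"), "subject_id"),
                         used("chem_gene", "object_id")),
                       gene_universe$gene_id)
  if (length(miss_gene)) {
    report$gene <- data.frame(id = miss_gene, problem = "gene not in gene_universe")
  }
  miss_phen <- setdiff(used(c("chem_phenotype", "gene_phenotype"), "object_id"),
                       phenotype_hierarchy$nodes$id)
  if (length(miss_phen)) {
    report$phen <- data.frame(id = miss_phen, problem = "phenotype not in phenotype_hierarchy")
  }
  miss_dis <- setdiff(used(c("chem_disease", "gene_disease"), "object_id"),
                      disease_hierarchy$nodes$id)
  if (length(miss_dis)) {
    report$dis <- data.frame(id = miss_dis, problem = "disease not in disease_hierarchy")
  }
  miss_chem <- setdiff(used(c("chem_gene", "chem_phenotype", "chem_disease"), "subject_id"),
                       chemical_hierarchy$nodes$id)
  if (length(miss_chem)) {
    report$chem <- data.frame(id = miss_chem, problem = "chemical not in chemical_hierarchy")
  }
  report <- if (length(report)) do.call(rbind, c(report, make.row.names = FALSE)) else
    data.frame(id = character(), problem = character())
  if (strict && nrow(report)) {
    stop_validation("snapshot integrity violations: ",
                    paste(utils::head(paste0(report$id, " (", report$problem, ")"), 5),
                          collapse = "; "))
  }
  structure(
    list(relations = rel,
         phenotype_hierarchy = phenotype_hierarchy,
         disease_hierarchy = disease_hierarchy,
         chemical_hierarchy = chemical_hierarchy,
         gene_universe = gene_universe,
         snapshot_label = snapshot_label,
         integrity_report = report),
    class = "knowledge_snapshot"
  )
}

#' @export
print.knowledge_snapshot <- function(x, ...) {
  cat("<knowledge_snapshot> '", x$snapshot_label, "'\n", sep = "")
  for (k in .relation_kinds) cat(sprintf("  %-15s %6d relations\n", k, nrow(x$relations[[k]])))
  cat("  gene universe  ", nrow(x$gene_universe), " genes; ",
      nrow(x$integrity_report), " integrity flag(s)\n", sep = "")
  invisible(x)
}

#' Write a snapshot as canonical TSV serialization
#'
#' One TSV per relation kind (rows in canonical order, article sets
#' pipe-joined and sorted), the three vocabularies (OBO for phenotypes,
#' tree-vocabulary TSV for diseases and chemicals), the gene universe, and a
#' `manifest.tsv` naming every part. Writing then re-reading yields an
#' identical record set, and assembling twice from the same files yields
#' byte-identical files.
#'
#' @param snapshot A `knowledge_snapshot`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_snapshot <- function(snapshot, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (k in .relation_kinds) {
    r <- snapshot$relations[[k]]
    flat <- data.frame(subject_id = r$subject_id, object_id = r$object_id,
                       direct_evidence = ifelse(is.na(r$direct_evidence), "", r$direct_evidence),
                       organism_id = ifelse(is.na(r$organism_id), "", r$organism_id),
                       support_articles = join_multi(r$support_articles),
                       stringsAsFactors = FALSE)
    f <- file.path(dir, paste0(k, ".tsv"))
    utils::write.table(flat, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, basename(f))
  }
  write_obo(snapshot$phenotype_hierarchy, file.path(dir, "phenotypes.obo"))
  write_tree_vocab(snapshot$disease_hierarchy, file.path(dir, "diseases.tsv"))
  write_tree_vocab(snapshot$chemical_hierarchy, file.path(dir, "chemicals.tsv"))
  utils::write.table(snapshot$gene_universe, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- data.frame(
    part = c(.relation_kinds, "phenotypes", "diseases", "chemicals", "genes", "label"),
    file = c(files, "phenotypes.obo", "diseases.tsv", "chemicals.tsv", "genes.tsv",
             snapshot$snapshot_label)
  )
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a snapshot back from its canonical serialization
#'
#' @param dir Directory written by [write_snapshot()].
#' @inheritParams knowledge_snapshot
#' @return A `knowledge_snapshot`.
#' @export
read_snapshot <- function(dir, strict = FALSE) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  label <- manifest$file[manifest$part == "label"]
  rel <- stats::setNames(lapply(.relation_kinds, function(k) {
    load_relation_table(file.path(dir, paste0(k, ".tsv")), k)
  }), .relation_kinds)
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t", header = TRUE,
                             colClasses = "character", stringsAsFactors = FALSE)
  knowledge_snapshot(
    relations = rel,
    phenotype_hierarchy = parse_obo(file.path(dir, "phenotypes.obo")),
    disease_hierarchy = parse_tree_vocab(file.path(dir, "diseases.tsv"), "disease"),
    chemical_hierarchy = parse_tree_vocab(file.path(dir, "chemicals.tsv"), "chemical"),
    gene_universe = genes,
    snapshot_label = label,
    strict = strict
  )
}

#' Load a tetramer export table
#'
#' Reads a chemical-gene-phenotype-disease tetramer export (CSV/TSV or xlsx)
#' one row per tetramer. All rows are parsed and the row count preserved —
#' no deduplication happens at load time. Phenotype identifiers must be GO
#' accessions.
#'
#' @param path CSV/TSV (optionally gzipped) or `.xlsx` file.
#' @param column_map Named character vector mapping `chemical_id`, `gene_id`,
#'   `phenotype_id`, `disease_id` (and optionally `sheet` for xlsx input and
#'   per-edge article-count columns `n_articles_cg`, `n_articles_cp`,
#'   `n_articles_cd`, `n_articles_gp`, `n_articles_gd`) to the file's
#'   columns. Gene columns carrying symbols rather than numeric ids are
#'   passed through untouched when `gene_as_symbol = TRUE`.
#' @param gene_as_symbol Treat the gene column as a symbol, not a numeric id.
#' @return Data frame with canonical identifier columns (and any article
#'   count columns found).
#' @export
load_tetramer_export <- function(path,
                                 column_map = c(chemical_id = "chemical_id",
                                                gene_id = "gene_id",
                                                phenotype_id = "phenotype_id",
                                                disease_id = "disease_id"),
                                 gene_as_symbol = FALSE) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  if (grepl("\\.xlsx$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop_format("reading xlsx requires the 'readxl' package")
    }
    sheet <- if (!is.na(column_map["sheet"])) column_map[["sheet"]] else 1L
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet,
                                           col_types = "text"),
                        stringsAsFactors = FALSE)
  } else {
    df <- read_delim_commented(path)
  }
  for (f in c("chemical_id", "gene_id", "phenotype_id", "disease_id")) {
    col <- column_map[f]
    if (is.na(col) || !col %in% names(df)) {
      stop_format("missing mapped column for '", f, "': ",
                  if (is.na(col)) "<unmapped>" else col)
    }
    empty <- is.na(df[[col]]) | !nzchar(trimws(df[[col]]))
    if (any(empty)) {
      stop_format("empty '", f, "' at row(s) ",
                  paste(utils::head(which(empty), 5), collapse = ", "))
    }
  }
  out <- data.frame(
    chemical_id = normalize_identifier(df[[column_map[["chemical_id"]]]], "chemical"),
    gene_id = if (gene_as_symbol) trimws(df[[column_map[["gene_id"]]]]) else
      normalize_identifier(df[[column_map[["gene_id"]]]], "gene"),
    phenotype_id = normalize_identifier(df[[column_map[["phenotype_id"]]]], "phenotype"),
    disease_id = normalize_identifier(df[[column_map[["disease_id"]]]], "disease"),
    stringsAsFactors = FALSE
  )
  for (f in c("n_articles_cg", "n_articles_cp", "n_articles_cd",
              "n_articles_gp", "n_articles_gd")) {
    col <- column_map[f]
    if (!is.na(col) && col %in% names(df)) out[[f]] <- as.integer(df[[col]])
  }
  out
}
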