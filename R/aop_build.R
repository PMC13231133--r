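# Candidate AOP construction: a leveled phenotype network whose edges carry
# the genes shared between phenotype gene-sets drawn from tetramers, ending
# in a terminal disease outcome.

.bio_levels <- c("molecular", "cellular", "system", "behavioral")

#' Tetramer gene sets per phenotype
#'
#' For each listed phenotype, the distinct genes of the tetramers containing
#' it. Phenotypes absent from every tetramer are included with an empty set
#' and flagged.
#'
#' @param tetramers A `tetramer_set` (typically restricted to the shared
#'   dimers of several queries, the default recipe for pathway building).
#' @param phenotype_ids Non-empty character vector.
#' @return List with `gene_sets` (named list of sorted gene-id vectors) and
#'   `flagged_empty` (phenotypes with no tetramer).
#' @export
phenotype_gene_sets <- function(tetramers, phenotype_ids) {
  if (!length(phenotype_ids)) stop_validation("phenotype_ids must be non-empty")
  sets <- stats::setNames(lapply(phenotype_ids, function(p) {
    sort(unique(tetramers$gene_id[tetramers$phenotype_id == p]))
  }), phenotype_ids)
  list(gene_sets = sets,
       flagged_empty = phenotype_ids[lengths(sets) == 0L])
}

#' Shared-gene edges between phenotype gene sets
#'
#' For every unordered pair of phenotypes whose gene sets intersect, one
#' edge carrying the intersection; pairs with disjoint sets are omitted.
#'
#' @param gene_sets Named list of gene-id vectors (>= 2 phenotypes).
#' @return Data frame `phenotype_a`, `phenotype_b`, `n_shared`, and
#'   list-column `shared_genes`.
#' @export
shared_gene_edges <- function(gene_sets) {
  if (length(gene_sets) < 2L) stop_validation("need gene sets for at least two phenotypes")
  ids <- names(gene_sets)
  combos <- utils::combn(seq_along(ids), 2L)
  rows <- list()
  for (j in seq_len(ncol(combos))) {
    a <- combos[1L, j]; b <- combos[2L, j]
    shared <- intersect(gene_sets[[a]], gene_sets[[b]])
    if (length(shared)) {
      rows[[length(rows) + 1L]] <- list(phenotype_a = ids[a], phenotype_b = ids[b],
                                        n_shared = length(shared),
                                        shared_genes = sort(shared))
    }
  }
  out <- data.frame(
    phenotype_a = vapply(rows, `[[`, character(1), "phenotype_a"),
    phenotype_b = vapply(rows, `[[`, character(1), "phenotype_b"),
    n_shared = vapply(rows, `[[`, integer(1), "n_shared"),
    stringsAsFactors = FALSE
  )
  out$shared_genes <- lapply(rows, `[[`, "shared_genes")
  out
}

#' Assemble a candidate AOP graph
#'
#' Builds the candidate pathway object: stressor chemicals, phenotype nodes
#' ordered by level of biological organization
#' (molecular < cellular < system < behavioral), shared-gene edges, and a
#' terminal disease outcome. Edges are computed between all phenotype pairs
#' — level ordering is presentation metadata, not a constraint on linkage.
#' Every edge's gene set is verified to be the intersection of its
#' endpoints' gene sets.
#'
#' @param stressors Character vector of chemical ids.
#' @param phenotypes Data frame with columns `phenotype_id`, `level` (one of
#'   the four levels; user-assigned, never inferred).
#' @param gene_sets Named list of gene vectors (one per phenotype).
#' @param outcome Terminal disease id.
#' @return Object of class `aop_graph_candidate` with `stressors`, `nodes`
#'   (`phenotype_id`, `level`, `n_genes`, list-column `gene_set`), `edges`
#'   (from [shared_gene_edges()]) and `outcome`.
#' @export
assemble_aop_graph <- function(stressors, phenotypes, gene_sets, outcome) {
  bad <- !phenotypes$level %in% .bio_levels
  if (any(bad)) {
    stop_validation("unknown level label(s): ",
                    paste(unique(phenotypes$level[bad]), collapse = ", "),
                    " (expected ", paste(.bio_levels, collapse = " < "), ")")
  }
  miss <- setdiff(phenotypes$phenotype_id, names(gene_sets))
  if (length(miss)) stop_validation("no gene set for phenotype(s): ",
                                    paste(miss, collapse = ", "))
  gene_sets <- gene_sets[phenotypes$phenotype_id]
  nodes <- data.frame(phenotype_id = phenotypes$phenotype_id,
                      level = phenotypes$level,
                      n_genes = lengths(gene_sets),
                      stringsAsFactors = FALSE)
  nodes$gene_set <- lapply(gene_sets, sort)
  ord <- order(match(nodes$level, .bio_levels), nodes$phenotype_id)
  nodes <- nodes[ord, , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- shared_gene_edges(stats::setNames(nodes$gene_set, nodes$phenotype_id))
  # invariant: edge gene sets are intersections of their endpoints' sets
  for (i in seq_len(nrow(edges))) {
    expect <- intersect(gene_sets[[edges$phenotype_a[i]]], gene_sets[[edges$phenotype_b[i]]])
    stopifnot(setequal(edges$shared_genes[[i]], expect))
  }
  structure(list(stressors = sort(unique(stressors)), nodes = nodes,
                 edges = edges, outcome = outcome),
            class = "aop_graph_candidate")
}

#' @export
print.aop_graph_candidate <- function(x, ...) {
  cat("<aop_graph_candidate> ", length(x$stressors), " stressor(s) -> ",
      nrow(x$nodes), " phenotype nodes (", nrow(x$edges),
      " shared-gene edges) -> ", x$outcome, "\n", sep = "")
  invisible(x)
}

#' Write a candidate AOP graph as GraphML
#'
#' Node attributes: role (stressor/phenotype/outcome), level, gene count;
#' edge attributes: shared-gene list (pipe-joined), count. Stressors link to
#' every phenotype and every phenotype links to the outcome, mirroring the
#' tetramer construction in which each stressor is curated to every gene and
#' phenotype and each gene to the outcome disease.
#'
#' @param candidate An `aop_graph_candidate`.
#' @param path Output `.graphml` path.
#' @export
write_aop_graphml <- function(candidate, path) {
  verts <- data.frame(
    name = c(candidate$stressors, candidate$nodes$phenotype_id, candidate$outcome),
    role = c(rep("stressor", length(candidate$stressors)),
             rep("phenotype", nrow(candidate$nodes)), "outcome"),
    level = c(rep("", length(candidate$stressors)), candidate$nodes$level, ""),
    n_genes = c(rep(0L, length(candidate$stressors)), candidate$nodes$n_genes, 0L),
    stringsAsFactors = FALSE
  )
  scaffold <- rbind(
    expand.grid(from = candidate$stressors, to = candidate$nodes$phenotype_id,
                stringsAsFactors = FALSE),
    data.frame(from = candidate$nodes$phenotype_id, to = candidate$outcome)
  )
  scaffold$shared_genes <- ""
  scaffold$n_shared <- 0L
  shared <- data.frame(from = candidate$edges$phenotype_a,
                       to = candidate$edges$phenotype_b,
                       shared_genes = join_multi(candidate$edges$shared_genes),
                       n_shared = candidate$edges$n_shared,
                       stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(rbind(scaffold, shared),
                                     directed = TRUE, vertices = verts)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Serialize / parse a candidate AOP graph as structured text
#'
#' A sectioned TSV (`# stressors`, `# nodes`, `# edges`, `# outcome`) whose
#' round trip preserves the node and edge sets exactly.
#' @param candidate An `aop_graph_candidate`.
#' @param path File path.
#' @export
write_aop_candidate <- function(candidate, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("# stressors", candidate$stressors), con)
  writeLines("# nodes", con)
  nodes <- data.frame(phenotype_id = candidate$nodes$phenotype_id,
                      level = candidate$nodes$level,
                      gene_set = join_multi(candidate$nodes$gene_set))
  utils::write.table(nodes, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("# edges", con)
  edges <- data.frame(phenotype_a = candidate$edges$phenotype_a,
                      phenotype_b = candidate$edges$phenotype_b,
                      shared_genes = join_multi(candidate$edges$shared_genes))
  utils::write.table(edges, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c("# outcome", candidate$outcome), con)
  invisible(path)
}

#' @rdname write_aop_candidate
#' @export
read_aop_candidate <- function(path) {
  lines <- readLines(path, warn = FALSE)
  marks <- grep("^# ", lines)
  section <- function(name) {
    i <- which(lines[marks] == paste0("# ", name))
    if (!length(i)) stop_format("missing section: ", name)
    from <- marks[i] + 1L
    to <- if (i < length(marks)) marks[i + 1L] - 1L else length(lines)
    lines[seq(from, to)]
  }
  stressors <- section("stressors")
  nodes <- utils::read.table(text = section("nodes"), sep = "\t", header = TRUE,
                             colClasses = "character", stringsAsFactors = FALSE)
  edges_txt <- section("edges")
  gene_sets <- stats::setNames(split_multi(nodes$gene_set), nodes$phenotype_id)
  assemble_aop_graph(
    stressors = stressors,
    phenotypes = nodes[, c("phenotype_id", "level")],
    gene_sets = gene_sets,
    outcome = section("outcome")[1]
  )
}
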