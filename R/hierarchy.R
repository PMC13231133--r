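# Rooted acyclic term hierarchies (GO, MEDIC disease, chemical vocabulary)
# and the subsumption algebra over them: descendant closure and ancestor
# queries. Curated knowledge bases display data annotated to descendant terms
# on the parent, so every hierarchical query here works on the closure.

#' Construct an ontology hierarchy
#'
#' A hierarchy is a rooted directed acyclic term graph: nodes carry an id and
#' a name, parent links point child -> parent and carry a relation label
#' (`is_a`, `part_of`, `tree_number`). Multi-parent terms are allowed (GO is
#' a DAG; MEDIC is a poly-hierarchy).
#'
#' @param nodes Data frame with columns `id`, `name`.
#' @param parents Data frame with columns `child`, `parent`, `relation`
#'   (zero rows allowed).
#' @param check When `TRUE` (default) verify acyclicity, that parents are
#'   member nodes, and derive roots.
#' @return An object of class `ontology_hierarchy`.
#' @export
ontology_hierarchy <- function(nodes,
                               parents = data.frame(child = character(),
                                                    parent = character(),
                                                    relation = character()),
                               check = TRUE) {
  nodes <- data.frame(id = as.character(nodes$id),
                      name = as.character(nodes$name),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id)) {
    nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  }
  parents <- data.frame(child = as.character(parents$child),
                        parent = as.character(parents$parent),
                        relation = if (nrow(parents)) as.character(parents$relation) else character(),
                        stringsAsFactors = FALSE)
  parents <- unique(parents)
  if (check && nrow(parents)) {
    dangling <- setdiff(unique(c(parents$child, parents$parent)), nodes$id)
    if (length(dangling)) {
      stop_validation("parent link references undeclared term(s): ",
                      paste(utils::head(dangling, 5), collapse = ", "))
    }
    g <- igraph::graph_from_data_frame(parents[, c("child", "parent")],
                                       vertices = nodes$id)
    if (!igraph::is_dag(g)) {
      cyc <- igraph::girth(igraph::as_undirected(g))  # fallback display only
      comp <- tryCatch({
        fb <- igraph::feedback_arc_set(g)
        e <- igraph::ends(g, fb[1])
        paste(e[1, 1], "->", e[1, 2])
      }, error = function(e) "")
      stop_validation("cycle detected in hierarchy (e.g. involving ", comp, ")")
    }
  }
  roots <- setdiff(nodes$id, parents$child)
  structure(
    list(
      nodes = nodes,
      parents = parents,
      roots = sort(roots),
      # adjacency caches used by the closure queries
      children_of = split(parents$child, factor(parents$parent, levels = unique(parents$parent))),
      parents_of = split(parents$parent, factor(parents$child, levels = unique(parents$child)))
    ),
    class = "ontology_hierarchy"
  )
}

#' @export
print.ontology_hierarchy <- function(x, ...) {
  cat("<ontology_hierarchy> ", nrow(x$nodes), " terms, ",
      nrow(x$parents), " parent links, ", length(x$roots), " root(s)\n", sep = "")
  invisible(x)
}

#' @keywords internal
hierarchy_has <- function(hierarchy, term_id) {
  term_id %in% hierarchy$nodes$id
}

.reach <- function(adjacency, start) {
  seen <- character()
  frontier <- start
  while (length(frontier)) {
    seen <- c(seen, frontier)
    nxt <- unlist(adjacency[frontier], use.names = FALSE)
    frontier <- setdiff(unique(nxt), seen)
  }
  unique(seen)
}

#' Descendant closure of a term
#'
#' Returns the term itself together with all transitive descendants, the set
#' over which subsumption queries aggregate annotated data.
#'
#' @param hierarchy An `ontology_hierarchy`.
#' @param term_id A member term id.
#' @return Sorted character vector of term ids (always contains `term_id`).
#' @export
descendant_closure <- function(hierarchy, term_id) {
  if (length(term_id) != 1L || !hierarchy_has(hierarchy, term_id)) {
    stop_lookup("unknown term: ", term_id)
  }
  sort(.reach(hierarchy$children_of, term_id))
}

#' Transitive ancestors of a term
#'
#' @inheritParams descendant_closure
#' @return Sorted character vector of ancestor ids, excluding the term itself.
#' @export
ancestors <- function(hierarchy, term_id) {
  if (length(term_id) != 1L || !hierarchy_has(hierarchy, term_id)) {
    stop_lookup("unknown term: ", term_id)
  }
  sort(setdiff(.reach(hierarchy$parents_of, term_id), term_id))
}

#' Parse an OBO 1.2/1.4 term file into a hierarchy
#'
#' Reads `[Term]` stanzas (`id`, `name`, `is_a`, optional
#' `relationship: part_of`). Obsolete terms are excluded together with their
#' links. `part_of` links are only followed when `part_of = TRUE`;
#' `is_a` is the conservative core of subsumption.
#'
#' @param path Path to an OBO text file (optionally gzip-compressed).
#' @param part_of Include `relationship: part_of` links as parent links.
#' @return An `ontology_hierarchy`.
#' @export
parse_obo <- function(path, part_of = FALSE) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)

  term_starts <- which(lines == "[Term]")
  stanza_starts <- grep("^\\[", lines)
  ids <- character(); names_ <- character(); obsolete <- logical()
  links <- list()
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    end <- if (length(nxt)) nxt[1] - 1L else length(lines)
    block <- lines[(s + 1L):end]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": *"), "", grep(paste0("^", key, ":"), block, value = TRUE))
      if (length(v)) v else NA_character_
    }
    id <- get1("id")[1]
    if (is.na(id)) next
    is_obs <- identical(trimws(get1("is_obsolete")[1]), "true")
    ids <- c(ids, id)
    names_ <- c(names_, sub(" *!.*$", "", get1("name")[1]))
    obsolete <- c(obsolete, is_obs)
    if (!is_obs) {
      isa <- sub(" *!.*$", "", sub("^is_a: *", "", grep("^is_a:", block, value = TRUE)))
      po <- character()
      if (part_of) {
        po <- grep("^relationship: *part_of ", block, value = TRUE)
        po <- sub(" *!.*$", "", sub("^relationship: *part_of *", "", po))
      }
      if (length(isa) || length(po)) {
        links[[id]] <- data.frame(
          child = id,
          parent = c(isa, po),
          relation = c(rep("is_a", length(isa)), rep("part_of", length(po))),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  keep <- !obsolete
  nodes <- data.frame(id = ids[keep], name = names_[keep], stringsAsFactors = FALSE)
  parents <- if (length(links)) do.call(rbind, links) else
    data.frame(child = character(), parent = character(), relation = character())
  # links pointing at obsolete or undeclared terms are a validation error
  dangling <- setdiff(parents$parent, nodes$id)
  if (length(dangling)) {
    stop_validation("is_a/part_of target(s) not declared as non-obsolete terms: ",
                    paste(utils::head(dangling, 5), collapse = ", "))
  }
  ontology_hierarchy(nodes, parents)
}

#' Parse a tree-number vocabulary TSV into a hierarchy
#'
#' Reads the TSV dialect used for the MEDIC disease vocabulary and the
#' chemical vocabulary: one row per term with explicit parent-id columns
#' and/or slash-delimited tree numbers. Parentage is the union of both
#' encodings; a tree number `A.B.C` makes the term whose tree number is
#' `A.B` a parent.
#'
#' @param path TSV file, `#` comment headers allowed, optionally gzipped.
#' @param namespace `"disease"` or `"chemical"` (identifier normalization).
#' @param column_map Named character vector mapping canonical fields
#'   (`id`, `name`, `parent_ids`, `tree_numbers`) to the file's column names.
#' @return An `ontology_hierarchy`.
#' @export
parse_tree_vocab <- function(path, namespace = c("disease", "chemical"),
                             column_map = c(id = "id", name = "name",
                                            parent_ids = "parent_ids",
                                            tree_numbers = "tree_numbers")) {
  namespace <- match.arg(namespace)
  df <- read_delim_commented(path)
  if (nrow(df) == 0L) {
    return(ontology_hierarchy(data.frame(id = character(), name = character())))
  }
  need <- column_map[["id"]]
  if (!need %in% names(df)) stop_format("missing mapped column: ", need)
  id <- normalize_identifier(df[[column_map[["id"]]]], namespace)
  nm <- if (column_map[["name"]] %in% names(df)) df[[column_map[["name"]]]] else id

  parent_ids <- if (!is.na(column_map["parent_ids"]) &&
                    column_map[["parent_ids"]] %in% names(df)) {
    split_multi(df[[column_map[["parent_ids"]]]])
  } else {
    rep(list(character()), nrow(df))
  }
  tree_numbers <- if (!is.na(column_map["tree_numbers"]) &&
                      column_map[["tree_numbers"]] %in% names(df)) {
    split_multi(df[[column_map[["tree_numbers"]]]])
  } else {
    rep(list(character()), nrow(df))
  }

  # explicit parent-id links
  links <- data.frame(child = rep(id, lengths(parent_ids)),
                      parent = unlist(parent_ids, use.names = FALSE),
                      stringsAsFactors = FALSE)
  if (nrow(links)) links$parent <- normalize_identifier(links$parent, namespace)
  links$relation <- rep("parent_id", nrow(links))

  # tree-number prefix links: owner of tree number sans last segment is parent
  tn_owner <- data.frame(tn = unlist(tree_numbers, use.names = FALSE),
                         id = rep(id, lengths(tree_numbers)),
                         stringsAsFactors = FALSE)
  if (nrow(tn_owner)) {
    parent_tn <- sub("[./][^./]+$", "", tn_owner$tn)
    has_parent <- parent_tn != tn_owner$tn
    idx <- match(parent_tn[has_parent], tn_owner$tn)
    ok <- !is.na(idx)
    tn_links <- data.frame(child = tn_owner$id[has_parent][ok],
                           parent = tn_owner$id[idx[ok]],
                           relation = "tree_number",
                           stringsAsFactors = FALSE)
    links <- rbind(links, tn_links[tn_links$child != tn_links$parent, ])
  }
  ontology_hierarchy(data.frame(id = id, name = nm, stringsAsFactors = FALSE),
                     unique(links))
}

#' Write a hierarchy in the tree-vocabulary TSV dialect
#'
#' Inverse of [parse_tree_vocab()] (explicit parent-id encoding only).
#' @param hierarchy An `ontology_hierarchy`.
#' @param path Output path.
#' @export
write_tree_vocab <- function(hierarchy, path) {
  pid <- split(hierarchy$parents$parent, factor(hierarchy$parents$child,
                                                levels = hierarchy$nodes$id))
  df <- data.frame(
    id = hierarchy$nodes$id,
    name = hierarchy$nodes$name,
    parent_ids = join_multi(pid),
    tree_numbers = "",
    stringsAsFactors = FALSE
  )
  df <- df[order(df$id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a hierarchy as a minimal OBO term file
#'
#' @inheritParams write_tree_vocab
#' @export
write_obo <- function(hierarchy, path) {
  ord <- order(hierarchy$nodes$id)
  ids <- hierarchy$nodes$id[ord]
  nms <- hierarchy$nodes$name[ord]
  isa <- split(hierarchy$parents$parent, factor(hierarchy$parents$child, levels = ids))
  out <- c("format-version: 1.2", "")
  blocks <- mapply(function(id, nm) {
    p <- sort(unique(isa[[id]]))
    c("[Term]", paste0("id: ", id), paste0("name: ", nm),
      if (length(p)) paste0("is_a: ", p), "")
  }, ids, nms, SIMPLIFY = FALSE)
  writeLines(c(out, unlist(blocks, use.names = FALSE)), path)
  invisible(path)
}
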