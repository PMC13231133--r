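# Seeded synthetic knowledge snapshots with planted, machine-checkable
# structure: event-coverage tiers, full tetramers, near-miss decoys (tuples
# missing exactly one of the five required edges), a multi-query shared
# gene-phenotype dimer block, and per-event disease sets with a prescribed
# intersection structure. Every planted fact is recorded in a ground-truth
# manifest so pipeline recoveries can be compared exactly.
#
# The generated pathway mirrors the shape of the autism AOP: six events (one
# MIE, four KEs, one AO) with the third key event as a bifurcated offshoot
# rejoining at the fourth. All identifiers are synthetic.

.edge_kinds <- c("chem_gene", "chem_phenotype", "chem_disease",
                 "gene_phenotype", "gene_disease")

#' Synthetic snapshot configuration
#'
#' Defaults encode the study conditions the pipeline is meant to reproduce:
#' coverage tiers with 12 six-event and 64 five-event chemicals (76 at five
#' or more) and lower tiers filling the total to 3,648 intersecting
#' chemicals; three tetramer query chemicals totalling 2,021 / 2,161 / 1,373
#' tetramers against one disease with 291 shared gene-phenotype dimers over
#' 136 genes and 53 phenotypes, of which six designated phenotypes cover 93
#' genes; and per-event disease sets of 149/619/55/471/842 with a 17-disease
#' core and 108 additional diseases when the smallest event is left out.
#'
#' @param seed Integer seed driving one explicit pseudo-random stream.
#' @param n_chemicals Chemical budget for coverage tiers plus background
#'   chemicals (planted tetramer/decoy/query chemicals are allocated
#'   separately).
#' @param coverage_tiers Named integer vector, names = event-coverage score
#'   (1..6), values = number of chemicals to plant at that score.
#' @param n_background_genes,n_background_phenotypes,n_background_diseases
#'   Sizes of the background entity pools used by random background edges.
#' @param anchor_subtree_size Descendant terms under each event's phenotype
#'   anchor (subsumption is exercised by annotating to random descendants).
#' @param extra_parent_prob Probability that a hierarchy node receives a
#'   second parent (exercises multi-parent closure; GO is a DAG and the
#'   disease vocabulary a poly-hierarchy).
#' @param background_density Named numeric vector in `[0, 1]` per relation
#'   kind: probability of each possible background edge. Zero (the default)
#'   makes planted recoveries exact.
#' @param n_planted_tetramers,n_decoys Planted full tetramers and near-miss
#'   decoys (each decoy omits exactly one of the five edges, cycling through
#'   the edge kinds).
#' @param article_geom_p Geometric parameter for per-edge article counts
#'   (each edge cites `1 + rgeom(article_geom_p)` synthetic articles).
#' @param dimer_plan `NULL`, or a list with `totals` (tetramer count per
#'   query chemical), `n_shared`, `n_shared_genes`, `n_shared_phenotypes`,
#'   `n_selected`, `selected_gene_union` describing the planted shared-dimer
#'   block.
#' @param event_disease_plan `NULL`, or a list with `sizes` (5 per-event
#'   disease-set sizes), `core`, `loo_extra` and `loo_event_index` (the
#'   event left out by the leave-one-out expansion).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chemicals = 3663L,
                             coverage_tiers = c(`6` = 12L, `5` = 64L, `4` = 222L,
                                                `3` = 450L, `2` = 900L, `1` = 1995L),
                             n_background_genes = 40L,
                             n_background_phenotypes = 60L,
                             n_background_diseases = 30L,
                             anchor_subtree_size = 4L,
                             extra_parent_prob = 0.1,
                             background_density = c(chem_gene = 0, chem_phenotype = 0,
                                                    chem_disease = 0, gene_phenotype = 0,
                                                    gene_disease = 0),
                             n_planted_tetramers = 50L,
                             n_decoys = 50L,
                             article_geom_p = 0.5,
                             dimer_plan = list(totals = c(2021L, 2161L, 1373L),
                                               n_shared = 291L,
                                               n_shared_genes = 136L,
                                               n_shared_phenotypes = 53L,
                                               n_selected = 6L,
                                               selected_gene_union = 93L),
                             event_disease_plan = list(sizes = c(149L, 619L, 55L,
                                                                 471L, 842L),
                                                       core = 17L,
                                                       loo_extra = 108L,
                                                       loo_event_index = 3L)) {
  tiers <- coverage_tiers[coverage_tiers > 0L]
  scores <- as.integer(names(tiers))
  if (any(is.na(scores)) || any(scores < 1L) || any(scores > 6L)) {
    stop_validation("coverage tier scores must be named 1..6")
  }
  if (sum(tiers) > n_chemicals) {
    stop_validation("infeasible config: coverage tiers (", sum(tiers),
                    ") exceed the chemical budget (", n_chemicals, ")")
  }
  dens <- background_density
  missing_kind <- setdiff(.edge_kinds, names(dens))
  dens[missing_kind] <- 0
  if (any(dens < 0 | dens > 1)) stop_validation("background densities must lie in [0, 1]")
  if (!is.null(dimer_plan)) {
    dp <- dimer_plan
    if (any(dp$totals < dp$n_shared)) {
      stop_validation("infeasible dimer plan: per-chemical totals below shared count")
    }
    n_ov <- min(2L * dp$n_selected, dp$selected_gene_union)
    if (dp$n_shared < dp$n_shared_genes || dp$n_shared < dp$n_shared_phenotypes ||
        dp$selected_gene_union > dp$n_shared_genes ||
        dp$n_selected > dp$n_shared_phenotypes ||
        dp$n_shared < dp$selected_gene_union + n_ov +
          (dp$n_shared_phenotypes - dp$n_selected)) {
      stop_validation("infeasible dimer plan: shared pairs cannot cover the gene/phenotype pools")
    }
  }
  if (!is.null(event_disease_plan)) {
    ep <- event_disease_plan
    if (length(ep$sizes) != 5L) stop_validation("event_disease_plan needs 5 sizes")
    priv <- ep$sizes - ep$core -
      ifelse(seq_along(ep$sizes) == ep$loo_event_index, 0L, ep$loo_extra)
    if (any(priv < 0L)) stop_validation("infeasible event_disease_plan sizes")
  }
  structure(list(seed = as.integer(seed), n_chemicals = as.integer(n_chemicals),
                 coverage_tiers = tiers,
                 n_background_genes = n_background_genes,
                 n_background_phenotypes = n_background_phenotypes,
                 n_background_diseases = n_background_diseases,
                 anchor_subtree_size = anchor_subtree_size,
                 extra_parent_prob = extra_parent_prob,
                 background_density = dens[.edge_kinds],
                 n_planted_tetramers = as.integer(n_planted_tetramers),
                 n_decoys = as.integer(n_decoys),
                 article_geom_p = article_geom_p,
                 dimer_plan = dimer_plan,
                 event_disease_plan = event_disease_plan),
            class = "synthetic_config")
}

# internal AOP constructor from frames (same structure load_aop_definitions builds)
#' @keywords internal
aop_from_frames <- function(aop_id, events, kers) {
  structure(list(
    aops = stats::setNames(list(structure(
      list(aop_id = aop_id, events = events, kers = kers),
      class = "aop_definition")), aop_id),
    events = events,
    components = data.frame(event_id = character(), term_id = character())
  ), class = "aop_set")
}

#' Generate a synthetic knowledge snapshot
#'
#' Emits a referentially consistent snapshot, the synthetic pathway and its
#' event mapping, and a ground-truth manifest recording every planted
#' structure. Identical configurations (same seed) generate identical
#' output; background edges may only ever add recoveries on top of the
#' manifest, never remove them, and any background edge that happens to
#' complete a decoy is recorded as a promotion.
#'
#' @param config A `synthetic_config`.
#' @return List with elements `snapshot` (`knowledge_snapshot`), `aop`
#'   (`aop_set`), `mapping` (`event_mapping`) and `manifest`.
#' @export
generate_snapshot <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_snapshot_impl(config))
}

#' @keywords internal
generate_snapshot_impl <- function(config) {
  counters <- new.env(parent = emptyenv())
  alloc <- function(key, fmt, n) {
    if (n == 0L) return(character())
    start <- if (is.null(counters[[key]])) 0L else counters[[key]]
    counters[[key]] <- start + as.integer(n)
    sprintf(fmt, start + seq_len(n))
  }
  new_phen <- function(n) alloc("phen", "GO:%07d", n)
  new_dis <- function(n) alloc("dis", "MESH:D%06d", n)
  new_chem <- function(n) alloc("chem", "MESH:C%06d", n)
  new_gene <- function(n) alloc("gene", "GENE:%d", n)

  edges <- stats::setNames(lapply(.edge_kinds, function(k) list()), .edge_kinds)
  add_edges <- function(kind, subject, object, evidence = NA_character_) {
    if (!length(subject)) return(invisible())
    edges[[kind]][[length(edges[[kind]]) + 1L]] <<- data.frame(
      subject_id = subject, object_id = object,
      direct_evidence = rep_len(evidence, length(subject)),
      stringsAsFactors = FALSE)
    invisible()
  }

  # random tree under `root` where node i attaches to an earlier node, plus
  # optional second parents (always to earlier nodes, so acyclicity holds)
  random_tree_links <- function(ids, root, extra_p) {
    n <- length(ids)
    if (!n) return(NULL)
    parent <- character(n)
    extra <- list()
    for (i in seq_len(n)) {
      pool <- c(root, ids[seq_len(i - 1L)])
      parent[i] <- pool[sample.int(length(pool), 1L)]
      if (length(pool) > 1L && stats::runif(1) < extra_p) {
        alt <- setdiff(pool, parent[i])
        extra[[length(extra) + 1L]] <- c(ids[i], alt[sample.int(length(alt), 1L)])
      }
    }
    links <- data.frame(child = ids, parent = parent, relation = "is_a")
    if (length(extra)) {
      ex <- do.call(rbind, extra)
      links <- rbind(links, data.frame(child = ex[, 1], parent = ex[, 2],
                                       relation = "is_a"))
    }
    links
  }
  flat_links <- function(ids, root) {
    if (!length(ids)) return(NULL)
    data.frame(child = ids, parent = root, relation = "is_a")
  }

  ## ---- phenotype hierarchy: root, five event anchors with subtrees, and a
  ## background branch holding every other phenotype
  ph_root <- new_phen(1L)
  anchors <- new_phen(5L)
  ph_links <- list(flat_links(anchors, ph_root))
  anchor_members <- list()
  for (e in 1:5) {
    sub <- new_phen(config$anchor_subtree_size)
    ph_links[[length(ph_links) + 1L]] <-
      random_tree_links(sub, anchors[e], config$extra_parent_prob)
    anchor_members[[e]] <- c(anchors[e], sub)
  }
  bg_branch <- new_phen(1L)
  ph_links[[length(ph_links) + 1L]] <- flat_links(bg_branch, ph_root)
  bg_phens <- new_phen(config$n_background_phenotypes)
  ph_links[[length(ph_links) + 1L]] <-
    random_tree_links(bg_phens, bg_branch, config$extra_parent_prob)

  ## ---- disease hierarchy: root, AO node with descendants, flat "other" branch
  d_root <- new_dis(1L)
  ao_node <- new_dis(1L)
  ao_desc <- new_dis(3L)
  other_branch <- new_dis(1L)
  d_links <- list(
    flat_links(c(ao_node, other_branch), d_root),
    random_tree_links(ao_desc, ao_node, config$extra_parent_prob)
  )
  ao_members <- c(ao_node, ao_desc)
  bg_dis <- new_dis(config$n_background_diseases)
  d_links[[length(d_links) + 1L]] <- flat_links(bg_dis, other_branch)

  ## ---- gene universe seeds: receptor-family genes mapped to the MIE
  mie_genes <- new_gene(3L)
  gene_symbols <- stats::setNames(paste0("NRX", 1:3), mie_genes)
  bg_genes <- new_gene(config$n_background_genes)
  gene_symbols[bg_genes] <- sprintf("BGS%04d", seq_along(bg_genes))

  events <- c("MIE:101", "KE:102", "KE:103", "KE:104", "KE:105", "AO:106")
  aop_events <- data.frame(
    event_id = events,
    event_type = c("MIE", "KE", "KE", "KE", "KE", "AO"),
    event_title = c("receptor antagonism (synthetic)",
                    "signaling cascade inhibition (synthetic)",
                    "receptor expression decrease (synthetic)",
                    "synaptic organization change (synthetic)",
                    "network function decrease (synthetic)",
                    "behavioral outcome (synthetic)"),
    stringsAsFactors = FALSE
  )
  kers <- data.frame(from = c("MIE:101", "KE:102", "KE:103", "KE:104", "KE:105"),
                     to = c("KE:102", "KE:104", "KE:104", "KE:105", "AO:106"),
                     stringsAsFactors = FALSE)
  aop <- aop_from_frames("AOP:900", aop_events, kers)
  mapping <- as_event_mapping(data.frame(
    event_id = c("MIE:101", "MIE:101", "MIE:101", "MIE:101",
                 "KE:102", "KE:103", "KE:104", "KE:105", "AO:106"),
    term_kind = c("gene", "gene", "gene_pattern", "phenotype",
                  "phenotype", "phenotype", "phenotype", "phenotype", "disease"),
    term = c(mie_genes[1], mie_genes[2], "NRX*", anchors[1],
             anchors[2], anchors[3], anchors[4], anchors[5], ao_node),
    evidence_filter = c(rep("", 8), "marker_mechanism"),
    stringsAsFactors = FALSE
  ))

  ## ---- coverage tiers: each tier-k chemical touches exactly k distinct
  ## events, via a random descendant of the event's anchor (subsumption), a
  ## mapped gene (MIE only, half the time), or a marker/mechanism disease
  ## edge into the AO subtree
  tiers <- config$coverage_tiers
  tier_rows <- list()
  for (s in names(tiers)) {
    k <- as.integer(s)
    m <- tiers[[s]]
    chems <- new_chem(m)
    for (i in seq_len(m)) {
      evs <- sort(sample.int(6L, k))
      for (e in evs) {
        if (e == 6L) {
          add_edges("chem_disease", chems[i],
                    ao_members[sample.int(length(ao_members), 1L)],
                    evidence = "marker_mechanism")
        } else if (e == 1L && stats::runif(1) < 0.5) {
          add_edges("chem_gene", chems[i],
                    mie_genes[sample.int(2L, 1L)])
        } else {
          mem <- anchor_members[[e]]
          add_edges("chem_phenotype", chems[i], mem[sample.int(length(mem), 1L)])
        }
      }
      tier_rows[[length(tier_rows) + 1L]] <-
        data.frame(chemical_id = chems[i], score = k,
                   events = paste(events[evs], collapse = "|"),
                   stringsAsFactors = FALSE)
    }
  }
  bg_chems <- new_chem(config$n_chemicals - sum(tiers))

  ## ---- per-event disease blocks: one dedicated chemical and gene per
  ## event; disease sets share a core across all five events and an extra
  ## block absent from the left-out event
  ev_plan <- NULL
  if (!is.null(config$event_disease_plan)) {
    ep <- config$event_disease_plan
    core_dis <- new_dis(ep$core)
    loo_dis <- new_dis(ep$loo_extra)
    d_links[[length(d_links) + 1L]] <- flat_links(c(core_dis, loo_dis), other_branch)
    ev_chems <- new_chem(5L)
    ev_genes <- new_gene(5L)
    gene_symbols[ev_genes] <- sprintf("EVG%d", 1:5)
    sets <- list()
    for (e in 1:5) {
      n_priv <- ep$sizes[e] - ep$core - if (e == ep$loo_event_index) 0L else ep$loo_extra
      priv <- new_dis(n_priv)
      d_links[[length(d_links) + 1L]] <- flat_links(priv, other_branch)
      set_e <- c(core_dis, if (e != ep$loo_event_index) loo_dis, priv)
      sets[[events[e]]] <- set_e
      add_edges("chem_gene", ev_chems[e], ev_genes[e])
      add_edges("chem_phenotype", ev_chems[e], anchors[e])
      add_edges("gene_phenotype", ev_genes[e], anchors[e])
      add_edges("chem_disease", rep(ev_chems[e], length(set_e)), set_e,
                evidence = "marker_mechanism")
      add_edges("gene_disease", rep(ev_genes[e], length(set_e)), set_e)
      tier_rows[[length(tier_rows) + 1L]] <-
        data.frame(chemical_id = ev_chems[e], score = 1L,
                   events = events[e], stringsAsFactors = FALSE)
    }
    ev_plan <- list(sets = sets, core = core_dis, loo_extra = loo_dis,
                    loo_event = events[ep$loo_event_index],
                    chemicals = ev_chems, genes = ev_genes)
  }

  ## ---- shared-dimer block: query chemicals sharing exactly the planted
  ## gene-phenotype pairs, padded with chemical-private pairs to each total
  dimer <- NULL
  if (!is.null(config$dimer_plan)) {
    dp <- config$dimer_plan
    q_chems <- new_chem(length(dp$totals))
    d_genes <- new_gene(dp$n_shared_genes)
    gene_symbols[d_genes] <- sprintf("DMG%04d", seq_along(d_genes))
    d_phens <- new_phen(dp$n_shared_phenotypes)
    ph_links[[length(ph_links) + 1L]] <- flat_links(d_phens, bg_branch)
    dimer_dis <- new_dis(1L)
    d_links[[length(d_links) + 1L]] <- flat_links(dimer_dis, other_branch)

    sel_ph <- d_phens[seq_len(dp$n_selected)]
    sel_gene <- d_genes[seq_len(dp$selected_gene_union)]
    # pairs on the selected phenotypes use exactly the selected genes
    p1 <- data.frame(gene_id = sel_gene,
                     phenotype_id = rep_len(sel_ph, length(sel_gene)))
    # overlap pairs: re-annotate the first genes to the next phenotype in the
    # cycle so consecutive selected phenotypes share genes (the gene union is
    # unchanged; these overlaps are what the candidate-pathway edges carry)
    n_ov <- min(2L * dp$n_selected, length(sel_gene))
    p_ov <- if (dp$n_selected > 1L && n_ov > 0L) {
      data.frame(gene_id = sel_gene[seq_len(n_ov)],
                 phenotype_id = sel_ph[(seq_len(n_ov) %% dp$n_selected) + 1L])
    } else p1[0, ]
    p1 <- rbind(p1, p_ov)
    rest_ph <- d_phens[-seq_len(dp$n_selected)]
    rest_gene <- d_genes[-seq_len(dp$selected_gene_union)]
    # cover every remaining phenotype and gene
    p2 <- data.frame(gene_id = rep_len(if (length(rest_gene)) rest_gene else d_genes,
                                       length(rest_ph)),
                     phenotype_id = rest_ph)
    n_more <- dp$n_shared - nrow(p1) - nrow(p2)
    if (n_more < 0L) stop_validation("infeasible dimer plan: n_shared too small")
    grid_n <- length(rest_ph) * dp$n_shared_genes
    existing <- paste(p2$gene_id, p2$phenotype_id)
    pick <- sample.int(grid_n, min(grid_n, n_more + nrow(p2)))
    g_idx <- ((pick - 1L) %% dp$n_shared_genes) + 1L
    ph_idx <- ((pick - 1L) %/% dp$n_shared_genes) + 1L
    p3 <- data.frame(gene_id = d_genes[g_idx], phenotype_id = rest_ph[ph_idx])
    p3 <- p3[!paste(p3$gene_id, p3$phenotype_id) %in% existing, , drop = FALSE]
    p3 <- utils::head(p3, n_more)
    if (nrow(p3) < n_more) stop_validation("infeasible dimer plan: pair grid exhausted")
    shared_pairs <- rbind(p1, p2, p3)
    rownames(shared_pairs) <- NULL

    add_edges("gene_phenotype", shared_pairs$gene_id, shared_pairs$phenotype_id)
    add_edges("gene_disease", d_genes, rep(dimer_dis, length(d_genes)))
    priv_pairs <- list()
    for (q in seq_along(q_chems)) {
      n_priv <- dp$totals[q] - dp$n_shared
      pp <- new_phen(n_priv)
      ph_links[[length(ph_links) + 1L]] <- flat_links(pp, bg_branch)
      pg <- d_genes[rep_len(seq_along(d_genes), n_priv)]
      priv_pairs[[q]] <- data.frame(gene_id = pg, phenotype_id = pp,
                                    stringsAsFactors = FALSE)
      add_edges("gene_phenotype", pg, pp)
      used_g <- unique(c(shared_pairs$gene_id, pg))
      used_p <- unique(c(shared_pairs$phenotype_id, pp))
      add_edges("chem_gene", rep(q_chems[q], length(used_g)), used_g)
      add_edges("chem_phenotype", rep(q_chems[q], length(used_p)), used_p)
      add_edges("chem_disease", q_chems[q], dimer_dis, evidence = "marker_mechanism")
    }
    dimer <- list(chemicals = q_chems, disease = dimer_dis,
                  shared_pairs = shared_pairs, private_pairs = priv_pairs,
                  selected_phenotypes = sel_ph,
                  selected_gene_union = length(sel_gene),
                  totals = dp$totals)
  }

  ## ---- planted tetramers (entity-disjoint) and near-miss decoys (one
  ## named edge omitted, cycling through the five kinds)
  plant_block <- function(n, omit = NULL) {
    if (!n) {
      return(data.frame(chemical_id = character(), gene_id = character(),
                        phenotype_id = character(), disease_id = character()))
    }
    ch <- new_chem(n); g <- new_gene(n); p <- new_phen(n); d <- new_dis(n)
    gene_symbols[g] <<- sprintf("PL%05d", seq_along(g) +
                                  if (is.null(omit)) 0L else 50000L)
    ph_links[[length(ph_links) + 1L]] <<- flat_links(p, bg_branch)
    d_links[[length(d_links) + 1L]] <<- flat_links(d, other_branch)
    keep <- function(kind, i) is.null(omit) || omit[i] != kind
    for (i in seq_len(n)) {
      if (keep("chem_gene", i)) add_edges("chem_gene", ch[i], g[i])
      if (keep("chem_phenotype", i)) add_edges("chem_phenotype", ch[i], p[i])
      if (keep("chem_disease", i)) add_edges("chem_disease", ch[i], d[i],
                                             evidence = "marker_mechanism")
      if (keep("gene_phenotype", i)) add_edges("gene_phenotype", g[i], p[i])
      if (keep("gene_disease", i)) add_edges("gene_disease", g[i], d[i])
    }
    data.frame(chemical_id = ch, gene_id = g, phenotype_id = p, disease_id = d,
               stringsAsFactors = FALSE)
  }
  planted <- plant_block(config$n_planted_tetramers)
  omit <- rep_len(.edge_kinds, config$n_decoys)
  decoys <- plant_block(config$n_decoys, omit = omit)
  if (nrow(decoys)) decoys$missing_edge <- omit

  ## ---- background edges
  dens <- config$background_density
  rand_edges <- function(kind, subjects, objects, evidence = NA_character_) {
    p <- dens[[kind]]
    if (is.na(p) || p <= 0 || !length(subjects) || !length(objects)) return(invisible())
    n_pairs <- length(subjects) * length(objects)
    n_draw <- stats::rbinom(1L, n_pairs, p)
    if (!n_draw) return(invisible())
    pick <- sample.int(n_pairs, n_draw)
    s_idx <- ((pick - 1L) %% length(subjects)) + 1L
    o_idx <- ((pick - 1L) %/% length(subjects)) + 1L
    ev <- if (kind == "chem_disease") {
      sample(c("marker_mechanism", "therapeutic"), n_draw, replace = TRUE)
    } else evidence
    add_edges(kind, subjects[s_idx], objects[o_idx], evidence = ev)
  }
  all_anchor_phens <- unlist(anchor_members, use.names = FALSE)
  rand_edges("chem_gene", bg_chems, bg_genes)
  rand_edges("chem_phenotype", bg_chems, c(bg_phens, all_anchor_phens))
  rand_edges("chem_disease", bg_chems, c(bg_dis, ao_members))
  rand_edges("gene_phenotype", bg_genes, bg_phens)
  rand_edges("gene_disease", bg_genes, bg_dis)

  ## ---- finalize tables: articles per edge, hierarchies, snapshot
  rel <- lapply(edges, function(lst) {
    if (!length(lst)) return(NULL)
    do.call(rbind, lst)
  })
  n_edges_total <- sum(vapply(rel, function(r) if (is.null(r)) 0L else nrow(r), integer(1)))
  counts <- 1L + stats::rgeom(n_edges_total, config$article_geom_p)
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  art_ids <- sprintf("A%07d", seq_len(ends[length(ends)]))
  offset <- 0L
  relations <- list()
  for (k in .edge_kinds) {
    r <- rel[[k]]
    if (is.null(r)) { relations[[k]] <- NULL; next }
    idx <- offset + seq_len(nrow(r))
    r$relation_kind <- k
    r$organism_id <- NA_character_
    r$support_articles <- lapply(idx, function(i) art_ids[starts[i]:ends[i]])
    offset <- offset + nrow(r)
    relations[[k]] <- r
  }

  name_for <- function(ids, what) paste0("synthetic ", what, " ", seq_along(ids))
  ph_nodes <- data.frame(id = sprintf("GO:%07d", seq_len(counters$phen)))
  ph_nodes$name <- name_for(ph_nodes$id, "phenotype")
  d_nodes <- data.frame(id = sprintf("MESH:D%06d", seq_len(counters$dis)))
  d_nodes$name <- name_for(d_nodes$id, "disease")

  all_chems <- sprintf("MESH:C%06d", seq_len(counters$chem))
  c_root <- "MESH:C900001"; cat_a <- "MESH:C900002"; cat_b <- "MESH:C900003"
  c_nodes <- data.frame(id = c(c_root, cat_a, cat_b, all_chems),
                        name = c("chemical root", "category A", "category B",
                                 name_for(all_chems, "chemical")))
  c_links <- rbind(
    data.frame(child = c(cat_a, cat_b), parent = c_root, relation = "is_a"),
    data.frame(child = all_chems,
               parent = ifelse(seq_along(all_chems) %% 2L == 1L, cat_a, cat_b),
               relation = "is_a")
  )

  all_genes <- sprintf("GENE:%d", seq_len(counters$gene))
  sym <- gene_symbols[all_genes]
  sym[is.na(sym)] <- sprintf("ZZX%05d", which(is.na(sym)))
  gene_universe <- data.frame(gene_id = all_genes, gene_symbol = unname(sym),
                              stringsAsFactors = FALSE)

  snapshot <- knowledge_snapshot(
    relations = relations,
    phenotype_hierarchy = ontology_hierarchy(ph_nodes, do.call(rbind, ph_links)),
    disease_hierarchy = ontology_hierarchy(d_nodes, do.call(rbind, d_links)),
    chemical_hierarchy = ontology_hierarchy(c_nodes, c_links),
    gene_universe = gene_universe,
    snapshot_label = paste0("synthetic-seed-", config$seed),
    strict = TRUE
  )

  # decoy-promotion audit: a background edge may have completed a decoy
  promotions <- character()
  if (nrow(decoys)) {
    for (i in seq_len(nrow(decoys))) {
      kind <- decoys$missing_edge[i]
      r <- snapshot$relations[[kind]]
      s <- switch(kind, chem_gene = , chem_phenotype = , chem_disease = decoys$chemical_id[i],
                  decoys$gene_id[i])
      o <- switch(kind, chem_gene = decoys$gene_id[i],
                  chem_phenotype = , gene_phenotype = decoys$phenotype_id[i],
                  decoys$disease_id[i])
      if (any(r$subject_id == s & r$object_id == o)) {
        promotions <- c(promotions, i)
      }
    }
  }

  tiers_df <- if (length(tier_rows)) do.call(rbind, tier_rows) else
    data.frame(chemical_id = character(), score = integer(), events = character())
  manifest <- list(
    seed = config$seed, events = events, mapping = mapping,
    tiers = tiers_df,
    tetramers = planted, decoys = decoys,
    promoted_decoys = as.integer(promotions),
    dimer_plan = dimer, event_disease_plan = ev_plan,
    category_parents = c(cat_a, cat_b)
  )
  list(snapshot = snapshot, aop = aop, mapping = mapping, manifest = manifest)
}

#' Write a generated synthetic dataset to disk
#'
#' Emits the same file dialects the loaders read: the canonical snapshot
#' serialization, the AOP event/KER TSV, the event-mapping TSV, and the
#' ground-truth manifest as structured TSVs.
#'
#' @param generated Output of [generate_snapshot()].
#' @param dir Output directory.
#' @export
write_synthetic <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_snapshot(generated$snapshot, dir)
  aop <- generated$aop$aops[[1]]
  down <- stats::setNames(lapply(aop$events$event_id, function(e) {
    aop$kers$to[aop$kers$from == e]
  }), aop$events$event_id)
  aop_df <- data.frame(aop_id = aop$aop_id, aop$events,
                       downstream_event_ids = join_multi(down),
                       stringsAsFactors = FALSE)
  utils::write.table(aop_df, file.path(dir, "aop.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(generated$mapping),
                     file.path(dir, "event_mapping.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(generated$manifest$tiers, file.path(dir, "manifest_tiers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(generated$manifest$tetramers,
                     file.path(dir, "manifest_tetramers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(generated$manifest$decoys, file.path(dir, "manifest_decoys.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
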