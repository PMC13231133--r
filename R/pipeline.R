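# End-to-end pipeline: chemical-event coverage and ranking, tetramer
# enumeration with shared-dimer discovery and chord export, candidate-AOP
# construction, and disease-network intersection — each stage written as TSV
# under an output directory together with a run manifest.

#' Run the full linked analysis
#'
#' Chains the four analysis stages over either a synthetic snapshot (from a
#' `synthetic_config`) or a snapshot directory on disk — exactly one of the
#' two must be given. Every output is regenerated deterministically from the
#' configuration and seed; the run manifest records per-stage entity counts
#' and input digests.
#'
#' @param config A list with fields:
#'   * `synthetic`: a [synthetic_config()] (exclusive with `snapshot_dir`);
#'   * `snapshot_dir`: directory holding a canonical snapshot serialization,
#'     with `aop_path` and `mapping_path` naming the pathway and
#'     event-mapping TSVs (defaults: `aop.tsv`, `event_mapping.tsv` inside
#'     `snapshot_dir`);
#'   * `outdir`: output directory (required);
#'   * `min_score`: ranking threshold (default 5);
#'   * `query_chemicals`, `query_disease`: tetramer-stage query (defaults:
#'     the generator's planted query block when synthetic);
#'   * `selected_phenotypes`, `levels`: phenotypes and biological levels for
#'     candidate-AOP construction (defaults: the planted selection);
#'   * `outcome`: terminal disease of the candidate AOP.
#' @return Report bundle (list) with the per-stage objects and `counts`.
#' @export
run_full_analysis <- function(config) {
  has_syn <- !is.null(config$synthetic)
  has_dir <- !is.null(config$snapshot_dir)
  if (has_syn == has_dir) {
    stop_validation("config must contain exactly one of 'synthetic' or 'snapshot_dir'")
  }
  if (is.null(config$outdir)) stop_validation("config$outdir is required")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(name, conditionMessage(e)), file.path(outdir, "FAILED"))
      stop(errorCondition(paste0("stage '", name, "' failed: ", conditionMessage(e)),
                          class = c("aoplink_stage_error", "aoplink_error")))
    })
  }

  manifest <- NULL
  digests <- character()
  if (has_syn) {
    gen <- stage("load", generate_snapshot(config$synthetic))
    snapshot <- gen$snapshot; aop <- gen$aop; mapping <- gen$mapping
    manifest <- gen$manifest
    digests <- c(synthetic_seed = as.character(config$synthetic$seed))
  } else {
    snapshot <- stage("load", read_snapshot(config$snapshot_dir))
    aop_path <- config$aop_path %||% file.path(config$snapshot_dir, "aop.tsv")
    mapping_path <- config$mapping_path %||% file.path(config$snapshot_dir, "event_mapping.tsv")
    aop <- stage("load", load_aop_definitions(aop_path, config$event_component_path))
    mapping <- stage("load", load_event_mapping(mapping_path))
    inputs <- c(list.files(config$snapshot_dir, full.names = TRUE), aop_path, mapping_path)
    digests <- tools::md5sum(unique(inputs))
  }
  target_aop <- if (length(aop$aops) == 1L) aop$aops[[1]] else
    aop$aops[[config$aop_id %||% names(aop$aops)[1]]]
  counts <- list()

  ## stage 1 — coverage and ranking
  coverage <- stage("coverage", event_coverage(snapshot, mapping, target_aop))
  min_score <- config$min_score %||% 5L
  ranked <- stage("coverage", rank_chemicals(coverage, min_score))
  write_coverage(coverage, file.path(outdir, "coverage.tsv"), min_score = 1L)
  utils::write.table(ranked, file.path(outdir, "ranked.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts$n_chemicals <- length(coverage$chemicals)
  counts$n_ranked <- nrow(ranked)
  counts$n_top_tier <- sum(coverage$score == length(coverage$events))

  ## stage 2 — tetramers, shared dimers, chord export
  query_chems <- config$query_chemicals %||% manifest$dimer_plan$chemicals
  query_disease <- config$query_disease %||% manifest$dimer_plan$disease
  tetramer_sets <- NULL; shared <- NULL; restricted <- NULL
  if (length(query_chems) >= 2L) {
    tetramer_sets <- stage("tetramers", lapply(query_chems, function(ch) {
      enumerate_tetramers(snapshot, chemical = ch, disease = query_disease)
    }))
    names(tetramer_sets) <- query_chems
    for (ch in query_chems) {
      write_tetramers(tetramer_sets[[ch]],
                      file.path(outdir, paste0("tetramers_", gsub(":", "_", ch), ".csv")))
    }
    shared <- stage("dimers", shared_dimers(tetramer_sets))
    utils::write.table(shared$dimers, file.path(outdir, "shared_dimers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    restricted <- stage("dimers", do.call(rbind, lapply(tetramer_sets,
                                                        restrict_to_dimers,
                                                        dimers = shared$dimers)))
    if (nrow(restricted)) {
      write_chord(stage("dimers", chord_data(restricted)),
                  file.path(outdir, "chord.txt"))
    }
    counts$n_tetramers <- vapply(tetramer_sets, nrow, integer(1))
    counts$n_shared_dimers <- nrow(shared$dimers)
    counts$n_shared_genes <- nrow(shared$gene_tally)
    counts$n_shared_phenotypes <- nrow(shared$phenotype_tally)
  }

  ## stage 3 — candidate AOP construction over the shared-dimer tetramers
  candidate <- NULL
  sel <- config$selected_phenotypes %||% manifest$dimer_plan$selected_phenotypes
  if (!is.null(restricted) && length(sel)) {
    levels <- config$levels %||%
      rep_len(c("molecular", "cellular", "system", "behavioral"), length(sel))
    outcome <- config$outcome %||% query_disease %||% "MESH:D000000"
    gs <- stage("build-aop", phenotype_gene_sets(restricted, sel))
    candidate <- stage("build-aop", assemble_aop_graph(
      stressors = query_chems,
      phenotypes = data.frame(phenotype_id = sel, level = levels),
      gene_sets = gs$gene_sets,
      outcome = outcome))
    write_aop_candidate(candidate, file.path(outdir, "aop_candidate.txt"))
    write_aop_graphml(candidate, file.path(outdir, "aop_candidate.graphml"))
    counts$n_selected_genes <- length(unique(unlist(gs$gene_sets)))
    counts$n_candidate_edges <- nrow(candidate$edges)
  }

  ## stage 4 — per-event disease sets, Venn regions, leave-one-out, related AOPs
  mech_events <- target_aop$events$event_id[target_aop$events$event_type != "AO"]
  mech_events <- intersect(mech_events, unique(mapping$event_id))
  disease_sets <- NULL; venn <- NULL; loo <- NULL
  if (length(mech_events) >= 2L) {
    disease_sets <- stage("disease-net", stats::setNames(lapply(mech_events, function(e) {
      diseases_for_event(snapshot, mapping, e)
    }), mech_events))
    venn <- stage("disease-net", venn_cells(disease_sets))
    write_venn(venn, file.path(outdir, "venn_regions.tsv"))
    if (length(disease_sets) >= 3L) {
      drop <- names(disease_sets)[which.min(lengths(disease_sets))]
      loo <- stage("disease-net", core_and_loo(disease_sets, drop))
      utils::write.table(
        data.frame(set = c(rep("core", length(loo$core)),
                           rep("additional", length(loo$additional))),
                   disease_id = c(loo$core, loo$additional)),
        file.path(outdir, "disease_core.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      counts$loo_dropped <- drop
    }
    counts$n_event_diseases <- lengths(disease_sets)
    counts$n_core_diseases <- length(venn$core)
    if (!is.null(loo)) counts$n_loo_additional <- length(loo$additional)
  }
  related <- stage("disease-net", related_aops(aop, mech_events))
  utils::write.table(related, file.path(outdir, "related_aops.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  run_manifest <- data.frame(
    key = c("snapshot_label", "seed",
            paste0("digest.", names(digests)),
            paste0("count.", names(unlist(counts)))),
    value = c(snapshot$snapshot_label,
              as.character(config$synthetic$seed %||% NA),
              unname(digests), as.character(unlist(counts))),
    stringsAsFactors = FALSE
  )
  utils::write.table(run_manifest, file.path(outdir, "run_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(snapshot = snapshot, coverage = coverage, ranked = ranked,
                 tetramer_sets = tetramer_sets, shared = shared,
                 candidate = candidate, disease_sets = disease_sets,
                 venn = venn, loo = loo, related = related,
                 manifest = manifest, counts = counts, outdir = outdir))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
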