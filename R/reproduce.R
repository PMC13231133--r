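# Reproduction of the deposited supplementary analyses from local copies of
# the four extended-data workbooks (chemical-by-event coverage plus the
# three chemical-specific tetramer exports). The workbooks are not bundled:
# they must be downloaded separately and pointed to by directory.

# guess an identifier column by name, falling back to a position
#' @keywords internal
guess_col <- function(nms, patterns, fallback) {
  for (p in patterns) {
    hit <- grep(p, nms, ignore.case = TRUE, value = TRUE)
    if (length(hit)) return(hit[1])
  }
  nms[fallback]
}

#' Recompute the supplementary-table analyses
#'
#' From a directory holding the four deposited workbooks — the
#' chemical-by-event coverage table (`Table S1.xlsx`) and the three tetramer
#' exports for bisphenol A, particulate matter and valproic acid
#' (`Table S2.xlsx` .. `Table S4.xlsx`) — recomputes: the distinct-chemical
#' total and the five-or-more / all-six coverage tiers; per-event chemical
#' counts; the three tetramer row counts; the shared gene-phenotype dimers
#' with their gene and phenotype counts; and the gene-set union of the six
#' phenotypes selected for pathway construction.
#'
#' Identifier columns are guessed by name (`*ChemicalID*`, `*GeneSymbol*`,
#' `*PhenotypeID*`, `*DiseaseID*`, case-insensitive) with positional
#' fallbacks, since the deposited workbooks carry display names alongside
#' accessions.
#'
#' @param dir Directory containing the four `.xlsx` files.
#' @param files Workbook file names, in order S1..S4.
#' @param selected_phenotypes The six phenotype accessions carried into
#'   pathway construction (defaults: oxidative stress response, glutathione
#'   metabolism, lipid metabolism, inflammatory response, social behavior,
#'   locomotory behavior).
#' @return List with `coverage` (a `coverage_matrix`), `tetramer_counts`,
#'   `shared` (from [shared_dimers()]), `n_unique_chemicals`,
#'   `n_five_plus`, `n_all_six`, `per_event_counts`,
#'   `selected_gene_union`.
#' @export
reproduce_supplementary <- function(dir,
                                    files = c("Table S1.xlsx", "Table S2.xlsx",
                                              "Table S3.xlsx", "Table S4.xlsx"),
                                    selected_phenotypes = c(
                                      "GO:0006979", "GO:0006749", "GO:0006629",
                                      "GO:0006954", "GO:0035176", "GO:0007626")) {
  paths <- file.path(dir, files)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop_format("supplementary workbook(s) not found: ",
                paste(missing, collapse = ", "),
                " — download the extended data and point 'dir' at it")
  }
  coverage <- read_coverage_table(paths[1])
  tet <- lapply(paths[2:4], function(p) {
    nms <- if (grepl("\\.xlsx$", p, ignore.case = TRUE)) {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop_format("reading xlsx requires the 'readxl' package")
      }
      names(readxl::read_excel(p, n_max = 0))
    } else {
      names(read_delim_commented(p))
    }
    cmap <- c(
      chemical_id = guess_col(nms, c("chemical.*id", "^chemical"), 1L),
      gene_id = guess_col(nms, c("gene.*symbol", "gene.*id", "^gene"), 2L),
      phenotype_id = guess_col(nms, c("phenotype.*id", "GO.?ID", "^phenotype"), 3L),
      disease_id = guess_col(nms, c("disease.*id", "^disease"), 4L))
    load_tetramer_export(p, cmap, gene_as_symbol = TRUE)
  })
  shared <- shared_dimers(tet)
  restricted <- do.call(rbind, lapply(tet, restrict_to_dimers,
                                      dimers = shared$dimers))
  sel_union <- phenotype_gene_sets(
    restricted[restricted$phenotype_id %in% selected_phenotypes, , drop = FALSE],
    selected_phenotypes)
  list(
    coverage = coverage,
    n_unique_chemicals = length(coverage$chemicals),
    n_five_plus = sum(coverage$score >= 5L),
    n_all_six = sum(coverage$score == length(coverage$events)),
    per_event_counts = colSums(coverage$incidence),
    tetramer_counts = vapply(tet, nrow, integer(1)),
    shared = shared,
    n_shared_dimers = nrow(shared$dimers),
    n_shared_genes = nrow(shared$gene_tally),
    n_shared_phenotypes = nrow(shared$phenotype_tally),
    selected_gene_union = length(unique(unlist(sel_union$gene_sets)))
  )
}

#' Directory expected to hold the deposited supplementary workbooks
#'
#' Resolution order: option `aoplink.supplementary_dir`, then environment
#' variable `AOPLINK_SUPPLEMENTARY_DIR`, then `supplementary/` under the
#' working directory.
#' @return A path (possibly non-existent; callers check).
#' @export
supplementary_dir <- function() {
  getOption("aoplink.supplementary_dir",
            default = {
              env <- Sys.getenv("AOPLINK_SUPPLEMENTARY_DIR")
              if (nzchar(env)) env else file.path(getwd(), "supplementary")
            })
}
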