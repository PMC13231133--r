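# Identifier normalization and gene-symbol pattern expansion.
#
# Canonical identifier form is an upper-case namespace prefix joined by a
# colon: "MESH:D001321", "GO:0006979", "GENE:2099", "OMIM:209850". Source
# files mix prefixed and bare forms; bare identifiers are prefixed using the
# declared namespace of their column.

.id_namespaces <- c("chemical", "gene", "phenotype", "disease", "article")

#' Normalize a raw identifier into canonical prefixed form
#'
#' @param raw Character vector of raw identifiers (bare or prefixed, any case).
#' @param namespace One of `"chemical"`, `"gene"`, `"phenotype"`, `"disease"`,
#'   `"article"`. Chemicals and diseases live in the MeSH namespace (diseases
#'   may also be OMIM); phenotypes are GO accessions (`GO:` + 7 digits); genes
#'   are numeric NCBI gene identifiers prefixed `GENE:`.
#' @return Character vector of canonical identifiers. Normalization is
#'   idempotent: applying it to its own output is a no-op.
#' @examples
#' normalize_identifier("d001321", "disease")   # "MESH:D001321"
#' normalize_identifier("GO:0006979", "phenotype")
#' @export
normalize_identifier <- function(raw, namespace) {
  namespace <- match.arg(namespace, .id_namespaces)
  if (any(is.na(raw) | !nzchar(trimws(raw)))) {
    stop_validation("empty identifier in namespace '", namespace, "'")
  }
  x <- toupper(trimws(raw))
  out <- switch(namespace,
    phenotype = {
      bare <- sub("^GO:", "", x)
      bad <- !grepl("^\\d{7}$", bare)
      if (any(bad)) {
        stop_validation(
          "malformed GO identifier(s): ",
          paste(utils::head(raw[bad], 5), collapse = ", ")
        )
      }
      paste0("GO:", bare)
    },
    gene = {
      bare <- sub("^GENE:", "", x)
      bad <- !grepl("^\\d+$", bare)
      if (any(bad)) {
        stop_validation(
          "malformed gene identifier(s) (numeric NCBI id expected): ",
          paste(utils::head(raw[bad], 5), collapse = ", ")
        )
      }
      paste0("GENE:", bare)
    },
    disease = ,
    chemical = {
      bare <- sub("^(MESH|OMIM):", "", x)
      is_omim <- grepl("^OMIM:", x) | (namespace == "disease" & grepl("^\\d+$", bare))
      bad <- !is_omim & !grepl("^[CD]\\d{6,9}$", bare)
      bad <- bad | (is_omim & !grepl("^\\d+$", bare))
      if (any(bad)) {
        stop_validation(
          "malformed ", namespace, " identifier(s): ",
          paste(utils::head(raw[bad], 5), collapse = ", ")
        )
      }
      ifelse(is_omim, paste0("OMIM:", bare), paste0("MESH:", bare))
    },
    article = x
  )
  out
}

#' Expand a gene-symbol pattern over a gene universe
#'
#' Patterns are either a literal symbol (matching exactly that symbol,
#' case-insensitively) or a prefix wildcard ending in `*` (e.g. `"GRIN*"`),
#' matching every symbol with that prefix. A lone `*` is rejected: an
#' unbounded match is never meaningful. An exclusion list reproduces, as
#' declarative configuration, the manual vetting step by which off-family
#' symbols caught by a wildcard are removed.
#'
#' @param pattern Single symbol or prefix pattern ending in `*`.
#' @param gene_universe Data frame with columns `gene_id`, `gene_symbol`.
#' @param exclude Character vector of symbols to drop from the match.
#' @return Character vector of canonical gene ids (sorted).
#' @examples
#' uni <- data.frame(gene_id = c("GENE:1", "GENE:2", "GENE:3"),
#'                   gene_symbol = c("GRIN1", "GRIN2A", "ESR1"))
#' expand_gene_pattern("GRIN*", uni)
#' @export
expand_gene_pattern <- function(pattern, gene_universe, exclude = character()) {
  if (length(pattern) != 1L || is.na(pattern) || !nzchar(trimws(pattern))) {
    stop_validation("gene pattern must be a non-empty string")
  }
  pattern <- trimws(pattern)
  if (pattern == "*") {
    stop_validation("a lone '*' gene pattern is not allowed (unbounded match)")
  }
  sym <- toupper(gene_universe$gene_symbol)
  keep <- if (endsWith(pattern, "*")) {
    prefix <- toupper(substr(pattern, 1L, nchar(pattern) - 1L))
    startsWith(sym, prefix)
  } else {
    sym == toupper(pattern)
  }
  if (length(exclude)) keep <- keep & !(sym %in% toupper(exclude))
  sort(unique(gene_universe$gene_id[keep]))
}

#' @keywords internal
is_gene_pattern <- function(term) {
  grepl("\\*$", term)
}
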