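# Internal helpers shared across modules.

#' @keywords internal
stop_validation <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("aoplink_validation_error", "aoplink_error")))
}

#' @keywords internal
stop_format <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("aoplink_format_error", "aoplink_error")))
}

#' @keywords internal
stop_lookup <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("aoplink_lookup_error", "aoplink_error")))
}

# Gzip is detected from the two magic bytes, not the file extension:
# bulk downloads circulate under both names.
#' @keywords internal
is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

#' @keywords internal
open_text <- function(path) {
  if (is_gzip(path)) gzfile(path, "rt") else file(path, "rt")
}

# Read a TSV/CSV with leading '#' commentary, returning a data.frame of
# character columns. Delimiter is sniffed from the header line.
#' @keywords internal
read_delim_commented <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame())
  }
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  utils::read.table(
    text = lines, sep = sep, header = TRUE, quote = "\"",
    colClasses = "character", check.names = FALSE,
    stringsAsFactors = FALSE, comment.char = "", na.strings = NULL
  )
}

#' @keywords internal
split_multi <- function(x, sep = "|") {
  out <- strsplit(ifelse(is.na(x), "", x), sep, fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

#' @keywords internal
join_multi <- function(x, sep = "|") {
  vapply(x, function(v) paste(sort(unique(v)), collapse = sep), character(1))
}

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds one explicit pseudo-random stream for the expression and restores the
#' caller's RNG state afterwards, so generators never leak global randomness.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
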