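# Adverse outcome pathway definitions: typed event graphs (MIE/KE/AO nodes,
# KER edges) plus the event -> ontology-term component mapping, and the
# cross-AOP event-sharing query.

.event_types <- c("MIE", "KE", "AO")

#' Load AOP definitions and event components
#'
#' `aop_path` is a TSV with one row per (AOP, event) membership: columns
#' `aop_id`, `event_id`, `event_type` (MIE/KE/AO), `event_title`, and
#' `downstream_event_ids` — a pipe-separated list of the event's KER targets
#' within that AOP (empty for terminal events). `event_component_path` is a
#' TSV in the event-component dialect with columns `event_id`, `term_id`
#' mapping events to ontology terms; events with no component row are
#' retained with an empty component list. Events appearing in several AOPs
#' are shared by id.
#'
#' @param aop_path Event/KER TSV (see above).
#' @param event_component_path Optional event-component TSV.
#' @return Object of class `aop_set`: list with `aops` (named list of
#'   `aop_definition`: `aop_id`, `events` data frame, `kers` data frame with
#'   `from`/`to`), `events` (all events, one row per id), `components`
#'   (data frame `event_id`, `term_id`).
#' @export
load_aop_definitions <- function(aop_path, event_component_path = NULL) {
  df <- read_delim_commented(aop_path)
  need <- c("aop_id", "event_id", "event_type", "event_title")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_format("missing column(s) in AOP file: ", paste(miss, collapse = ", "))
  df$event_type <- toupper(trimws(df$event_type))
  bad <- !df$event_type %in% .event_types
  if (any(bad)) {
    stop_validation("unknown event type(s): ",
                    paste(unique(df$event_type[bad]), collapse = ", "))
  }
  down <- if ("downstream_event_ids" %in% names(df)) {
    split_multi(df$downstream_event_ids)
  } else {
    rep(list(character()), nrow(df))
  }

  aop_ids <- unique(df$aop_id)
  aops <- stats::setNames(lapply(aop_ids, function(a) {
    rows <- which(df$aop_id == a)
    ev <- df[rows, c("event_id", "event_type", "event_title")]
    ev <- ev[!duplicated(ev$event_id), , drop = FALSE]
    # one event must not be typed both MIE and AO within one AOP
    ty <- tapply(df$event_type[rows], df$event_id[rows], function(t) unique(t))
    conflict <- names(ty)[vapply(ty, function(t) all(c("MIE", "AO") %in% t), logical(1))]
    if (length(conflict)) {
      stop_validation("event typed both MIE and AO in ", a, ": ",
                      paste(conflict, collapse = ", "))
    }
    kers <- data.frame(
      from = rep(df$event_id[rows], lengths(down[rows])),
      to = unlist(down[rows], use.names = FALSE),
      stringsAsFactors = FALSE
    )
    undeclared <- setdiff(kers$to, ev$event_id)
    if (length(undeclared)) {
      stop_validation("KER edge in ", a, " names undeclared event(s): ",
                      paste(undeclared, collapse = ", "))
    }
    rownames(ev) <- NULL
    structure(list(aop_id = a, events = ev, kers = unique(kers)),
              class = "aop_definition")
  }), aop_ids)

  events <- df[!duplicated(df$event_id), c("event_id", "event_type", "event_title")]
  rownames(events) <- NULL

  components <- data.frame(event_id = character(), term_id = character())
  if (!is.null(event_component_path)) {
    cmp <- read_delim_commented(event_component_path)
    miss <- setdiff(c("event_id", "term_id"), names(cmp))
    if (length(miss)) stop_format("missing column(s) in event-component file: ",
                                  paste(miss, collapse = ", "))
    components <- unique(cmp[, c("event_id", "term_id")])
    rownames(components) <- NULL
  }
  structure(list(aops = aops, events = events, components = components),
            class = "aop_set")
}

#' @export
print.aop_definition <- function(x, ...) {
  cat("<aop_definition> ", x$aop_id, ": ", nrow(x$events), " events, ",
      nrow(x$kers), " KERs\n", sep = "")
  invisible(x)
}

#' @export
print.aop_set <- function(x, ...) {
  cat("<aop_set> ", length(x$aops), " AOP(s), ", nrow(x$events),
      " distinct events, ", nrow(x$components), " component mappings\n", sep = "")
  invisible(x)
}

#' Find other AOPs sharing the queried events
#'
#' AOP events are modular and re-used across pathways; diseases reached by
#' other pathways through a shared event are candidate co-morbidities. For
#' each queried event this lists every AOP containing it together with that
#' AOP's AO-typed events (one row per event/AOP/AO; AOPs with no AO yield a
#' row with `ao_event_id = NA`). Events contained in no AOP yield no rows.
#'
#' @param aop_set An `aop_set` from [load_aop_definitions()].
#' @param event_ids Character vector of event ids to query.
#' @param exclude_aop Optional AOP ids to omit (e.g. the pathway under study).
#' @return Data frame `event_id`, `aop_id`, `ao_event_id`, `ao_event_title`.
#' @export
related_aops <- function(aop_set, event_ids, exclude_aop = character()) {
  rows <- list()
  for (ev in event_ids) {
    for (a in aop_set$aops) {
      if (a$aop_id %in% exclude_aop) next
      if (!ev %in% a$events$event_id) next
      aos <- a$events[a$events$event_type == "AO", , drop = FALSE]
      if (nrow(aos) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          event_id = ev, aop_id = a$aop_id,
          ao_event_id = NA_character_, ao_event_title = NA_character_)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          event_id = ev, aop_id = a$aop_id,
          ao_event_id = aos$event_id, ao_event_title = aos$event_title)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(event_id = character(), aop_id = character(),
                      ao_event_id = character(), ao_event_title = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Packaged autism AOP definition (AOP:522 shape)
#'
#' The estrogen-antagonism autism pathway: six events (one MIE, four KEs, one
#' AO) with five KERs, bifurcated at KE:195 which rejoins at KE:2208.
#' @return An `aop_set` containing the single pathway.
#' @export
autism_aop <- function() {
  load_aop_definitions(system.file("extdata", "aop522_events.tsv", package = "aoplink"))
}
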