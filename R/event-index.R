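#' Build a bibliome-wide event index
#'
#' Aggregates event occurrences across a corpus into three lookup tables:
#'
#' * per generalization key ([generalization_key()]) at each enabled level:
#'   occurrence count and maximum confidence;
#' * per event type (and level): the set of keys with their leaf argument
#'   symbols, supporting partial-match queries ("same event type and at
#'   least one equivalent argument");
#' * per directed canonical (agent, target) pair, overall and per coarse
#'   event type: occurrence count and maximum confidence of the flattened
#'   pairwise relations.
#'
#' @param documents list of `bib_document` objects.
#' @param symbol_table optional symbol table enabling the `normalized_id`
#'   level; events whose leaf symbols are not all resolvable are skipped at
#'   that level.
#' @param levels generalization levels to index.
#' @return an object of class `event_index`.
#' @export
build_event_index <- function(documents, symbol_table = NULL,
                              levels = c("canonical", "normalized_id")) {
  levels <- match.arg(levels, several.ok = TRUE)
  if (is.null(symbol_table)) levels <- setdiff(levels, "normalized_id")
  idx <- structure(list(exact = new.env(parent = emptyenv()),
                        by_type = new.env(parent = emptyenv()),
                        pair = new.env(parent = emptyenv()),
                        levels = levels, symbol_table = symbol_table,
                        n_events = 0L),
                   class = "event_index")
  for (doc in documents) idx <- index_add_document(idx, doc)
  idx
}

index_add_document <- function(idx, doc) {
  for (ev in doc$events) {
    idx$n_events <- idx$n_events + 1L
    for (level in idx$levels) {
      key <- tryCatch(generalization_key(ev, doc, level, idx$symbol_table),
                      error = function(e) NULL)
      if (is.null(key)) next
      rec <- idx$exact[[key]]
      if (is.null(rec)) {
        rec <- list(count = 0L, max_conf = 0, event_type = ev$event_type,
                    level = level, leaves = leaf_symbols(ev, doc))
        tkey <- paste0(level, "|", ev$event_type)
        idx$by_type[[tkey]] <- c(idx$by_type[[tkey]], key)
      }
      rec$count <- rec$count + 1L
      rec$max_conf <- max(rec$max_conf, ev$confidence)
      idx$exact[[key]] <- rec
    }
    rel <- flatten_to_relations(ev, doc)
    for (k in seq_len(nrow(rel))) {
      for (pkey in c(paste(rel$agent[k], rel$target[k], sep = "|"),
                     paste(rel$agent[k], rel$target[k], rel$layer[k],
                           rel$base[k], sep = "|"))) {
        rec <- idx$pair[[pkey]] %||% c(count = 0, max_conf = 0)
        idx$pair[[pkey]] <- c(count = unname(rec["count"]) + 1,
                              max_conf = max(rec["max_conf"], rel$confidence[k]))
      }
    }
  }
  idx
}

#' Query an event index
#'
#' `index_exact()` returns the occurrence count and maximum confidence of a
#' generalization key; `index_partial()` counts occurrences of *other* keys
#' with the same event type sharing at least one leaf argument symbol;
#' `index_pair()` returns count and maximum confidence for a directed
#' canonical pair, overall or restricted to one coarse event type.
#'
#' @param idx an `event_index`.
#' @param key a generalization key string.
#' @return a numeric vector `c(count, max_conf)`; zero count and zero
#'   confidence when the key is unseen.
#' @export
index_exact <- function(idx, key) {
  rec <- idx$exact[[key]]
  if (is.null(rec)) return(c(count = 0, max_conf = 0))
  c(count = rec$count, max_conf = rec$max_conf)
}

#' @rdname index_exact
#' @param level generalization level.
#' @param event_type GE event type.
#' @param leaves canonical leaf symbols of the query event.
#' @param exclude_key key to exclude (normally the query event's own exact key).
#' @export
index_partial <- function(idx, level, event_type, leaves, exclude_key = NULL) {
  keys <- idx$by_type[[paste0(level, "|", event_type)]]
  total <- 0
  for (k in keys) {
    if (!is.null(exclude_key) && k == exclude_key) next
    rec <- idx$exact[[k]]
    if (length(intersect(rec$leaves, leaves)) > 0) total <- total + rec$count
  }
  c(count = total)
}

#' @rdname index_exact
#' @param agent,target canonical symbols of the directed pair.
#' @param layer,base optional coarse event type restriction.
#' @export
index_pair <- function(idx, agent, target, layer = NULL, base = NULL) {
  pkey <- if (is.null(layer)) paste(agent, target, sep = "|") else
    paste(agent, target, layer, base, sep = "|")
  rec <- idx$pair[[pkey]]
  if (is.null(rec)) return(c(count = 0, max_conf = 0))
  rec
}

#' @export
print.event_index <- function(x, ...) {
  cat("<event_index>", x$n_events, "event occurrences,",
      length(ls(x$exact)), "generalization keys,",
      length(ls(x$pair)), "pair entries; levels:",
      paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}
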