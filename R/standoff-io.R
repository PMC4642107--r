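#' Parse a standoff .a1 entity annotation file
#'
#' Reads T-prefixed entity lines of the form
#' `ID<TAB>Type Start End<TAB>Text`. Offsets are 0-based, end-exclusive over
#' the flat character sequence of the document text. Every span is verified
#' against the document substring.
#'
#' @param raw_text contents of the .a1 file as a single string.
#' @param document_text the full document text the offsets refer to.
#' @return a named list of entity annotations, keyed by id. Each entity is a
#'   list with fields `id`, `entity_type`, `start`, `end`, `text`.
#' @export
parse_a1 <- function(raw_text, document_text) {
  lines <- split_lines(raw_text)
  entities <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line)) next
    ent <- parse_span_line(line, i, document_text, "a1")
    if (!startsWith(ent$id, "T"))
      stop("malformed .a1 line ", i, ": entity id must be T-prefixed")
    if (!ent$type %in% ENTITY_TYPES)
      stop("malformed .a1 line ", i, ": unknown entity type '", ent$type, "'")
    if (ent$id %in% names(entities))
      stop("integrity error at .a1 line ", i, ": duplicate id ", ent$id)
    entities[[ent$id]] <- list(id = ent$id, entity_type = ent$type,
                               start = ent$start, end = ent$end,
                               text = ent$text)
  }
  entities
}

#' Parse a standoff .a2 event annotation file
#'
#' Reads trigger lines (same grammar as .a1 lines, but typed with event
#' types) followed by E-prefixed event lines
#' `ID<TAB>Type:TriggerID Role:ArgID ...`. Arguments may reference entities
#' from the .a1 layer or other events from the same file (nesting). Dangling
#' references, reference cycles, and events without a Theme are rejected.
#'
#' Confidence and negation are not part of standard .a2; they default to 1.0
#' and `FALSE` and can be overridden from a sidecar table
#' (see [read_confidence_tsv()]).
#'
#' @param raw_text contents of the .a2 file as a single string.
#' @param entities named entity list from [parse_a1()].
#' @param document_text the full document text.
#' @return a named list of event annotations keyed by id, each a list with
#'   fields `id`, `event_type`, `trigger_start`, `trigger_end`,
#'   `trigger_text`, `args` (list of `list(role, ref)`), `confidence`,
#'   `negated`.
#' @export
parse_a2 <- function(raw_text, entities, document_text) {
  lines <- split_lines(raw_text)
  triggers <- list()
  raw_events <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line)) next
    if (startsWith(line, "T")) {
      trg <- parse_span_line(line, i, document_text, "a2")
      if (trg$id %in% names(triggers) || trg$id %in% names(entities))
        stop("integrity error at .a2 line ", i, ": duplicate id ", trg$id)
      triggers[[trg$id]] <- trg
    } else if (startsWith(line, "E")) {
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(fields) != 2)
        stop("malformed .a2 line ", i, ": expected 2 tab-separated fields")
      parts <- strsplit(fields[[2]], " ", fixed = TRUE)[[1]]
      parts <- parts[nzchar(parts)]
      if (length(parts) < 1)
        stop("malformed .a2 line ", i, ": empty event definition")
      head_kv <- strsplit(parts[[1]], ":", fixed = TRUE)[[1]]
      if (length(head_kv) != 2)
        stop("malformed .a2 line ", i, ": event head must be Type:TriggerID")
      args <- list()
      if (length(parts) > 1) {
        for (p in parts[-1]) {
          kv <- strsplit(p, ":", fixed = TRUE)[[1]]
          if (length(kv) != 2)
            stop("malformed .a2 line ", i, ": argument must be Role:ID")
          args[[length(args) + 1L]] <- list(role = normalize_role(kv[[1]]),
                                            ref = kv[[2]])
        }
      }
      raw_events[[fields[[1]]]] <- list(id = fields[[1]], event_type = head_kv[[1]],
                                        trigger_id = head_kv[[2]], args = args,
                                        line = i)
    } else {
      stop("malformed .a2 line ", i, ": unknown annotation prefix")
    }
  }
  events <- list()
  for (ev in raw_events) {
    trg <- triggers[[ev$trigger_id]]
    if (is.null(trg))
      stop("resolution error at .a2 line ", ev$line, ": unknown trigger ",
           ev$trigger_id)
    if (trg$type != ev$event_type)
      stop("integrity error at .a2 line ", ev$line,
           ": trigger type does not match event type")
    for (a in ev$args) {
      ok <- (startsWith(a$ref, "T") && a$ref %in% names(entities)) ||
            (startsWith(a$ref, "E") && a$ref %in% names(raw_events))
      if (!ok)
        stop("resolution error at .a2 line ", ev$line,
             ": unknown argument reference ", a$ref)
    }
    if (!any(vapply(ev$args, function(a) a$role == "Theme", logical(1))))
      stop("structural error: event ", ev$id, " has no Theme argument")
    events[[ev$id]] <- list(id = ev$id, event_type = ev$event_type,
                            trigger_start = trg$start, trigger_end = trg$end,
                            trigger_text = trg$text, args = ev$args,
                            confidence = 1.0, negated = FALSE)
  }
  check_no_cycles(events)
  events
}

# roles Theme2, Theme3 ... are aliases for Theme (multi-theme Binding)
normalize_role <- function(role) {
  base <- sub("[0-9]+$", "", role)
  if (!base %in% c("Theme", "Cause"))
    stop("unknown argument role '", role, "'")
  base
}

check_no_cycles <- function(events) {
  state <- new.env(parent = emptyenv())
  visit <- function(id) {
    s <- state[[id]] %||% "new"
    if (s == "open") stop("structural error: reference cycle through ", id)
    if (s == "done") return(invisible())
    state[[id]] <- "open"
    for (a in events[[id]]$args) {
      if (startsWith(a$ref, "E")) {
        if (is.null(events[[a$ref]]))
          stop("resolution error: unknown event reference ", a$ref)
        visit(a$ref)
      }
    }
    state[[id]] <- "done"
  }
  for (id in names(events)) visit(id)
  invisible(events)
}

parse_span_line <- function(line, lineno, document_text, what) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) != 3)
    stop("malformed .", what, " line ", lineno,
         ": expected 3 tab-separated fields")
  mid <- strsplit(fields[[2]], " ", fixed = TRUE)[[1]]
  if (length(mid) != 3)
    stop("malformed .", what, " line ", lineno,
         ": expected 'Type Start End'")
  start <- suppressWarnings(as.integer(mid[[2]]))
  end <- suppressWarnings(as.integer(mid[[3]]))
  if (is.na(start) || is.na(end))
    stop("malformed .", what, " line ", lineno, ": non-numeric offsets")
  if (start < 0 || start >= end)
    stop("integrity error at .", what, " line ", lineno,
         ": require 0 <= start < end")
  if (end > nchar(document_text))
    stop("integrity error at .", what, " line ", lineno,
         ": span exceeds document length")
  sub <- substr(document_text, start + 1L, end)
  if (sub != fields[[3]])
    stop("integrity error at .", what, " line ", lineno,
         ": span text '", fields[[3]], "' does not match document '", sub, "'")
  list(id = fields[[1]], type = mid[[1]], start = start, end = end,
       text = fields[[3]])
}

split_lines <- function(raw_text) {
  if (length(raw_text) != 1) raw_text <- paste(raw_text, collapse = "\n")
  if (!nzchar(raw_text)) return(character(0))
  strsplit(raw_text, "\n", fixed = TRUE)[[1]]
}

#' Serialize entities to .a1 format
#'
#' @param entities named entity list as produced by [parse_a1()].
#' @return a single string in .a1 format (possibly empty).
#' @export
write_a1 <- function(entities) {
  if (length(entities) == 0) return("")
  lines <- vapply(entities, function(e) {
    sprintf("%s\t%s %d %d\t%s", e$id, e$entity_type, e$start, e$end, e$text)
  }, character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Serialize events to .a2 format
#'
#' Trigger lines are emitted first (deduplicated by type and span, numbered
#' after the highest T-id used by `entities`), followed by event lines. The
#' round trip `parse_a2(write_a2(events, entities), ...)` reproduces the
#' events up to trigger-identifier renaming. Confidence and negation are not
#' serialized here (see [write_confidence_tsv()]).
#'
#' @param events named event list as produced by [parse_a2()].
#' @param entities entity list of the same document, used only to avoid
#'   reusing T-identifiers.
#' @return a single string in .a2 format (possibly empty).
#' @export
write_a2 <- function(events, entities = list()) {
  if (length(events) == 0) return("")
  used <- suppressWarnings(as.integer(sub("^T", "", names(entities))))
  next_t <- if (length(used) && any(!is.na(used))) max(used, na.rm = TRUE) + 1L else 1L
  trig_key <- character(0)
  trig_lines <- character(0)
  trig_id <- character(0)
  ev_lines <- character(0)
  for (ev in events) {
    key <- paste(ev$event_type, ev$trigger_start, ev$trigger_end, sep = "|")
    pos <- match(key, trig_key)
    if (is.na(pos)) {
      id <- paste0("T", next_t)
      next_t <- next_t + 1L
      trig_key <- c(trig_key, key)
      trig_id <- c(trig_id, id)
      trig_lines <- c(trig_lines, sprintf("%s\t%s %d %d\t%s", id,
                                          ev$event_type, ev$trigger_start,
                                          ev$trigger_end, ev$trigger_text))
      pos <- length(trig_key)
    }
    arg_str <- vapply(ev$args, function(a) paste0(a$role, ":", a$ref),
                      character(1))
    ev_lines <- c(ev_lines, paste0(ev$id, "\t",
                                   paste(c(paste0(ev$event_type, ":",
                                                  trig_id[[pos]]), arg_str),
                                         collapse = " ")))
  }
  paste0(paste(c(trig_lines, ev_lines), collapse = "\n"), "\n")
}

#' Read and write the confidence/negation sidecar table
#'
#' Standard .a2 has no confidence field, so per-event confidence scores and
#' negation flags travel in a sidecar TSV with columns
#' `event_id`, `confidence`, `negated`. An absent sidecar leaves the
#' defaults (confidence 1.0, negated FALSE).
#'
#' @param raw_text sidecar file contents.
#' @param events named event list to annotate.
#' @return `read_confidence_tsv`: the event list with confidence/negated
#'   filled in; `write_confidence_tsv`: the sidecar string.
#' @export
read_confidence_tsv <- function(raw_text, events) {
  lines <- split_lines(raw_text)
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line)) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 3)
      stop("malformed confidence sidecar line ", i)
    if (is.null(events[[f[[1]]]]))
      stop("resolution error in confidence sidecar: unknown event ", f[[1]])
    conf <- as.numeric(f[[2]])
    if (is.na(conf) || conf <= 0 || conf > 1)
      stop("integrity error in confidence sidecar line ", i,
           ": confidence must be in (0, 1]")
    events[[f[[1]]]]$confidence <- conf
    events[[f[[1]]]]$negated <- identical(f[[3]], "1") ||
      identical(toupper(f[[3]]), "TRUE")
  }
  events
}

#' @rdname read_confidence_tsv
#' @export
write_confidence_tsv <- function(events) {
  if (length(events) == 0) return("")
  lines <- vapply(events, function(ev) {
    sprintf("%s\t%s\t%d", ev$id, format_confidence(ev$confidence),
            as.integer(ev$negated))
  }, character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}

# fixed-width confidence formatting so write -> read -> write is bit-exact
format_confidence <- function(x) formatC(x, digits = 6, format = "f")

#' Read a network TSV file
#'
#' Headerless tab-separated records `agent_id  target_id  interaction_type
#' [confidence]`. The interaction type must belong to the GRN vocabulary
#' (Requirement is additionally accepted, for gold files).
#'
#' @param file path to a network TSV file.
#' @param text alternatively, the file contents as a string.
#' @return a data frame with columns `agent_id`, `target_id`, `grn_type`
#'   and (if present in the input) `confidence`.
#' @export
read_network_tsv <- function(file = NULL, text = NULL) {
  raw <- if (is.null(text)) {
    paste(readLines(file, warn = FALSE), collapse = "\n")
  } else text
  lines <- split_lines(raw)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(agent_id = character(0), target_id = character(0),
                      grn_type = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(!ncols %in% c(3L, 4L)))
    stop("malformed network TSV: line ", which(!ncols %in% c(3L, 4L))[1],
         " does not have 3 or 4 columns")
  df <- data.frame(agent_id = vapply(parts, `[[`, character(1), 1),
                   target_id = vapply(parts, `[[`, character(1), 2),
                   grn_type = vapply(parts, `[[`, character(1), 3),
                   stringsAsFactors = FALSE)
  bad <- !df$grn_type %in% GOLD_RELATION_TYPES
  if (any(bad))
    stop("vocabulary error: unknown interaction type '",
         df$grn_type[bad][1], "'")
  if (all(ncols == 4L))
    df$confidence <- as.numeric(vapply(parts, `[[`, character(1), 4))
  if (anyDuplicated(df[c("agent_id", "target_id", "grn_type")]))
    stop("integrity error: duplicate (agent, target, type) record")
  df
}

#' Write a network TSV file
#'
#' @param records data frame with columns `agent_id`, `target_id`,
#'   `grn_type` and optionally `confidence`.
#' @param file optional path; when `NULL` the serialized string is returned.
#' @return the serialized string, invisibly when written to a file.
#' @export
write_network_tsv <- function(records, file = NULL) {
  if (nrow(records) == 0) {
    out <- ""
  } else {
    if (any(!records$grn_type %in% GOLD_RELATION_TYPES))
      stop("vocabulary error: unknown interaction type in records")
    cols <- list(records$agent_id, records$target_id, records$grn_type)
    if (!is.null(records$confidence))
      cols <- c(cols, list(format_confidence(records$confidence)))
    out <- paste0(paste(do.call(paste, c(cols, sep = "\t")),
                        collapse = "\n"), "\n")
  }
  if (is.null(file)) return(out)
  writeLines(out, file, sep = "")
  invisible(out)
}

#' Read a gold symbol table
#'
#' Headerless two-column TSV mapping surface gene symbols to standardized
#' gene identifiers (e.g. `sigmaB<TAB>sigB`). Keys are canonicalized before
#' lookup by the consumers, so lexical variants of a listed surface form
#' resolve to the same identifier.
#'
#' @inheritParams read_network_tsv
#' @return a data frame with columns `surface` and `gene_id`.
#' @export
read_symbol_table <- function(file = NULL, text = NULL) {
  raw <- if (is.null(text)) {
    paste(readLines(file, warn = FALSE), collapse = "\n")
  } else text
  lines <- split_lines(raw)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(surface = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed symbol table: expected 2 tab-separated columns")
  data.frame(surface = vapply(parts, `[[`, character(1), 1),
             gene_id = vapply(parts, `[[`, character(1), 2),
             stringsAsFactors = FALSE)
}

#' @rdname read_symbol_table
#' @param table data frame with columns `surface`, `gene_id`.
#' @param file optional output path.
#' @export
write_symbol_table <- function(table, file = NULL) {
  out <- if (nrow(table) == 0) "" else
    paste0(paste(paste(table$surface, table$gene_id, sep = "\t"),
                 collapse = "\n"), "\n")
  if (is.null(file)) return(out)
  writeLines(out, file, sep = "")
  invisible(out)
}
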