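#' Canonicalize a gene symbol
#'
#' Collapses small lexical variants of gene/protein symbols by lower-casing
#' and removing every non-alphanumeric character, so that e.g. `"Esr-1"`,
#' `"ESR1"` and `"esr 1"` all map to `"esr1"`. The operation is idempotent.
#'
#' @param symbol character vector of surface symbols.
#' @return character vector of canonical symbols (lower-case alphanumeric).
#' @export
canonicalize <- function(symbol) {
  if (length(symbol) == 0) return(character(0))
  out <- gsub("[^a-z0-9]", "", tolower(symbol))
  if (any(!nzchar(out)))
    stop("canonicalization error: symbol '", symbol[!nzchar(out)][1],
         "' contains no alphanumeric characters")
  out
}

#' Compute the generalization key of an event
#'
#' Events with the same event type and pairwise-equivalent arguments share a
#' key and are grouped together across the bibliome. At the `canonical`
#' level arguments are compared by canonicalized surface symbol; at the
#' `normalized_id` level by standardized gene identifier (resolved through a
#' symbol table). Argument order is irrelevant (multiset semantics); nested
#' event arguments contribute their own key recursively.
#'
#' @param event an event annotation.
#' @param doc the `bib_document` the event belongs to.
#' @param level `"canonical"` or `"normalized_id"`.
#' @param symbol_table data frame with columns `surface`, `gene_id`;
#'   required at the `normalized_id` level.
#' @return a single key string.
#' @export
generalization_key <- function(event, doc, level = c("canonical", "normalized_id"),
                               symbol_table = NULL) {
  level <- match.arg(level)
  lookup <- if (level == "normalized_id") symbol_lookup(symbol_table) else NULL
  paste0(level, "|", key_body(event, doc, level, lookup))
}

key_body <- function(event, doc, level, lookup) {
  argkeys <- vapply(event$args, function(a) {
    if (startsWith(a$ref, "T")) {
      ent <- doc$entities[[a$ref]]
      sym <- canonicalize(ent$text)
      if (level == "normalized_id") {
        id <- lookup[[sym]]
        if (is.null(id))
          stop("key error: no standardized id for symbol '", ent$text,
               "' at normalized_id level")
        sym <- id
      }
      paste0(a$role, "=", sym)
    } else {
      paste0(a$role, "=(", key_body(doc$events[[a$ref]], doc, level, lookup), ")")
    }
  }, character(1))
  paste0(event$event_type, "[", paste(sort(argkeys), collapse = ","), "]")
}

symbol_lookup <- function(symbol_table) {
  if (is.null(symbol_table)) return(NULL)
  env <- new.env(parent = emptyenv())
  keys <- canonicalize(symbol_table$surface)
  for (i in seq_along(keys)) env[[keys[[i]]]] <- symbol_table$gene_id[[i]]
  env
}

# leaf gene/protein symbols (canonical) mentioned anywhere in the event
leaf_symbols <- function(event, doc) {
  syms <- character(0)
  for (a in event$args) {
    if (startsWith(a$ref, "T")) {
      syms <- c(syms, canonicalize(doc$entities[[a$ref]]$text))
    } else {
      syms <- c(syms, leaf_symbols(doc$events[[a$ref]], doc))
    }
  }
  unique(syms)
}

empty_relations <- function() {
  data.frame(agent = character(0), target = character(0),
             agent_entity_type = character(0), target_entity_type = character(0),
             layer = character(0), base = character(0),
             confidence = numeric(0), negated = logical(0),
             source_doc = character(0), source_event = character(0),
             stringsAsFactors = FALSE)
}

relation_row <- function(agent, target, agent_et, target_et, layer, base,
                         conf, negated, doc_id, event_id) {
  data.frame(agent = agent, target = target, agent_entity_type = agent_et,
             target_entity_type = target_et, layer = layer, base = base,
             confidence = conf, negated = negated, source_doc = doc_id,
             source_event = event_id, stringsAsFactors = FALSE)
}

#' Flatten a nested event into pairwise relations
#'
#' Network interpretation of a complex event structure:
#'
#' * a Binding event with two or more entity Themes yields one relation per
#'   unordered Theme pair, emitted in both orientations with coarse type
#'   (None, Binding) — downstream entity-type filtering selects the
#'   compatible orientation;
#' * a regulation-family event with an entity Cause yields agent→target
#'   relations for every target reachable by descending Theme links:
#'   an entity Theme gives base Other; a nested Transcription or
#'   Gene_expression event contributes its entity Themes with the matching
#'   base; a nested regulation is recursed into, composing regulatory
#'   layers by sign multiplication ([compose_layers()]);
#' * anything else yields nothing.
#'
#' The relation confidence is the minimum confidence along the event chain
#' and the negation flag is the logical OR along the chain. Per event, at
#' most one relation is emitted for each distinct (agent, target) pair (the
#' highest-confidence path wins).
#'
#' @param event an event annotation.
#' @param doc the `bib_document` containing it.
#' @return a data frame of pairwise relations with columns `agent`,
#'   `target` (canonical symbols), `agent_entity_type`, `target_entity_type`,
#'   `layer`, `base`, `confidence`, `negated`, `source_doc`, `source_event`.
#' @export
flatten_to_relations <- function(event, doc) {
  rows <- list()
  if (event$event_type == "Binding") {
    ents <- entity_args(event, doc, "Theme")
    if (length(ents) >= 2) {
      for (i in seq_len(length(ents) - 1)) {
        for (j in seq(i + 1, length(ents))) {
          a <- ents[[i]]; b <- ents[[j]]
          for (pair in list(c(1, 2), c(2, 1))) {
            x <- list(a, b)[[pair[1]]]; y <- list(a, b)[[pair[2]]]
            rows[[length(rows) + 1L]] <- relation_row(
              canonicalize(x$text), canonicalize(y$text),
              x$entity_type, y$entity_type, "None", "Binding",
              event$confidence, event$negated, doc$doc_id, event$id)
          }
        }
      }
    }
  } else if (event$event_type %in% names(REGULATION_FAMILY)) {
    causes <- entity_args(event, doc, "Cause")
    if (length(causes) > 0) {
      targets <- descend_reg(event, doc)
      for (cs in causes) {
        for (k in seq_len(nrow(targets))) {
          rows[[length(rows) + 1L]] <- relation_row(
            canonicalize(cs$text), targets$target[[k]],
            cs$entity_type, targets$target_entity_type[[k]],
            targets$layer[[k]], targets$base[[k]],
            targets$confidence[[k]], targets$negated[[k]],
            doc$doc_id, event$id)
        }
      }
    }
  }
  if (length(rows) == 0) return(empty_relations())
  out <- do.call(rbind, rows)
  # one relation per distinct (agent, target) pair per event, best path first
  out <- out[order(-out$confidence), , drop = FALSE]
  out <- out[!duplicated(out[c("agent", "target")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

entity_args <- function(event, doc, role) {
  refs <- Filter(function(a) a$role == role && startsWith(a$ref, "T"), event$args)
  lapply(refs, function(a) doc$entities[[a$ref]])
}

# targets reachable through Theme links of a regulation event, with the
# composed layer (including this event's own layer), min confidence and
# OR-ed negation along the chain
descend_reg <- function(event, doc) {
  layer <- REGULATION_FAMILY[[event$event_type]]
  acc <- list()
  for (a in event$args) {
    if (a$role != "Theme") next
    if (startsWith(a$ref, "T")) {
      ent <- doc$entities[[a$ref]]
      acc[[length(acc) + 1L]] <- data.frame(
        target = canonicalize(ent$text), target_entity_type = ent$entity_type,
        layer = layer, base = "Other", confidence = event$confidence,
        negated = event$negated, stringsAsFactors = FALSE)
    } else {
      sub <- doc$events[[a$ref]]
      if (sub$event_type %in% c("Transcription", "Gene_expression")) {
        base <- if (sub$event_type == "Transcription") "Transcription" else "GeneExpression"
        for (ent in entity_args(sub, doc, "Theme")) {
          acc[[length(acc) + 1L]] <- data.frame(
            target = canonicalize(ent$text), target_entity_type = ent$entity_type,
            layer = layer, base = base,
            confidence = min(event$confidence, sub$confidence),
            negated = event$negated || sub$negated, stringsAsFactors = FALSE)
        }
      } else if (sub$event_type %in% names(REGULATION_FAMILY)) {
        subrows <- descend_reg(sub, doc)
        if (nrow(subrows) > 0) {
          subrows$layer <- vapply(subrows$layer, function(l)
            compose_layers(layer, l), character(1))
          subrows$confidence <- pmin(event$confidence, subrows$confidence)
          subrows$negated <- event$negated | subrows$negated
          acc[[length(acc) + 1L]] <- subrows
        }
      }
      # other nested event types carry no gene target semantics here
    }
  }
  if (length(acc) == 0)
    return(data.frame(target = character(0), target_entity_type = character(0),
                      layer = character(0), base = character(0),
                      confidence = numeric(0), negated = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, acc)
}

#' Flatten every event of a corpus
#'
#' @param documents a list of `bib_document` objects.
#' @return the row-bound [flatten_to_relations()] output for every event.
#' @export
corpus_relations <- function(documents) {
  rows <- lapply(documents, function(doc) {
    do.call(rbind, c(list(empty_relations()),
                     lapply(doc$events, flatten_to_relations, doc = doc)))
  })
  out <- do.call(rbind, c(list(empty_relations()), rows))
  rownames(out) <- NULL
  out
}
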