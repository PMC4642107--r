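#' Generator configuration for a synthetic bibliome
#'
#' Defines the study conditions the synthetic corpus emulates: a planted
#' typed regulatory network mentioned repeatedly across documents as nested
#' event structures, per-event confidence scores correlated with
#' correctness (true events draw from `conf_correct`, injected false
#' positives from `conf_incorrect`), lexical variation of gene symbols, and
#' a configurable type-confusion process for the false positives.
#'
#' The default type distribution gives Binding weight 0: the conversion
#' pipeline systematically refactors surviving Binding evidence to
#' Transcription, so a planted gold Binding edge could never be recovered
#' (it behaves like the Requirement type — plantable for evaluation
#' exercises, never produced). Planted Transcription edges are instead
#' realized partly through Binding events, which exercises the refactoring
#' path.
#'
#' @param n_genes number of genes in the synthetic vocabulary.
#' @param n_edges number of planted directed edges.
#' @param n_docs number of documents.
#' @param sentences_per_doc sentences per document (one per line).
#' @param mentions_per_edge event mentions realizing each planted edge.
#' @param type_distribution named probability vector over GRN types
#'   (optionally including `Requirement`).
#' @param fp_rate expected fraction of events that are injected false
#'   positives, in [0, 1).
#' @param type_confusion row-stochastic matrix over the coarse event-type
#'   categories governing the realized type
#'   of a false positive given the intended one; `NULL` means uniform.
#' @param conf_correct,conf_incorrect Beta(a, b) parameter pairs for true
#'   and false event confidences.
#' @param variant_rate probability that a gene mention uses a lexical
#'   variant (case/punctuation variant or listed alias) instead of the
#'   standardized symbol.
#' @param unmatched_symbol_rate probability that a false-positive mention
#'   uses a symbol absent from the gold symbol table.
#' @param seed random seed; generation is fully reproducible given the seed.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 30, n_edges = 60, n_docs = 40,
                             sentences_per_doc = 8, mentions_per_edge = 3,
                             type_distribution = c(Binding = 0,
                                                   Transcription = 0.35,
                                                   Regulation = 0.15,
                                                   Activation = 0.3,
                                                   Inhibition = 0.2),
                             fp_rate = 0.3, type_confusion = NULL,
                             conf_correct = c(5, 2),
                             conf_incorrect = c(2, 5),
                             variant_rate = 0.2,
                             unmatched_symbol_rate = 0.05, seed = 1) {
  stopifnot(n_genes >= 2, n_edges >= 1, n_docs >= 1, sentences_per_doc >= 1,
            mentions_per_edge >= 1)
  if (n_edges > n_genes * (n_genes - 1))
    stop("config error: n_edges exceeds the number of ordered gene pairs")
  if (!all(names(type_distribution) %in% GOLD_RELATION_TYPES))
    stop("config error: unknown GRN type in type_distribution")
  if (abs(sum(type_distribution) - 1) > 1e-9)
    stop("config error: type_distribution must sum to 1")
  if (fp_rate < 0 || fp_rate >= 1)
    stop("config error: fp_rate must be in [0, 1)")
  if (any(c(conf_correct, conf_incorrect) <= 0))
    stop("config error: Beta parameters must be positive")
  if (variant_rate < 0 || variant_rate > 1 ||
      unmatched_symbol_rate < 0 || unmatched_symbol_rate > 1)
    stop("config error: rates must lie in [0, 1]")
  cats <- coarse_categories()
  if (is.null(type_confusion)) {
    type_confusion <- matrix(1 / length(cats), nrow = length(cats),
                             ncol = length(cats), dimnames = list(cats, cats))
  } else {
    stopifnot(identical(dim(type_confusion), c(length(cats), length(cats))),
              all(abs(rowSums(type_confusion) - 1) < 1e-9))
    dimnames(type_confusion) <- list(cats, cats)
  }
  structure(list(n_genes = n_genes, n_edges = n_edges, n_docs = n_docs,
                 sentences_per_doc = sentences_per_doc,
                 mentions_per_edge = mentions_per_edge,
                 type_distribution = type_distribution, fp_rate = fp_rate,
                 type_confusion = type_confusion,
                 conf_correct = conf_correct, conf_incorrect = conf_incorrect,
                 variant_rate = variant_rate,
                 unmatched_symbol_rate = unmatched_symbol_rate, seed = seed),
            class = "generator_config")
}

# unique gene-like symbols: three lowercase letters + one uppercase, with
# pairwise distinct canonical forms
make_symbols <- function(n, taken = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    s <- paste0(paste(sample(letters, 3, replace = TRUE), collapse = ""),
                sample(LETTERS, 1))
    cs <- canonicalize(s)
    if (!cs %in% c(taken, canonicalize(out %||% character(0)))) {
      out <- c(out, s)
      taken <- c(taken, cs)
    }
  }
  out
}

draw_conf <- function(n, ab) {
  pmin(pmax(round(stats::rbeta(n, ab[[1]], ab[[2]]), 6), 1e-6), 1)
}

# allowed (agent, target) entity types per GRN type, mirroring the
# entity-type filtering rules
sample_edge_entity_types <- function(grn_type) {
  rule <- ENTITY_TYPE_RULES[[grn_type]] %||%
    list(agent = "Gene", target = "Protein")   # Requirement: arbitrary
  c(agent = sample(rule$agent, 1), target = sample(rule$target, 1))
}

verb_of <- c(Positive = "activates", Negative = "represses",
             Unspecified = "modulates")
regnoun_of <- c(Positive = "activation", Negative = "repression",
                Unspecified = "control")

# realization plan of one true mention of a planted edge
plan_true_mention <- function(grn_type, agent_et, target_et) {
  switch(grn_type,
    Binding = list(kind = "binding"),
    Transcription = {
      if (agent_et == "Gene" && target_et == "Protein" &&
          stats::runif(1) < 0.25) {
        list(kind = "binding")
      } else {
        list(kind = "nested",
             layer = sample(c("Unspecified", "Positive", "Negative"), 1),
             base = sample(c("Transcription", "GeneExpression"), 1))
      }
    },
    Activation = {
      if (stats::runif(1) < 0.7) list(kind = "direct", layer = "Positive")
      else list(kind = "double",
                layers = if (stats::runif(1) < 0.5)
                  c("Positive", "Positive") else c("Negative", "Negative"))
    },
    Inhibition = {
      if (stats::runif(1) < 0.7) list(kind = "direct", layer = "Negative")
      else list(kind = "double",
                layers = if (stats::runif(1) < 0.5)
                  c("Positive", "Negative") else c("Negative", "Positive"))
    },
    Regulation = {
      if (stats::runif(1) < 0.85) list(kind = "direct", layer = "Unspecified")
      else list(kind = "double",
                layers = c("Unspecified",
                           sample(c("Unspecified", "Positive", "Negative"), 1)))
    },
    stop("no event realization for gold type ", grn_type))
}

# realization plan of one false-positive mention of a coarse category
plan_fp_mention <- function(coarse) {
  lb <- strsplit(coarse, "|", fixed = TRUE)[[1]]
  layer <- lb[[1]]; base <- lb[[2]]
  if (layer == "None") {
    switch(base,
      Binding = list(kind = "binding"),
      Transcription = list(kind = "orphan", orphan_type = "Transcription",
                           orphan_word = "transcribed"),
      GeneExpression = list(kind = "orphan", orphan_type = "Gene_expression",
                            orphan_word = "expressed"),
      Other = list(kind = "orphan", orphan_type = "Phosphorylation",
                   orphan_word = "phosphorylated"))
  } else if (base == "Other") {
    list(kind = "direct", layer = layer)
  } else {
    list(kind = "nested", layer = layer, base = base)
  }
}

n_plan_events <- function(plan) {
  if (plan$kind %in% c("nested", "double")) 2L else 1L
}

# render a plan as clause text plus entity/event specs with clause-relative
# offsets
render_clause <- function(plan, agent_surface, agent_et, target_surface,
                          target_et, confs) {
  buf <- ""
  marks <- list()
  add <- function(word, mark = NULL) {
    if (nzchar(buf)) buf <<- paste0(buf, " ")
    s <- nchar(buf)
    buf <<- paste0(buf, word)
    if (!is.null(mark)) marks[[mark]] <<- c(s, nchar(buf))
  }
  reg_type <- function(layer)
    names(REGULATION_FAMILY)[REGULATION_FAMILY == layer]
  ents <- list()
  evs <- list()
  if (plan$kind == "binding") {
    add(agent_surface, "agent"); add("binds", "t1"); add(target_surface, "target")
    ents <- list(agent = list(type = agent_et, mark = "agent",
                              text = agent_surface),
                 target = list(type = target_et, mark = "target",
                               text = target_surface))
    evs <- list(list(event_type = "Binding", trigger = "t1",
                     args = list(list(role = "Theme", ent = "agent"),
                                 list(role = "Theme", ent = "target")),
                     confidence = confs[[1]]))
  } else if (plan$kind == "direct") {
    add(agent_surface, "agent"); add(verb_of[[plan$layer]], "t1")
    add(target_surface, "target")
    ents <- list(agent = list(type = agent_et, mark = "agent",
                              text = agent_surface),
                 target = list(type = target_et, mark = "target",
                               text = target_surface))
    evs <- list(list(event_type = reg_type(plan$layer), trigger = "t1",
                     args = list(list(role = "Cause", ent = "agent"),
                                 list(role = "Theme", ent = "target")),
                     confidence = confs[[1]]))
  } else if (plan$kind %in% c("nested", "double")) {
    if (plan$kind == "nested") {
      outer_layer <- plan$layer
      inner_type <- if (plan$base == "Transcription") "Transcription" else
        "Gene_expression"
      inner_word <- if (plan$base == "Transcription") "transcription" else
        "expression"
    } else {
      outer_layer <- plan$layers[[1]]
      inner_type <- reg_type(plan$layers[[2]])
      inner_word <- regnoun_of[[plan$layers[[2]]]]
    }
    add(agent_surface, "agent"); add(verb_of[[outer_layer]], "t1")
    add("the"); add(inner_word, "t2"); add("of"); add(target_surface, "target")
    ents <- list(agent = list(type = agent_et, mark = "agent",
                              text = agent_surface),
                 target = list(type = target_et, mark = "target",
                               text = target_surface))
    evs <- list(list(event_type = inner_type, trigger = "t2",
                     args = list(list(role = "Theme", ent = "target")),
                     confidence = confs[[2]]),
                list(event_type = reg_type(outer_layer), trigger = "t1",
                     args = list(list(role = "Cause", ent = "agent"),
                                 list(role = "Theme", ev = 1L)),
                     confidence = confs[[1]]))
  } else if (plan$kind == "orphan") {
    add(target_surface, "target"); add("is"); add(plan$orphan_word, "t1")
    ents <- list(target = list(type = target_et, mark = "target",
                               text = target_surface))
    evs <- list(list(event_type = plan$orphan_type, trigger = "t1",
                     args = list(list(role = "Theme", ent = "target")),
                     confidence = confs[[1]]))
  }
  list(text = buf, marks = marks, ents = ents, evs = evs)
}

#' Generate a synthetic bibliome with a planted regulatory network
#'
#' Produces a seeded corpus of annotated documents plus the ground truth:
#' the planted typed network, the gold symbol table (standardized symbols,
#' aliases), per-event tp/fp labels, and per-document gold event sets. With
#' `fp_rate = 0`, `variant_rate = 0` and `unmatched_symbol_rate = 0` the
#' rule-based conversion recovers the planted network exactly.
#'
#' @param config a [generator_config()].
#' @return a list with `corpus` (named `bib_document` list) and `truth`
#'   (list with `network`, `symbol_table`, `labels`, `gold_documents`,
#'   `n_true`, `n_fp`).
#' @export
generate_bibliome <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  # --- vocabulary -----------------------------------------------------
  n <- config$n_genes
  ids <- make_symbols(n)
  aliases <- make_symbols(n, taken = canonicalize(ids))
  n_oov <- max(4L, ceiling(n / 2))
  oov <- make_symbols(n_oov, taken = canonicalize(c(ids, aliases)))
  symbol_table <- data.frame(surface = c(ids, aliases),
                             gene_id = c(ids, ids), stringsAsFactors = FALSE)
  mention_surface <- function(gene_idx) {
    id <- ids[[gene_idx]]
    if (stats::runif(1) >= config$variant_rate) return(id)
    switch(sample(3, 1),
           aliases[[gene_idx]],
           paste0(substr(id, 1, 3), "-", substr(id, 4, 4)),
           toupper(id))
  }
  # --- planted network ------------------------------------------------
  pair_idx <- expand.grid(agent = seq_len(n), target = seq_len(n))
  pair_idx <- pair_idx[pair_idx$agent != pair_idx$target, ]
  sel <- pair_idx[sample(nrow(pair_idx), config$n_edges), ]
  types <- sample(names(config$type_distribution), config$n_edges,
                  replace = TRUE, prob = config$type_distribution)
  network <- data.frame(agent_id = ids[sel$agent], target_id = ids[sel$target],
                        grn_type = types, stringsAsFactors = FALSE)
  edge_ets <- lapply(types, sample_edge_entity_types)
  # --- mention plans --------------------------------------------------
  mentions <- list()
  for (e in seq_len(config$n_edges)) {
    if (types[[e]] == "Requirement") next  # plantable but never mentioned
    for (m in seq_len(config$mentions_per_edge)) {
      plan <- plan_true_mention(types[[e]], edge_ets[[e]][["agent"]],
                                edge_ets[[e]][["target"]])
      mentions[[length(mentions) + 1L]] <- list(
        plan = plan, agent = sel$agent[[e]], target = sel$target[[e]],
        agent_et = edge_ets[[e]][["agent"]],
        target_et = edge_ets[[e]][["target"]], label = "tp")
    }
  }
  n_true <- length(mentions)
  n_fp <- round(n_true * config$fp_rate / (1 - config$fp_rate))
  cats <- coarse_categories()
  for (k in seq_len(n_fp)) {
    # intended coarse type: from a realization of a random planted edge
    src <- mentions[[sample(n_true, 1)]]
    intended <- plan_coarse(src$plan)
    realized <- sample(cats, 1, prob = config$type_confusion[intended, ])
    gpair <- sample(n, 2)
    mentions[[length(mentions) + 1L]] <- list(
      plan = plan_fp_mention(realized), agent = gpair[[1]],
      target = gpair[[2]], agent_et = sample(ENTITY_TYPES, 1),
      target_et = sample(ENTITY_TYPES, 1), label = "fp",
      oov = stats::runif(1) < config$unmatched_symbol_rate)
  }
  # --- slot assignment and surfaces ------------------------------------
  doc_of <- sample(config$n_docs, length(mentions), replace = TRUE)
  sent_of <- sample(config$sentences_per_doc, length(mentions), replace = TRUE)
  for (i in seq_along(mentions)) {
    m <- mentions[[i]]
    m$agent_surface <- if (isTRUE(m$oov)) sample(oov, 1) else
      mention_surface(m$agent)
    m$target_surface <- mention_surface(m$target)
    ab <- if (m$label == "tp") config$conf_correct else config$conf_incorrect
    m$confs <- draw_conf(n_plan_events(m$plan), ab)
    mentions[[i]] <- m
  }
  # --- document assembly ------------------------------------------------
  corpus <- list()
  gold_documents <- list()
  labels <- list()
  for (d in seq_len(config$n_docs)) {
    doc_id <- sprintf("SYN%04d", d)
    lines <- character(config$sentences_per_doc)
    entities <- list()
    events <- list()
    doc_labels <- character(0)
    t_counter <- 0L; e_counter <- 0L
    for (s in seq_len(config$sentences_per_doc)) {
      here <- which(doc_of == d & sent_of == s)
      if (length(here) == 0) {
        lines[[s]] <- "No relevant interactions were reported."
        next
      }
      line_offset <- if (s == 1) 0L else
        sum(nchar(lines[seq_len(s - 1)])) + (s - 1L)
      clause_texts <- character(0)
      for (mi in here) {
        m <- mentions[[mi]]
        rc <- render_clause(m$plan, m$agent_surface, m$agent_et,
                            m$target_surface, m$target_et, m$confs)
        clause_offset <- line_offset +
          (if (length(clause_texts)) sum(nchar(clause_texts)) +
             2L * length(clause_texts) else 0L)
        ent_ids <- list()
        for (en in names(rc$ents)) {
          spec <- rc$ents[[en]]
          t_counter <- t_counter + 1L
          id <- paste0("T", t_counter)
          mk <- rc$marks[[spec$mark]]
          entities[[id]] <- list(id = id, entity_type = spec$type,
                                 start = clause_offset + mk[[1]],
                                 end = clause_offset + mk[[2]],
                                 text = spec$text)
          ent_ids[[en]] <- id
        }
        ev_ids <- character(0)
        for (vi in seq_along(rc$evs)) {
          spec <- rc$evs[[vi]]
          e_counter <- e_counter + 1L
          id <- paste0("E", e_counter)
          ev_ids[[vi]] <- id
          mk <- rc$marks[[spec$trigger]]
          args <- lapply(spec$args, function(a) {
            if (!is.null(a$ent)) list(role = a$role, ref = ent_ids[[a$ent]])
            else list(role = a$role, ref = ev_ids[[a$ev]])
          })
          events[[id]] <- list(id = id, event_type = spec$event_type,
                               trigger_start = clause_offset + mk[[1]],
                               trigger_end = clause_offset + mk[[2]],
                               trigger_text = substr(rc$text, mk[[1]] + 1,
                                                     mk[[2]]),
                               args = args, confidence = spec$confidence,
                               negated = FALSE)
          doc_labels[[id]] <- m$label
        }
        clause_texts <- c(clause_texts, rc$text)
      }
      lines[[s]] <- paste0(paste(clause_texts, collapse = "; "), ".")
    }
    text <- paste(lines, collapse = "\n")
    doc <- new_document(doc_id, text, entities, events)
    corpus[[doc_id]] <- doc
    labels[[doc_id]] <- doc_labels
    gold_documents[[doc_id]] <- new_document(
      doc_id, text, entities,
      events[names(events)[doc_labels[names(events)] == "tp"]],
      doc$sentences)
  }
  list(corpus = corpus,
       truth = list(network = network, symbol_table = symbol_table,
                    labels = labels, gold_documents = gold_documents,
                    n_true = n_true, n_fp = n_fp, config = config))
}

# coarse category a plan realizes (for the type-confusion process)
plan_coarse <- function(plan) {
  switch(plan$kind,
         binding = "None|Binding",
         direct = paste(plan$layer, "Other", sep = "|"),
         nested = paste(plan$layer, plan$base, sep = "|"),
         double = paste(compose_layers(plan$layers[[1]], plan$layers[[2]]),
                        "Other", sep = "|"),
         orphan = paste("None", switch(plan$orphan_type,
                                       Transcription = "Transcription",
                                       Gene_expression = "GeneExpression",
                                       "Other"), sep = "|"))
}

#' Build labeled query sets from a generated bibliome
#'
#' @param corpus,truth the two components returned by [generate_bibliome()].
#' @return a list of labeled `query_set` objects covering the corpus.
#' @export
make_labeled_querysets <- function(corpus, truth) {
  out <- list()
  for (doc_id in names(corpus))
    out <- c(out, make_query_sets(corpus[[doc_id]], truth$labels[[doc_id]]))
  out
}
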