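#' Restrict relations to a document subset
#'
#' Emulates dataset restriction (e.g. all articles vs. organism-specific
#' article lists): only relations extracted from the listed documents
#' survive.
#'
#' @param relations pairwise relation data frame ([corpus_relations()]).
#' @param doc_ids character vector of document ids, or `"all"` (identity).
#' @return the restricted relation data frame.
#' @export
restrict_documents <- function(relations, doc_ids = "all") {
  if (identical(doc_ids, "all")) return(relations)
  out <- relations[relations$source_doc %in% doc_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve canonical symbols through a gold symbol table
#'
#' Surface symbols in the table are canonicalized before lookup, so
#' computationally generated symbols match manually curated ones whenever
#' they differ only by small lexical variation. Relations whose agent or
#' target does not resolve to a standardized gene identifier are dropped.
#'
#' @param relations pairwise relation data frame (canonical `agent`/`target`).
#' @param symbol_table data frame with columns `surface`, `gene_id`.
#' @return the surviving relations with added columns `agent_id`, `target_id`.
#' @export
match_symbols <- function(relations, symbol_table) {
  lookup <- symbol_lookup(symbol_table)
  resolve <- function(sym) {
    id <- lookup[[sym]]
    if (is.null(id)) NA_character_ else id
  }
  relations$agent_id <- vapply(relations$agent, resolve, character(1))
  relations$target_id <- vapply(relations$target, resolve, character(1))
  out <- relations[!is.na(relations$agent_id) & !is.na(relations$target_id), ,
                   drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a coarse event type to a GRN interaction type
#'
#' The rule table, applied top-down:
#'
#' | coarse event type                  | GRN type      |
#' |------------------------------------|---------------|
#' | Binding                            | Binding       |
#' | any regulation of Transcription    | Transcription |
#' | any regulation of Gene expression  | Transcription |
#' | Positive regulation of anything    | Activation    |
#' | Negative regulation of anything    | Inhibition    |
#' | Unspecified regulation of anything | Regulation    |
#'
#' A plain (unregulated) non-Binding coarse type maps to no GRN type.
#'
#' @param layer regulatory layer, one of [REG_LAYERS].
#' @param base coarse base, one of [COARSE_BASES].
#' @return a GRN type string, or `NA_character_` when no rule applies.
#' @export
map_type_rule <- function(layer, base) {
  stopifnot(layer %in% REG_LAYERS, base %in% COARSE_BASES)
  if (layer == "None" && base == "Binding") return("Binding")
  if (layer != "None" && base %in% c("Transcription", "GeneExpression"))
    return("Transcription")
  if (layer == "Positive") return("Activation")
  if (layer == "Negative") return("Inhibition")
  if (layer == "Unspecified") return("Regulation")
  NA_character_
}

# Allowed entity types per GRN interaction type (target slot, agent slot).
ENTITY_TYPE_RULES <- list(
  Binding       = list(target = "Protein", agent = "Gene"),
  Transcription = list(target = c("Protein", "PolymeraseComplex"),
                       agent = c("Gene", "Operon")),
  Regulation    = list(target = c("Protein", "PolymeraseComplex"),
                       agent = c("Gene", "Operon", "Protein", "ProteinComplex")),
  Activation    = list(target = c("Protein", "PolymeraseComplex"),
                       agent = c("Gene", "Operon", "Protein", "ProteinComplex")),
  Inhibition    = list(target = c("Protein", "PolymeraseComplex"),
                       agent = c("Gene", "Operon", "Protein", "ProteinComplex"))
)

#' Entity-type filtering of typed interactions
#'
#' Keeps an interaction only when its agent and target entity types are
#' compatible with its GRN type: Binding requires a Protein target and a
#' Gene agent (excluding protein–protein interactions); Transcription
#' requires a Protein/PolymeraseComplex target and a Gene/Operon agent; the
#' regulatory types additionally allow Protein and ProteinComplex agents.
#'
#' @param interactions data frame with columns `grn_type`,
#'   `agent_entity_type`, `target_entity_type` (plus anything else).
#' @return the kept subset of `interactions`.
#' @export
filter_entity_types <- function(interactions) {
  if (nrow(interactions) == 0) return(interactions)
  if (any(is.na(interactions$agent_entity_type)) ||
      any(is.na(interactions$target_entity_type)))
    stop("filter error: interaction with missing entity type")
  keep <- vapply(seq_len(nrow(interactions)), function(i) {
    rule <- ENTITY_TYPE_RULES[[interactions$grn_type[[i]]]]
    if (is.null(rule)) return(FALSE)
    interactions$target_entity_type[[i]] %in% rule$target &&
      interactions$agent_entity_type[[i]] %in% rule$agent
  }, logical(1))
  out <- interactions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Refactor surviving Binding interactions to Transcription
#'
#' Binding evidence that survives the entity-type filter (Protein target,
#' Gene agent) aligns with transcription-factor/promoter binding and is
#' systematically re-typed to Transcription. Must run *after*
#' [filter_entity_types()].
#'
#' @param interactions typed interaction data frame.
#' @return the same data frame with Binding rows re-typed.
#' @export
refactor_binding <- function(interactions) {
  interactions$grn_type[interactions$grn_type == "Binding"] <- "Transcription"
  interactions
}

#' Select at most one edge per ordered (agent, target) pair
#'
#' Sequential selection rules applied per ordered pair:
#'
#' 1. *specificity* — drop Regulation edges when any more specific type
#'    (Activation, Inhibition, Transcription, Binding) is present;
#' 2. *contradiction* — when both Activation and Inhibition remain, keep
#'    only the type of the single highest-confidence edge among them
#'    (confidence ties resolved in favour of Activation);
#' 3. *mechanism suppression* — drop mechanism edges (Transcription,
#'    Binding) when a regulatory edge (Activation, Inhibition, Regulation)
#'    remains;
#' 4. *residual tie-break* — among the remaining edges keep the one with
#'    the highest confidence, ties broken by lexicographic type order, then
#'    by input order.
#'
#' @param interactions data frame with columns `agent_id`, `target_id`,
#'   `grn_type`, `confidence`.
#' @return a data frame with at most one row per ordered pair.
#' @export
select_edges <- function(interactions) {
  if (nrow(interactions) == 0) return(interactions)
  key <- paste(interactions$agent_id, interactions$target_id, sep = "\r")
  picked <- lapply(split(seq_len(nrow(interactions)), key), function(rows) {
    cand <- interactions[rows, , drop = FALSE]
    cand$.ord <- rows
    # (1) specificity
    if (any(cand$grn_type %in% c("Activation", "Inhibition", "Transcription",
                                 "Binding")))
      cand <- cand[cand$grn_type != "Regulation", , drop = FALSE]
    # (2) contradiction
    if (any(cand$grn_type == "Activation") && any(cand$grn_type == "Inhibition")) {
      reg <- cand[cand$grn_type %in% c("Activation", "Inhibition"), , drop = FALSE]
      best <- reg[order(-reg$confidence,
                        match(reg$grn_type, c("Activation", "Inhibition")),
                        reg$.ord), , drop = FALSE][1, ]
      loser <- setdiff(c("Activation", "Inhibition"), best$grn_type)
      cand <- cand[cand$grn_type != loser, , drop = FALSE]
    }
    # (3) mechanism suppression
    if (any(cand$grn_type %in% c("Activation", "Inhibition", "Regulation")))
      cand <- cand[!cand$grn_type %in% c("Transcription", "Binding"), ,
                   drop = FALSE]
    # (4) residual tie-break
    cand[order(-cand$confidence, cand$grn_type, cand$.ord), , drop = FALSE][1, ]
  })
  out <- do.call(rbind, picked)
  out <- out[order(out$.ord), , drop = FALSE]
  out$.ord <- NULL
  rownames(out) <- NULL
  out
}

#' Rule-based conversion of an event corpus to a GRN network
#'
#' End-to-end pipeline: flatten nested events to pairwise relations,
#' restrict to a document subset, (optionally) drop negated relations,
#' resolve symbols through the gold table, map coarse event types to GRN
#' types, filter by entity-type compatibility, refactor surviving Binding
#' edges to Transcription, and select one edge per ordered pair.
#'
#' @param documents list of `bib_document` objects.
#' @param symbol_table gold symbol table (`surface`, `gene_id`).
#' @param doc_restriction `"all"` or a vector of document ids.
#' @param drop_negated drop relations carrying a negation context before
#'   type mapping (default `FALSE`: negation is ignored, the behaviour of
#'   the original conversion).
#' @param apply_entity_filter,apply_refactor,apply_selection stage toggles
#'   for ablation experiments.
#' @return a data frame of GRN interactions (`agent_id`, `target_id`,
#'   `grn_type`, `confidence`, entity types), with a `stage_counts`
#'   attribute recording the relation count after each stage.
#' @export
convert_rule_based <- function(documents, symbol_table, doc_restriction = "all",
                               drop_negated = FALSE,
                               apply_entity_filter = TRUE,
                               apply_refactor = TRUE,
                               apply_selection = TRUE) {
  counts <- c()
  rel <- corpus_relations(documents)
  counts["flattened"] <- nrow(rel)
  rel <- restrict_documents(rel, doc_restriction)
  counts["restricted"] <- nrow(rel)
  if (drop_negated) rel <- rel[!rel$negated, , drop = FALSE]
  counts["negation"] <- nrow(rel)
  rel <- match_symbols(rel, symbol_table)
  counts["symbol_matched"] <- nrow(rel)
  if (nrow(rel) > 0) {
    rel$grn_type <- mapply(map_type_rule, rel$layer, rel$base)
    rel <- rel[!is.na(rel$grn_type), , drop = FALSE]
  } else {
    rel$grn_type <- character(0)
  }
  counts["type_mapped"] <- nrow(rel)
  if (apply_entity_filter) rel <- filter_entity_types(rel)
  counts["entity_filtered"] <- nrow(rel)
  if (apply_refactor) rel <- refactor_binding(rel)
  if (apply_selection) rel <- select_edges(rel)
  counts["selected"] <- nrow(rel)
  out <- rel[, intersect(c("agent_id", "target_id", "grn_type", "confidence",
                           "agent_entity_type", "target_entity_type",
                           "source_doc"), names(rel)), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage_counts") <- counts
  out
}
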