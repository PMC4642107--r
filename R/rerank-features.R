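#' Label predicted events against gold events
#'
#' A predicted event is a true positive when a gold event of the same
#' document matches it recursively: equal event type, equal trigger span
#' (optionally within a small character tolerance), and equal argument
#' multisets — entity arguments compared by span and entity type, event
#' arguments compared recursively. Each gold event matches at most one
#' prediction; predictions are matched greedily in order of decreasing
#' confidence (ties by document order).
#'
#' @param predicted_doc `bib_document` carrying the predicted events.
#' @param gold_doc `bib_document` carrying the gold events (same text).
#' @param tolerance maximum absolute offset difference allowed when
#'   comparing trigger/entity spans (default 0, exact offsets).
#' @return a named character vector (`"tp"`/`"fp"`) keyed by predicted
#'   event id, in document order, with attribute `matched_gold` (named
#'   vector mapping matched prediction ids to gold event ids).
#' @export
label_candidates <- function(predicted_doc, gold_doc, tolerance = 0) {
  preds <- predicted_doc$events
  golds <- gold_doc$events
  labels <- stats::setNames(rep("fp", length(preds)), names(preds))
  matched_gold <- character(0)
  if (length(preds) > 0) {
    conf <- vapply(preds, function(e) e$confidence, numeric(1))
    order_idx <- order(-conf, seq_along(preds))
    gold_used <- stats::setNames(rep(FALSE, length(golds)), names(golds))
    for (i in order_idx) {
      pe <- preds[[i]]
      for (gid in names(golds)) {
        if (gold_used[[gid]]) next
        if (events_equal(pe, predicted_doc, golds[[gid]], gold_doc, tolerance)) {
          labels[[pe$id]] <- "tp"
          gold_used[[gid]] <- TRUE
          matched_gold[[pe$id]] <- gid
          break
        }
      }
    }
  }
  attr(labels, "matched_gold") <- matched_gold
  labels
}

events_equal <- function(e1, d1, e2, d2, tol = 0) {
  if (e1$event_type != e2$event_type) return(FALSE)
  if (abs(e1$trigger_start - e2$trigger_start) > tol ||
      abs(e1$trigger_end - e2$trigger_end) > tol) return(FALSE)
  args_equal_multiset(e1$args, d1, e2$args, d2, tol)
}

# multiset equality with backtracking over argument pairings
args_equal_multiset <- function(a1, d1, a2, d2, tol) {
  if (length(a1) != length(a2)) return(FALSE)
  if (length(a1) == 0) return(TRUE)
  used <- rep(FALSE, length(a2))
  match_from <- function(i) {
    if (i > length(a1)) return(TRUE)
    for (j in seq_along(a2)) {
      if (used[j]) next
      if (arg_equal(a1[[i]], d1, a2[[j]], d2, tol)) {
        used[j] <<- TRUE
        if (match_from(i + 1)) return(TRUE)
        used[j] <<- FALSE
      }
    }
    FALSE
  }
  match_from(1)
}

arg_equal <- function(x, d1, y, d2, tol) {
  if (x$role != y$role) return(FALSE)
  x_is_ent <- startsWith(x$ref, "T")
  y_is_ent <- startsWith(y$ref, "T")
  if (x_is_ent != y_is_ent) return(FALSE)
  if (x_is_ent) {
    ex <- d1$entities[[x$ref]]; ey <- d2$entities[[y$ref]]
    ex$entity_type == ey$entity_type &&
      abs(ex$start - ey$start) <= tol && abs(ex$end - ey$end) <= tol
  } else {
    events_equal(d1$events[[x$ref]], d1, d2$events[[y$ref]], d2, tol)
  }
}

n_event_args <- function(event) length(event$args)

#' Group a document's events into per-sentence query sets
#'
#' The sentence is the unit within which ranking scores are comparable:
#' each non-empty sentence of the document yields one query set holding all
#' events whose trigger lies inside it.
#'
#' @param doc a `bib_document`.
#' @param labels optional named `"tp"`/`"fp"` vector ([label_candidates()]);
#'   missing labels default to `"unknown"`.
#' @return a list of `query_set` objects. Each holds `doc_id`, `sentence`
#'   (start/end), the `doc`, and a `candidates` data frame with columns
#'   `event_id`, `base_confidence`, `n_args`, `label`, `rank_score`.
#' @export
make_query_sets <- function(doc, labels = NULL) {
  if (length(doc$events) == 0) return(list())
  sent_idx <- vapply(doc$events, function(ev)
    sentence_of(doc, ev$trigger_start), integer(1))
  out <- list()
  for (s in sort(unique(sent_idx))) {
    ids <- names(doc$events)[sent_idx == s]
    cand <- data.frame(
      event_id = ids,
      base_confidence = vapply(ids, function(id)
        doc$events[[id]]$confidence, numeric(1)),
      n_args = vapply(ids, function(id)
        n_event_args(doc$events[[id]]), integer(1)),
      label = if (is.null(labels)) "unknown" else
        unname(ifelse(is.na(labels[ids]), "unknown", labels[ids])),
      rank_score = NA_real_,
      stringsAsFactors = FALSE)
    rownames(cand) <- NULL
    out[[length(out) + 1L]] <- structure(
      list(doc_id = doc$doc_id, sentence_index = s,
           sentence = c(start = doc$sentences$start[[s]],
                        end = doc$sentences$end[[s]]),
           doc = doc, candidates = cand),
      class = "query_set")
  }
  out
}

#' @export
print.query_set <- function(x, ...) {
  cat("<query_set>", x$doc_id, "sentence", x$sentence_index, "-",
      nrow(x$candidates), "candidates\n")
  invisible(x)
}

rerank_feature_names <- function(feature_config = rerank_feature_config()) {
  types <- c(GE_EVENT_TYPES, "other")
  nm <- character(0)
  if (feature_config$event)
    nm <- c(nm, "base_conf", paste0("type_", types), "n_args",
            paste0("path_h", seq_len(8)))
  if (feature_config$sentence)
    nm <- c(nm, "ctx_n", "ctx_conf_mean", "ctx_conf_max", "ctx_conf_min",
            paste0("ctx_type_", types))
  if (feature_config$bibliome)
    nm <- c(nm,
            unlist(lapply(feature_config$levels, function(lvl)
              paste0("bib_", lvl, "_", c("exact_n", "exact_maxc", "partial_n")))),
            "net_pair_n", "net_pair_maxc")
  nm
}

#' Feature-group configuration for the re-ranker
#'
#' The three feature groups can be toggled independently, supporting
#' ablation experiments: `event` (confidence, event type, argument count,
#' hashed trigger-to-leaf role/type paths), `sentence` (statistics over the
#' co-candidates of the same sentence), and `bibliome` (exact and partial
#' generalization-key occurrence counts and confidences per level, plus the
#' network-interpretation pairwise counts).
#'
#' @param event,sentence,bibliome logical toggles.
#' @param levels generalization levels for the bibliome group.
#' @return a list.
#' @export
rerank_feature_config <- function(event = TRUE, sentence = TRUE,
                                  bibliome = TRUE,
                                  levels = c("canonical", "normalized_id")) {
  list(event = event, sentence = sentence, bibliome = bibliome,
       levels = levels)
}

#' Extract the re-ranking feature vector of one candidate event
#'
#' @param event_id id of the candidate within the query set's document.
#' @param qs a `query_set`.
#' @param idx an `event_index` (the bibliome).
#' @param feature_config a [rerank_feature_config()].
#' @return a named numeric vector.
#' @export
extract_event_features <- function(event_id, qs, idx,
                                   feature_config = rerank_feature_config()) {
  doc <- qs$doc
  ev <- doc$events[[event_id]]
  types <- c(GE_EVENT_TYPES, "other")
  type_slot <- function(tp) as.numeric(types == if (tp %in% GE_EVENT_TYPES) tp else "other")
  v <- numeric(0)
  if (feature_config$event) {
    paths <- trigger_paths(ev, doc)
    ph <- numeric(8)
    for (p in paths) {
      b <- string_bucket(p, 8)
      ph[b] <- ph[b] + 1
    }
    v <- c(v, ev$confidence, type_slot(ev$event_type), length(ev$args), ph)
  }
  if (feature_config$sentence) {
    others <- qs$candidates$event_id[qs$candidates$event_id != event_id]
    confs <- qs$candidates$base_confidence[qs$candidates$event_id != event_id]
    hist <- numeric(length(types))
    for (oid in others) hist <- hist + type_slot(doc$events[[oid]]$event_type)
    v <- c(v, length(others),
           if (length(confs)) mean(confs) else 0,
           if (length(confs)) max(confs) else 0,
           if (length(confs)) min(confs) else 0,
           hist)
  }
  if (feature_config$bibliome) {
    leaves <- leaf_symbols(ev, doc)
    for (lvl in feature_config$levels) {
      key <- tryCatch(generalization_key(ev, doc, lvl, idx$symbol_table),
                      error = function(e) NULL)
      if (is.null(key) || !lvl %in% idx$levels) {
        v <- c(v, 0, 0, 0)
      } else {
        ex <- index_exact(idx, key)
        pa <- index_partial(idx, lvl, ev$event_type, leaves, exclude_key = key)
        v <- c(v, ex[["count"]], ex[["max_conf"]], pa[["count"]])
      }
    }
    rel <- flatten_to_relations(ev, doc)
    if (nrow(rel) == 0) {
      v <- c(v, 0, 0)
    } else {
      stats <- vapply(seq_len(nrow(rel)), function(k)
        index_pair(idx, rel$agent[[k]], rel$target[[k]]), numeric(2))
      v <- c(v, sum(stats[1, ]), max(stats[2, ]))
    }
  }
  stats::setNames(v, rerank_feature_names(feature_config))
}

# role/type paths from the root trigger to every argument leaf
trigger_paths <- function(event, doc) {
  out <- character(0)
  for (a in event$args) {
    if (startsWith(a$ref, "T")) {
      out <- c(out, paste(event$event_type, a$role, "GGP", sep = ">"))
    } else {
      sub <- trigger_paths(doc$events[[a$ref]], doc)
      out <- c(out, paste(event$event_type, a$role, sub, sep = ">"))
    }
  }
  out
}

string_bucket <- function(s, buckets) {
  v <- utf8ToInt(s)
  (sum(v * (seq_along(v) %% 31 + 1)) %% buckets) + 1
}

# feature matrix for all candidates of a list of query sets
query_set_features <- function(query_sets, idx, feature_config) {
  nm <- rerank_feature_names(feature_config)
  rows <- list()
  for (qs in query_sets) {
    for (id in qs$candidates$event_id) {
      rows[[length(rows) + 1L]] <- extract_event_features(id, qs, idx,
                                                          feature_config)
    }
  }
  if (length(rows) == 0)
    return(matrix(numeric(0), ncol = length(nm), dimnames = list(NULL, nm)))
  do.call(rbind, rows)
}

# sentence-level features for the threshold regressor
sentence_features <- function(qs) {
  types <- c(GE_EVENT_TYPES, "other")
  sc <- qs$candidates$rank_score
  if (anyNA(sc)) stop("sentence features require assigned rank scores")
  cf <- qs$candidates$base_confidence
  hist <- numeric(length(types))
  for (id in qs$candidates$event_id) {
    tp <- qs$doc$events[[id]]$event_type
    slot <- if (tp %in% GE_EVENT_TYPES) tp else "other"
    hist[types == slot] <- hist[types == slot] + 1
  }
  # deciles of the sentence's score distribution: the threshold target is by
  # construction an order statistic of these scores, so give the linear
  # regressor the order statistics directly
  qq <- stats::quantile(sc, probs = seq(0, 1, 0.1), names = FALSE, type = 7)
  stats::setNames(
    c(nrow(qs$candidates), mean(sc), min(sc), max(sc), max(sc) - min(sc),
      if (length(sc) > 1) stats::sd(sc) else 0,
      mean(cf), min(cf), max(cf),
      sum(qs$candidates$n_args == 1), sum(qs$candidates$n_args > 1), qq, hist),
    c("n_cand", "score_mean", "score_min", "score_max", "score_spread",
      "score_sd", "conf_mean", "conf_min", "conf_max", "n_single_arg",
      "n_multi_arg", paste0("score_q", seq(0, 100, 10)),
      paste0("sent_type_", types)))
}
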