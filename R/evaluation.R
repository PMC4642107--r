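#' Score a predicted network against a gold network
#'
#' Relations are paired on the ordered (agent, target) identifier pair. In
#' `strict` mode a gold relation is a *match* when a predicted relation on
#' its pair has the same interaction type, a *substitution* when a
#' prediction exists on the pair with a different type, and a *deletion*
#' otherwise; in `relaxed` mode the type is ignored, so any prediction on a
#' gold pair is a match. Predicted relations on pairs absent from the gold
#' network are *insertions*; when several predictions land on one pair, the
#' highest-confidence one is paired and the rest count as insertions.
#'
#' The Slot Error Rate is the standard slot-error formula
#' \deqn{SER = (S + I + D) / N}
#' with `N` the number of gold relations; values below 1 indicate useful
#' predictions. Note that official shared-task scorers may weight
#' substitutions differently; this implementation counts each substitution
#' as one full error.
#'
#' @param predicted data frame with columns `agent_id`, `target_id`,
#'   `grn_type` and optionally `confidence`.
#' @param gold data frame with columns `agent_id`, `target_id`, `grn_type`.
#' @param mode `"strict"` or `"relaxed"`.
#' @return an object of class `network_score` with fields `matches`,
#'   `substitutions`, `insertions`, `deletions`, `precision`, `recall`,
#'   `f_score`, `ser`.
#' @export
score_network <- function(predicted, gold, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  if (nrow(gold) == 0)
    stop("score error: SER is undefined for an empty gold network")
  conf <- predicted$confidence %||% rep(1, nrow(predicted))
  # one representative prediction per ordered pair (highest confidence);
  # the remainder are insertions
  extra_insertions <- 0L
  rep_pred <- predicted
  if (nrow(predicted) > 0) {
    ord <- order(-conf, seq_len(nrow(predicted)))
    rep_pred <- predicted[ord, , drop = FALSE]
    dup <- duplicated(rep_pred[c("agent_id", "target_id")])
    extra_insertions <- sum(dup)
    rep_pred <- rep_pred[!dup, , drop = FALSE]
  }
  pred_key <- paste(rep_pred$agent_id, rep_pred$target_id, sep = "\r")
  gold_key <- paste(gold$agent_id, gold$target_id, sep = "\r")
  matches <- 0L; substitutions <- 0L; deletions <- 0L
  for (i in seq_len(nrow(gold))) {
    hit <- match(gold_key[[i]], pred_key)
    if (is.na(hit)) {
      deletions <- deletions + 1L
    } else if (mode == "relaxed" ||
               rep_pred$grn_type[[hit]] == gold$grn_type[[i]]) {
      matches <- matches + 1L
    } else {
      substitutions <- substitutions + 1L
    }
  }
  insertions <- sum(!pred_key %in% gold_key) + extra_insertions
  n_gold <- nrow(gold)
  p <- safe_div(matches, nrow(predicted))
  r <- matches / n_gold
  structure(list(mode = mode, matches = matches, substitutions = substitutions,
                 insertions = insertions, deletions = deletions,
                 precision = p, recall = r, f_score = fscore(p, r),
                 ser = (substitutions + insertions + deletions) / n_gold,
                 n_gold = n_gold, n_predicted = nrow(predicted)),
            class = "network_score")
}

#' @export
print.network_score <- function(x, ...) {
  cat(sprintf("<network_score> %s: SER %.3f | P %.3f R %.3f F %.3f (M %d S %d I %d D %d; gold %d, predicted %d)\n",
              x$mode, x$ser, x$precision, x$recall, x$f_score, x$matches,
              x$substitutions, x$insertions, x$deletions, x$n_gold,
              x$n_predicted))
  invisible(x)
}

#' Score predicted events against gold events
#'
#' Matches predicted and gold events per document with the recursive
#' structural matcher of [label_candidates()] and tallies tp/fp/fn overall
#' and per event-type group ([EVENT_TYPE_GROUPS]): matched predictions are
#' tp, unmatched predictions fp, unmatched gold events fn.
#'
#' @param predicted_corpus named list of `bib_document` objects.
#' @param gold_corpus named list of `bib_document` objects over the same
#'   document ids.
#' @param tolerance span-matching tolerance ([label_candidates()]).
#' @return an object of class `event_score` with overall precision, recall
#'   and F plus a `by_group` data frame.
#' @export
score_events <- function(predicted_corpus, gold_corpus, tolerance = 0) {
  groups <- c(names(EVENT_TYPE_GROUPS), "Other")
  counts <- matrix(0L, nrow = length(groups), ncol = 3,
                   dimnames = list(groups, c("tp", "fp", "fn")))
  for (doc_id in names(predicted_corpus)) {
    pdoc <- predicted_corpus[[doc_id]]
    gdoc <- gold_corpus[[doc_id]]
    if (is.null(gdoc)) stop("no gold document for ", doc_id)
    labels <- label_candidates(pdoc, gdoc, tolerance)
    matched_gold <- attr(labels, "matched_gold")
    for (id in names(labels)) {
      g <- event_type_group(pdoc$events[[id]]$event_type)
      col <- if (labels[[id]] == "tp") "tp" else "fp"
      counts[g, col] <- counts[g, col] + 1L
    }
    for (gid in setdiff(names(gdoc$events), unname(matched_gold))) {
      g <- event_type_group(gdoc$events[[gid]]$event_type)
      counts[g, "fn"] <- counts[g, "fn"] + 1L
    }
  }
  tot <- colSums(counts)
  p <- safe_div(tot[["tp"]], tot[["tp"]] + tot[["fp"]])
  r <- safe_div(tot[["tp"]], tot[["tp"]] + tot[["fn"]])
  by_group <- data.frame(group = groups,
                         tp = counts[, "tp"], fp = counts[, "fp"],
                         fn = counts[, "fn"], stringsAsFactors = FALSE)
  by_group$precision <- mapply(function(tp, fp) safe_div(tp, tp + fp),
                               by_group$tp, by_group$fp)
  by_group$recall <- mapply(function(tp, fn) safe_div(tp, tp + fn),
                            by_group$tp, by_group$fn)
  by_group$f_score <- mapply(fscore, by_group$precision, by_group$recall)
  rownames(by_group) <- NULL
  structure(list(tp = tot[["tp"]], fp = tot[["fp"]], fn = tot[["fn"]],
                 precision = p, recall = r, f_score = fscore(p, r),
                 by_group = by_group),
            class = "event_score")
}

#' @export
print.event_score <- function(x, ...) {
  cat(sprintf("<event_score> P %.3f R %.3f F %.3f (tp %d fp %d fn %d)\n",
              x$precision, x$recall, x$f_score, x$tp, x$fp, x$fn))
  shown <- x$by_group[x$by_group$tp + x$by_group$fp + x$by_group$fn > 0, ]
  for (i in seq_len(nrow(shown))) {
    cat(sprintf("  %-13s P %.3f R %.3f F %.3f\n", shown$group[[i]],
                shown$precision[[i]], shown$recall[[i]], shown$f_score[[i]]))
  }
  invisible(x)
}
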