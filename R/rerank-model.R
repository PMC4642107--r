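#' Train the per-sentence pairwise ranking model
#'
#' Pairwise reduction of ranking to large-margin classification: for every
#' (true positive, false positive) candidate pair *within the same query
#' set* a feature-difference vector is formed (in both orientations), and a
#' linear soft-margin SVM is fitted to the differences. The resulting
#' weight vector scores candidates; scores are comparable only within a
#' sentence, which is exactly how they are consumed. No preference pairs
#' ever span two sentences.
#'
#' @param query_sets labeled `query_set` list ([make_query_sets()]).
#' @param idx the bibliome `event_index`.
#' @param feature_config a [rerank_feature_config()].
#' @param cost soft-margin cost of the underlying SVM.
#' @param seed random seed (training is deterministic given the seed).
#' @return an object of class `event_ranker`.
#' @export
train_ranker <- function(query_sets, idx,
                         feature_config = rerank_feature_config(),
                         cost = 1, seed = 1) {
  feats <- query_set_features(query_sets, idx, feature_config)
  center <- colMeans(feats)
  scl <- apply(feats, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  x <- scale(feats, center = center, scale = scl)
  offsets <- cumsum(c(0, vapply(query_sets, function(q)
    nrow(q$candidates), numeric(1))))
  diffs <- list()
  for (qi in seq_along(query_sets)) {
    lab <- query_sets[[qi]]$candidates$label
    tp_rows <- offsets[qi] + which(lab == "tp")
    fp_rows <- offsets[qi] + which(lab == "fp")
    for (i in tp_rows) for (j in fp_rows) {
      d <- x[i, ] - x[j, ]
      diffs[[length(diffs) + 1L]] <- d
      diffs[[length(diffs) + 1L]] <- -d
    }
  }
  if (length(diffs) == 0)
    stop("training error: no query set contains both tp and fp candidates")
  dx <- do.call(rbind, diffs)
  dy <- factor(rep(c("pref", "not"), length.out = nrow(dx)),
               levels = c("not", "pref"))
  set.seed(seed)
  fit <- e1071::svm(dx, dy, type = "C-classification", kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  # libSVM orients the decision values by the first training label; flip so
  # that larger score always means "preferred"
  if (stats::predict(fit, rbind(dx[1, ]), decision.values = TRUE) ==
      "pref" && dy[1] == "not") w <- -w
  if (dy[1] == "pref" &&
      stats::predict(fit, rbind(dx[1, ])) == "not") w <- -w
  structure(list(w = w, center = center, scale = scl,
                 feature_config = feature_config, cost = cost, seed = seed),
            class = "event_ranker")
}

#' @export
print.event_ranker <- function(x, ...) {
  cat("<event_ranker> linear pairwise ranking model over",
      length(x$w), "features\n")
  invisible(x)
}

ranker_scores <- function(ranker, feats) {
  x <- scale(feats, center = ranker$center, scale = ranker$scale)
  drop(x %*% ranker$w)
}

#' Assign rank scores to query-set candidates
#'
#' @param ranker an `event_ranker`.
#' @param query_sets list of `query_set` objects.
#' @param idx the bibliome `event_index` used for feature extraction.
#' @return the query sets with `rank_score` filled in.
#' @export
score_candidates <- function(ranker, query_sets, idx) {
  lapply(query_sets, function(qs) {
    feats <- query_set_features(list(qs), idx, ranker$feature_config)
    qs$candidates$rank_score <- ranker_scores(ranker, feats)
    qs
  })
}

# per-sentence F of a retained candidate subset: tp retained = tp,
# fp retained = fp, tp removed = fn; empty retained set scores 1 when the
# sentence has no tp at all, else 0
sentence_f <- function(labels, retained) {
  tp <- sum(retained & labels == "tp")
  fp <- sum(retained & labels == "fp")
  fn <- sum(!retained & labels == "tp")
  if (tp + fp == 0) return(if (tp + fn == 0) 1 else 0)
  fscore(safe_div(tp, tp + fp), safe_div(tp, tp + fn))
}

#' Per-sentence threshold target
#'
#' The regression target for a labeled, scored sentence: the rank score of
#' the lowest-scoring event in the retention set maximizing the
#' within-sentence F-score, found by brute force over the score-ordered cut
#' points (ties resolved toward the larger retained set). Sentences with
#' only false positives get the maximum score plus `fallback_offset`
#' (everything removed); sentences with only true positives get the minimum
#' score minus `fallback_offset` (everything retained with margin).
#'
#' @param qs a scored, labeled `query_set`.
#' @param fallback_offset margin used for single-label sentences
#'   (default 0.2).
#' @return a single threshold value.
#' @export
threshold_target <- function(qs, fallback_offset = 0.2) {
  stopifnot(fallback_offset > 0)
  sc <- qs$candidates$rank_score
  lab <- qs$candidates$label
  if (anyNA(sc)) stop("threshold target requires assigned rank scores")
  if (all(lab == "fp")) return(max(sc) + fallback_offset)
  if (all(lab == "tp")) return(min(sc) - fallback_offset)
  ord <- order(-sc, seq_along(sc))
  # only cut points realizable by a threshold (no ties across the cut)
  valid <- vapply(seq_along(ord), function(k) {
    k == length(ord) || sc[ord[k]] > sc[ord[k + 1]]
  }, logical(1))
  best_f <- -1; best_k <- NA_integer_
  for (k in which(valid)) {
    retained <- logical(length(sc))
    retained[ord[seq_len(k)]] <- TRUE
    f <- sentence_f(lab, retained)
    if (f > best_f || (f == best_f && !is.na(best_k) && k > best_k)) {
      best_f <- f; best_k <- k
    }
  }
  sc[ord[best_k]]
}

#' Oracle per-sentence thresholds
#'
#' Gold-informed bounds on the attainable filtering performance. The
#' best-case oracle picks the F-maximizing threshold in every sentence
#' (removing everything in all-false-positive sentences); the worst-case
#' oracle is identical except that it is not allowed to filter anything
#' from all-false-positive sentences (threshold `-Inf` there).
#'
#' @param query_sets scored, labeled query sets.
#' @param mode `"best"` or `"worst"`.
#' @param fallback_offset margin for removed-everything thresholds.
#' @return numeric vector of thresholds, one per query set.
#' @export
oracle_thresholds <- function(query_sets, mode = c("best", "worst"),
                              fallback_offset = 0.2) {
  mode <- match.arg(mode)
  vapply(query_sets, function(qs) {
    if (mode == "worst" && all(qs$candidates$label == "fp")) return(-Inf)
    threshold_target(qs, fallback_offset)
  }, numeric(1))
}

#' Train the per-sentence threshold regressor
#'
#' Linear large-margin (epsilon-insensitive) regression of the per-sentence
#' threshold targets onto sentence-level features: candidate count, rank
#' score statistics (mean, min, max, spread, sd), base-confidence
#' statistics, argument-count split, and the sentence's event-type
#' histogram. Degenerate constant targets yield a constant regressor.
#'
#' @param query_sets scored, labeled query sets (at least 2).
#' @param targets numeric per-sentence targets ([threshold_target()]);
#'   computed from the query sets when omitted.
#' @param cost,epsilon SVR hyperparameters.
#' @param seed random seed (training is deterministic given the seed).
#' @param fallback_offset passed to [threshold_target()] when targets are
#'   computed here.
#' @return an object of class `threshold_regressor` with a `predict()`
#'   method taking a list of scored query sets.
#' @export
train_threshold_regressor <- function(query_sets, targets = NULL, cost = 1,
                                      epsilon = 0.1, seed = 1,
                                      fallback_offset = 0.2) {
  if (length(query_sets) < 2)
    stop("training error: need at least 2 training sentences")
  if (is.null(targets))
    targets <- vapply(query_sets, threshold_target, numeric(1),
                      fallback_offset = fallback_offset)
  feats <- do.call(rbind, lapply(query_sets, sentence_features))
  if (max(targets) - min(targets) < 1e-12) {
    return(structure(list(kind = "constant", value = targets[[1]]),
                     class = "threshold_regressor"))
  }
  center <- colMeans(feats)
  scl <- apply(feats, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  x <- scale(feats, center = center, scale = scl)
  set.seed(seed)
  fit <- e1071::svm(x, targets, type = "eps-regression", kernel = "linear",
                    cost = cost, epsilon = epsilon, scale = FALSE)
  structure(list(kind = "svr", fit = fit, center = center, scale = scl),
            class = "threshold_regressor")
}

#' @export
predict.threshold_regressor <- function(object, query_sets, ...) {
  if (object$kind == "constant")
    return(rep(object$value, length(query_sets)))
  feats <- do.call(rbind, lapply(query_sets, sentence_features))
  x <- scale(feats, center = object$center, scale = object$scale)
  unname(stats::predict(object$fit, x))
}

#' @export
print.threshold_regressor <- function(x, ...) {
  if (x$kind == "constant") {
    cat("<threshold_regressor> constant at", x$value, "\n")
  } else {
    cat("<threshold_regressor> linear epsilon-insensitive regressor\n")
  }
  invisible(x)
}

#' Apply a score threshold to one sentence
#'
#' Removes candidates with `rank_score < threshold`, then cascades: a
#' retained event whose event-valued argument was removed (within this
#' query set) is removed as well, so the output stays structurally valid.
#' Lowering the threshold never removes a previously retained event.
#'
#' @param qs a scored `query_set`.
#' @param threshold the score threshold.
#' @return the query set with a logical `retained` candidate column.
#' @export
apply_filter <- function(qs, threshold) {
  sc <- qs$candidates$rank_score
  if (anyNA(sc)) stop("apply_filter requires assigned rank scores")
  retained <- sc >= threshold
  names(retained) <- qs$candidates$event_id
  retained <- cascade_removals(retained, qs$doc)
  qs$candidates$retained <- unname(retained[qs$candidates$event_id])
  qs
}

# iteratively remove events whose event arguments are removed; ids absent
# from `retained` (outside the filtering scope) are treated as retained
cascade_removals <- function(retained, doc) {
  repeat {
    changed <- FALSE
    for (id in names(retained)) {
      if (!retained[[id]]) next
      for (a in doc$events[[id]]$args) {
        if (startsWith(a$ref, "E") && !is.na(retained[a$ref]) &&
            isFALSE(retained[[a$ref]])) {
          retained[[id]] <- FALSE
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) return(retained)
  }
}

#' Filter a corpus of query sets with per-sentence thresholds
#'
#' Applies one threshold per query set and cascades removals across the
#' whole document (an event referencing a removed event in another sentence
#' is removed too).
#'
#' @param query_sets scored query sets.
#' @param thresholds numeric vector, one per query set.
#' @return the query sets, each with a `retained` candidate column.
#' @export
filter_corpus <- function(query_sets, thresholds) {
  stopifnot(length(query_sets) == length(thresholds))
  by_doc <- split(seq_along(query_sets),
                  vapply(query_sets, function(q) q$doc_id, character(1)))
  for (rows in by_doc) {
    doc <- query_sets[[rows[[1]]]]$doc
    retained <- logical(0)
    for (qi in rows) {
      r <- query_sets[[qi]]$candidates$rank_score >= thresholds[[qi]]
      names(r) <- query_sets[[qi]]$candidates$event_id
      retained <- c(retained, r)
    }
    retained <- cascade_removals(retained, doc)
    for (qi in rows) {
      query_sets[[qi]]$candidates$retained <-
        unname(retained[query_sets[[qi]]$candidates$event_id])
    }
  }
  query_sets
}

#' Precision/recall/F of a filtered candidate set
#'
#' Retained true positives count as tp, retained false positives as fp, and
#' removed true positives as fn; `n_gold` (total gold events) can exceed
#' the number of tp candidates when the upstream extractor missed gold
#' events.
#'
#' @param query_sets scored, labeled query sets.
#' @param thresholds per-sentence thresholds (`-Inf` retains everything).
#' @param n_gold number of gold events (defaults to the number of tp
#'   candidates).
#' @param subset optional: `"single"`/`"multi"` restricts the tally to
#'   single-argument or multiple-argument candidates (retention is still
#'   decided globally).
#' @return a list with `precision`, `recall`, `f`, `tp`, `fp`, `fn`.
#' @export
filter_metrics <- function(query_sets, thresholds, n_gold = NULL,
                           subset = NULL) {
  filtered <- filter_corpus(query_sets, thresholds)
  tp <- 0L; fp <- 0L; n_tp_total <- 0L
  for (qs in filtered) {
    keep <- rep(TRUE, nrow(qs$candidates))
    if (identical(subset, "single")) keep <- qs$candidates$n_args == 1
    if (identical(subset, "multi")) keep <- qs$candidates$n_args > 1
    cand <- qs$candidates[keep, , drop = FALSE]
    tp <- tp + sum(cand$retained & cand$label == "tp")
    fp <- fp + sum(cand$retained & cand$label == "fp")
    n_tp_total <- n_tp_total + sum(cand$label == "tp")
  }
  if (is.null(n_gold)) n_gold <- n_tp_total
  p <- safe_div(tp, tp + fp)
  r <- safe_div(tp, n_gold)
  list(precision = p, recall = r, f = fscore(p, r),
       tp = tp, fp = fp, fn = n_gold - tp)
}

#' Random-ranking baseline under the worst-case oracle
#'
#' Replaces rank scores by uniform random values, applies the worst-case
#' oracle thresholds, and averages precision/recall/F over `n_runs` runs.
#' Quantifies how much of the oracle's gain is attributable to gold access
#' rather than to the ranking itself.
#'
#' @param query_sets labeled query sets (scores are ignored).
#' @param n_runs number of randomized runs (default 10).
#' @param seed random seed; results are reproducible given the seed.
#' @param fallback_offset oracle margin.
#' @inheritParams filter_metrics
#' @return a list with averaged `precision`, `recall`, `f` and the
#'   per-run metrics in `runs`.
#' @export
random_rank_baseline <- function(query_sets, n_runs = 10, seed = 1,
                                 fallback_offset = 0.2, n_gold = NULL,
                                 subset = NULL) {
  if (length(query_sets) == 0) stop("no query sets given")
  set.seed(seed)
  runs <- vector("list", n_runs)
  for (run in seq_len(n_runs)) {
    qss <- lapply(query_sets, function(qs) {
      qs$candidates$rank_score <- stats::runif(nrow(qs$candidates))
      qs
    })
    thr <- oracle_thresholds(qss, "worst", fallback_offset)
    runs[[run]] <- filter_metrics(qss, thr, n_gold = n_gold, subset = subset)
  }
  list(precision = mean(vapply(runs, `[[`, numeric(1), "precision")),
       recall = mean(vapply(runs, `[[`, numeric(1), "recall")),
       f = mean(vapply(runs, `[[`, numeric(1), "f")),
       runs = runs)
}

#' End-to-end re-ranking experiment on a labeled corpus
#'
#' Splits the corpus documents into a training and a test portion, builds
#' the bibliome index over the full corpus, trains the ranker on
#' within-sentence preference pairs of the training portion, derives
#' per-sentence threshold targets from the ranker's training-portion scores,
#' trains the threshold regressor on them, and finally scores, thresholds
#' and filters the test portion. Returns the filtered metrics next to the
#' unfiltered baseline.
#'
#' After regression, a global shift of the predicted thresholds is
#' calibrated by maximizing the filtered F-score on the training portion
#' (mirroring how the fallback offset itself was established empirically);
#' set `calibrate = FALSE` to use the raw regressor output.
#'
#' @param corpus named list of `bib_document` objects.
#' @param labels named list (by doc id) of `"tp"`/`"fp"` label vectors.
#' @param symbol_table symbol table enabling the normalized-id level.
#' @param train_fraction fraction of documents used for training.
#' @param feature_config a [rerank_feature_config()].
#' @param fallback_offset threshold-target margin.
#' @param ranker_cost,regressor_cost,regressor_epsilon hyperparameters.
#' @param calibrate calibrate a global threshold shift on the training
#'   portion.
#' @param seed controls the document split and all training.
#' @return a list with the trained `ranker` and `regressor`, the scored
#'   test query sets, predicted `thresholds` (shift applied), the
#'   calibrated `threshold_shift`, and `baseline`/`filtered` metric lists.
#' @export
run_rerank_experiment <- function(corpus, labels, symbol_table = NULL,
                                  train_fraction = 0.5,
                                  feature_config = rerank_feature_config(),
                                  fallback_offset = 0.2, ranker_cost = 1,
                                  regressor_cost = 1,
                                  regressor_epsilon = 0.1,
                                  calibrate = TRUE, seed = 1) {
  idx <- build_event_index(corpus, symbol_table)
  set.seed(seed)
  ids <- names(corpus)
  train_ids <- sort(sample(ids, size = max(1, round(train_fraction * length(ids)))))
  test_ids <- setdiff(ids, train_ids)
  qss <- function(which_ids) {
    out <- list()
    for (id in which_ids)
      out <- c(out, make_query_sets(corpus[[id]], labels[[id]]))
    out
  }
  qss_train <- qss(train_ids)
  qss_test <- qss(test_ids)
  ranker <- train_ranker(qss_train, idx, feature_config, cost = ranker_cost,
                         seed = seed)
  qss_train <- score_candidates(ranker, qss_train, idx)
  targets <- vapply(qss_train, threshold_target, numeric(1),
                    fallback_offset = fallback_offset)
  regressor <- train_threshold_regressor(qss_train, targets,
                                         cost = regressor_cost,
                                         epsilon = regressor_epsilon,
                                         seed = seed)
  shift <- 0
  if (calibrate) {
    pred_train <- predict(regressor, qss_train)
    grid <- seq(-1.5, 0.5, by = 0.05)
    train_f <- vapply(grid, function(d)
      filter_metrics(qss_train, pred_train + d)$f, numeric(1))
    shift <- grid[[which.max(train_f)]]
  }
  qss_test <- score_candidates(ranker, qss_test, idx)
  thresholds <- predict(regressor, qss_test) + shift
  baseline <- filter_metrics(qss_test, rep(-Inf, length(qss_test)))
  filtered <- filter_metrics(qss_test, thresholds)
  list(ranker = ranker, regressor = regressor, index = idx,
       train_ids = train_ids, test_ids = test_ids,
       query_sets_train = qss_train, query_sets_test = qss_test,
       thresholds = thresholds, threshold_shift = shift,
       baseline = baseline, filtered = filtered)
}
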