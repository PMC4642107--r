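two_event_doc <- function() {
  text <- "sigA activates sigB; katX represses katY."
  a1 <- paste0("T1\tGene 0 4\tsigA\nT2\tProtein 15 19\tsigB\n",
               "T3\tGene 21 25\tkatX\nT4\tProtein 36 40\tkatY")
  a2 <- paste0("T5\tPositive_regulation 5 14\tactivates\n",
               "T6\tNegative_regulation 26 35\trepresses\n",
               "E1\tPositive_regulation:T5 Theme:T2 Cause:T1\n",
               "E2\tNegative_regulation:T6 Theme:T4 Cause:T3")
  doc_from_standoff("TWO", text, a1, a2)
}

test_that("candidate labelling matches structures recursively", {
  doc <- two_event_doc()
  gold <- new_document(doc$doc_id, doc$text, doc$entities,
                       doc$events["E1"], doc$sentences)
  lab <- label_candidates(doc, gold)
  expect_equal(unname(lab[c("E1", "E2")]), c("tp", "fp"))

  # same structure, wrong event type -> fp
  wrong <- doc
  wrong$events$E1$event_type <- "Regulation"
  wrong$events$E1$trigger_text <- "activates"
  lab2 <- label_candidates(wrong, gold)
  expect_equal(unname(lab2["E1"]), "fp")
})

test_that("each gold event matches at most one duplicate prediction", {
  text <- "sigA activates sigB; sigA activates sigB."
  a1 <- paste0("T1\tGene 0 4\tsigA\nT2\tProtein 15 19\tsigB\n",
               "T3\tGene 21 25\tsigA\nT4\tProtein 36 40\tsigB")
  a2 <- paste0("T5\tPositive_regulation 5 14\tactivates\n",
               "E1\tPositive_regulation:T5 Theme:T2 Cause:T1\n",
               "E2\tPositive_regulation:T5 Theme:T2 Cause:T1")
  doc <- doc_from_standoff("DUP", text, a1, a2)
  doc$events$E1$confidence <- 0.4
  doc$events$E2$confidence <- 0.9
  gold <- new_document(doc$doc_id, doc$text, doc$entities, doc$events["E1"],
                       doc$sentences)
  lab <- label_candidates(doc, gold)
  expect_equal(sum(lab == "tp"), 1)
  # greedy by confidence: the higher-confidence duplicate wins the match
  expect_equal(unname(lab["E2"]), "tp")
  expect_equal(unname(lab["E1"]), "fp")
})

test_that("query sets partition events by sentence", {
  gen <- generate_bibliome(generator_config(n_genes = 8, n_edges = 10,
                                            n_docs = 4, fp_rate = 0.3,
                                            seed = 6))
  for (doc_id in names(gen$corpus)) {
    doc <- gen$corpus[[doc_id]]
    qss <- make_query_sets(doc, gen$truth$labels[[doc_id]])
    expect_true(all(vapply(qss, function(q) nrow(q$candidates) > 0,
                           logical(1))))
    covered <- unlist(lapply(qss, function(q) q$candidates$event_id))
    expect_setequal(covered, names(doc$events))
    for (q in qss) {
      for (id in q$candidates$event_id) {
        ev <- doc$events[[id]]
        expect_gte(ev$trigger_start, q$sentence[["start"]])
        expect_lte(ev$trigger_end, q$sentence[["end"]])
      }
    }
  }
})

test_that("event features reflect context and bibliome evidence", {
  doc <- two_event_doc()
  qs <- make_query_sets(doc)[[1]]
  empty_idx <- build_event_index(list())
  v <- extract_event_features("E1", qs, empty_idx)
  expect_true(all(v[grepl("^bib_|^net_", names(v))] == 0))
  expect_equal(unname(v["ctx_n"]), 1)
  expect_equal(unname(v["base_conf"]), 1)
  expect_equal(unname(v["type_Positive_regulation"]), 1)
  expect_equal(unname(v["n_args"]), 2)

  # index over 5 copies of the same document: exact canonical key count 5
  copies <- lapply(1:5, function(i) {
    d <- two_event_doc(); d$doc_id <- paste0("C", i)
    d$events$E1$confidence <- c(0.5, 0.9, 0.2, 0.6, 0.1)[i]
    d
  })
  idx <- build_event_index(copies)
  v2 <- extract_event_features("E1", qs, idx)
  expect_equal(unname(v2["bib_canonical_exact_n"]), 5)
  expect_equal(unname(v2["bib_canonical_exact_maxc"]), 0.9)
  expect_gt(unname(v2["net_pair_n"]), 0)

  # a sole candidate has no sentence context
  solo <- make_query_sets(new_document(doc$doc_id, doc$text, doc$entities,
                                       doc$events["E1"], doc$sentences))[[1]]
  expect_equal(unname(extract_event_features("E1", solo, empty_idx)["ctx_n"]),
               0)
})

synthetic_querysets <- function(seed = 13, fp_rate = 0.4) {
  gen <- generate_bibliome(generator_config(n_genes = 8, n_edges = 12,
                                            n_docs = 8, mentions_per_edge = 2,
                                            sentences_per_doc = 4,
                                            fp_rate = fp_rate, seed = seed))
  idx <- build_event_index(gen$corpus, gen$truth$symbol_table)
  list(qss = make_labeled_querysets(gen$corpus, gen$truth), idx = idx)
}

test_that("ranker orders separable candidates and is seed-deterministic", {
  fix <- synthetic_querysets()
  r1 <- train_ranker(fix$qss, fix$idx, seed = 5)
  r2 <- train_ranker(fix$qss, fix$idx, seed = 5)
  expect_identical(r1$w, r2$w)

  scored <- score_candidates(r1, fix$qss, fix$idx)
  # resubstitution: within-sentence pairwise ordering should be strong
  good <- 0; tot <- 0
  for (q in scored) {
    s <- q$candidates$rank_score; l <- q$candidates$label
    for (i in which(l == "tp")) for (j in which(l == "fp")) {
      tot <- tot + 1; good <- good + (s[i] > s[j])
    }
  }
  expect_gt(good / tot, 0.8)
  # scoring is deterministic
  scored2 <- score_candidates(r1, fix$qss, fix$idx)
  expect_identical(scored[[1]]$candidates$rank_score,
                   scored2[[1]]$candidates$rank_score)
})

test_that("ranker training demands a mixed query set", {
  fix <- synthetic_querysets(fp_rate = 0)
  expect_error(train_ranker(fix$qss, fix$idx), "training error")
})

test_that("threshold targets come from exhaustive per-sentence search", {
  mk_qs <- function(scores, labels) {
    structure(list(doc_id = "X", sentence_index = 1,
                   sentence = c(start = 0, end = 10), doc = NULL,
                   candidates = data.frame(
                     event_id = paste0("E", seq_along(scores)),
                     base_confidence = 0.5, n_args = 1L, label = labels,
                     rank_score = scores, stringsAsFactors = FALSE)),
              class = "query_set")
  }
  expect_equal(threshold_target(mk_qs(c(0.9, 0.1), c("tp", "fp"))), 0.9)
  expect_equal(threshold_target(mk_qs(c(0.3, 0.1), c("fp", "fp"))), 0.5)
  expect_equal(threshold_target(mk_qs(c(0.1, 0.8), c("tp", "tp"))), -0.1)

  set.seed(123)
  for (rep in 1:200) {
    n <- sample(1:10, 1)
    scores <- round(runif(n), 3)
    labels <- sample(c("tp", "fp"), n, replace = TRUE)
    qs <- mk_qs(scores, labels)
    expect_equal(threshold_target(qs), oracle_threshold(scores, labels),
                 label = paste(scores, labels, collapse = " "))
  }
})

test_that("filtering is monotone, cascading, and structurally valid", {
  doc <- chain_doc(c("Positive", "Negative"))
  qss <- make_query_sets(doc)
  qs <- qss[[1]]
  qs$candidates$rank_score <- c(E1 = 0.1, E2 = 0.9,
                                E3 = 0.8)[qs$candidates$event_id]
  low <- apply_filter(qs, -1)
  expect_true(all(low$candidates$retained))
  high <- apply_filter(qs, 2)
  expect_false(any(high$candidates$retained))
  # removing the nested Theme event removes its parents
  mid <- apply_filter(qs, 0.5)
  ret <- setNames(mid$candidates$retained, mid$candidates$event_id)
  expect_false(ret[["E1"]])  # below threshold
  expect_false(ret[["E2"]])  # cascaded: Theme chain broken
  expect_false(ret[["E3"]])
  # monotonicity across thresholds
  for (t in seq(-1, 2, 0.25)) {
    a <- apply_filter(qs, t)$candidates$retained
    b <- apply_filter(qs, t + 0.25)$candidates$retained
    expect_true(all(b <= a))
  }
})

test_that("threshold regression recovers a linear target and degenerates safely", {
  fix <- synthetic_querysets(seed = 21)
  set.seed(2)
  qss <- lapply(fix$qss, function(q) {
    q$candidates$rank_score <- runif(nrow(q$candidates))
    q
  })
  feats <- do.call(rbind, lapply(qss, bibliome:::sentence_features))
  targets <- drop(2.5 - 1.2 * feats[, "score_mean"] + 0.4 * feats[, "n_cand"])
  reg <- train_threshold_regressor(qss, targets, cost = 1e4, epsilon = 1e-4)
  expect_lt(max(abs(predict(reg, qss) - targets)), 1e-3)

  const <- train_threshold_regressor(qss, rep(0.7, length(qss)))
  expect_equal(predict(const, qss), rep(0.7, length(qss)))
  expect_error(train_threshold_regressor(qss[1]), "at least 2")

  r1 <- train_threshold_regressor(qss, targets, seed = 9)
  r2 <- train_threshold_regressor(qss, targets, seed = 9)
  expect_identical(predict(r1, qss), predict(r2, qss))
})

test_that("oracles bound each other and the random baseline reproduces", {
  fix <- synthetic_querysets(seed = 17)
  ranker <- train_ranker(fix$qss, fix$idx, seed = 1)
  qss <- score_candidates(ranker, fix$qss, fix$idx)
  best <- oracle_thresholds(qss, "best")
  worst <- oracle_thresholds(qss, "worst")
  fb <- filter_metrics(qss, best)
  fw <- filter_metrics(qss, worst)
  expect_gte(fb$f, fw$f)
  # all-fp sentences: best removes everything, worst retains everything
  allfp <- which(vapply(qss, function(q) all(q$candidates$label == "fp"),
                        logical(1)))
  expect_true(length(allfp) > 0)
  expect_true(all(is.infinite(worst[allfp]) & worst[allfp] < 0))
  expect_true(all(best[allfp] >
                    vapply(qss[allfp], function(q)
                      max(q$candidates$rank_score), numeric(1))))

  rb1 <- random_rank_baseline(qss, n_runs = 3, seed = 7)
  rb2 <- random_rank_baseline(qss, n_runs = 3, seed = 7)
  expect_identical(rb1$f, rb2$f)
  expect_error(random_rank_baseline(list()), "no query sets")
})
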