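pairdoc <- function() index_fixture_doc("P1", c(0.3, 0.7))

test_that("pair features aggregate forward and reverse evidence", {
  idx <- build_event_index(list(pairdoc()))
  # binding flattening emits both orientations, so forward and reverse both
  # carry the two occurrences
  v <- build_pair_features("genea", "geneb", idx)
  expect_equal(unname(v["n_fwd_None_Binding"]), 2)
  expect_equal(unname(v["n_fwd_total"]), 2)
  expect_equal(unname(v["maxc_fwd_None_Binding"]), 0.7)
  expect_equal(unname(v["maxc_fwd_total"]), 0.7)
  expect_equal(unname(v["rev_dominates"]), 0)

  # a genuinely one-directional pair: regulation chain
  cd <- chain_doc("Positive", base = "Transcription", confs = c(0.8, 0.6))
  idx2 <- build_event_index(list(cd))
  v2 <- build_pair_features("genea", "geneb", idx2)
  expect_equal(unname(v2["n_fwd_Positive_Transcription"]), 1)
  expect_equal(unname(v2["n_rev_total"]), 0)
  expect_equal(unname(v2["maxc_rev_total"]), 0)
  expect_equal(unname(v2["rev_dominates"]), 0)
  expect_error(build_pair_features("geneb", "genex", idx2),
               "precondition error")
})

test_that("reverse dominance reflects confidence asymmetry", {
  cd1 <- chain_doc("Positive", confs = c(0.6, 0.6))
  # reverse direction with a higher confidence, built by swapping symbols
  text <- "geneB activates geneA."
  a1 <- "T1\tGene 0 5\tgeneB\nT2\tProtein 16 21\tgeneA"
  a2 <- paste0("T3\tPositive_regulation 6 15\tactivates\n",
               "E1\tPositive_regulation:T3 Theme:T2 Cause:T1")
  cd2 <- doc_from_standoff("R1", text, a1, a2)
  cd2$events$E1$confidence <- 0.8
  idx <- build_event_index(list(cd1, cd2))
  v <- build_pair_features("genea", "geneb", idx)
  expect_equal(unname(v["maxc_fwd_total"]), 0.6)
  expect_equal(unname(v["maxc_rev_total"]), 0.8)
  expect_equal(unname(v["rev_dominates"]), 1)
})

test_that("entity-type features are one-hot encoded on demand", {
  idx <- build_event_index(list(pairdoc()))
  v <- build_pair_features("genea", "geneb", idx, "Gene", "Protein",
                           include_entity_types = TRUE)
  expect_equal(unname(v["agent_et_Gene"]), 1)
  expect_equal(unname(v["target_et_Protein"]), 1)
  expect_equal(sum(v[grepl("^agent_et_", names(v))]), 1)
  expect_error(build_pair_features("genea", "geneb", idx,
                                   include_entity_types = TRUE),
               "entity types required")
})

test_that("separable synthetic pairs train to perfect cross-validated F", {
  set.seed(4)
  n <- 40
  feats <- matrix(rnorm(n * 4), n, 4,
                  dimnames = list(NULL, paste0("f", 1:4)))
  gold <- ifelse(feats[, 1] > 0, "Activation", "none")
  feats[, 1] <- feats[, 1] + sign(feats[, 1]) * 2  # widen the margin
  cfg <- ml_config(C_grid = 2^(0:4), gamma_grid = 2^(-4:0), random_seed = 3)
  clf <- suppressWarnings(train_type_classifiers(feats, gold, cfg))
  expect_equal(clf$models$Activation$cv_f, 1)
  pred <- predict(clf, feats)
  expect_equal(unname(pred[, "Activation"]), gold == "Activation")
  # all-negative type yields a constant-negative predictor
  expect_equal(clf$models$Binding$kind, "constant")
  expect_false(clf$models$Binding$value)
})

test_that("grid search is deterministic under a fixed seed", {
  set.seed(8)
  n <- 30
  feats <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  gold <- ifelse(feats[, 2] + 0.3 * rnorm(n) > 0, "Inhibition", "none")
  cfg <- ml_config(C_grid = 2^seq(-3, 7, 2), gamma_grid = 2^seq(-7, 1, 2),
                   random_seed = 42)
  c1 <- suppressWarnings(train_type_classifiers(feats, gold, cfg))
  c2 <- suppressWarnings(train_type_classifiers(feats, gold, cfg))
  expect_identical(c1$models$Inhibition$C, c2$models$Inhibition$C)
  expect_identical(c1$models$Inhibition$gamma, c2$models$Inhibition$gamma)
})

test_that("hybrid conversion reproduces the rule-based network on zero noise", {
  gen <- generate_bibliome(generator_config(n_genes = 15, n_edges = 40,
                                            n_docs = 20, mentions_per_edge = 4,
                                            sentences_per_doc = 10,
                                            fp_rate = 0, variant_rate = 0,
                                            unmatched_symbol_rate = 0,
                                            seed = 2))
  ids <- names(gen$corpus)
  train_ids <- ids[1:14]
  test_ids <- ids[15:20]
  lp <- make_labeled_pairs(gen$corpus, gen$truth$symbol_table,
                           gen$truth$network, doc_restriction = train_ids)
  cfg <- ml_config(C_grid = 2^seq(-1, 9, 2), gamma_grid = 2^seq(-9, 1, 2),
                   random_seed = 1)
  clf <- suppressWarnings(train_type_classifiers(lp$features,
                                                 lp$pairs$gold_type, cfg))
  ml_net <- convert_ml(gen$corpus, gen$truth$symbol_table, clf, "hybrid",
                       doc_restriction = test_ids)
  rb_net <- convert_rule_based(gen$corpus, gen$truth$symbol_table,
                               doc_restriction = test_ids)
  key <- function(d) sort(paste(d$agent_id, d$target_id, d$grn_type))
  expect_identical(key(ml_net), key(rb_net))
})

test_that("ml_full mode demands entity-type features", {
  gen <- generate_bibliome(generator_config(n_genes = 6, n_edges = 8,
                                            n_docs = 4, fp_rate = 0, seed = 3))
  lp <- make_labeled_pairs(gen$corpus, gen$truth$symbol_table,
                           gen$truth$network)
  clf <- suppressWarnings(train_type_classifiers(
    lp$features, lp$pairs$gold_type,
    ml_config(C_grid = 2, gamma_grid = 0.1, random_seed = 1)))
  expect_error(convert_ml(gen$corpus, gen$truth$symbol_table, clf, "ml_full"),
               "configuration error")
})
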