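test_that("type mapping follows the conversion table top-down", {
  expect_equal(map_type_rule("None", "Binding"), "Binding")
  # "regulation of transcription" precedes the polarity rows
  expect_equal(map_type_rule("Positive", "Transcription"), "Transcription")
  expect_equal(map_type_rule("Negative", "GeneExpression"), "Transcription")
  expect_equal(map_type_rule("Positive", "Other"), "Activation")
  expect_equal(map_type_rule("Negative", "Other"), "Inhibition")
  expect_equal(map_type_rule("Unspecified", "Other"), "Regulation")
  expect_true(is.na(map_type_rule("None", "Other")))
})

test_that("type mapping is total and deterministic over the coarse space", {
  for (layer in REG_LAYERS) {
    for (base in COARSE_BASES) {
      r1 <- map_type_rule(layer, base)
      expect_true(is.na(r1) || r1 %in% GRN_TYPES)
      expect_identical(r1, map_type_rule(layer, base))
    }
  }
})

test_that("entity-type filtering enforces slot compatibility", {
  mk <- function(type, agent_et, target_et)
    data.frame(agent_id = "a", target_id = "b", grn_type = type,
               confidence = 0.5, agent_entity_type = agent_et,
               target_entity_type = target_et, stringsAsFactors = FALSE)
  expect_equal(nrow(filter_entity_types(mk("Binding", "Gene", "Protein"))), 1)
  expect_equal(nrow(filter_entity_types(mk("Binding", "Protein", "Protein"))), 0)
  expect_equal(nrow(filter_entity_types(mk("Activation", "Operon",
                                           "PolymeraseComplex"))), 1)
  expect_equal(nrow(filter_entity_types(mk("Transcription", "Protein",
                                           "Protein"))), 0)
  expect_equal(nrow(filter_entity_types(mk("Regulation", "ProteinComplex",
                                           "Protein"))), 1)
  bad <- mk("Binding", NA, "Protein")
  expect_error(filter_entity_types(bad), "filter error")
})

test_that("filtering is a pure filter (output subset of input)", {
  set.seed(9)
  n <- 60
  df <- data.frame(agent_id = paste0("a", 1:n), target_id = paste0("b", 1:n),
                   grn_type = sample(GRN_TYPES, n, replace = TRUE),
                   confidence = runif(n),
                   agent_entity_type = sample(ENTITY_TYPES, n, replace = TRUE),
                   target_entity_type = sample(ENTITY_TYPES, n, replace = TRUE),
                   stringsAsFactors = FALSE)
  kept <- filter_entity_types(df)
  expect_lte(nrow(kept), nrow(df))
  keys <- function(d) paste(d$agent_id, d$target_id, d$grn_type)
  expect_true(all(keys(kept) %in% keys(df)))
})

test_that("binding refactoring re-types only binding edges", {
  df <- data.frame(agent_id = c("a", "c"), target_id = c("b", "d"),
                   grn_type = c("Binding", "Activation"),
                   confidence = c(0.5, 0.6), stringsAsFactors = FALSE)
  out <- refactor_binding(df)
  expect_equal(out$grn_type, c("Transcription", "Activation"))
  expect_equal(nrow(refactor_binding(df[0, ])), 0)
})

test_that("edge selection applies the sequential per-pair rules", {
  mk <- function(types, confs)
    data.frame(agent_id = "a", target_id = "b", grn_type = types,
               confidence = confs, stringsAsFactors = FALSE)
  expect_equal(select_edges(mk(c("Transcription", "Regulation"),
                               c(0.2, 0.9)))$grn_type, "Transcription")
  expect_equal(select_edges(mk(c("Activation", "Inhibition"),
                               c(0.9, 0.4)))$grn_type, "Activation")
  expect_equal(select_edges(mk(c("Transcription", "Activation"),
                               c(0.95, 0.1)))$grn_type, "Activation")
  expect_equal(select_edges(mk(c("Binding", "Regulation"),
                               c(0.1, 0.9)))$grn_type, "Binding")
})

test_that("edge selection matches the brute-force oracle on random inputs", {
  set.seed(31)
  for (rep in 1:120) {
    n <- sample(1:6, 1)
    df <- data.frame(agent_id = "a", target_id = "b",
                     grn_type = sample(GRN_TYPES, n, replace = TRUE),
                     confidence = round(runif(n), 3), stringsAsFactors = FALSE)
    out <- select_edges(df)
    expect_equal(nrow(out), 1)
    pick <- oracle_select_pair(df)
    expect_equal(out$grn_type, df$grn_type[pick])
    expect_equal(out$confidence, df$confidence[pick])
  }
})

test_that("symbol matching resolves canonicalized table entries", {
  rel <- data.frame(agent = c("sigmab", "sigmab", "zzz"),
                    target = c("katx", "sigb", "katx"),
                    confidence = 0.5, stringsAsFactors = FALSE)
  tab <- data.frame(surface = c("sigmaB", "SigB", "katX"),
                    gene_id = c("sigB", "sigB", "katX"),
                    stringsAsFactors = FALSE)
  out <- match_symbols(rel, tab)
  expect_equal(nrow(out), 2)  # zzz dropped
  expect_equal(out$agent_id, c("sigB", "sigB"))
  # two surface variants resolve to one id
  expect_equal(out$target_id, c("katX", "sigB"))
})

test_that("document restriction keeps only listed sources", {
  rel <- data.frame(agent = letters[1:5], target = letters[2:6],
                    source_doc = paste0("D", 1:5), stringsAsFactors = FALSE)
  expect_identical(restrict_documents(rel, "all"), rel)
  expect_equal(nrow(restrict_documents(rel, character(0))), 0)
  expect_equal(restrict_documents(rel, c("D2", "D4"))$source_doc,
               c("D2", "D4"))
})

test_that("rule-based conversion recovers a zero-noise planted network", {
  gen <- generate_bibliome(generator_config(n_genes = 8, n_edges = 12,
                                            n_docs = 6, mentions_per_edge = 2,
                                            fp_rate = 0, variant_rate = 0,
                                            unmatched_symbol_rate = 0,
                                            seed = 11))
  net <- convert_rule_based(gen$corpus, gen$truth$symbol_table)
  sc <- score_network(net, gen$truth$network, "strict")
  expect_equal(sc$ser, 0)
  expect_equal(sc$f_score, 1)

  expect_equal(nrow(convert_rule_based(list(), gen$truth$symbol_table)), 0)
  empty_tab <- data.frame(surface = "unrelated", gene_id = "unrelated",
                          stringsAsFactors = FALSE)
  expect_equal(nrow(convert_rule_based(gen$corpus, empty_tab)), 0)
})

test_that("select_edges output never keeps contradictory or shadowed edges", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(2:10, 1)
    df <- data.frame(agent_id = sample(c("a", "c"), n, replace = TRUE),
                     target_id = sample(c("b", "d"), n, replace = TRUE),
                     grn_type = sample(GRN_TYPES, n, replace = TRUE),
                     confidence = round(runif(n), 3), stringsAsFactors = FALSE)
    out <- select_edges(df)
    key <- paste(out$agent_id, out$target_id)
    expect_equal(anyDuplicated(key), 0)
    for (k in unique(key)) {
      types <- out$grn_type[key == k]
      expect_false(all(c("Activation", "Inhibition") %in% types))
      expect_false(any(types %in% c("Transcription", "Binding")) &&
                     any(types %in% c("Activation", "Inhibition",
                                      "Regulation")))
    }
  }
})
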