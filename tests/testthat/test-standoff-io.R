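test_that("parse_a1 reads entity lines and verifies spans", {
  text <- "sigB binds katX."
  ents <- parse_a1("T1\tProtein 0 4\tsigB\nT2\tGene 11 15\tkatX", text)
  expect_length(ents, 2)
  expect_equal(ents$T1$entity_type, "Protein")
  expect_equal(ents$T1$start, 0)
  expect_equal(ents$T1$end, 4)
  expect_equal(ents$T1$text, "sigB")

  expect_equal(parse_a1("", text), list())
  expect_error(parse_a1("T9\tGene 5 3\tx", text), "start < end")
  expect_error(parse_a1("T1\tProtein 0 4\tsigX", text), "does not match")
  expect_error(parse_a1("T1\tProtein 0 4", text), "tab-separated")
  expect_error(parse_a1("T1\tFrob 0 4\tsigB", text), "unknown entity type")
  expect_error(parse_a1("T1\tProtein 0 4\tsigB\nT1\tProtein 0 4\tsigB", text),
               "duplicate")
})

test_that("parse_a2 resolves nested events and rejects broken structures", {
  text <- "sigA activates sigB transcription now."
  a1 <- "T1\tGene 0 4\tsigA\nT2\tProtein 15 19\tsigB"
  a2 <- paste0("T3\tPositive_regulation 5 14\tactivates\n",
               "T4\tTranscription 20 33\ttranscription\n",
               "E1\tTranscription:T4 Theme:T2\n",
               "E2\tPositive_regulation:T3 Theme:E1 Cause:T1")
  ents <- parse_a1(a1, text)
  evs <- parse_a2(a2, ents, text)
  expect_length(evs, 2)
  expect_equal(evs$E2$event_type, "Positive_regulation")
  expect_equal(evs$E2$args[[1]]$ref, "E1")
  expect_equal(evs$E2$args[[2]]$role, "Cause")
  expect_equal(evs$E1$confidence, 1.0)  # sidecar default
  expect_false(evs$E1$negated)

  expect_error(parse_a2("T3\tRegulation 5 14\tactivates \n", ents, text),
               "does not match|tab-separated")
  expect_error(
    parse_a2("T3\tRegulation 5 14\tactivates\nE1\tRegulation:T3 Theme:E1",
             ents, text), "cycle")
  expect_error(
    parse_a2("T3\tRegulation 5 14\tactivates\nE1\tRegulation:T3 Theme:T9",
             ents, text), "unknown argument reference")
  expect_error(
    parse_a2("T3\tRegulation 5 14\tactivates\nE1\tRegulation:T3 Cause:T1",
             ents, text), "no Theme")
})

test_that("a2 writing round-trips nested events up to trigger renaming", {
  text <- "sigA activates sigB transcription now."
  a1 <- "T1\tGene 0 4\tsigA\nT2\tProtein 15 19\tsigB"
  a2 <- paste0("T3\tPositive_regulation 5 14\tactivates\n",
               "T4\tTranscription 20 33\ttranscription\n",
               "E1\tTranscription:T4 Theme:T2\n",
               "E2\tPositive_regulation:T3 Theme:E1 Cause:T1")
  ents <- parse_a1(a1, text)
  evs <- parse_a2(a2, ents, text)
  back <- parse_a2(write_a2(evs, ents), ents, text)
  expect_setequal(names(back), names(evs))
  for (id in names(evs))
    expect_true(bibliome:::events_equal(evs[[id]], list(entities = ents,
                                                        events = evs),
                                        back[[id]], list(entities = ents,
                                                         events = back)))
  expect_equal(write_a2(list()), "")
  expect_equal(parse_a1(write_a1(ents), text), ents)
})

test_that("confidence sidecar round-trips and validates", {
  text <- "sigA activates sigB."
  ents <- parse_a1("T1\tGene 0 4\tsigA\nT2\tProtein 15 19\tsigB", text)
  evs <- parse_a2(paste0("T3\tPositive_regulation 5 14\tactivates\n",
                         "E1\tPositive_regulation:T3 Theme:T2 Cause:T1"),
                  ents, text)
  evs2 <- read_confidence_tsv("E1\t0.731000\t1", evs)
  expect_equal(evs2$E1$confidence, 0.731)
  expect_true(evs2$E1$negated)
  expect_equal(read_confidence_tsv(write_confidence_tsv(evs2), evs), evs2)
  expect_error(read_confidence_tsv("E9\t0.5\t0", evs), "unknown event")
  expect_error(read_confidence_tsv("E1\t1.5\t0", evs), "confidence")
})

test_that("network TSV round-trips and rejects unknown types", {
  rec <- read_network_tsv(text = "sigB\tkatX\tActivation")
  expect_equal(rec$agent_id, "sigB")
  expect_equal(rec$target_id, "katX")
  expect_equal(rec$grn_type, "Activation")

  net <- data.frame(agent_id = c("a", "b", "c"), target_id = c("x", "y", "z"),
                    grn_type = c("Binding", "Inhibition", "Requirement"),
                    confidence = c(0.5, 0.25, 1), stringsAsFactors = FALSE)
  expect_equal(read_network_tsv(text = write_network_tsv(net)), net)
  expect_error(read_network_tsv(text = "a\tb\tFrobnication"), "vocabulary")
  expect_error(read_network_tsv(text = "a\tb\tBinding\na\tb\tBinding"),
               "duplicate")
  expect_equal(nrow(read_network_tsv(text = "")), 0)
})

test_that("symbol tables read and write", {
  tab <- read_symbol_table(text = "sigmaB\tsigB\nsigB\tsigB")
  expect_equal(tab$surface, c("sigmaB", "sigB"))
  expect_equal(tab$gene_id, c("sigB", "sigB"))
  expect_equal(read_symbol_table(text = write_symbol_table(tab)), tab)
})

test_that("documents validate sentence segmentation invariants", {
  text <- "sigA activates sigB.\nNothing here."
  ents <- parse_a1("T1\tGene 0 4\tsigA", text)
  doc <- new_document("D1", text, ents)
  expect_equal(nrow(doc$sentences), 2)
  expect_equal(doc$sentences$start, c(0, 21))
  # entity straddling a sentence boundary is rejected
  bad <- list(T1 = list(id = "T1", entity_type = "Gene", start = 15,
                        end = 25, text = substr(text, 16, 25)))
  expect_error(new_document("D1", text, bad), "exactly one sentence")
  expect_error(new_document("D1", text,
                            sentences = data.frame(start = c(0, 10),
                                                   end = c(12, 20))),
               "non-overlapping")
})
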