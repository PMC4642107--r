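# Shared fixtures and independent reference implementations ("oracles")
# used to cross-check the package's own code paths.

# build a document from standoff strings
doc_from_standoff <- function(doc_id, text, a1 = "", a2 = "", conf = NULL) {
  entities <- parse_a1(a1, text)
  events <- parse_a2(a2, entities, text)
  if (!is.null(conf)) events <- read_confidence_tsv(conf, events)
  new_document(doc_id, text, entities, events)
}

# document holding a regulation chain: outer layers[1] ( ... layers[d] (base
# container (Theme = B)) ), with Cause = A on the outermost event only
chain_doc <- function(layers, base = "Transcription", confs = NULL,
                      negs = NULL) {
  d <- length(layers)
  if (is.null(confs)) confs <- rep(0.8, d + 1)
  if (is.null(negs)) negs <- rep(FALSE, d + 1)
  reg_type <- function(layer) switch(layer, Positive = "Positive_regulation",
                                     Negative = "Negative_regulation",
                                     Unspecified = "Regulation")
  words <- c(vapply(layers, function(l) switch(l, Positive = "activates",
                                               Negative = "represses",
                                               Unspecified = "modulates"),
                    character(1)),
             switch(base, Transcription = "transcription",
                    GeneExpression = "expression", Other = "production"))
  text <- paste(c("geneA", words, "of", "geneB."), collapse = " ")
  pos <- function(word) {
    s <- regexpr(word, text, fixed = TRUE)[[1]] - 1L
    c(s, s + nchar(word))
  }
  a1 <- paste0("T1\tGene ", 0, " ", 5, "\tgeneA\n",
               "T2\tProtein ", pos("geneB")[1], " ", pos("geneB")[2], "\tgeneB\n")
  trig <- character(0)
  for (i in seq_len(d + 1)) {
    p <- pos(words[[i]])
    tp <- if (i <= d) reg_type(layers[[i]]) else
      switch(base, Transcription = "Transcription",
             GeneExpression = "Gene_expression", Other = "Phosphorylation")
    trig <- c(trig, sprintf("T%d\t%s %d %d\t%s", i + 2, tp, p[1], p[2],
                            words[[i]]))
  }
  evs <- character(0)
  # innermost event first: container over geneB
  inner_type <- if (base == "Other") "Phosphorylation" else
    switch(base, Transcription = "Transcription",
           GeneExpression = "Gene_expression")
  if (base == "Other") {
    # leaf is a direct entity theme on the deepest regulation instead
    evs <- c(evs, sprintf("E1\t%s:T%d Theme:T2",
                          reg_type(layers[[d]]), d + 2))
    lower <- "E1"
    from <- d - 1
  } else {
    evs <- c(evs, sprintf("E1\t%s:T%d Theme:T2", inner_type, d + 3))
    lower <- "E1"
    from <- d
  }
  k <- 1
  for (i in rev(seq_len(from))) {
    k <- k + 1
    cause <- if (i == 1) " Cause:T1" else ""
    evs <- c(evs, sprintf("E%d\t%s:T%d Theme:%s%s", k, reg_type(layers[[i]]),
                          i + 2, lower, cause))
    lower <- paste0("E", k)
  }
  if (from == 0 || (base == "Other" && d == 1)) {
    # single-level chain over an entity theme: attach Cause to E1
    evs[1] <- paste0(evs[1], " Cause:T1")
  }
  conf <- paste(sprintf("E%d\t%f\t%d", seq_len(k), confs[seq_len(k)],
                        as.integer(negs[seq_len(k)])), collapse = "\n")
  doc_from_standoff("CHAIN", text, a1, paste0(paste(trig, collapse = "\n"),
                                              "\n", paste(evs, collapse = "\n")),
                    conf)
}

# independent polarity oracle: Unspecified absorbs, otherwise signs multiply
oracle_chain_layer <- function(layers) {
  if (any(layers == "Unspecified")) return("Unspecified")
  if (sum(layers == "Negative") %% 2 == 0) "Positive" else "Negative"
}

# independent edge-selection oracle: enumerate every candidate edge of a pair
# and keep the unique one the sequential rules retain
oracle_select_pair <- function(df) {
  alive <- seq_len(nrow(df))
  tp <- df$grn_type
  if (length(intersect(tp[alive],
                       c("Activation", "Inhibition", "Transcription",
                         "Binding"))) > 0)
    alive <- alive[tp[alive] != "Regulation"]
  if ("Activation" %in% tp[alive] && "Inhibition" %in% tp[alive]) {
    contro <- alive[tp[alive] %in% c("Activation", "Inhibition")]
    mx <- max(df$confidence[contro])
    top <- contro[df$confidence[contro] == mx]
    winner <- if ("Activation" %in% tp[top]) "Activation" else "Inhibition"
    alive <- alive[!(tp[alive] %in% c("Activation", "Inhibition")) |
                     tp[alive] == winner]
  }
  if (any(tp[alive] %in% c("Activation", "Inhibition", "Regulation")))
    alive <- alive[!tp[alive] %in% c("Transcription", "Binding")]
  alive[order(-df$confidence[alive], tp[alive], alive)][1]
}

# independent S/I/D enumerator for network scoring
oracle_score_network <- function(pred, gold, mode) {
  pk <- paste(pred$agent_id, pred$target_id)
  gk <- paste(gold$agent_id, gold$target_id)
  conf <- if (is.null(pred$confidence)) rep(1, nrow(pred)) else pred$confidence
  M <- S <- D <- I <- 0
  rep_of <- integer(0)
  for (key in unique(pk)) {
    rows <- which(pk == key)
    best <- rows[which.max(conf[rows] + (length(rows):1) * 1e-12)]
    # highest confidence wins; earlier row on ties
    best <- rows[order(-conf[rows], rows)][1]
    rep_of[key] <- best
    I <- I + (length(rows) - 1)
  }
  for (i in seq_len(nrow(gold))) {
    if (!gk[i] %in% names(rep_of)) D <- D + 1
    else if (mode == "relaxed" ||
             pred$grn_type[rep_of[[gk[i]]]] == gold$grn_type[i]) M <- M + 1
    else S <- S + 1
  }
  I <- I + sum(!unique(pk) %in% gk)
  list(matches = M, substitutions = S, insertions = I, deletions = D,
       ser = (S + I + D) / nrow(gold))
}

# independent per-sentence threshold search: try every candidate score as a
# threshold (retained = score >= t), maximize within-sentence F, ties toward
# the larger retained set
oracle_threshold <- function(scores, labels, offset = 0.2) {
  if (all(labels == "fp")) return(max(scores) + offset)
  if (all(labels == "tp")) return(min(scores) - offset)
  f_of <- function(ret) {
    tp <- sum(ret & labels == "tp"); fp <- sum(ret & labels == "fp")
    fn <- sum(!ret & labels == "tp")
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }
  best_f <- -1; best_t <- NA; best_n <- -1
  for (t in sort(unique(scores), decreasing = TRUE)) {
    ret <- scores >= t
    f <- f_of(ret)
    if (f > best_f || (f == best_f && sum(ret) > best_n)) {
      best_f <- f; best_t <- t; best_n <- sum(ret)
    }
  }
  best_t
}

random_network <- function(n, genes = paste0("g", 1:6),
                           types = GRN_TYPES) {
  data.frame(agent_id = sample(genes, n, replace = TRUE),
             target_id = sample(genes, n, replace = TRUE),
             grn_type = sample(types, n, replace = TRUE),
             confidence = round(runif(n), 3), stringsAsFactors = FALSE)
}

# drop duplicate (agent, target, type) triples so gold files stay valid
dedup_network <- function(net) {
  net[!duplicated(net[c("agent_id", "target_id", "grn_type")]), , drop = FALSE]
}

index_fixture_doc <- function(doc_id, confs) {
  # n identical Binding events (same generalization key) with given confidences
  n <- length(confs)
  lines <- rep("geneA binds geneB.", n)
  text <- paste(lines, collapse = "\n")
  a1 <- character(0); a2 <- character(0); cf <- character(0)
  for (i in seq_len(n)) {
    off <- (i - 1) * 19
    a1 <- c(a1, sprintf("T%d\tGene %d %d\tgeneA", 2 * i - 1, off, off + 5),
            sprintf("T%d\tProtein %d %d\tgeneB", 2 * i, off + 12, off + 17))
    a2 <- c(a2, sprintf("T%d\tBinding %d %d\tbinds", 100 + i, off + 6, off + 11),
            sprintf("E%d\tBinding:T%d Theme:T%d Theme:T%d", i, 100 + i,
                    2 * i - 1, 2 * i))
    cf <- c(cf, sprintf("E%d\t%f\t0", i, confs[i]))
  }
  doc_from_standoff(doc_id, text, paste(a1, collapse = "\n"),
                    paste(a2, collapse = "\n"), paste(cf, collapse = "\n"))
}
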