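#' Configuration for the ML-based type conversion
#'
#' @param C_grid,gamma_grid grids for the RBF soft-margin parameters,
#'   searched exhaustively by cross-validation (defaults: the standard
#'   exponential grids \eqn{C \in 2^{-5..15}}, \eqn{\gamma \in 2^{-15..3}}).
#' @param n_folds number of stratified cross-validation folds.
#' @param include_entity_type_features add categorical agent/target entity
#'   type features (required for the `ml_full` conversion mode, which
#'   replaces the rule-based entity-type filter).
#' @param random_seed seed controlling fold assignment; training is
#'   deterministic given the seed.
#' @return a list of class `ml_config`.
#' @export
ml_config <- function(C_grid = 2^seq(-5, 15, by = 2),
                      gamma_grid = 2^seq(-15, 3, by = 2),
                      n_folds = 5, include_entity_type_features = FALSE,
                      random_seed = 1) {
  stopifnot(length(C_grid) > 0, all(C_grid > 0),
            length(gamma_grid) > 0, all(gamma_grid > 0), n_folds >= 2)
  structure(list(C_grid = C_grid, gamma_grid = gamma_grid, n_folds = n_folds,
                 include_entity_type_features = include_entity_type_features,
                 random_seed = random_seed), class = "ml_config")
}

pair_feature_names <- function(include_entity_types) {
  cats <- gsub("[|]", "_", coarse_categories())
  nm <- c(paste0("n_fwd_", cats), "n_fwd_total",
          paste0("n_rev_", cats), "n_rev_total",
          paste0("maxc_fwd_", cats), "maxc_fwd_total",
          "maxc_rev_total", "rev_dominates")
  if (include_entity_types)
    nm <- c(nm, paste0("agent_et_", ENTITY_TYPES),
            paste0("target_et_", ENTITY_TYPES))
  nm
}

#' Bibliome features for an agent–target pair
#'
#' Aggregates the event index into the pair feature vector used by the
#' ML conversion: forward and reverse event counts per coarse event type
#' and in total, maximum confidences, whether the reverse direction's
#' maximal confidence dominates the forward one, and (optionally) one-hot
#' agent/target entity types. `agent` and `target` may be vectors of
#' canonical variants of the same gene (counts are summed, confidences
#' maxed over variant combinations).
#'
#' @param agent,target canonical symbol(s) of the pair.
#' @param idx an `event_index`.
#' @param agent_entity_type,target_entity_type entity types (required when
#'   `include_entity_types` is `TRUE`).
#' @param include_entity_types include the categorical entity-type features.
#' @return a named numeric feature vector.
#' @export
build_pair_features <- function(agent, target, idx,
                                agent_entity_type = NULL,
                                target_entity_type = NULL,
                                include_entity_types = FALSE) {
  cats <- coarse_categories()
  dir_stats <- function(from, to) {
    n <- numeric(length(cats)); mc <- numeric(length(cats))
    n_tot <- 0; mc_tot <- 0
    for (a in from) for (t in to) {
      tot <- index_pair(idx, a, t)
      n_tot <- n_tot + tot[["count"]]
      mc_tot <- max(mc_tot, tot[["max_conf"]])
      for (ci in seq_along(cats)) {
        lb <- strsplit(cats[[ci]], "|", fixed = TRUE)[[1]]
        rec <- index_pair(idx, a, t, lb[[1]], lb[[2]])
        n[ci] <- n[ci] + rec[["count"]]
        mc[ci] <- max(mc[ci], rec[["max_conf"]])
      }
    }
    list(n = n, mc = mc, n_tot = n_tot, mc_tot = mc_tot)
  }
  fwd <- dir_stats(agent, target)
  if (fwd$n_tot < 1)
    stop("precondition error: no forward event between '",
         paste(agent, collapse = "/"), "' and '",
         paste(target, collapse = "/"), "'")
  rev <- dir_stats(target, agent)
  v <- c(fwd$n, fwd$n_tot, rev$n, rev$n_tot, fwd$mc, fwd$mc_tot, rev$mc_tot,
         as.numeric(rev$mc_tot > fwd$mc_tot))
  if (include_entity_types) {
    if (is.null(agent_entity_type) || is.null(target_entity_type))
      stop("filter error: entity types required for entity-type features")
    v <- c(v, as.numeric(ENTITY_TYPES == agent_entity_type),
           as.numeric(ENTITY_TYPES == target_entity_type))
  }
  stats::setNames(v, pair_feature_names(include_entity_types))
}

# canonical variants per standardized id, from the symbol table
canonical_variants <- function(symbol_table) {
  split(canonicalize(symbol_table$surface), symbol_table$gene_id)
}

# per-id-level candidate pairs and their feature matrix from matched relations
pair_candidates <- function(matched, idx, symbol_table, include_entity_types) {
  if (nrow(matched) == 0)
    return(list(pairs = matched[0, c("agent_id", "target_id")], features = NULL))
  variants <- canonical_variants(symbol_table)
  key <- paste(matched$agent_id, matched$target_id, sep = "\r")
  groups <- split(seq_len(nrow(matched)), key)
  pairs <- do.call(rbind, lapply(groups, function(rows) {
    g <- matched[rows, , drop = FALSE]
    majority <- function(x) names(sort(table(x), decreasing = TRUE))[1]
    data.frame(agent_id = g$agent_id[[1]], target_id = g$target_id[[1]],
               agent_entity_type = majority(g$agent_entity_type),
               target_entity_type = majority(g$target_entity_type),
               stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  # all observed (agent, target) entity-type combinations per pair; the
  # hybrid mode's entity filter tests the predicted type against each of
  # them, mirroring the per-relation semantics of the rule-based filter
  et_combos <- lapply(groups, function(rows) {
    unique(paste(matched$agent_entity_type[rows],
                 matched$target_entity_type[rows], sep = "|"))
  })
  names(et_combos) <- NULL
  features <- t(vapply(seq_len(nrow(pairs)), function(i) {
    build_pair_features(variants[[pairs$agent_id[[i]]]],
                        variants[[pairs$target_id[[i]]]], idx,
                        pairs$agent_entity_type[[i]],
                        pairs$target_entity_type[[i]],
                        include_entity_types)
  }, numeric(length(pair_feature_names(include_entity_types)))))
  list(pairs = pairs, features = features, et_combos = et_combos)
}

# does any observed entity-type combination admit this GRN type?
any_combo_compatible <- function(grn_type, combos) {
  rule <- ENTITY_TYPE_RULES[[grn_type]]
  for (combo in combos) {
    et <- strsplit(combo, "|", fixed = TRUE)[[1]]
    if (et[[1]] %in% rule$agent && et[[2]] %in% rule$target) return(combo)
  }
  NULL
}

#' Label candidate pairs against a gold network
#'
#' Builds the per-pair feature matrix for every agent–target pair with at
#' least one forward event in the corpus, labelled with the gold GRN type
#' of the pair (or `"none"` when the pair is absent from the gold network).
#'
#' The bibliome index backing the features always spans all `documents`;
#' `doc_restriction` only restricts which relations form candidate pairs
#' (bibliome-wide evidence, dataset-restricted candidates).
#'
#' @param documents corpus documents.
#' @param symbol_table gold symbol table.
#' @param gold_network data frame (`agent_id`, `target_id`, `grn_type`).
#' @param include_entity_types include entity-type features.
#' @param doc_restriction optional document restriction for the candidates.
#' @return a list with `pairs` (pair table + `gold_type`), `features`
#'   (numeric matrix) and the `index` used.
#' @export
make_labeled_pairs <- function(documents, symbol_table, gold_network,
                               include_entity_types = FALSE,
                               doc_restriction = "all") {
  idx <- build_event_index(documents, symbol_table, levels = "canonical")
  rel <- match_symbols(restrict_documents(corpus_relations(documents),
                                          doc_restriction), symbol_table)
  cand <- pair_candidates(rel, idx, symbol_table, include_entity_types)
  if (nrow(cand$pairs) > 0) {
    gk <- paste(gold_network$agent_id, gold_network$target_id, sep = "\r")
    pk <- paste(cand$pairs$agent_id, cand$pairs$target_id, sep = "\r")
    cand$pairs$gold_type <- ifelse(pk %in% gk,
                                   gold_network$grn_type[match(pk, gk)], "none")
  }
  c(cand, list(index = idx))
}

#' Train per-type RBF-SVM conversion classifiers
#'
#' One binary soft-margin RBF SVM per GRN interaction type, with `(C, γ)`
#' chosen by exhaustive grid search maximizing the mean F-score over
#' stratified cross-validation folds. Types with fewer positive or negative
#' examples than folds are trained at default parameters without grid
#' search (with a warning); single-class types get a constant predictor.
#'
#' @param features numeric feature matrix ([make_labeled_pairs()]).
#' @param gold_types character vector of gold GRN types (`"none"` for
#'   non-edges), one per feature row.
#' @param config an [ml_config()].
#' @return an object of class `grn_type_classifiers` with a `predict()`
#'   method returning a logical matrix (pairs × GRN types).
#' @export
train_type_classifiers <- function(features, gold_types, config = ml_config()) {
  stopifnot(nrow(features) == length(gold_types))
  center <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  x <- scale(features, center = center, scale = scl)
  models <- list()
  for (type in GRN_TYPES) {
    y <- factor(ifelse(gold_types == type, "pos", "neg"),
                levels = c("neg", "pos"))
    n_pos <- sum(y == "pos"); n_neg <- sum(y == "neg")
    if (n_pos == 0 || n_neg == 0) {
      models[[type]] <- list(kind = "constant",
                             value = if (n_pos > 0) TRUE else FALSE)
      next
    }
    if (min(n_pos, n_neg) < config$n_folds) {
      warning("type ", type, ": too few examples for grid search; ",
              "training at default parameters")
      fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                        cost = 1, gamma = 1 / ncol(x), scale = FALSE)
      models[[type]] <- list(kind = "svm", fit = fit, C = 1, gamma = 1 / ncol(x))
      next
    }
    folds <- stratified_folds(y, config$n_folds, config$random_seed)
    best <- list(f = -1, C = NA, gamma = NA)
    for (C in config$C_grid) {
      for (g in config$gamma_grid) {
        fs <- vapply(seq_len(config$n_folds), function(k) {
          tr <- folds != k
          fit <- e1071::svm(x[tr, , drop = FALSE], y[tr],
                            type = "C-classification", kernel = "radial",
                            cost = C, gamma = g, scale = FALSE)
          pred <- stats::predict(fit, x[!tr, , drop = FALSE])
          truth <- y[!tr]
          tp <- sum(pred == "pos" & truth == "pos")
          p <- safe_div(tp, sum(pred == "pos"))
          r <- safe_div(tp, sum(truth == "pos"))
          fscore(p, r)
        }, numeric(1))
        f <- mean(fs)
        if (f > best$f) best <- list(f = f, C = C, gamma = g)
      }
    }
    fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                      cost = best$C, gamma = best$gamma, scale = FALSE)
    models[[type]] <- list(kind = "svm", fit = fit, C = best$C,
                           gamma = best$gamma, cv_f = best$f)
  }
  structure(list(models = models, center = center, scale = scl,
                 config = config,
                 include_entity_type_features = config$include_entity_type_features,
                 feature_names = colnames(features)),
            class = "grn_type_classifiers")
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in levels(y)) {
    rows <- which(y == cls)
    folds[rows] <- sample(rep(seq_len(k), length.out = length(rows)))
  }
  folds
}

#' @export
predict.grn_type_classifiers <- function(object, features, ...) {
  x <- scale(features, center = object$center, scale = object$scale)
  out <- matrix(FALSE, nrow = nrow(features), ncol = length(GRN_TYPES),
                dimnames = list(NULL, GRN_TYPES))
  for (type in GRN_TYPES) {
    m <- object$models[[type]]
    out[, type] <- if (m$kind == "constant") m$value else
      stats::predict(m$fit, x) == "pos"
  }
  out
}

#' @export
print.grn_type_classifiers <- function(x, ...) {
  cat("<grn_type_classifiers> per-type RBF SVMs\n")
  for (type in GRN_TYPES) {
    m <- x$models[[type]]
    if (m$kind == "constant") {
      cat(sprintf("  %-13s constant predictor (%s)\n", type, m$value))
    } else {
      cat(sprintf("  %-13s C = %g, gamma = %g\n", type, m$C, m$gamma))
    }
  }
  invisible(x)
}

#' ML and hybrid conversion of an event corpus to a GRN network
#'
#' Every candidate pair positively classified for a GRN type yields a
#' candidate edge with confidence equal to the pair's forward maximal event
#' confidence. In `hybrid` mode the rule-based entity-type filter, Binding
#' refactoring, and edge selection are then applied; in `ml_full` mode the
#' classifiers (which must include entity-type features) replace the filter
#' and only edge selection runs.
#'
#' As in [make_labeled_pairs()], the feature index spans all `documents`
#' while `doc_restriction` only restricts the candidate pairs.
#'
#' @inheritParams convert_rule_based
#' @param classifiers a `grn_type_classifiers` object.
#' @param mode `"hybrid"` or `"ml_full"`.
#' @return a GRN interaction data frame as in [convert_rule_based()].
#' @export
convert_ml <- function(documents, symbol_table, classifiers,
                       mode = c("hybrid", "ml_full"), doc_restriction = "all") {
  mode <- match.arg(mode)
  if (mode == "ml_full" && !classifiers$include_entity_type_features)
    stop("configuration error: ml_full mode requires classifiers trained ",
         "with entity-type features")
  idx <- build_event_index(documents, symbol_table, levels = "canonical")
  rel <- match_symbols(restrict_documents(corpus_relations(documents),
                                          doc_restriction), symbol_table)
  cand <- pair_candidates(rel, idx, symbol_table,
                          classifiers$include_entity_type_features)
  empty <- data.frame(agent_id = character(0), target_id = character(0),
                      grn_type = character(0), confidence = numeric(0),
                      agent_entity_type = character(0),
                      target_entity_type = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(cand$pairs) == 0) return(empty)
  pos <- predict(classifiers, cand$features)
  rows <- list()
  for (i in seq_len(nrow(cand$pairs))) {
    for (type in GRN_TYPES[pos[i, ]]) {
      agent_et <- cand$pairs$agent_entity_type[[i]]
      target_et <- cand$pairs$target_entity_type[[i]]
      if (mode == "hybrid") {
        combo <- any_combo_compatible(type, cand$et_combos[[i]])
        if (is.null(combo)) next  # entity-type filter, per observed combos
        et <- strsplit(combo, "|", fixed = TRUE)[[1]]
        agent_et <- et[[1]]
        target_et <- et[[2]]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        agent_id = cand$pairs$agent_id[[i]],
        target_id = cand$pairs$target_id[[i]],
        grn_type = type,
        confidence = cand$features[i, "maxc_fwd_total"],
        agent_entity_type = agent_et,
        target_entity_type = target_et,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  edges <- do.call(rbind, rows)
  if (mode == "hybrid") edges <- refactor_binding(edges)
  edges <- select_edges(edges)
  rownames(edges) <- NULL
  edges
}
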