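#' GRN conversion ablation report
#'
#' Runs the rule-based conversion with and without entity-type filtering,
#' and optionally restricted to a document subset, scoring each setting
#' against the gold network in strict and relaxed mode. Mirrors the
#' method/dataset ablation tables of the conversion system ("TC" = type
#' conversion only, "TC, ETF" = with entity-type filtering).
#'
#' @param documents corpus documents.
#' @param symbol_table gold symbol table.
#' @param gold_network gold relation data frame.
#' @param doc_restrictions named list of document restrictions (each
#'   `"all"` or a vector of doc ids).
#' @param seed recorded in the provenance block.
#' @return an `experiment_report`: list with `rows` (data frame) and
#'   `provenance`.
#' @export
run_grn_ablation <- function(documents, symbol_table, gold_network,
                             doc_restrictions = list("all corpus" = "all"),
                             seed = NA_integer_) {
  rows <- list()
  for (etf in c(FALSE, TRUE)) {
    for (ds in names(doc_restrictions)) {
      net <- convert_rule_based(documents, symbol_table,
                                doc_restriction = doc_restrictions[[ds]],
                                apply_entity_filter = etf)
      strict <- score_network(net, gold_network, "strict")
      relaxed <- score_network(net, gold_network, "relaxed")
      rows[[length(rows) + 1L]] <- data.frame(
        method = if (etf) "TC, ETF" else "TC", dataset = ds,
        n_edges = nrow(net), ser = strict$ser, f = strict$f_score,
        precision = strict$precision, recall = strict$recall,
        rel_p = relaxed$precision, rel_r = relaxed$recall,
        rel_f = relaxed$f_score, rel_ser = relaxed$ser,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(rows = do.call(rbind, rows),
                 provenance = report_provenance(seed,
                   list(doc_restrictions = doc_restrictions))),
            class = "experiment_report")
}

#' Oracle suite report for the re-ranking system
#'
#' Computes the five-row oracle comparison on scored, labeled query sets:
#' best-case oracle (re-ranked), worst-case oracle (re-ranked), worst-case
#' oracle with randomized rankings (averaged over `n_random_runs`), the
#' current system (regressed thresholds), and the unfiltered baseline —
#' overall and split into single-argument and multiple-argument events.
#'
#' @param query_sets scored, labeled query sets (test portion).
#' @param thresholds regressed per-sentence thresholds of the current
#'   system.
#' @param n_random_runs runs to average for the random-ranking row.
#' @param seed seed for the randomized rankings (recorded in provenance).
#' @param fallback_offset oracle margin.
#' @return an `experiment_report` with one row per (system, event split).
#' @export
run_oracle_suite <- function(query_sets, thresholds, n_random_runs = 10,
                             seed = 1, fallback_offset = 0.2) {
  best <- oracle_thresholds(query_sets, "best", fallback_offset)
  worst <- oracle_thresholds(query_sets, "worst", fallback_offset)
  none <- rep(-Inf, length(query_sets))
  rows <- list()
  for (split in c("all", "single", "multi")) {
    subset <- if (split == "all") NULL else split
    add <- function(system, m) {
      rows[[length(rows) + 1L]] <<- data.frame(
        system = system, split = split, precision = m$precision,
        recall = m$recall, f = m$f, stringsAsFactors = FALSE)
    }
    add("best-case oracle (re-ranked)",
        filter_metrics(query_sets, best, subset = subset))
    add("worst-case oracle (re-ranked)",
        filter_metrics(query_sets, worst, subset = subset))
    add("worst-case oracle (random)",
        random_rank_baseline(query_sets, n_runs = n_random_runs, seed = seed,
                             fallback_offset = fallback_offset,
                             subset = subset))
    add("current system", filter_metrics(query_sets, thresholds,
                                         subset = subset))
    add("baseline (unfiltered)", filter_metrics(query_sets, none,
                                                subset = subset))
  }
  structure(list(rows = do.call(rbind, rows),
                 provenance = report_provenance(seed,
                   list(n_random_runs = n_random_runs,
                        fallback_offset = fallback_offset))),
            class = "experiment_report")
}

report_provenance <- function(seed, config) {
  list(seed = seed, config = config,
       package_version = as.character(utils::packageVersion("bibliome")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  print(x$rows, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an experiment report as JSON
#'
#' Flat row schema plus a provenance block (seed, configuration, package
#' version), sufficient to re-run the report reproducibly.
#'
#' @param report an `experiment_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(list(rows = report$rows,
                            provenance = report$provenance),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
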