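#' Construct a validated annotated document
#'
#' A document bundles the flat text, the entity layer, the (possibly nested)
#' event layer and an explicit sentence segmentation. Validation enforces
#' the standoff invariants: spans match the text, sentence spans are ordered
#' and non-overlapping, and every entity and trigger span falls inside
#' exactly one sentence.
#'
#' @param doc_id document identifier (PMID-like string).
#' @param text full document text (flat character sequence; offsets are
#'   0-based, end-exclusive).
#' @param entities named entity list, as from [parse_a1()].
#' @param events named event list, as from [parse_a2()].
#' @param sentences data frame with 0-based, end-exclusive columns
#'   `start`, `end`; one row per sentence, in document order.
#' @return an object of class `bib_document`.
#' @export
new_document <- function(doc_id, text, entities = list(), events = list(),
                         sentences = NULL) {
  if (is.null(sentences)) sentences <- sentences_from_lines(text)
  stopifnot(is.data.frame(sentences), all(c("start", "end") %in% names(sentences)))
  if (nrow(sentences) > 1) {
    if (any(diff(sentences$start) <= 0) ||
        any(sentences$start[-1] < sentences$end[-nrow(sentences)]))
      stop("integrity error: sentence spans must be ordered and non-overlapping")
  }
  if (nrow(sentences) > 0 && any(sentences$start < 0 | sentences$end > nchar(text) |
                                 sentences$start >= sentences$end))
    stop("integrity error: sentence span outside document")
  doc <- structure(list(doc_id = doc_id, text = text, entities = entities,
                        events = events, sentences = sentences),
                   class = "bib_document")
  for (e in entities) check_in_sentence(doc, e$start, e$end, e$id)
  for (ev in events) check_in_sentence(doc, ev$trigger_start, ev$trigger_end, ev$id)
  doc
}

# One sentence per line; the newline separators are not part of any sentence.
sentences_from_lines <- function(text) {
  if (!nzchar(text))
    return(data.frame(start = integer(0), end = integer(0)))
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  start <- cumsum(c(0L, nchar(lines) + 1L))[seq_along(lines)]
  keep <- nchar(lines) > 0
  data.frame(start = start[keep], end = (start + nchar(lines))[keep])
}

check_in_sentence <- function(doc, start, end, id) {
  hit <- which(doc$sentences$start <= start & end <= doc$sentences$end)
  if (length(hit) != 1)
    stop("integrity error: span of ", id, " in document ", doc$doc_id,
         " does not fall inside exactly one sentence")
  invisible(hit)
}

sentence_of <- function(doc, start) {
  which(doc$sentences$start <= start & start < doc$sentences$end)[1]
}

#' @export
print.bib_document <- function(x, ...) {
  cat("<bib_document>", x$doc_id, "-", nrow(x$sentences), "sentences,",
      length(x$entities), "entities,", length(x$events), "events\n")
  invisible(x)
}

#' Read and write document corpora on disk
#'
#' A corpus directory holds one set of files per document:
#' `<doc_id>.txt` (text), `<doc_id>.a1` (entities), `<doc_id>.a2` (events),
#' and optional sidecars `<doc_id>.conf.tsv` (per-event confidence and
#' negation) and `<doc_id>.sent.tsv` (explicit sentence spans,
#' `start<TAB>end`). Without a sentence sidecar, one sentence per text line
#' is assumed.
#'
#' @param dir corpus directory.
#' @return `read_corpus`: a named list of `bib_document` objects;
#'   `write_corpus`: the directory path, invisibly.
#' @export
read_corpus <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = FALSE))
  docs <- list()
  for (f in txts) {
    doc_id <- sub("\\.txt$", "", f)
    docs[[doc_id]] <- read_document(dir, doc_id)
  }
  docs
}

#' @rdname read_corpus
#' @param doc_id document identifier (file stem).
#' @export
read_document <- function(dir, doc_id) {
  slurp <- function(ext) {
    p <- file.path(dir, paste0(doc_id, ext))
    if (!file.exists(p)) return(NULL)
    paste(readLines(p, warn = FALSE), collapse = "\n")
  }
  text <- slurp(".txt")
  if (is.null(text)) stop("no .txt file for document ", doc_id)
  entities <- parse_a1(slurp(".a1") %||% "", text)
  events <- parse_a2(slurp(".a2") %||% "", entities, text)
  conf <- slurp(".conf.tsv")
  if (!is.null(conf)) events <- read_confidence_tsv(conf, events)
  sent <- slurp(".sent.tsv")
  sentences <- NULL
  if (!is.null(sent)) {
    lines <- split_lines(sent)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sentences <- data.frame(start = as.integer(vapply(parts, `[[`, character(1), 1)),
                            end = as.integer(vapply(parts, `[[`, character(1), 2)))
  }
  new_document(doc_id, text, entities, events, sentences)
}

#' @rdname read_corpus
#' @param corpus named list of `bib_document` objects.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (doc in corpus) write_document(doc, dir)
  invisible(dir)
}

#' @rdname read_corpus
#' @param doc a `bib_document`.
#' @export
write_document <- function(doc, dir) {
  put <- function(ext, content) {
    writeLines(content, file.path(dir, paste0(doc$doc_id, ext)), sep = "")
  }
  put(".txt", if (endsWith(doc$text, "\n")) doc$text else paste0(doc$text, "\n"))
  put(".a1", write_a1(doc$entities))
  put(".a2", write_a2(doc$events, doc$entities))
  put(".conf.tsv", write_confidence_tsv(doc$events))
  sent <- if (nrow(doc$sentences) == 0) "" else
    paste0(paste(paste(doc$sentences$start, doc$sentences$end, sep = "\t"),
                 collapse = "\n"), "\n")
  put(".sent.tsv", sent)
  invisible(doc$doc_id)
}
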