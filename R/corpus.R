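#' Bibliographic record collections
#'
#' A `corpus` holds a set of bibliographic reference records, one per
#' database accession (e.g. a PMID). Each record carries a title, an
#' abstract (possibly empty), the controlled-vocabulary terms assigned by
#' the database verbatim (subheadings after `/` and the major-topic marker
#' `*` are preserved), and a tag naming the database of origin.
#'
#' Corpora are the common currency of the package: the development set, the
#' validation set and the database population sample are all corpora.
#'
#' @param records a data frame with columns `accession` (character,
#'   non-empty, unique), `title` (character), `abstract` (character),
#'   `cv_terms` (list of character vectors) and `source` (character).
#'   Missing columns other than `accession` are filled with empty values.
#' @param label a short tag for the collection, e.g. `"development"`,
#'   `"population"`.
#' @return an object of class `corpus`.
#' @examples
#' corp <- corpus(data.frame(accession = c("1", "2"),
#'                           title = c("Brachytherapy for prostate cancer.",
#'                                     "External beam radiotherapy.")),
#'                label = "demo")
#' corpus_size(corp)
#' @export
corpus <- function(records = NULL, label = "corpus") {
  if (is.null(records)) {
    records <- tibble::tibble(accession = character(), title = character(),
                              abstract = character(), cv_terms = list(),
                              source = character())
  }
  records <- tibble::as_tibble(records)
  if (!"accession" %in% names(records)) {
    stop("records must have an 'accession' column", call. = FALSE)
  }
  records$accession <- as.character(records$accession)
  if (!"title" %in% names(records))    records$title    <- character(nrow(records))
  if (!"abstract" %in% names(records)) records$abstract <- character(nrow(records))
  if (!"source" %in% names(records))   records$source   <- character(nrow(records))
  if (!"cv_terms" %in% names(records)) {
    records$cv_terms <- replicate(nrow(records), character(), simplify = FALSE)
  }
  records$title[is.na(records$title)]       <- ""
  records$abstract[is.na(records$abstract)] <- ""
  records$cv_terms <- lapply(records$cv_terms, function(x) {
    if (length(x) == 0) character() else as.character(x)
  })
  records <- records[, c("accession", "title", "abstract", "cv_terms", "source")]
  obj <- structure(list(records = records, label = as.character(label)[1]),
                   class = "corpus")
  validate_corpus(obj)
  obj
}

validate_corpus <- function(x) {
  rec <- x$records
  if (any(!nzchar(rec$accession)) || anyNA(rec$accession)) {
    stop("every record needs a non-empty accession", call. = FALSE)
  }
  dup <- rec$accession[duplicated(rec$accession)]
  if (length(dup) > 0) {
    stop("duplicate accession(s) in corpus: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  empty <- !nzchar(rec$title) & !nzchar(rec$abstract)
  if (any(empty)) {
    stop("record(s) with neither title nor abstract: ",
         paste(rec$accession[empty], collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @rdname corpus
#' @param x a `corpus`.
#' @export
corpus_size <- function(x) {
  stopifnot(inherits(x, "corpus"))
  nrow(x$records)
}

#' @rdname corpus
#' @export
corpus_label <- function(x) {
  stopifnot(inherits(x, "corpus"))
  x$label
}

#' @rdname corpus
#' @export
accessions <- function(x) {
  stopifnot(inherits(x, "corpus"))
  x$records$accession
}

#' @rdname corpus
#' @param ... ignored.
#' @exportS3Method tibble::as_tibble
as_tibble.corpus <- function(x, ...) {
  x$records
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus '%s': %d record%s>\n", x$label, corpus_size(x),
              if (corpus_size(x) == 1) "" else "s"))
  if (corpus_size(x) > 0) {
    shown <- utils::head(x$records, 5)
    for (i in seq_len(nrow(shown))) {
      ti <- shown$title[i]
      if (nchar(ti) > 60) ti <- paste0(substr(ti, 1, 57), "...")
      cat(sprintf("  %s  %s\n", format(shown$accession[i], width = 10), ti))
    }
    if (corpus_size(x) > 5) cat(sprintf("  ... and %d more\n", corpus_size(x) - 5))
  }
  invisible(x)
}

#' Subset a corpus by accession
#'
#' @param x a `corpus`.
#' @param ids character vector of accessions to keep.
#' @param label optional new label; defaults to the input label.
#' @return a `corpus` containing the records whose accession is in `ids`,
#'   in corpus order.
#' @export
corpus_subset <- function(x, ids, label = corpus_label(x)) {
  stopifnot(inherits(x, "corpus"))
  corpus(x$records[x$records$accession %in% ids, , drop = FALSE], label = label)
}

#' Pool corpora and drop duplicate accessions
#'
#' Records are concatenated in the order given; when the same accession
#' occurs more than once (within or across corpora) the first occurrence
#' wins. Pooling the references extracted from several systematic reviews
#' into one test set is the typical use.
#'
#' @param corpora a list of `corpus` objects (a single `corpus` is accepted).
#' @param label label for the merged corpus.
#' @return a `corpus` whose size is the number of distinct accessions.
#' @examples
#' a <- corpus(data.frame(accession = c("1", "2"), title = c("t1", "t2")))
#' b <- corpus(data.frame(accession = c("2", "3"), title = c("t2", "t3")))
#' corpus_size(merge_dedupe(list(a, b)))  # 3
#' @export
merge_dedupe <- function(corpora, label = "merged") {
  if (inherits(corpora, "corpus")) corpora <- list(corpora)
  stopifnot(length(corpora) >= 1, all(vapply(corpora, inherits, logical(1), "corpus")))
  recs <- do.call(rbind, lapply(corpora, function(x) x$records))
  recs <- recs[!duplicated(recs$accession), , drop = FALSE]
  corpus(recs, label = label)
}
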