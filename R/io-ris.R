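#' Read RIS reference files
#'
#' Parses RIS records delimited by `TY` / `ER` tags. The accession is taken
#' from `ID` or `AN` (first present); `TI`/`T1` give the title, `AB`/`N2`
#' the abstract, and each `KW` line contributes one controlled-vocabulary
#' term. Records lacking any accession field get a deterministic surrogate
#' accession `"ris:<ordinal>"` (ordinal = position in the file, 1-based).
#' Records with neither title nor abstract are skipped; the number skipped
#' is attached to the result as attribute `"skipped"` and reported with a
#' warning.
#'
#' @param path path to a RIS file.
#' @param label corpus label.
#' @param source tag recorded in each record's `source` field.
#' @return a [corpus].
#' @seealso [read_medline()]
#' @export
read_ris <- function(path, label = "corpus", source = "ris") {
  lines <- read_text_lines(path)
  tag_re <- "^([A-Z][A-Z0-9])\\s{2}-\\s?(.*)$"
  recs <- list()
  cur <- NULL
  ordinal <- 0L
  skipped <- 0L
  finish <- function(cur, ordinal) {
    if (is.null(cur)) return(NULL)
    acc <- cur$id
    if (is.null(acc) || !nzchar(acc)) acc <- sprintf("ris:%d", ordinal)
    title <- paste(cur$ti, collapse = " ")
    abstract <- paste(cur$ab, collapse = " ")
    if (!nzchar(title) && !nzchar(abstract)) return("skip")
    list(accession = acc, title = title, abstract = abstract, cv_terms = cur$kw)
  }
  for (ln in lines) {
    m <- regmatches(ln, regexec(tag_re, ln))[[1]]
    if (length(m) != 3) next                     # stray/continuation: ignore
    tag <- m[2]; val <- trimws(m[3])
    if (tag == "TY") {
      ordinal <- ordinal + 1L
      cur <- list(id = NULL, ti = character(), ab = character(), kw = character())
    } else if (tag == "ER") {
      r <- finish(cur, ordinal)
      if (identical(r, "skip")) skipped <- skipped + 1L
      else if (!is.null(r)) recs[[length(recs) + 1L]] <- r
      cur <- NULL
    } else if (!is.null(cur)) {
      if (tag %in% c("ID", "AN") && is.null(cur$id)) cur$id <- val
      else if (tag %in% c("TI", "T1")) cur$ti <- c(cur$ti, val)
      else if (tag %in% c("AB", "N2")) cur$ab <- c(cur$ab, val)
      else if (tag == "KW") cur$kw <- c(cur$kw, val)
    }
  }
  r <- finish(cur, ordinal)                      # tolerate a missing final ER
  if (identical(r, "skip")) skipped <- skipped + 1L
  else if (!is.null(r)) recs[[length(recs) + 1L]] <- r
  if (skipped > 0) {
    warning(sprintf("skipped %d RIS record(s) with neither title nor abstract",
                    skipped), call. = FALSE)
  }
  out <- if (length(recs) == 0) {
    corpus(label = label)
  } else {
    corpus(tibble::tibble(
      accession = vapply(recs, `[[`, character(1), "accession"),
      title = vapply(recs, `[[`, character(1), "title"),
      abstract = vapply(recs, `[[`, character(1), "abstract"),
      cv_terms = lapply(recs, `[[`, "cv_terms"),
      source = source
    ), label = label)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Serialize a corpus to and from JSON-lines
#'
#' One JSON object per line with fields `accession`, `title`, `abstract`,
#' `cv_terms` and `source`; used for compact plain-text fixtures.
#'
#' @param x a [corpus].
#' @param path output (or input) file path.
#' @param label corpus label for `read_corpus_jsonl`.
#' @return `write_corpus_jsonl` returns `path` invisibly;
#'   `read_corpus_jsonl` returns a [corpus].
#' @export
write_corpus_jsonl <- function(x, path) {
  stopifnot(inherits(x, "corpus"))
  lines <- vapply(seq_len(corpus_size(x)), function(i) {
    rec <- x$records[i, ]
    jsonlite::toJSON(list(accession = rec$accession, title = rec$title,
                          abstract = rec$abstract,
                          cv_terms = rec$cv_terms[[1]],
                          source = rec$source),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path, label = "corpus") {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(corpus(label = label))
  recs <- lapply(lines, jsonlite::fromJSON)
  corpus(tibble::tibble(
    accession = vapply(recs, function(r) as.character(r$accession), character(1)),
    title = vapply(recs, function(r) r$title %||% "", character(1)),
    abstract = vapply(recs, function(r) r$abstract %||% "", character(1)),
    cv_terms = lapply(recs, function(r) as.character(r$cv_terms %||% character())),
    source = vapply(recs, function(r) r$source %||% "", character(1))
  ), label = label)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
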