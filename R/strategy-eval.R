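#' Evaluate a search strategy against a local corpus
#'
#' Runs every line of a parsed strategy over the corpus with
#' database-faithful semantics and records the set of matching accessions
#' per line:
#'
#' * a text term matches a record when some token of the searched fields
#'   equals it, or starts with it when the term carries a trailing
#'   truncation `*`;
#' * field tags restrict matching: `ti` = title tokens, `ab` = abstract
#'   tokens, `kw` = tokens of the normalized controlled-vocabulary
#'   headings;
#' * a controlled-vocabulary line (`Heading/`) matches when any of the
#'   record's headings — major-topic marker and subheadings stripped,
#'   case folded — equals the heading (no explosion, no MeSH tree);
#' * `and` / `or` are set intersection / union; `or/a-b` is the union of
#'   lines a..b; `and/a,b` the intersection; an accession list (`.ui.`)
#'   selects the records whose accession is listed.
#'
#' All comparisons are case-insensitive.
#'
#' @param strategy a `search_strategy` from [parse_strategy()].
#' @param corpus a non-empty [corpus].
#' @param min_length tokenizer setting (see [tokenize()]).
#' @return a `result_set`: list with `lines` (named list, line number ->
#'   character vector of accessions), `strategy` and `corpus_label`.
#' @examples
#' corp <- corpus(data.frame(
#'   accession = c("r1", "r2", "r3"),
#'   title = c("prostate cancer brachytherapy", "prostate cancer", "breast cancer")))
#' strat <- parse_strategy(c("1 brachytherapy.ab,ti.",
#'                           "2 (prostat* and cancer).ab,ti.",
#'                           "3 and/1,2"))
#' hit_counts(evaluate_strategy(strat, corp))
#' @export
evaluate_strategy <- function(strategy, corpus, min_length = 2L) {
  stopifnot(inherits(strategy, "search_strategy"), inherits(corpus, "corpus"))
  if (corpus_size(corpus) == 0) stop("cannot evaluate against an empty corpus",
                                     call. = FALSE)
  idx <- corpus_search_index(corpus, min_length)
  results <- list()
  for (ln in strategy$lines) {
    hits <- eval_node(ln$expression, idx, results)
    results[[as.character(ln$line_number)]] <- hits
  }
  structure(list(lines = results, strategy = strategy,
                 corpus_label = corpus_label(corpus)),
            class = "result_set")
}

# precomputed per-record token sets per field + normalized headings
corpus_search_index <- function(corpus, min_length = 2L) {
  rec <- corpus$records
  list(
    accession = rec$accession,
    ti = lapply(rec$title, function(x) unique(tokenize(x, min_length))),
    ab = lapply(rec$abstract, function(x) unique(tokenize(x, min_length))),
    kw = lapply(rec$cv_terms, function(terms) {
      unique(as.character(unlist(lapply(normalize_heading(terms), tokenize,
                                        min_length), use.names = FALSE)))
    }),
    headings = lapply(rec$cv_terms, function(terms) unique(normalize_heading(terms))),
    n = nrow(rec)
  )
}

eval_node <- function(x, idx, results, fields = NULL) {
  get_line <- function(n) {
    key <- as.character(n)
    if (is.null(results[[key]])) {
      stop(sprintf("reference to line %d before it was evaluated", n),
           call. = FALSE)
    }
    results[[key]]
  }
  switch(x$type,
    cv_heading = idx$accession[vapply(idx$headings, function(h)
      x$heading %in% h, logical(1))],
    fielded_text = eval_node(x$expr, idx, results, fields = x$fields),
    term = {
      if (is.null(fields)) {
        stop("text term outside a fielded expression", call. = FALSE)
      }
      match_rec <- logical(idx$n)
      for (f in fields) {
        toksets <- idx[[f]]
        if (x$truncated) {
          match_rec <- match_rec | vapply(toksets, function(tk)
            any(startsWith(tk, x$token)), logical(1))
        } else {
          match_rec <- match_rec | vapply(toksets, function(tk)
            x$token %in% tk, logical(1))
        }
      }
      idx$accession[match_rec]
    },
    and = Reduce(intersect, lapply(x$children, eval_node, idx, results, fields)),
    or = unique(unlist(lapply(x$children, eval_node, idx, results, fields))),
    line_ref = get_line(x$n),
    line_range_or = unique(unlist(lapply(seq(x$from, x$to), get_line))),
    line_list_and = Reduce(intersect, lapply(x$lines, get_line)),
    accession_list = idx$accession[idx$accession %in% x$ids],
    stop("unknown node type: ", x$type)
  )
}

#' Per-line hit counts of an evaluated strategy
#'
#' @param result a `result_set` from [evaluate_strategy()].
#' @return a tibble with columns `line`, `query` (the rendered expression,
#'   including any annotation) and `count`.
#' @export
hit_counts <- function(result) {
  stopifnot(inherits(result, "result_set"))
  lines <- result$strategy$lines
  tibble::tibble(
    line = vapply(lines, `[[`, integer(1), "line_number"),
    query = vapply(lines, function(ln) {
      txt <- format_query_node(ln$expression, top = TRUE)
      if (!is.na(ln$annotation)) txt <- sprintf("%s [%s]", txt, ln$annotation)
      txt
    }, character(1)),
    count = vapply(lines, function(ln)
      length(result$lines[[as.character(ln$line_number)]]), integer(1))
  )
}

#' Accessions retrieved by one line of an evaluated strategy
#'
#' @param result a `result_set`.
#' @param line line number; defaults to the last line.
#' @return character vector of accessions.
#' @export
retrieved <- function(result, line = NULL) {
  stopifnot(inherits(result, "result_set"))
  if (is.null(line)) {
    line <- max(vapply(result$strategy$lines, `[[`, integer(1), "line_number"))
  }
  out <- result$lines[[as.character(line)]]
  if (is.null(out)) stop("no such line: ", line, call. = FALSE)
  out
}

#' @export
print.result_set <- function(x, ...) {
  cat(sprintf("<result_set over corpus '%s'>\n", x$corpus_label))
  print(hit_counts(x), n = Inf)
  invisible(x)
}

#' Export per-line hit counts as CSV or a markdown table
#'
#' @param result a `result_set`.
#' @param path output file; `NULL` returns the rendered text invisibly
#'   without writing (markdown only).
#' @param format `"csv"` or `"markdown"`.
#' @return the path (or the markdown text), invisibly.
#' @export
write_hit_counts <- function(result, path = NULL, format = c("csv", "markdown")) {
  format <- match.arg(format)
  tab <- hit_counts(result)
  if (format == "csv") {
    stopifnot(!is.null(path))
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(path))
  }
  md <- c("| Number | Searches | Results |", "| --- | --- | --- |",
          sprintf("| %d | %s | %s |", tab$line, gsub("\\|", "\\\\|", tab$query),
                  format(tab$count, big.mark = ",", trim = TRUE)))
  text <- paste(md, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(path))
  }
  invisible(text)
}
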