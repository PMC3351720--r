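#' Randomly split a test set into development and validation sets
#'
#' Splits the accessions of a quasi-gold-standard test set into a
#' development set used to derive the strategy and a held-out validation
#' set used to test it. The development fraction defaults to two-thirds;
#' its size is `round(ratio * n)` with halves rounded away from zero, so
#' 38 references split into 25 for development and 13 for validation. The
#' sample is uniform without replacement and fully reproducible from
#' `seed`.
#'
#' @param ids character vector (or set) of accessions, at least 3.
#' @param seed integer seed; mandatory, so the split is auditable.
#' @param ratio development-set fraction in (0, 1); default 2/3.
#' @return a `split_result`: list with `dev_ids`, `val_ids`, `seed`,
#'   `ratio`.
#' @examples
#' s <- split_test_set(as.character(1:38), seed = 7)
#' length(s$dev_ids); length(s$val_ids)
#' @export
split_test_set <- function(ids, seed, ratio = 2 / 3) {
  ids <- unique(as.character(ids))
  if (length(ids) < 3) {
    stop("need at least 3 ids to form non-empty development and validation sets",
         call. = FALSE)
  }
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory", call. = FALSE)
  if (!(ratio > 0 && ratio < 1)) stop("ratio must lie in (0, 1)", call. = FALSE)
  n_dev <- round_half_up(ratio * length(ids))
  n_dev <- max(1L, min(length(ids) - 1L, n_dev))
  dev_ids <- withr::with_seed(as.integer(seed), sample(ids, n_dev))
  structure(list(dev_ids = sort(dev_ids),
                 val_ids = sort(setdiff(ids, dev_ids)),
                 seed = as.integer(seed), ratio = ratio),
            class = "split_result")
}

round_half_up <- function(x) floor(x + 0.5)

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result: %d development / %d validation (seed %d)>\n",
              length(x$dev_ids), length(x$val_ids), x$seed))
  invisible(x)
}

#' Validate a strategy against a held-out reference set
#'
#' Runs the strategy over `corpus`, then — mirroring the standard
#' accession-check lines of a documented validation — appends an accession
#' list line for `val_ids` and an AND of it with the strategy's final
#' content line. The report gives per-line hit counts, the validation
#' sensitivity and the accessions missed.
#'
#' @param strategy a `search_strategy`.
#' @param corpus [corpus] containing (at least) the validation records.
#' @param val_ids accessions of the held-out validation set (subset of the
#'   corpus accessions).
#' @param dev_ids optional: the development ids used to build the strategy;
#'   when given, any overlap with `val_ids` is an error.
#' @param annotation annotation for the appended accession-list line.
#' @param min_length tokenizer setting.
#' @return a `validation_report`: list with `strategy_text`, `counts`
#'   (per-line tibble), `sensitivity`, `missed`, `val_ids`, `corpus_label`,
#'   `timestamp`.
#' @export
validate_strategy <- function(strategy, corpus, val_ids, dev_ids = NULL,
                              annotation = "validation set", min_length = 2L) {
  stopifnot(inherits(strategy, "search_strategy"), inherits(corpus, "corpus"))
  val_ids <- unique(as.character(val_ids))
  if (length(val_ids) == 0) stop("val_ids must be non-empty", call. = FALSE)
  outside <- setdiff(val_ids, accessions(corpus))
  if (length(outside) > 0) {
    stop("validation id(s) not in corpus: ", paste(outside, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(dev_ids)) {
    overlap <- intersect(val_ids, dev_ids)
    if (length(overlap) > 0) {
      stop("validation set overlaps development set: ",
           paste(overlap, collapse = ", "), call. = FALSE)
    }
  }
  last <- strategy_length(strategy)
  ui_line <- sprintf('%d (%s).ui. [%s]', last + 1L,
                     paste(sprintf('"%s"', val_ids), collapse = " or "),
                     annotation)
  and_line <- sprintf("%d %d and %d", last + 2L, last, last + 1L)
  extended <- parse_strategy(c(format_strategy(strategy), ui_line, and_line))
  res <- evaluate_strategy(extended, corpus, min_length)
  hits <- retrieved(res)
  missed <- setdiff(val_ids, hits)
  sens <- 1 - length(missed) / length(val_ids)
  structure(list(strategy_text = format_strategy(extended),
                 counts = hit_counts(res),
                 sensitivity = sens,
                 missed = missed,
                 val_ids = val_ids,
                 corpus_label = corpus_label(corpus),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report on corpus '%s'>\n", x$corpus_label))
  cat(sprintf("  sensitivity: %.4f (%d of %d retrieved)\n", x$sensitivity,
              length(x$val_ids) - length(x$missed), length(x$val_ids)))
  if (length(x$missed) > 0) {
    cat("  missed:", paste(x$missed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write the standardized internal documentation bundle
#'
#' Transparency demands that every step of the development and validation
#' of a strategy be stored for later quality control: the preliminary
#' search, the systematic reviews the test set came from, the frequency
#' tables (text words and controlled vocabulary), the candidate-term list,
#' the strategy itself, the build log and the validation result. This
#' writes them as a deterministic set of plain-text files (CSV + strategy
#' text + JSON log + a markdown index); rerunning on identical inputs is
#' byte-identical apart from the timestamp, which can be pinned for exact
#' reproducibility.
#'
#' @param out_dir output directory (created if needed).
#' @param term_table text-word frequency table ([term_stats()]); mandatory.
#' @param strategy the built `search_strategy` (or a `build_result`);
#'   mandatory.
#' @param cv_table controlled-vocabulary frequency table ([cv_stats()] or
#'   a named vector from [cv_frequencies()]).
#' @param candidates categorized candidate table ([categorize_terms()]).
#' @param build_log the `log` element of a `build_result` (or a whole
#'   `build_result`).
#' @param validation a `validation_report`.
#' @param preliminary_search free-text record of the preliminary search
#'   (e.g. the Cochrane Library query used to find the source reviews).
#' @param sr_list character vector identifying the systematic reviews the
#'   test set was extracted from.
#' @param timestamp timestamp string written into the index; defaults to
#'   the current time.
#' @return character vector of the files written, invisibly.
#' @export
report_bundle <- function(out_dir, term_table, strategy,
                          cv_table = NULL, candidates = NULL, build_log = NULL,
                          validation = NULL, preliminary_search = NULL,
                          sr_list = NULL,
                          timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) {
  missing_parts <- character()
  if (missing(term_table) || is.null(term_table)) missing_parts <- c(missing_parts, "term_table")
  if (missing(strategy) || is.null(strategy)) missing_parts <- c(missing_parts, "strategy")
  if (length(missing_parts) > 0) {
    stop("missing mandatory artifact(s): ", paste(missing_parts, collapse = ", "),
         call. = FALSE)
  }
  if (inherits(strategy, "build_result")) {
    if (is.null(build_log)) build_log <- strategy$log
    strategy <- strategy$strategy
  }
  if (inherits(build_log, "build_result")) build_log <- build_log$log
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(name) {
    path <- file.path(out_dir, name)
    written <<- c(written, path)
    path
  }
  utils::write.csv(term_table, emit("term_frequencies.csv"), row.names = FALSE)
  writeLines(format_strategy(strategy), emit("strategy.txt"))
  if (!is.null(cv_table)) {
    if (!is.data.frame(cv_table)) {
      cv_table <- tibble::tibble(term = names(cv_table),
                                 frequency = as.integer(cv_table))
    }
    utils::write.csv(cv_table, emit("cv_frequencies.csv"), row.names = FALSE)
  }
  if (!is.null(candidates)) {
    utils::write.csv(candidates, emit("candidate_terms.csv"), row.names = FALSE)
  }
  if (!is.null(build_log)) {
    jsonlite::write_json(build_log, emit("build_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  if (!is.null(validation)) {
    utils::write.csv(validation$counts, emit("validation_counts.csv"),
                     row.names = FALSE)
    writeLines(c(sprintf("sensitivity,%g", validation$sensitivity),
                 sprintf("missed,%s", paste(validation$missed, collapse = ";"))),
               emit("validation_summary.csv"))
  }
  if (!is.null(preliminary_search)) {
    writeLines(preliminary_search, emit("preliminary_search.txt"))
  }
  if (!is.null(sr_list)) {
    writeLines(sr_list, emit("source_reviews.txt"))
  }
  index <- c("# Search strategy documentation bundle", "",
             paste0("Generated: ", timestamp), "",
             "Contents:", paste0("- ", basename(written)))
  writeLines(index, file.path(out_dir, "INDEX.md"))
  written <- c(written, file.path(out_dir, "INDEX.md"))
  invisible(written)
}
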