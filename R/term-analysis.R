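#' Tokenize free text into lowercase word tokens
#'
#' The tokenizer deliberately does the minimum: lowercase, split on every
#' non-alphabetic character, drop tokens shorter than `min_length` and any
#' purely numeric fragments. There is no stemming and no stopword removal —
#' uninformative high-frequency words ("patients", "results", "using") are
#' filtered later by the population-set comparison, not by a stopword list,
#' so that the frequency table shows them honestly.
#'
#' @param text a character vector; each element tokenized independently.
#' @param min_length minimum token length kept (default 2).
#' @return for a single string, a character vector of tokens; for a longer
#'   input, a list of such vectors.
#' @examples
#' tokenize("follow-up of PSA (prostate-specific antigen)")
#' @export
tokenize <- function(text, min_length = 2L) {
  out <- lapply(text, function(x) {
    if (is.na(x) || !nzchar(x)) return(character())
    toks <- strsplit(tolower(x), "[^[:alpha:]]+")[[1]]
    toks[nchar(toks) >= min_length & !grepl("^[0-9]+$", toks)]
  })
  if (length(text) == 1) out[[1]] else out
}

# unique tokens of title + abstract, one vector per record
record_token_sets <- function(corpus, min_length = 2L) {
  lapply(seq_len(corpus_size(corpus)), function(i) {
    unique(c(tokenize(corpus$records$title[i], min_length),
             tokenize(corpus$records$abstract[i], min_length)))
  })
}

#' Per-term document frequencies in a corpus
#'
#' Counts, for every text word, the number of *records* whose title or
#' abstract contains the token at least once (document frequency). A token
#' occurring five times inside one abstract still counts once.
#'
#' @param corpus a non-empty [corpus].
#' @param min_length minimum token length (passed to [tokenize()]).
#' @return a named integer vector, term -> number of records, sorted by
#'   decreasing count with alphabetical tie-break.
#' @export
doc_frequencies <- function(corpus, min_length = 2L) {
  stopifnot(inherits(corpus, "corpus"))
  if (corpus_size(corpus) == 0) {
    stop("cannot compute document frequencies of an empty corpus", call. = FALSE)
  }
  toks <- unlist(record_token_sets(corpus, min_length), use.names = FALSE)
  if (length(toks) == 0) return(stats::setNames(integer(), character()))
  tab <- table(toks)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts))]
}

#' Aggregated controlled-vocabulary document frequencies
#'
#' Databases list a heading separately for each subheading used
#' ("Brachytherapy/methods", "*Brachytherapy"), so headings are normalized
#' before counting: the leading major-topic marker `*` and any
#' `/subheading` suffix are stripped and the heading is lowercased. A
#' heading is counted once per record however many subheadings it appears
#' with.
#'
#' @param corpus a [corpus].
#' @return a named integer vector, normalized heading -> number of records,
#'   sorted by decreasing count with alphabetical tie-break.
#' @export
cv_frequencies <- function(corpus) {
  stopifnot(inherits(corpus, "corpus"))
  per_rec <- lapply(corpus$records$cv_terms, function(terms) {
    unique(normalize_heading(terms))
  })
  toks <- unlist(per_rec, use.names = FALSE)
  if (length(toks) == 0) return(stats::setNames(integer(), character()))
  tab <- table(toks)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts))]
}

normalize_heading <- function(x) {
  x <- sub("^\\*", "", trimws(x))
  x <- sub("/.*$", "", x)
  tolower(trimws(x))
}

#' Term frequency and sensitivity table: development versus population set
#'
#' For every text word occurring in the development set, reports its
#' document frequency in the development set and in the population sample,
#' and the corresponding sensitivities `freq / N`. Sensitivity in the
#' development set answers "what fraction of known-relevant references does
#' this term retrieve"; sensitivity in the population set estimates how
#' common the term is across the whole database, i.e. how unspecific it is.
#'
#' @param dev development-set [corpus] (non-empty).
#' @param pop population-sample [corpus] (non-empty).
#' @param min_length minimum token length (passed to [tokenize()]).
#' @return a tibble with columns `term`, `kind` (`"text_word"`),
#'   `freq_dev`, `freq_pop`, `sens_dev`, `sens_pop`, sorted by decreasing
#'   `freq_dev` with alphabetical tie-break. The sensitivities are the
#'   exact ratios of the stored integer counts.
#' @examples
#' dev <- corpus(data.frame(accession = as.character(1:4),
#'                          title = c("prostate brachytherapy", "prostate seed",
#'                                    "prostate cancer", "breast cancer")))
#' pop <- corpus(data.frame(accession = paste0("p", 1:8),
#'                          title = rep(c("hip fracture", "prostate cancer"),
#'                                      c(7, 1))))
#' term_stats(dev, pop)
#' @export
term_stats <- function(dev, pop, min_length = 2L) {
  stopifnot(inherits(dev, "corpus"), inherits(pop, "corpus"))
  if (corpus_size(dev) == 0 || corpus_size(pop) == 0) {
    stop("development and population sets must both be non-empty", call. = FALSE)
  }
  f_dev <- doc_frequencies(dev, min_length)
  f_pop <- doc_frequencies(pop, min_length)
  terms <- names(f_dev)
  freq_pop <- unname(f_pop[terms])
  freq_pop[is.na(freq_pop)] <- 0L
  out <- tibble::tibble(
    term = terms,
    kind = "text_word",
    freq_dev = unname(f_dev),
    freq_pop = as.integer(freq_pop),
    sens_dev = unname(f_dev) / corpus_size(dev),
    sens_pop = as.integer(freq_pop) / corpus_size(pop)
  )
  out[order(-out$freq_dev, out$term), ]
}

#' Controlled-vocabulary frequency/sensitivity table
#'
#' The controlled-vocabulary analogue of [term_stats()]: document
#' frequencies of normalized headings in the development set versus the
#' population sample.
#'
#' @inheritParams term_stats
#' @return a tibble with the same columns as [term_stats()], `kind =
#'   "controlled_vocabulary"`.
#' @export
cv_stats <- function(dev, pop) {
  stopifnot(inherits(dev, "corpus"), inherits(pop, "corpus"))
  if (corpus_size(dev) == 0 || corpus_size(pop) == 0) {
    stop("development and population sets must both be non-empty", call. = FALSE)
  }
  f_dev <- cv_frequencies(dev)
  f_pop <- cv_frequencies(pop)
  terms <- names(f_dev)
  freq_pop <- unname(f_pop[terms])
  freq_pop[is.na(freq_pop)] <- 0L
  out <- tibble::tibble(
    term = terms,
    kind = "controlled_vocabulary",
    freq_dev = unname(f_dev),
    freq_pop = as.integer(freq_pop),
    sens_dev = unname(f_dev) / corpus_size(dev),
    sens_pop = as.integer(freq_pop) / corpus_size(pop)
  )
  out[order(-out$freq_dev, out$term), ]
}

#' Screen terms by development-set frequency and population overrepresentation
#'
#' A term becomes a candidate when it is frequent among the known-relevant
#' references *and* rare in the database at large. The defaults implement
#' the usual screen: present in at least 20% of development-set references
#' (`sens_dev >= dev_threshold`) and a population sensitivity of 2% or less
#' (`sens_pop <= pop_threshold`). Both comparisons are inclusive.
#'
#' Terms that clear the development threshold but fail the population
#' threshold are kept as `near_miss` rather than discarded: a topically
#' essential but common word (e.g. "cancer") can still be promoted during
#' manual relevance review. Terms below the development threshold are
#' `excluded`. The three statuses partition the input.
#'
#' @param stats a term table from [term_stats()] or [cv_stats()].
#' @param dev_threshold minimum development-set sensitivity, in (0, 1).
#' @param pop_threshold maximum population-set sensitivity, in (0, 1).
#' @return the input tibble with a `status` column
#'   (`auto_pass` / `near_miss` / `excluded`).
#' @export
select_candidates <- function(stats, dev_threshold = 0.20, pop_threshold = 0.02) {
  stopifnot(is.data.frame(stats),
            all(c("term", "sens_dev", "sens_pop") %in% names(stats)))
  if (!(dev_threshold > 0 && dev_threshold < 1 &&
        pop_threshold > 0 && pop_threshold < 1)) {
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  dev_ok <- stats$sens_dev >= dev_threshold
  pop_ok <- stats$sens_pop <= pop_threshold
  stats$status <- ifelse(dev_ok & pop_ok, "auto_pass",
                         ifelse(dev_ok, "near_miss", "excluded"))
  stats
}

#' Attach topical categories to screened candidate terms
#'
#' Categorization is a relevance judgement the tool never makes on its own:
#' a user-supplied map assigns each chosen term to `health_condition`,
#' `intervention` or `questionable` (terms whose usefulness is unclear and
#' must be decided a priori, e.g. a grading score like "gleason"). Screened
#' terms absent from the map are returned with category `NA`
#' (uncategorized). Mapped terms that never passed the screen — or do not
#' occur in the corpus at all — are added with `screen_status =
#' "manual_add"`; their frequencies are computed from `dev`/`pop` when
#' those corpora are given and reported as 0 otherwise.
#'
#' @param candidates output of [select_candidates()] (text-word and/or
#'   controlled-vocabulary tables; rbind them to categorize both at once).
#' @param category_map named character vector or list, term -> category.
#' @param dev,pop optional corpora used to compute stats for `manual_add`
#'   terms.
#' @param min_length tokenizer setting used for on-demand counts.
#' @return a tibble of candidate terms with columns `term`, `kind`,
#'   `category`, `screen_status`, `freq_dev`, `freq_pop`, `sens_dev`,
#'   `sens_pop`.
#' @export
categorize_terms <- function(candidates, category_map,
                             dev = NULL, pop = NULL, min_length = 2L) {
  allowed <- c("health_condition", "intervention", "questionable")
  category_map <- unlist(category_map)
  if (length(category_map) > 0 && is.null(names(category_map))) {
    stop("category_map must be named by term", call. = FALSE)
  }
  bad <- setdiff(unique(category_map), allowed)
  if (length(bad) > 0) {
    stop("unknown category value(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
  }
  names(category_map) <- tolower(names(category_map))
  keep <- candidates$status %in% c("auto_pass", "near_miss")
  out <- candidates[keep, , drop = FALSE]
  out$category <- unname(category_map[out$term])
  out$screen_status <- out$status
  # mapped terms not among screened candidates: manual additions
  missing_terms <- setdiff(names(category_map), out$term)
  if (length(missing_terms) > 0) {
    n_dev <- if (is.null(dev)) NA_integer_ else corpus_size(dev)
    n_pop <- if (is.null(pop)) NA_integer_ else corpus_size(pop)
    fd_tw <- if (is.null(dev)) NULL else doc_frequencies(dev, min_length)
    fp_tw <- if (is.null(pop)) NULL else doc_frequencies(pop, min_length)
    fd_cv <- if (is.null(dev)) NULL else cv_frequencies(dev)
    fp_cv <- if (is.null(pop)) NULL else cv_frequencies(pop)
    lookup <- function(tabs, term) {
      for (tab in tabs) {
        if (!is.null(tab) && term %in% names(tab)) return(tab[[term]])
      }
      0L
    }
    add <- tibble::tibble(
      term = missing_terms,
      kind = vapply(missing_terms, function(tm) {
        if (!is.null(fd_cv) && tm %in% names(fd_cv)) "controlled_vocabulary"
        else "text_word"
      }, character(1), USE.NAMES = FALSE),
      freq_dev = vapply(missing_terms, function(tm) lookup(list(fd_tw, fd_cv), tm),
                        integer(1), USE.NAMES = FALSE),
      freq_pop = vapply(missing_terms, function(tm) lookup(list(fp_tw, fp_cv), tm),
                        integer(1), USE.NAMES = FALSE),
      sens_dev = NA_real_, sens_pop = NA_real_,
      status = "manual_add",
      category = unname(category_map[missing_terms]),
      screen_status = "manual_add"
    )
    if (!is.na(n_dev)) add$sens_dev <- add$freq_dev / n_dev
    if (!is.na(n_pop)) add$sens_pop <- add$freq_pop / n_pop
    add$sens_dev[is.na(add$sens_dev)] <- 0
    add$sens_pop[is.na(add$sens_pop)] <- 0
    add$freq_dev[is.na(add$freq_dev)] <- 0L
    out <- rbind(out[, names(add)], add)
  }
  cols <- c("term", "kind", "category", "screen_status",
            "freq_dev", "freq_pop", "sens_dev", "sens_pop")
  out[, cols]
}

#' Read a term -> category map from YAML
#'
#' The file maps each term to one of `health_condition`, `intervention`,
#' `questionable`, either flat (`term: category`) or grouped
#' (`category: [terms]`).
#'
#' @param path YAML file path.
#' @return a named character vector, term -> category.
#' @export
read_category_map <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("health_condition", "intervention", "questionable")
  if (all(names(raw) %in% allowed)) {           # grouped form
    out <- unlist(lapply(names(raw), function(cat) {
      stats::setNames(rep(cat, length(raw[[cat]])), unlist(raw[[cat]]))
    }))
  } else {
    out <- unlist(raw)
  }
  stats::setNames(as.character(out), tolower(names(out)))
}
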