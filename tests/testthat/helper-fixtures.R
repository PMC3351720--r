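# -- small deterministic corpora -------------------------------------------

make_corpus <- function(titles, abstracts = NULL, cv = NULL, ids = NULL,
                        label = "test") {
  n <- length(titles)
  if (is.null(abstracts)) abstracts <- rep("", n)
  if (is.null(cv)) cv <- replicate(n, character(), simplify = FALSE)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  corpus(tibble::tibble(accession = ids, title = titles, abstract = abstracts,
                        cv_terms = cv, source = "fixture"), label = label)
}

# development-set fixture with planted document frequencies shaped like the
# published worked example: patients in 25/25, prostate and cancer in 24/25,
# brachytherapy in 19/25
make_planted_dev <- function() {
  titles <- vapply(1:25, function(i) {
    toks <- c("patients",
              if (i <= 24) "prostate",
              if (i <= 24) "cancer",
              if (i <= 19) "brachytherapy",
              paste0("filler", letters[(i %% 26) + 1], letters[(i %% 5) + 1]))
    paste(toks, collapse = " ")
  }, character(1))
  make_corpus(titles, label = "development")
}

# -- independent naive strategy oracle -------------------------------------
# evaluates every record separately against each line's fully expanded
# predicate; shares no code with evaluate_strategy()

oracle_tokens <- function(text) {
  toks <- strsplit(tolower(text), "[^[:alpha:]]+")[[1]]
  toks[nchar(toks) >= 2]
}

oracle_headings <- function(cv) {
  x <- sub("^\\*", "", trimws(cv))
  tolower(trimws(sub("/.*$", "", x)))
}

oracle_record_view <- function(rec_row) {
  heads <- oracle_headings(rec_row$cv_terms[[1]])
  list(accession = rec_row$accession,
       ti = oracle_tokens(rec_row$title),
       ab = oracle_tokens(rec_row$abstract),
       kw = unlist(lapply(heads, oracle_tokens)),
       headings = heads)
}

oracle_match <- function(expr, view, strategy, fields = NULL) {
  line_expr <- function(n) {
    for (ln in strategy$lines) if (ln$line_number == n) return(ln$expression)
    stop("no line ", n)
  }
  switch(expr$type,
    cv_heading = expr$heading %in% view$headings,
    fielded_text = oracle_match(expr$expr, view, strategy, fields = expr$fields),
    term = {
      toks <- unlist(view[fields], use.names = FALSE)
      if (expr$truncated) any(startsWith(toks, expr$token))
      else expr$token %in% toks
    },
    and = all(vapply(expr$children, oracle_match, logical(1), view, strategy, fields)),
    or = any(vapply(expr$children, oracle_match, logical(1), view, strategy, fields)),
    line_ref = oracle_match(line_expr(expr$n), view, strategy),
    line_range_or = any(vapply(seq(expr$from, expr$to), function(n)
      oracle_match(line_expr(n), view, strategy), logical(1))),
    line_list_and = all(vapply(expr$lines, function(n)
      oracle_match(line_expr(n), view, strategy), logical(1))),
    accession_list = view$accession %in% expr$ids,
    stop("oracle: unknown node ", expr$type))
}

oracle_evaluate <- function(strategy, corpus) {
  views <- lapply(seq_len(corpus_size(corpus)),
                  function(i) oracle_record_view(corpus$records[i, ]))
  out <- list()
  for (ln in strategy$lines) {
    hit <- vapply(views, function(v) oracle_match(ln$expression, v, strategy),
                  logical(1))
    out[[as.character(ln$line_number)]] <- accessions(corpus)[hit]
  }
  out
}

# -- random corpora and strategies for property tests ----------------------

rand_vocab <- c("prostate", "cancer", "brachytherapy", "seed", "implant",
                "radical", "therapy", "beam", "external", "gleason",
                "antigen", "survival", "outcome", "dose", "toxicity",
                "followup", "biopsy", "grade", "risk", "margin")

rand_headings <- c("Prostatic Neoplasms", "Brachytherapy", "Humans",
                   "Radiotherapy Dosage", "Treatment Outcome")

rand_corpus <- function(n) {
  titles <- vapply(seq_len(n), function(i)
    paste(sample(rand_vocab, sample(2:6, 1), replace = TRUE), collapse = " "),
    character(1))
  abstracts <- vapply(seq_len(n), function(i)
    paste(sample(rand_vocab, sample(0:12, 1), replace = TRUE), collapse = " "),
    character(1))
  cv <- lapply(seq_len(n), function(i) {
    k <- sample(0:3, 1)
    if (k == 0) return(character())
    h <- sample(rand_headings, k)
    ifelse(runif(k) < 0.5, paste0(h, "/", sample(c("methods", "surgery"), k,
                                                 replace = TRUE)), h)
  })
  make_corpus(titles, abstracts, cv, ids = sprintf("r%03d", seq_len(n)))
}

rand_bool_text <- function(depth = 2) {
  tok <- function() {
    t <- sample(rand_vocab, 1)
    if (runif(1) < 0.3) paste0(substr(t, 1, max(2, nchar(t) - 3)), "*") else t
  }
  if (depth == 0 || runif(1) < 0.4) return(tok())
  op <- sample(c(" and ", " or "), 1)
  sprintf("(%s%s%s)", rand_bool_text(depth - 1), op, rand_bool_text(depth - 1))
}

rand_strategy_text <- function(corpus, n_lines) {
  lines <- character(n_lines)
  for (i in seq_len(n_lines)) {
    kind <- if (i == 1) sample(c("text", "cv", "ui"), 1)
            else sample(c("text", "cv", "ui", "or_range", "and_list", "bare"), 1)
    lines[i] <- switch(kind,
      text = {
        fields <- sample(list("ab,ti", "ti", "ab", "ti,ab,kw"), 1)[[1]]
        sprintf("%d %s.%s.", i, rand_bool_text(sample(0:2, 1)), fields)
      },
      cv = sprintf("%d %s/", i, sample(rand_headings, 1)),
      ui = sprintf("%d (%s).ui.", i,
                   paste(sprintf('"%s"', sample(accessions(corpus),
                                                min(3, corpus_size(corpus)))),
                         collapse = " or ")),
      or_range = {
        a <- sample(seq_len(i - 1), 1)
        sprintf("%d or/%d-%d", i, a, i - 1)
      },
      and_list = {
        ns <- sort(sample(seq_len(i - 1), min(2, i - 1)))
        sprintf("%d and/%s", i, paste(unique(ns), collapse = ","))
      },
      bare = {
        ns <- sample(seq_len(i - 1), min(2, i - 1), replace = TRUE)
        sprintf("%d %s", i, paste(unique(ns), collapse = " and "))
      })
  }
  lines
}
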