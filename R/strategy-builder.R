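#' Assemble the candidate terms of one category into a strategy block
#'
#' A block is the standard Ovid pattern: one line per controlled-vocabulary
#' candidate (`Heading/`), one fielded text line per text-word candidate
#' (over `.ab,ti.`), closed by an OR line unioning the block and annotated
#' with the category name. A text candidate can carry a `query` entry with
#' a ready-made Boolean pattern including truncation (e.g.
#' `"prostat* and (cancer or adenocarcinoma)"`); otherwise the bare term is
#' used.
#'
#' @param candidates a data frame of candidate terms of a single category,
#'   with columns `term`, `kind` and optionally `query`.
#' @param start_line number of the block's first line.
#' @param annotation label for the closing OR line (e.g. `"Health
#'   condition"`); `NULL` for none.
#' @return character vector of strategy lines in the Table-style dialect,
#'   ending with the closing OR line.
#' @export
assemble_block <- function(candidates, start_line = 1L, annotation = NULL) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) == 0) stop("cannot assemble a block from zero candidates",
                                  call. = FALSE)
  exprs <- vapply(seq_len(nrow(candidates)), function(i) {
    if (isTRUE(unname(candidates$kind[i]) == "controlled_vocabulary")) {
      paste0(candidates$term[i], "/")
    } else {
      q <- if ("query" %in% names(candidates) && !is.na(candidates$query[i]) &&
               nzchar(candidates$query[i])) candidates$query[i] else candidates$term[i]
      if (grepl("\\s", q)) sprintf("(%s).ab,ti.", q) else sprintf("%s.ab,ti.", q)
    }
  }, character(1))
  n <- length(exprs)
  lines <- sprintf("%d %s", seq(start_line, length.out = n), exprs)
  or_line <- sprintf("%d or/%d-%d", start_line + n, start_line, start_line + n - 1L)
  if (!is.null(annotation)) or_line <- sprintf("%s [%s]", or_line, annotation)
  c(lines, or_line)
}

#' Build a search strategy reaching full development-set recall
#'
#' Assembles the health-condition and intervention candidate blocks, ANDs
#' them, and evaluates the result on the development set. Every
#' health-condition and intervention candidate enters its block
#' unconditionally — the aim is a highly sensitive strategy, not a minimal
#' one. If development-set sensitivity falls short of 1.0, questionable
#' terms are added one at a time by greedy coverage: the term whose match
#' set covers the most still-uncovered records wins (ties broken by higher
#' development-set sensitivity, then alphabetically), is appended to the
#' block named by its `block_hint` (default `"intervention"`), and the
#' strategy is re-evaluated; the loop stops when the development set is
#' covered or no remaining questionable term covers a new record.
#' Non-coverage is a reported outcome, not an error.
#'
#' @param candidates a categorized candidate table from
#'   [categorize_terms()] (columns `term`, `kind`, `category`; optional
#'   `query` patterns and `block_hint` for questionable terms). Rows with
#'   `category` `NA` are ignored.
#' @param dev the development-set [corpus].
#' @param minimize if `TRUE`, after reaching full coverage, greedily drop
#'   block members whose removal leaves development-set coverage intact
#'   (precision tuning); candidates are considered in increasing
#'   development-set frequency order.
#' @param min_length tokenizer setting.
#' @return a `build_result`: list with `strategy` (parsed), `dev_sensitivity`,
#'   `used_questionable`, `uncovered` (accessions), `precision_dev` and
#'   `log` (per-step build log).
#' @export
build_strategy <- function(candidates, dev, minimize = FALSE, min_length = 2L) {
  stopifnot(is.data.frame(candidates), inherits(dev, "corpus"))
  cand <- candidates[!is.na(candidates$category), , drop = FALSE]
  hc <- cand[cand$category == "health_condition", , drop = FALSE]
  iv <- cand[cand$category == "intervention", , drop = FALSE]
  qs <- cand[cand$category == "questionable", , drop = FALSE]
  if (nrow(hc) == 0 || nrow(iv) == 0) {
    stop("need at least one health_condition and one intervention candidate",
         call. = FALSE)
  }
  dev_ids <- accessions(dev)
  log <- list()

  assemble_and_eval <- function(hc, iv) {
    strat <- compose_strategy(hc, iv)
    res <- evaluate_strategy(strat, dev, min_length)
    hits <- retrieved(res)
    list(strategy = strat, result = res, hits = hits,
         uncovered = setdiff(dev_ids, hits))
  }
  state <- assemble_and_eval(hc, iv)
  log[[length(log) + 1L]] <- list(step = "initial",
                                  covered = length(dev_ids) - length(state$uncovered),
                                  uncovered = length(state$uncovered))
  used_q <- character()
  if (length(state$uncovered) > 0 && nrow(qs) > 0) {
    # match set of each questionable term on the dev set, computed once
    q_hits <- lapply(seq_len(nrow(qs)), function(i)
      candidate_matches(qs[i, ], dev, min_length))
    names(q_hits) <- qs$term
    remaining <- seq_len(nrow(qs))
    while (length(state$uncovered) > 0 && length(remaining) > 0) {
      gain <- vapply(remaining, function(i)
        length(intersect(q_hits[[i]], state$uncovered)), integer(1))
      if (max(gain) == 0) break
      sens <- if ("sens_dev" %in% names(qs)) qs$sens_dev[remaining] else rep(0, length(remaining))
      ord <- order(-gain, -sens, qs$term[remaining])
      pick <- remaining[ord[1]]
      hint <- if ("block_hint" %in% names(qs) && !is.na(qs$block_hint[pick]) &&
                  nzchar(qs$block_hint[pick])) qs$block_hint[pick] else "intervention"
      if (hint == "health_condition") hc <- rbind_candidates(hc, qs[pick, ])
      else iv <- rbind_candidates(iv, qs[pick, ])
      used_q <- c(used_q, qs$term[pick])
      remaining <- setdiff(remaining, pick)
      state <- assemble_and_eval(hc, iv)
      log[[length(log) + 1L]] <- list(step = paste0("add_questionable:", qs$term[pick]),
                                      block = hint,
                                      covered = length(dev_ids) - length(state$uncovered),
                                      uncovered = length(state$uncovered))
    }
  }
  if (minimize && length(state$uncovered) == 0) {
    trimmed <- minimize_blocks(hc, iv, dev, dev_ids, min_length)
    hc <- trimmed$hc; iv <- trimmed$iv
    state <- assemble_and_eval(hc, iv)
    log[[length(log) + 1L]] <- list(step = "minimize",
                                    kept = nrow(hc) + nrow(iv),
                                    covered = length(dev_ids) - length(state$uncovered))
  }
  sens <- length(intersect(state$hits, dev_ids)) / length(dev_ids)
  prec <- if (length(state$hits) > 0)
    length(intersect(state$hits, dev_ids)) / length(state$hits) else NA_real_
  structure(list(strategy = state$strategy,
                 dev_sensitivity = sens,
                 used_questionable = used_q,
                 uncovered = state$uncovered,
                 precision_dev = prec,
                 result = state$result,
                 log = log),
            class = "build_result")
}

# health-condition block, intervention block, and/<or-lines> closing line
compose_strategy <- function(hc, iv) {
  hc_lines <- assemble_block(hc, start_line = 1L, annotation = "Health condition")
  hc_or <- nrow(hc) + 1L
  iv_lines <- assemble_block(iv, start_line = hc_or + 1L, annotation = "Intervention")
  iv_or <- hc_or + nrow(iv) + 1L
  and_line <- sprintf("%d and/%d,%d", iv_or + 1L, hc_or, iv_or)
  parse_strategy(c(hc_lines, iv_lines, and_line))
}

# dev-set match set of a single candidate rendered as a one-line strategy
candidate_matches <- function(cand_row, corpus, min_length = 2L) {
  block <- assemble_block(cand_row, start_line = 1L)
  strat <- parse_strategy(block)
  retrieved(evaluate_strategy(strat, corpus, min_length))
}

rbind_candidates <- function(a, b) {
  cols <- union(names(a), names(b))
  for (cn in setdiff(cols, names(a))) a[[cn]] <- NA
  for (cn in setdiff(cols, names(b))) b[[cn]] <- NA
  rbind(a[, cols], b[, cols])
}

# drop block members (least dev-frequent first) whose removal keeps coverage
minimize_blocks <- function(hc, iv, dev, dev_ids, min_length) {
  covered_with <- function(hc, iv) {
    strat <- compose_strategy(hc, iv)
    hits <- retrieved(evaluate_strategy(strat, dev, min_length))
    length(setdiff(dev_ids, hits)) == 0
  }
  for (block in c("hc", "iv")) {
    repeat {
      tab <- if (block == "hc") hc else iv
      if (nrow(tab) <= 1) break
      ord <- if ("freq_dev" %in% names(tab)) order(tab$freq_dev, tab$term)
             else seq_len(nrow(tab))
      dropped <- FALSE
      for (i in ord) {
        slim <- tab[-i, , drop = FALSE]
        ok <- if (block == "hc") covered_with(slim, iv) else covered_with(hc, slim)
        if (ok) {
          if (block == "hc") hc <- slim else iv <- slim
          dropped <- TRUE
          break
        }
      }
      if (!dropped) break
    }
  }
  list(hc = hc, iv = iv)
}

#' Sensitivity of a strategy for a reference set
#'
#' The fraction of a known-relevant reference set retrieved by the
#' strategy's final line when run over `corpus`.
#'
#' @param strategy a `search_strategy`.
#' @param corpus the [corpus] to run against.
#' @param reference_ids accessions of the known-relevant references
#'   (must be a subset of the corpus accessions; non-empty).
#' @param line strategy line whose result to score; defaults to the last.
#' @param min_length tokenizer setting.
#' @return sensitivity in `[0, 1]`.
#' @export
strategy_sensitivity <- function(strategy, corpus, reference_ids, line = NULL,
                                 min_length = 2L) {
  if (length(reference_ids) == 0) stop("reference_ids must be non-empty",
                                       call. = FALSE)
  missing_ids <- setdiff(reference_ids, accessions(corpus))
  if (length(missing_ids) > 0) {
    stop("reference id(s) not in corpus: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  hits <- retrieved(evaluate_strategy(strategy, corpus, min_length), line)
  length(intersect(hits, reference_ids)) / length(reference_ids)
}

#' Precision of a strategy for a reference set
#'
#' The fraction of retrieved records that belong to the reference set;
#' reported for information — no threshold is applied. The reciprocal is
#' the number needed to read (NNR).
#'
#' @inheritParams strategy_sensitivity
#' @return precision in `[0, 1]`, or `NA` if nothing was retrieved.
#' @export
strategy_precision <- function(strategy, corpus, reference_ids, line = NULL,
                               min_length = 2L) {
  hits <- retrieved(evaluate_strategy(strategy, corpus, min_length), line)
  if (length(hits) == 0) return(NA_real_)
  length(intersect(hits, reference_ids)) / length(hits)
}

#' @export
print.build_result <- function(x, ...) {
  cat("<build_result>\n")
  cat(sprintf("  dev sensitivity: %.4f\n", x$dev_sensitivity))
  cat(sprintf("  questionable terms used: %s\n",
              if (length(x$used_questionable) == 0) "none"
              else paste(x$used_questionable, collapse = ", ")))
  if (length(x$uncovered) > 0) {
    cat(sprintf("  uncovered records: %s\n", paste(x$uncovered, collapse = ", ")))
  }
  cat("  strategy:\n")
  cat(paste0("    ", strsplit(format_strategy(x$strategy), "\n")[[1]],
             collapse = "\n"), "\n")
  invisible(x)
}
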