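#' Read and write MEDLINE flat-file (.nbib) record collections
#'
#' `read_medline()` parses the flat-file dialect exported by PubMed
#' ("PubMed format"): records are blocks of `TAG - value` lines with
#' four-character tag fields, continuation lines indented with spaces, and
#' blocks separated by blank lines. Only the fields the analysis needs are
#' kept: `PMID` (accession), `TI` (title), `AB` (abstract) and `MH` (one
#' controlled-vocabulary term per line, verbatim, including any `*`
#' major-topic marker and `/subheading` qualifiers). Wrapped `TI`/`AB`
#' values are joined with single spaces.
#'
#' Input is decoded as UTF-8 with a Latin-1 fallback; no case folding or
#' other normalization happens at I/O time.
#'
#' @param path path to a `.nbib` / PubMed-format file.
#' @param label corpus label.
#' @param source tag recorded in each record's `source` field.
#' @return a [corpus].
#' @seealso [read_ris()], [write_medline()]
#' @export
read_medline <- function(path, label = "corpus", source = "medline") {
  lines <- read_text_lines(path)
  # split into blocks on blank lines
  blank <- !nzchar(trimws(lines))
  block_id <- cumsum(c(TRUE, blank[-length(blank)] & !blank[-1]))
  if (length(lines) == 0) return(corpus(label = label))
  tag_re <- "^([A-Z0-9]{1,4})\\s{0,3}- (.*)$"
  recs <- list()
  cur <- NULL           # list(pmid, ti, ab, mh, start_line)
  cur_tag <- ""
  flush_record <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur$pmid)) {
      stop(sprintf("MEDLINE block starting at line %d has no PMID", cur$start_line),
           call. = FALSE)
    }
    list(accession = cur$pmid,
         title = paste(cur$ti, collapse = " "),
         abstract = paste(cur$ab, collapse = " "),
         cv_terms = cur$mh)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) {              # blank: end of block
      r <- flush_record(cur)
      if (!is.null(r)) recs[[length(recs) + 1L]] <- r
      cur <- NULL; cur_tag <- ""
      next
    }
    m <- regmatches(ln, regexec(tag_re, ln))[[1]]
    if (length(m) == 3) {
      tag <- m[2]; val <- m[3]
      if (tag == "PMID" && !is.null(cur) && !is.null(cur$pmid)) {
        # new record without a blank separator
        r <- flush_record(cur)
        recs[[length(recs) + 1L]] <- r
        cur <- NULL
      }
      if (is.null(cur)) cur <- list(pmid = NULL, ti = character(),
                                    ab = character(), mh = character(),
                                    start_line = i)
      cur_tag <- tag
      if (tag == "PMID") cur$pmid <- trimws(val)
      else if (tag == "TI") cur$ti <- c(cur$ti, val)
      else if (tag == "AB") cur$ab <- c(cur$ab, val)
      else if (tag == "MH") cur$mh <- c(cur$mh, trimws(val))
    } else if (grepl("^\\s+\\S", ln)) {     # continuation of previous field
      if (is.null(cur)) {
        stop(sprintf("continuation line %d outside any record", i), call. = FALSE)
      }
      val <- trimws(ln)
      if (cur_tag == "TI") cur$ti <- c(cur$ti, val)
      else if (cur_tag == "AB") cur$ab <- c(cur$ab, val)
      else if (cur_tag == "MH") {
        n <- length(cur$mh)
        cur$mh[n] <- paste(cur$mh[n], val)
      }
    } else {
      stop(sprintf("malformed MEDLINE line %d: %s", i, ln), call. = FALSE)
    }
  }
  r <- flush_record(cur)
  if (!is.null(r)) recs[[length(recs) + 1L]] <- r
  if (length(recs) == 0) return(corpus(label = label))
  acc <- vapply(recs, `[[`, character(1), "accession")
  dup <- unique(acc[duplicated(acc)])
  if (length(dup) > 0) {
    stop("duplicate PMID(s) in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  corpus(tibble::tibble(
    accession = acc,
    title = vapply(recs, `[[`, character(1), "title"),
    abstract = vapply(recs, `[[`, character(1), "abstract"),
    cv_terms = lapply(recs, `[[`, "cv_terms"),
    source = source
  ), label = label)
}

#' @rdname read_medline
#' @param x a [corpus] to serialize.
#' @param width wrap column for `TI`/`AB` values (continuations indented
#'   six spaces, as PubMed exports them).
#' @export
write_medline <- function(x, path, width = 80L) {
  stopifnot(inherits(x, "corpus"))
  out <- character()
  wrap_field <- function(tag, value) {
    if (!nzchar(value)) return(character())
    head <- sprintf("%-4s- ", tag)
    wrapped <- strwrap(value, width = width, initial = head,
                       prefix = "      ")
    wrapped
  }
  for (i in seq_len(corpus_size(x))) {
    rec <- x$records[i, ]
    out <- c(out,
             sprintf("PMID- %s", rec$accession),
             wrap_field("TI", rec$title),
             wrap_field("AB", rec$abstract),
             if (length(rec$cv_terms[[1]]) > 0)
               sprintf("MH  - %s", rec$cv_terms[[1]]),
             "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

# Decode as UTF-8, falling back to Latin-1 for lines that fail validation.
read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw_lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  bad <- !validUTF8(raw_lines)
  if (any(bad)) {
    raw_lines[bad] <- iconv(raw_lines[bad], from = "latin1", to = "UTF-8")
  }
  raw_lines
}
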