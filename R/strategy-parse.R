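#' Parse an Ovid-style numbered search strategy
#'
#' Reads a multi-line search strategy in the numbered-line dialect used by
#' Ovid MEDLINE, one line per physical line:
#'
#' ```
#' 1 Prostatic Neoplasms/
#' 2 (prostat* and (cancer or adenocarcinoma)).ab,ti.
#' 3 or/1-2 [Health condition]
#' 4 ("18374503" or "11104883").ui. [development set]
#' 5 3 and 4
#' ```
#'
#' Supported constructs: controlled-vocabulary headings (`Heading/`,
#' non-exploded), fielded text expressions with Boolean operators and
#' trailing truncation (`*`), Ovid field suffixes (`.ab,ti.`) and the
#' Cochrane dialect (`:ti,ab,kw`) — both parse to the same node — set
#' combination lines (`or/1-2`, `and/3,7`), bare Boolean combinations of
#' line numbers (`8 and 9`), accession-number lists (`.ui.`) and bracketed
#' line annotations (`[Health condition]`). `NOT`, adjacency operators and
#' explosion (`exp`) are deliberately unsupported and raise a parse error.
#'
#' Line numbers must increase strictly from 1 and a line may only refer to
#' earlier lines.
#'
#' @param text the strategy, either a single string with embedded newlines
#'   or a character vector of lines. Blank lines are ignored.
#' @return a `search_strategy` object: a list of lines, each with
#'   `line_number`, `expression` (AST) and `annotation`.
#' @seealso [format_strategy()], [evaluate_strategy()]
#' @export
parse_strategy <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty strategy", call. = FALSE)
  parsed <- vector("list", length(lines))
  seen <- integer()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^(#?)(\\d+)[.)]?\\s+(.*)$", lines[i]))[[1]]
    if (length(m) != 4) {
      stop(sprintf("line %d: expected '<number> <expression>', got: %s",
                   i, lines[i]), call. = FALSE)
    }
    n <- as.integer(m[3])
    expected <- if (length(seen) == 0) 1L else seen[length(seen)] + 1L
    if (n != expected) {
      stop(sprintf("line numbers must increase strictly from 1; got %d where %d expected",
                   n, expected), call. = FALSE)
    }
    rest <- m[4]
    ann <- NA_character_
    am <- regmatches(rest, regexec("^(.*?)\\s*\\[([^][]*)\\]\\s*$", rest))[[1]]
    if (length(am) == 3) {
      rest <- am[2]
      ann <- am[3]
    }
    expr <- tryCatch(parse_line_expression(rest, n),
                     error = function(e) {
                       stop(sprintf("line %d: %s", n, conditionMessage(e)),
                            call. = FALSE)
                     })
    check_line_refs(expr, n)
    parsed[[i]] <- list(line_number = n, expression = expr, annotation = ann)
    seen <- c(seen, n)
  }
  structure(list(lines = parsed), class = "search_strategy")
}

# ---- AST node constructors -------------------------------------------------

node <- function(type, ...) structure(list(type = type, ...), class = "query_node")

cv_heading_node <- function(heading) node("cv_heading", heading = tolower(trimws(heading)))
fielded_text_node <- function(expr, fields) node("fielded_text", expr = expr,
                                                 fields = fields)
term_node <- function(token, truncated = FALSE) node("term", token = tolower(token),
                                                     truncated = truncated)
bool_node <- function(op, children) node(op, children = children)   # "and" / "or"
line_ref_node <- function(n) node("line_ref", n = as.integer(n))
line_range_or_node <- function(a, b) node("line_range_or", from = as.integer(a),
                                          to = as.integer(b))
line_list_and_node <- function(ns) node("line_list_and", lines = as.integer(ns))
accession_list_node <- function(ids) node("accession_list", ids = as.character(ids))

VALID_FIELDS <- c("ti", "ab", "kw")

# ---- line-level dispatch ---------------------------------------------------

parse_line_expression <- function(s, line_number) {
  s <- trimws(s)
  if (!nzchar(s)) stop("empty expression")
  # set-combination form: or/1-2, and/3,7
  m <- regmatches(s, regexec("^(or|and)/([0-9,\\s-]+)$", s, ignore.case = TRUE))[[1]]
  if (length(m) == 3) {
    op <- tolower(m[2])
    spec <- gsub("\\s", "", m[3])
    if (grepl("^\\d+-\\d+$", spec)) {
      ab <- as.integer(strsplit(spec, "-", fixed = TRUE)[[1]])
      if (ab[1] > ab[2]) stop(sprintf("bad line range %s", spec))
      if (op == "or") return(line_range_or_node(ab[1], ab[2]))
      return(line_list_and_node(seq(ab[1], ab[2])))
    }
    if (grepl("^\\d+(,\\d+)*$", spec)) {
      ns <- as.integer(strsplit(spec, ",", fixed = TRUE)[[1]])
      if (op == "and") return(line_list_and_node(ns))
      return(bool_node("or", lapply(ns, line_ref_node)))
    }
    stop(sprintf("cannot parse line combination '%s'", s))
  }
  # accession list: (...)".ui."
  if (grepl("\\.ui\\.$", s, ignore.case = TRUE)) {
    inner <- sub("\\.ui\\.$", "", s, ignore.case = TRUE)
    ids <- regmatches(inner, gregexpr('"([^"]+)"', inner))[[1]]
    ids <- gsub('"', "", ids)
    if (length(ids) == 0) stop("accession list (.ui.) without quoted identifiers")
    leftover <- gsub('"[^"]+"', "", inner)
    leftover <- gsub("[()[:space:]]", "", gsub("\\bor\\b", "", leftover, ignore.case = TRUE))
    if (nzchar(leftover)) {
      stop("accession list (.ui.) supports only quoted identifiers joined by 'or'")
    }
    return(accession_list_node(ids))
  }
  # Ovid field suffix: expr.ab,ti.
  m <- regmatches(s, regexec("^(.*)\\.([a-z]{2}(?:,[a-z]{2})*)\\.$", s,
                             ignore.case = TRUE, perl = TRUE))[[1]]
  if (length(m) == 3) {
    return(parse_fielded(m[2], m[3]))
  }
  # Cochrane field suffix: expr:ti,ab,kw
  m <- regmatches(s, regexec("^(.*):([a-z]{2}(?:,[a-z]{2})*)$", s,
                             ignore.case = TRUE, perl = TRUE))[[1]]
  if (length(m) == 3) {
    return(parse_fielded(m[2], m[3]))
  }
  # controlled-vocabulary heading: Heading/
  if (grepl("/$", s)) {
    heading <- sub("/$", "", s)
    if (grepl("^exp\\s", heading, ignore.case = TRUE)) {
      stop("explosion ('exp') is not supported")
    }
    if (grepl("[()]", heading) || grepl("\\b(and|or|not)\\b", heading,
                                        ignore.case = TRUE)) {
      stop(sprintf("cannot parse heading '%s'", s))
    }
    return(cv_heading_node(heading))
  }
  # bare Boolean combination of line numbers: "8 and 9"
  expr <- parse_bool_expr(s, atom = "line_ref")
  expr
}

parse_fielded <- function(body, fields_str) {
  fields <- tolower(strsplit(fields_str, ",", fixed = TRUE)[[1]])
  bad <- setdiff(fields, VALID_FIELDS)
  if (length(bad) > 0) {
    stop(sprintf("unknown field tag(s): %s (supported: %s)",
                 paste(bad, collapse = ", "),
                 paste(VALID_FIELDS, collapse = ", ")))
  }
  expr <- parse_bool_expr(body, atom = "term")
  fielded_text_node(expr, fields)
}

# ---- Boolean expression parser (recursive descent, AND binds tighter) ------

tokenize_query <- function(s) {
  pat <- "\\(|\\)|\"[^\"]*\"|[^()\"[:space:]]+"
  toks <- regmatches(s, gregexpr(pat, s))[[1]]
  toks
}

parse_bool_expr <- function(s, atom = c("term", "line_ref")) {
  atom <- match.arg(atom)
  toks <- tokenize_query(s)
  if (length(toks) == 0) stop("empty expression")
  lower <- tolower(toks)
  if (any(lower == "not")) stop("operator NOT is not supported")
  adj <- grep("^adj[0-9]*$", lower, value = TRUE)
  if (length(adj) > 0) {
    stop(sprintf("adjacency operator '%s' is not supported", adj[1]))
  }
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_or <- function() {
    left <- parse_and()
    children <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      children[[length(children) + 1L]] <- parse_and()
    }
    if (length(children) == 1) children[[1]] else bool_node("or", children)
  }
  parse_and <- function() {
    left <- parse_atom()
    children <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      children[[length(children) + 1L]] <- parse_atom()
    }
    if (length(children) == 1) children[[1]] else bool_node("and", children)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of expression")
    if (t == "(") {
      advance()
      e <- parse_or()
      if (is.na(peek()) || peek() != ")") stop("unbalanced parentheses")
      advance()
      return(e)
    }
    if (t == ")") stop("unbalanced parentheses")
    lt <- tolower(t)
    if (lt %in% c("and", "or")) stop(sprintf("operator '%s' without operand", t))
    if (lt == "not") stop("operator NOT is not supported")
    if (grepl("^adj[0-9]*$", lt)) stop(sprintf("adjacency operator '%s' is not supported", t))
    advance()
    t <- gsub('"', "", t)
    if (atom == "line_ref") {
      if (!grepl("^\\d+$", t)) {
        stop(sprintf("expected a line number, got '%s' (text terms need a field tag such as .ab,ti.)", t))
      }
      return(line_ref_node(t))
    }
    truncated <- grepl("\\*$", t)
    tok <- sub("\\*+$", "", t)
    if (grepl("\\*", tok)) stop(sprintf("mid-word wildcard in '%s' is not supported", t))
    if (!nzchar(tok)) stop("empty search term")
    term_node(tok, truncated)
  }
  out <- parse_or()
  if (!is.na(peek())) {
    stop(sprintf("trailing content after expression: '%s'", peek()))
  }
  out
}

# every line_ref/range/list must point strictly before the current line
check_line_refs <- function(expr, line_number) {
  refs <- collect_line_refs(expr)
  bad <- refs[refs >= line_number]
  if (length(bad) > 0) {
    stop(sprintf("line %d refers to line(s) %s, which are not earlier lines",
                 line_number, paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  if (any(refs < 1)) stop(sprintf("line %d refers to line 0", line_number),
                          call. = FALSE)
  invisible(TRUE)
}

collect_line_refs <- function(expr) {
  switch(expr$type,
    line_ref = expr$n,
    line_range_or = seq(expr$from, expr$to),
    line_list_and = expr$lines,
    and = ,
    or = unlist(lapply(expr$children, collect_line_refs)),
    integer())
}

# ---- serialization ---------------------------------------------------------

#' Render a strategy back to its text dialect
#'
#' `format_strategy(parse_strategy(s))` reparses to a structurally
#' identical strategy (round-trip property); annotations are preserved.
#'
#' @param strategy a `search_strategy`.
#' @return a single string, one numbered line per strategy line.
#' @export
format_strategy <- function(strategy) {
  stopifnot(inherits(strategy, "search_strategy"))
  lines <- vapply(strategy$lines, function(ln) {
    txt <- format_query_node(ln$expression, top = TRUE)
    if (!is.na(ln$annotation)) txt <- sprintf("%s [%s]", txt, ln$annotation)
    sprintf("%d %s", ln$line_number, txt)
  }, character(1))
  paste(lines, collapse = "\n")
}

format_query_node <- function(x, top = FALSE) {
  switch(x$type,
    cv_heading = paste0(x$heading, "/"),
    fielded_text = sprintf("%s.%s.", format_bool(x$expr, parens = needs_parens(x$expr)),
                           paste(x$fields, collapse = ",")),
    accession_list = sprintf("(%s).ui.", paste(sprintf('"%s"', x$ids),
                                               collapse = " or ")),
    line_range_or = sprintf("or/%d-%d", x$from, x$to),
    line_list_and = sprintf("and/%s", paste(x$lines, collapse = ",")),
    line_ref = as.character(x$n),
    term = format_bool(x, parens = FALSE),
    and = ,
    or = format_bool(x, parens = FALSE),
    stop("unknown node type: ", x$type))
}

needs_parens <- function(x) x$type %in% c("and", "or")

format_bool <- function(x, parens = FALSE) {
  out <- switch(x$type,
    term = paste0(x$token, if (x$truncated) "*"),
    line_ref = as.character(x$n),
    and = paste(vapply(x$children, format_bool_child, character(1), parent = "and"),
                collapse = " and "),
    or = paste(vapply(x$children, format_bool_child, character(1), parent = "or"),
               collapse = " or "),
    stop("unexpected node in Boolean expression: ", x$type))
  if (parens) paste0("(", out, ")") else out
}

# nested Boolean children always get parentheses so the nesting structure
# survives a reparse (an unparenthesized same-operator child would flatten)
format_bool_child <- function(x, parent) {
  format_bool(x, parens = x$type %in% c("and", "or"))
}

#' @export
print.search_strategy <- function(x, ...) {
  cat("<search_strategy:", length(x$lines), "lines>\n")
  cat(format_strategy(x), "\n")
  invisible(x)
}

#' Number of lines in a strategy
#' @param strategy a `search_strategy`.
#' @return integer line count.
#' @export
strategy_length <- function(strategy) {
  stopifnot(inherits(strategy, "search_strategy"))
  length(strategy$lines)
}
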