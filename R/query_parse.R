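#' Parse a bracket-filter boolean query
#'
#' Grammar (keywords case-insensitive):
#' ```
#' or_expr  := and_expr ("or" and_expr)*
#' and_expr := unary ("and" unary)*
#' unary    := "not" unary | "(" or_expr ")" | term
#' term     := SUBJECT ("[" KEY OP VALUE "]")*
#' ```
#' `not` binds tighter than `and`, `and` tighter than `or`. The SUBJECT is a
#' gene id / TF symbol, the keyword `all_expression` (every experiment with
#' `EXPERIMENT_TYPE=Expression`) or `all` (every experiment). Filters compare
#' experiment metadata keys (e.g. `TECHNOLOGY/METHOD`) or edge attributes
#' (`log2fc`, `pvalue`, `EDGE_TYPE`) with one of `=`, `!=`, `<`, `>`, `<=`,
#' `>=`; values containing spaces or colons may be double-quoted, e.g.
#' `AT2G46680[EDGE_TYPE="in planta:Bound"]`.
#'
#' @param text query string.
#' @return A `query_ast`: nested list of nodes with `op` in
#'   `"or"`, `"and"`, `"not"`, `"term"`.
#' @examples
#' parse_query('TF1[EXPERIMENT_TYPE=Expression] and not TF1[TECHNOLOGY/METHOD=ChIPseq]')
#' @export
parse_query <- function(text) {
  if (!.is_string(text) || !nzchar(trimws(text)))
    .stopf("empty query")
  toks <- .tokenize_query(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  ast <- .parse_or(st)
  if (st$pos <= length(st$toks))
    .stopf("syntax error at position %d: unexpected '%s'",
           st$toks[[st$pos]]$at, st$toks[[st$pos]]$text)
  class(ast) <- c("query_ast", "list")
  ast
}

# tokenizer: parens, brackets, operators, quoted strings, bare words
.tokenize_query <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, val, at) {
    toks[[length(toks) + 1L]] <<- list(type = type, text = val, at = at)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")", "[", "]")) {
      push(ch, ch, i); i <- i + 1L; next
    }
    two <- substr(text, i, i + 1L)
    if (two %in% c("!=", "<=", ">=")) { push("op", two, i); i <- i + 2L; next }
    if (ch %in% c("=", "<", ">")) { push("op", ch, i); i <- i + 1L; next }
    if (ch == '"') {
      j <- i + 1L
      while (j <= n && substr(text, j, j) != '"') j <- j + 1L
      if (j > n) .stopf("syntax error at position %d: unterminated quote", i)
      push("quoted", substr(text, i + 1L, j - 1L), i)
      i <- j + 1L; next
    }
    m <- regmatches(substr(text, i, n),
                    regexpr("^[^][()=<>!\"[:space:]]+", substr(text, i, n)))
    if (!length(m))
      .stopf("syntax error at position %d: unexpected character '%s'", i, ch)
    word <- m[[1]]
    lw <- tolower(word)
    if (lw %in% c("and", "or", "not")) push(lw, word, i)
    else push("word", word, i)
    i <- i + nchar(word)
  }
  toks
}

.peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL
.advance <- function(st) { tok <- .peek(st); st$pos <- st$pos + 1L; tok }
.expect <- function(st, type) {
  tok <- .peek(st)
  if (is.null(tok) || tok$type != type)
    .stopf("syntax error at position %s: expected '%s'",
           if (is.null(tok)) "end of query" else tok$at, type)
  .advance(st)
}

.parse_or <- function(st) {
  children <- list(.parse_and(st))
  while (!is.null(tok <- .peek(st)) && tok$type == "or") {
    .advance(st)
    children <- c(children, list(.parse_and(st)))
  }
  if (length(children) == 1L) children[[1]]
  else list(op = "or", children = children)
}

.parse_and <- function(st) {
  children <- list(.parse_unary(st))
  while (!is.null(tok <- .peek(st)) && tok$type == "and") {
    .advance(st)
    children <- c(children, list(.parse_unary(st)))
  }
  if (length(children) == 1L) children[[1]]
  else list(op = "and", children = children)
}

.parse_unary <- function(st) {
  tok <- .peek(st)
  if (is.null(tok)) .stopf("syntax error: unexpected end of query")
  if (tok$type == "not") {
    .advance(st)
    return(list(op = "not", child = .parse_unary(st)))
  }
  if (tok$type == "(") {
    .advance(st)
    inner <- .parse_or(st)
    .expect(st, ")")
    return(inner)
  }
  .parse_term(st)
}

.parse_term <- function(st) {
  tok <- .peek(st)
  if (is.null(tok) || !tok$type %in% c("word", "quoted"))
    .stopf("syntax error at position %s: expected a TF or keyword",
           if (is.null(tok)) "end of query" else tok$at)
  .advance(st)
  subject <- tok$text
  if (tolower(subject) %in% c("all", "all_expression"))
    subject <- tolower(subject)
  filters <- list()
  while (!is.null(tk <- .peek(st)) && tk$type == "[") {
    .advance(st)
    key <- character()
    repeat {
      kt <- .peek(st)
      if (is.null(kt)) .stopf("syntax error: unterminated filter")
      if (kt$type == "op") break
      if (!kt$type %in% c("word", "quoted", "<", ">"))
        .stopf("syntax error at position %d: bad filter key", kt$at)
      key <- c(key, kt$text)
      .advance(st)
    }
    key <- paste(key, collapse = "")
    op <- .expect(st, "op")$text
    vt <- .peek(st)
    if (is.null(vt) || !vt$type %in% c("word", "quoted"))
      .stopf("syntax error at position %s: expected a filter value",
             if (is.null(vt)) "end of query" else vt$at)
    .advance(st)
    value <- vt$text
    .expect(st, "]")
    filters[[length(filters) + 1L]] <-
      list(key = key, op = op, value = value)
  }
  list(op = "term", subject = subject, filters = filters)
}

#' Serialize a query AST back to query text
#'
#' `parse_query(serialize_query(ast))` reproduces `ast` exactly.
#'
#' @param ast a `query_ast` (or node).
#' @return Query string.
#' @export
serialize_query <- function(ast) {
  ser <- function(node) {
    switch(node$op,
      term = {
        f <- vapply(node$filters, function(fl) {
          v <- fl$value
          if (grepl("[][()=<>![:space:]\"]", v)) v <- paste0('"', v, '"')
          paste0("[", fl$key, fl$op, v, "]")
        }, character(1))
        paste0(node$subject, paste(f, collapse = ""))
      },
      not = {
        inner <- ser(node$child)
        if (node$child$op == "term") paste0("not ", inner)
        else paste0("not (", inner, ")")
      },
      and = paste(vapply(node$children, function(ch) {
        s <- ser(ch)
        if (ch$op %in% c("term", "not")) s else paste0("(", s, ")")
      }, character(1)), collapse = " and "),
      or = paste(vapply(node$children, function(ch) {
        s <- ser(ch)
        if (ch$op %in% c("term", "not")) s else paste0("(", s, ")")
      }, character(1)), collapse = " or "),
      .stopf("unknown AST node op '%s'", node$op)
    )
  }
  ser(ast)
}

#' @export
print.query_ast <- function(x, ...) {
  cat("<query_ast> ", serialize_query(x), "\n", sep = "")
  invisible(x)
}
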