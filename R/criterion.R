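#' @title Boolean criterion language over data columns
#'
#' @description
#' Criteria select "qualifying" measurements from an expression table, e.g.
#' `abs([logFC]) > 1 AND [P.value] < 0.05`.  Grammar (documented in the
#' README): column names in square brackets; numeric literals (optionally
#' signed); `abs()`; comparisons `<`, `<=`, `>`, `>=`, `=`; boolean
#' connectives `AND`, `OR`, `NOT` (case-insensitive) and parentheses.
#' `NOT` binds tightest, then `AND`, then `OR`.
#' @name criterion
NULL

crit_tokenize <- function(src) {
  tokens <- list()
  i <- 1L
  n <- nchar(src)
  push <- function(type, value, pos)
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value,
                                           pos = pos)
  while (i <= n) {
    ch <- substr(src, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    rest <- substr(src, i, n)
    if (ch == "[") {
      close <- regexpr("]", rest, fixed = TRUE)
      if (close < 0)
        stop_pb(paste0("unclosed '[' at position ", i),
                "pathbridge_syntax_error")
      push("COLUMN", substr(rest, 2, close - 1), i)
      i <- i + close
    } else if (grepl("^(<=|>=|<|>|=)", rest)) {
      op <- regmatches(rest, regexpr("^(<=|>=|<|>|=)", rest))
      push("CMP", op, i)
      i <- i + nchar(op)
    } else if (grepl("^[0-9.]", ch)) {
      num <- regmatches(rest, regexpr("^[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?",
                                      rest))
      push("NUMBER", as.numeric(num), i)
      i <- i + nchar(num)
    } else if (ch == "(") { push("LPAREN", "(", i); i <- i + 1L
    } else if (ch == ")") { push("RPAREN", ")", i); i <- i + 1L
    } else if (ch == "-") { push("MINUS", "-", i); i <- i + 1L
    } else if (grepl("^[A-Za-z_]", ch)) {
      word <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_.]*", rest))
      up <- toupper(word)
      if (up %in% c("AND", "OR", "NOT")) push(up, word, i)
      else if (up == "ABS") push("ABS", word, i)
      else stop_pb(paste0("unknown name '", word, "' at position ", i,
                          " (column names need [brackets])"),
                   "pathbridge_syntax_error")
      i <- i + nchar(word)
    } else {
      stop_pb(paste0("unexpected character '", ch, "' at position ", i),
              "pathbridge_syntax_error")
    }
  }
  tokens
}

#' Parse a criterion expression
#'
#' @param expr criterion source string, e.g.
#'   `"abs([logFC]) > 1 AND [P.value] < 0.05"`.
#' @return a `pb_criterion` carrying the expression tree and the referenced
#'   column names.
#' @export
parse_criterion <- function(expr) {
  tokens <- crit_tokenize(expr)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { t <- peek(); pos <<- pos + 1L; t }
  expect <- function(type) {
    t <- peek()
    if (is.null(t) || t$type != type)
      stop_pb(paste0("expected ", type, if (!is.null(t))
        paste0(" at position ", t$pos, ", found '", t$value, "'")
        else " at end of expression"), "pathbridge_syntax_error")
    advance()
  }

  parse_operand <- function() {
    t <- peek()
    if (is.null(t))
      stop_pb("unexpected end of expression", "pathbridge_syntax_error")
    if (t$type == "NUMBER") { advance(); list(kind = "num", value = t$value) }
    else if (t$type == "MINUS") {
      advance()
      list(kind = "neg", arg = parse_operand())
    }
    else if (t$type == "COLUMN") { advance(); list(kind = "col", name = t$value) }
    else if (t$type == "ABS") {
      advance(); expect("LPAREN")
      arg <- parse_operand()
      expect("RPAREN")
      list(kind = "abs", arg = arg)
    }
    else stop_pb(paste0("expected a value at position ", t$pos),
                 "pathbridge_syntax_error")
  }
  parse_atom <- function() {
    t <- peek()
    if (!is.null(t) && t$type == "LPAREN") {
      advance()
      e <- parse_or()
      expect("RPAREN")
      return(e)
    }
    lhs <- parse_operand()
    op <- expect("CMP")
    rhs <- parse_operand()
    list(kind = "cmp", op = op$value, lhs = lhs, rhs = rhs)
  }
  parse_unary <- function() {
    t <- peek()
    if (!is.null(t) && t$type == "NOT") {
      advance()
      return(list(kind = "not", arg = parse_unary()))
    }
    parse_atom()
  }
  parse_and <- function() {
    e <- parse_unary()
    while (!is.null(peek()) && peek()$type == "AND") {
      advance()
      e <- list(kind = "and", lhs = e, rhs = parse_unary())
    }
    e
  }
  parse_or <- function() {
    e <- parse_and()
    while (!is.null(peek()) && peek()$type == "OR") {
      advance()
      e <- list(kind = "or", lhs = e, rhs = parse_and())
    }
    e
  }

  ast <- parse_or()
  t <- peek()
  if (!is.null(t))
    stop_pb(paste0("unexpected '", t$value, "' at position ", t$pos),
            "pathbridge_syntax_error")
  cols <- character()
  walk <- function(node) {
    if (node$kind == "col") cols <<- c(cols, node$name)
    for (f in c("arg", "lhs", "rhs"))
      if (!is.null(node[[f]])) walk(node[[f]])
  }
  walk(ast)
  structure(list(source = expr, ast = ast, columns = unique(cols)),
            class = "pb_criterion")
}

#' @export
print.pb_criterion <- function(x, ...) {
  cat("Criterion: ", x$source, "\n  columns: ",
      paste(x$columns, collapse = ", "), "\n", sep = "")
  invisible(x)
}

eval_crit_node <- function(node, table) {
  switch(node$kind,
    num = node$value,
    neg = -eval_crit_node(node$arg, table),
    col = {
      if (!(node$name %in% names(table)))
        stop_pb(paste0("criterion references missing column '", node$name, "'"),
                "pathbridge_column_error")
      table[[node$name]]
    },
    abs = abs(eval_crit_node(node$arg, table)),
    cmp = {
      l <- eval_crit_node(node$lhs, table)
      r <- eval_crit_node(node$rhs, table)
      switch(node$op, "<" = l < r, "<=" = l <= r, ">" = l > r,
             ">=" = l >= r, "=" = l == r)
    },
    and = eval_crit_node(node$lhs, table) & eval_crit_node(node$rhs, table),
    or = eval_crit_node(node$lhs, table) | eval_crit_node(node$rhs, table),
    not = !eval_crit_node(node$arg, table))
}

#' Evaluate a criterion over a data table
#'
#' Rows where a referenced value is missing do not qualify (`NA`
#' propagates to `FALSE`), but they still count as measured.
#'
#' @param crit a `pb_criterion` (or a string, parsed on the fly).
#' @param table data frame with the referenced numeric columns.
#' @return logical vector, one element per row, never `NA`.
#' @export
criterion_matches <- function(crit, table) {
  if (is.character(crit)) crit <- parse_criterion(crit)
  res <- eval_crit_node(crit$ast, table)
  if (length(res) == 1) res <- rep(res, nrow(table))
  res & !is.na(res)
}
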