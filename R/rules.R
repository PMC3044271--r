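# Rule language: gated Boolean expressions over lagged, parameterized input
# terms.  A term "5*IL1(t-1)" reads: the IL1 input with sustained response
# r = 5 and delayed activation theta = 1; "-62*NFkB(t-96)" has a delayed
# response (r = -62).  Terms combine with AND / OR / NOT; NOT binds tighter
# than AND, AND tighter than OR.

#' Build an edge term
#'
#' A term is a leaf of a transfer-rule expression: one regulatory edge with
#' its two dynamic parameters.
#'
#' @param source name of the upstream node.
#' @param theta delayed activation, integer minutes >= 1: how long the source
#'   must have been on continuously before the edge transmits.
#' @param r sustained/delayed response, nonzero integer minutes. `r >= 1`
#'   means the edge output is sustained after the input condition lapses;
#'   `r <= -1` means activation is delayed by a further `|r|` minutes of
#'   accumulated input.
#' @return an object of class `bdn_expr` (a term node).
#' @export
edge_term <- function(source, theta = 1L, r = 1L) {
  theta <- as.integer(theta)
  r <- as.integer(r)
  if (is.na(theta) || theta < 1L)
    stop("theta must be an integer >= 1 (got ", theta, " for '", source, "')")
  if (is.na(r) || r == 0L)
    stop("r must be a nonzero integer (got 0 for '", source, "')")
  structure(list(op = "term", source = source, theta = theta, r = r),
            class = "bdn_expr")
}

expr_node <- function(op, args) structure(c(list(op = op), list(args = args)),
                                          class = "bdn_expr")

#' @export
print.bdn_expr <- function(x, ...) {
  cat(format_expr(x), "\n")
  invisible(x)
}

# ---- tokenizer ------------------------------------------------------------

# token: list(type = "op"|"term"|"lpar"|"rpar", ...)
tokenize_rule <- function(text) {
  tokens <- list()
  s <- text
  pos <- 1L
  push <- function(tok) tokens[[length(tokens) + 1L]] <<- tok
  repeat {
    s <- sub("^\\s+", "", s)
    if (!nzchar(s)) break
    if (grepl("^(AND|OR|NOT)\\b", s)) {
      op <- regmatches(s, regexpr("^(AND|OR|NOT)", s))
      push(list(type = "op", op = op))
      s <- substring(s, nchar(op) + 1L)
      next
    }
    if (startsWith(s, ")")) {
      push(list(type = "rpar"))
      s <- substring(s, 2L)
      next
    }
    # term: [int *] NAME ( t - int ) ; the optional grouping "(" is only
    # recognised where the name/lag pattern does not match.
    m <- regexpr(
      "^(-?[0-9]+)\\s*\\*\\s*([A-Za-z][A-Za-z0-9_/]*)\\s*\\(\\s*t\\s*-\\s*([0-9]+)\\s*\\)",
      s, perl = TRUE)
    if (m == 1L) {
      g <- regmatches(s, m)
      parts <- regmatches(g, regexec(
        "^(-?[0-9]+)\\s*\\*\\s*([A-Za-z][A-Za-z0-9_/]*)\\s*\\(\\s*t\\s*-\\s*([0-9]+)\\s*\\)", g))[[1]]
      term_token(push, parts[3], parts[4], parts[2], g)
      s <- substring(s, attr(m, "match.length") + 1L)
      next
    }
    m <- regexpr("^([A-Za-z][A-Za-z0-9_/]*)\\s*\\(\\s*t\\s*-\\s*([0-9]+)\\s*\\)",
                 s, perl = TRUE)
    if (m == 1L) {
      g <- regmatches(s, m)
      parts <- regmatches(g, regexec(
        "^([A-Za-z][A-Za-z0-9_/]*)\\s*\\(\\s*t\\s*-\\s*([0-9]+)\\s*\\)", g))[[1]]
      term_token(push, parts[2], parts[3], NULL, g)
      s <- substring(s, attr(m, "match.length") + 1L)
      next
    }
    if (startsWith(s, "(")) {
      push(list(type = "lpar"))
      s <- substring(s, 2L)
      next
    }
    bad <- regmatches(s, regexpr("^\\S+", s))
    stop("cannot parse rule at '", bad, "': expected a term like 'NAME(t-3)',",
         " an operator (AND/OR/NOT), or parentheses")
  }
  tokens
}

term_token <- function(push, name, lag, coef, text) {
  lag <- as.integer(lag)
  if (lag < 1L)
    stop("lag must be >= 1 in term '", text, "'")
  r <- if (is.null(coef)) 1L else as.integer(coef)
  if (r == 0L)
    stop("coefficient r must be nonzero in term '", text, "'")
  push(list(type = "term", source = name, theta = lag, r = r))
}

# ---- recursive-descent parser --------------------------------------------

#' Parse a transfer-rule expression
#'
#' Parses the rule syntax used by the bundled NF-kB model, e.g.
#' `"5*IL1(t-1) OR 3*LPS(t-87)"` or `"4*TNF(t-1) AND NOT A20(t-10)"`.
#' The integer coefficient before `*` is the sustained/delayed response `r`
#' (default 1 when absent); the lag in `(t-k)` is the delayed activation
#' `theta`.  Precedence: `NOT` > `AND` > `OR`; `NOT` applies to the single
#' following term or parenthesized group.
#'
#' @param text rule string.
#' @param target name of the node the rule drives (recorded on the result).
#' @return an object of class `bdn_rule`: list with `target` and the
#'   expression tree (`bdn_expr`).
#' @examples
#' parse_rule("5*IL1(t-1) OR 3*LPS(t-87)", "IRAK1")
#' @export
parse_rule <- function(text, target = NA_character_) {
  tokens <- tokenize_rule(text)
  if (length(tokens) == 0L) stop("empty rule for target '", target, "'")
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L
  expr <- parse_or(state)
  if (state$pos <= length(state$tokens)) {
    tok <- state$tokens[[state$pos]]
    stop("unexpected ", if (tok$type == "rpar") "')'" else
      paste0("token near '", tok$type, "'"), " in rule '", text, "'")
  }
  check_duplicate_sources(expr, target)
  structure(list(target = target, expr = expr), class = "bdn_rule")
}

peek <- function(state) {
  if (state$pos > length(state$tokens)) NULL else state$tokens[[state$pos]]
}
advance <- function(state) state$pos <- state$pos + 1L

parse_or <- function(state) {
  args <- list(parse_and(state))
  repeat {
    tok <- peek(state)
    if (is.null(tok) || tok$type != "op" || tok$op != "OR") break
    advance(state)
    args[[length(args) + 1L]] <- parse_and(state)
  }
  if (length(args) == 1L) args[[1L]] else expr_node("or", args)
}

parse_and <- function(state) {
  args <- list(parse_unary(state))
  repeat {
    tok <- peek(state)
    if (is.null(tok) || tok$type != "op" || tok$op != "AND") break
    advance(state)
    args[[length(args) + 1L]] <- parse_unary(state)
  }
  if (length(args) == 1L) args[[1L]] else expr_node("and", args)
}

parse_unary <- function(state) {
  tok <- peek(state)
  if (is.null(tok)) stop("rule ends where a term was expected")
  if (tok$type == "op" && tok$op == "NOT") {
    advance(state)
    structure(list(op = "not", arg = parse_unary(state)), class = "bdn_expr")
  } else {
    parse_primary(state)
  }
}

parse_primary <- function(state) {
  tok <- peek(state)
  if (is.null(tok)) stop("rule ends where a term was expected")
  if (tok$type == "term") {
    advance(state)
    edge_term(tok$source, tok$theta, tok$r)
  } else if (tok$type == "lpar") {
    advance(state)
    expr <- parse_or(state)
    tok <- peek(state)
    if (is.null(tok) || tok$type != "rpar")
      stop("unbalanced parentheses: missing ')'")
    advance(state)
    expr
  } else if (tok$type == "rpar") {
    stop("unbalanced parentheses: unexpected ')'")
  } else {
    stop("operator '", tok$op, "' found where a term was expected")
  }
}

check_duplicate_sources <- function(expr, target) {
  src <- vapply(expr_terms(expr), function(tm) tm$source, character(1))
  dup <- unique(src[duplicated(src)])
  if (length(dup))
    stop("duplicate edge", if (length(dup) > 1) "s", " from ",
         paste0("'", dup, "'", collapse = ", "),
         " in the rule for '", target, "'")
}

# ---- tree utilities -------------------------------------------------------

#' List the edge terms of an expression or rule
#'
#' @param expr a `bdn_expr` or `bdn_rule`.
#' @param negated internal: polarity of the enclosing context.
#' @return list of terms, each a list with `source`, `theta`, `r`, `negated`
#'   (TRUE when the term sits under an odd number of NOTs).
#' @export
expr_terms <- function(expr, negated = FALSE) {
  if (inherits(expr, "bdn_rule")) expr <- expr$expr
  switch(expr$op,
    term = list(list(source = expr$source, theta = expr$theta, r = expr$r,
                     negated = negated)),
    not = expr_terms(expr$arg, !negated),
    unlist(lapply(expr$args, expr_terms, negated = negated),
           recursive = FALSE)
  )
}

#' Print an expression or rule back in the rule syntax
#'
#' `format_expr` / `format_rule` are the inverse of [parse_rule()]:
#' `parse_rule(format_rule(rule), target)` recovers the same tree.
#'
#' @param expr a `bdn_expr`.
#' @return single rule string.
#' @export
format_expr <- function(expr) {
  fmt <- function(e) {
    switch(e$op,
      term = paste0(if (e$r != 1L) paste0(e$r, "*"), e$source,
                    "(t-", e$theta, ")"),
      not = paste0("NOT ", wrap(e$arg, c("and", "or"))),
      and = paste(vapply(e$args, wrap, "", wrap_ops = "or"),
                  collapse = " AND "),
      or = paste(vapply(e$args, fmt, ""), collapse = " OR ")
    )
  }
  wrap <- function(e, wrap_ops) {
    inner <- fmt(e)
    if (e$op %in% wrap_ops) paste0("(", inner, ")") else inner
  }
  fmt(expr)
}

#' @rdname format_expr
#' @param rule a `bdn_rule`.
#' @export
format_rule <- function(rule) format_expr(rule$expr)

#' @export
print.bdn_rule <- function(x, ...) {
  cat(x$target, "(t) = ", format_rule(x), "\n", sep = "")
  invisible(x)
}
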