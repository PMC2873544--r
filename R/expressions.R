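# Boolean expression abstract syntax trees and the equation-text parser.
#
# Expressions are nested lists of class "boolean_expression":
#   list(type = "var",   name = <character>)
#   list(type = "const", value = 0L or 1L)
#   list(type = "not",   arg = <expr>)
#   list(type = "and"/"or", lhs = <expr>, rhs = <expr>)

new_expr <- function(x) structure(x, class = "boolean_expression")

#' Build Boolean expression nodes
#'
#' Low-level constructors for Boolean expression trees. Leaves are species
#' references (`bool_var`) or the constants 0/1 (`bool_const`); internal
#' nodes are negation (`bool_not`) and the binary connectives
#' (`bool_and`, `bool_or`).
#'
#' @param name Species name (single character string).
#' @param value 0 or 1.
#' @param e,e1,e2 Boolean expressions.
#' @return An object of class `boolean_expression`.
#' @examples
#' e <- bool_or(bool_var("X"), bool_not(bool_var("Y")))
#' format(e)
#' @export
bool_var <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  new_expr(list(type = "var", name = name))
}

#' @rdname bool_var
#' @export
bool_const <- function(value) {
  value <- as.integer(value)
  stopifnot(length(value) == 1L, value %in% c(0L, 1L))
  new_expr(list(type = "const", value = value))
}

#' @rdname bool_var
#' @export
bool_not <- function(e) {
  stopifnot(inherits(e, "boolean_expression"))
  new_expr(list(type = "not", arg = e))
}

#' @rdname bool_var
#' @export
bool_and <- function(e1, e2) {
  stopifnot(inherits(e1, "boolean_expression"), inherits(e2, "boolean_expression"))
  new_expr(list(type = "and", lhs = e1, rhs = e2))
}

#' @rdname bool_var
#' @export
bool_or <- function(e1, e2) {
  stopifnot(inherits(e1, "boolean_expression"), inherits(e2, "boolean_expression"))
  new_expr(list(type = "or", lhs = e1, rhs = e2))
}

# Fold a list of expressions with a binary connective ("and"/"or").
fold_expr <- function(exprs, op) {
  stopifnot(length(exprs) >= 1L)
  out <- exprs[[1L]]
  if (length(exprs) > 1L) {
    combine <- if (op == "and") bool_and else bool_or
    for (e in exprs[-1L]) out <- combine(out, e)
  }
  out
}

#' Evaluate a Boolean expression
#'
#' @param expr A `boolean_expression`.
#' @param env Named vector (0/1 or logical) assigning a value to every
#'   variable occurring in `expr`.
#' @return 0 or 1 (integer).
#' @examples
#' eval_expression(bool_or(bool_var("A"), bool_not(bool_var("B"))),
#'                 c(A = 0, B = 1))
#' @export
eval_expression <- function(expr, env) {
  stopifnot(inherits(expr, "boolean_expression"))
  ev <- function(e) {
    switch(e$type,
      var = {
        if (is.na(match(e$name, names(env)))) {
          stop("no value for variable '", e$name, "'", call. = FALSE)
        }
        as.integer(env[[e$name]])
      },
      const = e$value,
      not = 1L - ev(e$arg),
      and = ev(e$lhs) * ev(e$rhs),
      or = {
        a <- ev(e$lhs); b <- ev(e$rhs)
        a + b - a * b
      },
      stop("malformed expression node", call. = FALSE)
    )
  }
  ev(expr)
}

#' Variables of a Boolean expression
#'
#' @param expr A `boolean_expression`.
#' @return Character vector of distinct variable names, in order of first
#'   appearance (left to right).
#' @export
expression_variables <- function(expr) {
  stopifnot(inherits(expr, "boolean_expression"))
  acc <- character(0)
  walk <- function(e) {
    switch(e$type,
      var = acc[[length(acc) + 1L]] <<- e$name,
      const = NULL,
      not = walk(e$arg),
      { walk(e$lhs); walk(e$rhs) }
    )
    invisible(NULL)
  }
  walk(expr)
  unique(acc)
}

# precedence: or = 1, and = 2, not = 3, leaf = 4
expr_prec <- function(e) {
  switch(e$type, or = 1L, and = 2L, not = 3L, 4L)
}

#' @export
format.boolean_expression <- function(x, ...) {
  fmt <- function(e, parent_prec) {
    p <- expr_prec(e)
    s <- switch(e$type,
      var = e$name,
      const = as.character(e$value),
      not = paste0("~", fmt(e$arg, p)),
      and = paste0(fmt(e$lhs, p), " && ", fmt(e$rhs, p)),
      or = paste0(fmt(e$lhs, p), " || ", fmt(e$rhs, p))
    )
    if (p < parent_prec) paste0("(", s, ")") else s
  }
  fmt(x, 0L)
}

#' @export
print.boolean_expression <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

## ---- tokenizer / recursive-descent parser -------------------------------

# Token: list(kind, text, pos). Kinds: NAME, CONST, AND, OR, NOT, LP, RP, EQ
tokenize_line <- function(line, lineno) {
  tokens <- list()
  i <- 1L
  n <- nchar(line)
  push <- function(kind, text, pos) {
    tokens[[length(tokens) + 1L]] <<- list(kind = kind, text = text, pos = pos)
  }
  while (i <= n) {
    ch <- substr(line, i, i)
    if (grepl("^[ \t]$", ch)) { i <- i + 1L; next }
    two <- substr(line, i, i + 1L)
    if (two == "&&") { push("AND", two, i); i <- i + 2L; next }
    if (two == "||") { push("OR", two, i); i <- i + 2L; next }
    if (ch == "&") { push("AND", ch, i); i <- i + 1L; next }
    if (ch == "|") { push("OR", ch, i); i <- i + 1L; next }
    if (ch == "~" || ch == "!") { push("NOT", ch, i); i <- i + 1L; next }
    if (ch == "(") { push("LP", ch, i); i <- i + 1L; next }
    if (ch == ")") { push("RP", ch, i); i <- i + 1L; next }
    if (ch == "=") { push("EQ", ch, i); i <- i + 1L; next }
    m <- regmatches(substr(line, i, n), regexpr("^[A-Za-z_.][A-Za-z0-9_.]*", substr(line, i, n)))
    if (length(m) == 1L) {
      word <- m
      if (word == "AND") push("AND", word, i)
      else if (word == "OR") push("OR", word, i)
      else if (word == "NOT") push("NOT", word, i)
      else push("NAME", word, i)
      i <- i + nchar(word)
      next
    }
    m <- regmatches(substr(line, i, n), regexpr("^[01]", substr(line, i, n)))
    if (length(m) == 1L) { push("CONST", m, i); i <- i + 1L; next }
    stop(sprintf("line %d: unexpected character '%s' at column %d", lineno, ch, i),
         call. = FALSE)
  }
  tokens
}

# Recursive-descent over tokens with precedence NOT > AND > OR,
# left-associative binary connectives.
parse_tokens <- function(tokens, lineno) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { tk <- tokens[[pos]]; pos <<- pos + 1L; tk }
  fail <- function(msg, tk = peek()) {
    where <- if (is.null(tk)) "end of line" else sprintf("'%s' (column %d)", tk$text, tk$pos)
    stop(sprintf("line %d: %s at %s", lineno, msg, where), call. = FALSE)
  }

  parse_or <- function() {
    e <- parse_and()
    while (!is.null(peek()) && peek()$kind == "OR") {
      advance()
      e <- bool_or(e, parse_and())
    }
    e
  }
  parse_and <- function() {
    e <- parse_not()
    while (!is.null(peek()) && peek()$kind == "AND") {
      advance()
      e <- bool_and(e, parse_not())
    }
    e
  }
  parse_not <- function() {
    if (!is.null(peek()) && peek()$kind == "NOT") {
      advance()
      return(bool_not(parse_not()))
    }
    parse_primary()
  }
  parse_primary <- function() {
    tk <- peek()
    if (is.null(tk)) fail("expected an operand")
    if (tk$kind == "NAME") { advance(); return(bool_var(tk$text)) }
    if (tk$kind == "CONST") { advance(); return(bool_const(as.integer(tk$text))) }
    if (tk$kind == "LP") {
      advance()
      e <- parse_or()
      if (is.null(peek()) || peek()$kind != "RP") fail("expected ')'")
      advance()
      return(e)
    }
    fail("unexpected token")
  }

  e <- parse_or()
  if (!is.null(peek())) fail("trailing input")
  e
}

#' Parse a single Boolean expression
#'
#' Accepts `&&`/`&`/`AND`, `||`/`|`/`OR`, `~`/`!`/`NOT`, parentheses,
#' variable names and the literals 0/1. Precedence is NOT > AND > OR;
#' binary connectives associate to the left.
#'
#' @param text Expression text, e.g. `"(A && ~B) || C"`.
#' @return A `boolean_expression`.
#' @export
parse_boolean_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- tokenize_line(text, 1L)
  if (length(tokens) == 0L) stop("empty expression", call. = FALSE)
  parse_tokens(tokens, 1L)
}

#' Parse a set of Boolean update equations
#'
#' Reads multi-line text in which each non-empty line defines the update
#' rule of one species, `Name = expression`. Expressions use the operators
#' `&&` (AND), `||` (OR) and `~` (NOT) -- the word aliases `AND`, `OR`,
#' `NOT` and the single-character forms `&`, `|`, `!` are also accepted --
#' plus parentheses and the literals 0/1. `#` starts a comment. Species of
#' the resulting model are all names appearing anywhere, left-hand sides
#' first (in file order), then names occurring only on right-hand sides.
#' Species without a left-hand side have no update rule and are treated as
#' constant model inputs downstream.
#'
#' @param text Character scalar (possibly multi-line) or character vector
#'   of lines.
#' @return A [boolean_model].
#' @examples
#' m <- parse_boolean_equations("X = X || ~Y\nY = Y || ~X")
#' m
#' @export
parse_boolean_equations <- function(text) {
  stopifnot(is.character(text))
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("#.*$", "", lines)
  targets <- character(0)
  exprs <- list()
  seen_any <- FALSE
  for (ln in seq_along(lines)) {
    tokens <- tokenize_line(lines[[ln]], ln)
    if (length(tokens) == 0L) next
    seen_any <- TRUE
    if (length(tokens) < 3L || tokens[[1L]]$kind != "NAME" || tokens[[2L]]$kind != "EQ") {
      stop(sprintf("line %d: expected 'Name = expression'", ln), call. = FALSE)
    }
    target <- tokens[[1L]]$text
    if (target %in% targets) {
      stop(sprintf("line %d: duplicate update rule for species '%s'", ln, target),
           call. = FALSE)
    }
    expr <- parse_tokens(tokens[-(1:2)], ln)
    targets[[length(targets) + 1L]] <- target
    exprs[[target]] <- expr
  }
  if (!seen_any) stop("empty input: no equations found", call. = FALSE)
  rhs_vars <- unique(unlist(lapply(exprs, expression_variables), use.names = FALSE))
  species <- c(targets, setdiff(rhs_vars, targets))
  rules <- lapply(targets, function(tg) {
    expression_to_rule(exprs[[tg]], expression_variables(exprs[[tg]]), target = tg)
  })
  names(rules) <- targets
  boolean_model(species, rules)
}
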