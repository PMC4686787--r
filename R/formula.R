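#' Formulas for computed attributes and suggestion conditions
#'
#' Computed attributes and suggestion-rule conditions are written in a tiny
#' closed expression language, deliberately not R: numbers, attribute names,
#' unary minus, parentheses, `+ - * /` with standard precedence and left
#' associativity, the calendar helper `years_between(a, b)`, and (for
#' conditions) a single comparison `== != < <= > >=` against a number, name
#' or quoted string. Nothing else parses, so evaluating a stored workflow can
#' only ever perform arithmetic and calendar difference.
#'
#' @param text Expression text.
#' @return A `flux_formula` object with fields `expression` (the source
#'   text), `ast` (the parse tree) and `referenced_names` (character vector
#'   of attribute names the expression reads).
#' @examples
#' f <- parse_formula("weight / (height * height)")
#' f$referenced_names
#' evaluate_formula(f, list(weight = 80, height = 2))
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop_formula_syntax("formula must be a single string", 1L)
  }
  toks <- formula_tokens(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  ast <- parse_condition(st)
  tk <- peek_token(st)
  if (tk$type != "EOF") {
    stop_formula_syntax(sprintf("unexpected '%s'", tk$text), tk$offset)
  }
  structure(
    list(
      expression = text,
      ast = ast,
      referenced_names = sort(unique(collect_names(ast)))
    ),
    class = "flux_formula"
  )
}

#' @export
print.flux_formula <- function(x, ...) {
  cat("<flux_formula> ", x$expression, "\n", sep = "")
  if (length(x$referenced_names)) {
    cat("  reads: ", paste(x$referenced_names, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

stop_formula_syntax <- function(msg, offset) {
  cond <- structure(
    class = c("flux_formula_syntax_error", "error", "condition"),
    list(
      message = sprintf("formula syntax error at character %d: %s", offset, msg),
      call = NULL, offset = offset
    )
  )
  stop(cond)
}

formula_tokens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  push <- function(type, txt, off) {
    toks[[length(toks) + 1L]] <<- list(type = type, text = txt, offset = off)
  }
  while (i <= n) {
    ch <- chars[[i]]
    if (ch %in% c(" ", "\t", "\n", "\r")) {
      i <- i + 1L
    } else if (grepl("[0-9]", ch) ||
               (ch == "." && i < n && grepl("[0-9]", chars[[i + 1L]]))) {
      j <- i
      seen_dot <- FALSE
      while (j <= n && (grepl("[0-9]", chars[[j]]) ||
                        (chars[[j]] == "." && !seen_dot))) {
        if (chars[[j]] == ".") seen_dot <- TRUE
        j <- j + 1L
      }
      push("NUM", paste(chars[i:(j - 1L)], collapse = ""), i)
      i <- j
    } else if (grepl("[A-Za-z_]", ch)) {
      j <- i
      while (j <= n && grepl("[A-Za-z0-9_]", chars[[j]])) j <- j + 1L
      push("IDENT", paste(chars[i:(j - 1L)], collapse = ""), i)
      i <- j
    } else if (ch %in% c("'", "\"")) {
      j <- i + 1L
      while (j <= n && chars[[j]] != ch) j <- j + 1L
      if (j > n) stop_formula_syntax("unterminated string literal", i)
      push("STR", if (j > i + 1L) paste(chars[(i + 1L):(j - 1L)], collapse = "") else "", i)
      i <- j + 1L
    } else if (ch %in% c("=", "!", "<", ">")) {
      nxt <- if (i < n) chars[[i + 1L]] else ""
      if (nxt == "=") {
        push("CMP", paste0(ch, "="), i)
        i <- i + 2L
      } else if (ch %in% c("<", ">")) {
        push("CMP", ch, i)
        i <- i + 1L
      } else {
        stop_formula_syntax(sprintf("unexpected '%s'", ch), i)
      }
    } else if (ch %in% c("+", "-", "*", "/")) {
      push("OP", ch, i)
      i <- i + 1L
    } else if (ch == "(") {
      push("LPAREN", ch, i); i <- i + 1L
    } else if (ch == ")") {
      push("RPAREN", ch, i); i <- i + 1L
    } else if (ch == ",") {
      push("COMMA", ch, i); i <- i + 1L
    } else {
      stop_formula_syntax(sprintf("unexpected character '%s'", ch), i)
    }
  }
  push("EOF", "", n + 1L)
  toks
}

peek_token <- function(st) st$toks[[st$pos]]

next_token <- function(st) {
  tk <- st$toks[[st$pos]]
  st$pos <- st$pos + 1L
  tk
}

expect_token <- function(st, type, what) {
  tk <- next_token(st)
  if (tk$type != type) {
    stop_formula_syntax(sprintf("expected %s, found '%s'", what, tk$text), tk$offset)
  }
  tk
}

# condition := sum (CMP sum)?   -- at most one comparison, lowest precedence
parse_condition <- function(st) {
  lhs <- parse_sum(st)
  tk <- peek_token(st)
  if (tk$type == "CMP") {
    next_token(st)
    rhs <- parse_sum(st)
    if (peek_token(st)$type == "CMP") {
      stop_formula_syntax("chained comparisons are not allowed",
                          peek_token(st)$offset)
    }
    return(list(type = "cmp", op = tk$text, lhs = lhs, rhs = rhs))
  }
  lhs
}

parse_sum <- function(st) {
  node <- parse_term(st)
  repeat {
    tk <- peek_token(st)
    if (tk$type == "OP" && tk$text %in% c("+", "-")) {
      next_token(st)
      node <- list(type = "binop", op = tk$text, lhs = node, rhs = parse_term(st))
    } else {
      return(node)
    }
  }
}

parse_term <- function(st) {
  node <- parse_factor(st)
  repeat {
    tk <- peek_token(st)
    if (tk$type == "OP" && tk$text %in% c("*", "/")) {
      next_token(st)
      node <- list(type = "binop", op = tk$text, lhs = node, rhs = parse_factor(st))
    } else {
      return(node)
    }
  }
}

parse_factor <- function(st) {
  tk <- peek_token(st)
  if (tk$type == "OP" && tk$text == "-") {
    next_token(st)
    return(list(type = "neg", operand = parse_factor(st)))
  }
  parse_primary(st)
}

parse_primary <- function(st) {
  tk <- next_token(st)
  if (tk$type == "NUM") {
    return(list(type = "num", value = as.numeric(tk$text)))
  }
  if (tk$type == "STR") {
    return(list(type = "str", value = tk$text))
  }
  if (tk$type == "IDENT") {
    if (peek_token(st)$type == "LPAREN") {
      if (tk$text != "years_between") {
        stop_formula_syntax(
          sprintf("unknown function '%s' (only years_between is available)", tk$text),
          tk$offset
        )
      }
      next_token(st) # (
      a <- expect_token(st, "IDENT", "an attribute name")
      expect_token(st, "COMMA", "','")
      b <- expect_token(st, "IDENT", "an attribute name")
      expect_token(st, "RPAREN", "')'")
      return(list(type = "call", fn = "years_between",
                  args = list(list(type = "var", name = a$text),
                              list(type = "var", name = b$text))))
    }
    return(list(type = "var", name = tk$text))
  }
  if (tk$type == "LPAREN") {
    node <- parse_condition(st)
    expect_token(st, "RPAREN", "')'")
    return(node)
  }
  stop_formula_syntax(sprintf("expected an expression, found '%s'",
                              if (tk$type == "EOF") "end of input" else tk$text),
                      tk$offset)
}

collect_names <- function(node) {
  switch(node$type,
    num = character(),
    str = character(),
    var = node$name,
    neg = collect_names(node$operand),
    binop = ,
    cmp = c(collect_names(node$lhs), collect_names(node$rhs)),
    call = unlist(lapply(node$args, collect_names)),
    stop("internal: unknown node type ", node$type)
  )
}

stop_eval <- function(code, symbol, msg) {
  cond <- structure(
    class = c("flux_eval_error", "error", "condition"),
    list(message = msg, call = NULL, code = code, symbol = symbol)
  )
  stop(cond)
}

#' Evaluate a formula over attribute values
#'
#' Evaluation is a plain tree walk over the parse tree; the only operations it
#' can perform are arithmetic, comparison, and completed-year difference
#' between two dates. Errors (unbound names, non-numeric operands, division by
#' zero) are raised as classed conditions (`flux_eval_error`) naming the
#' offending symbol, never returned as values.
#'
#' `years_between(a, b)` counts completed calendar years from date `b` to
#' date `a`, truncated toward zero, matching the clinical age convention.
#'
#' @param f A `flux_formula` from [parse_formula()].
#' @param context Named list binding every referenced name to a number, a
#'   `Date`, or (for comparisons only) a character token.
#' @return A numeric scalar, or a logical scalar for a comparison.
#' @export
evaluate_formula <- function(f, context) {
  stopifnot(inherits(f, "flux_formula"))
  eval_node(f$ast, context)
}

eval_node <- function(node, ctx) {
  switch(node$type,
    num = node$value,
    str = node$value,
    var = {
      if (!node$name %in% names(ctx) || is.null(ctx[[node$name]])) {
        stop_eval("unbound-name", node$name,
                  sprintf("formula references '%s', which has no value", node$name))
      }
      ctx[[node$name]]
    },
    neg = {
      v <- eval_node(node$operand, ctx)
      check_numeric_operand(v, node$operand)
      -v
    },
    binop = {
      l <- eval_node(node$lhs, ctx)
      r <- eval_node(node$rhs, ctx)
      check_numeric_operand(l, node$lhs)
      check_numeric_operand(r, node$rhs)
      if (node$op == "/" && r == 0) {
        stop_eval("division-by-zero", describe_node(node$rhs),
                  sprintf("division by zero (denominator %s is 0)",
                          describe_node(node$rhs)))
      }
      switch(node$op, "+" = l + r, "-" = l - r, "*" = l * r, "/" = l / r)
    },
    cmp = {
      l <- eval_node(node$lhs, ctx)
      r <- eval_node(node$rhs, ctx)
      comparable <- (is.numeric(l) && is.numeric(r)) ||
        (inherits(l, "Date") && inherits(r, "Date")) ||
        (is.character(l) && is.character(r))
      if (!comparable) {
        stop_eval("non-comparable-operands", describe_node(node$lhs),
                  "comparison operands must both be numbers, dates or text")
      }
      if (is.character(l) && !node$op %in% c("==", "!=")) {
        stop_eval("non-numeric-operand", describe_node(node$lhs),
                  "text values only support == and !=")
      }
      switch(node$op,
        "==" = l == r, "!=" = l != r,
        "<" = l < r, "<=" = l <= r, ">" = l > r, ">=" = l >= r)
    },
    call = {
      a <- eval_node(node$args[[1L]], ctx)
      b <- eval_node(node$args[[2L]], ctx)
      for (k in 1:2) {
        v <- list(a, b)[[k]]
        if (!inherits(v, "Date")) {
          stop_eval("non-date-operand", node$args[[k]]$name,
                    sprintf("years_between needs dates; '%s' is not a date",
                            node$args[[k]]$name))
        }
      }
      years_between(a, b)
    },
    stop("internal: unknown node type ", node$type)
  )
}

check_numeric_operand <- function(v, node) {
  if (!is.numeric(v)) {
    stop_eval("non-numeric-operand", describe_node(node),
              sprintf("arithmetic needs numbers; %s is not numeric",
                      describe_node(node)))
  }
}

describe_node <- function(node) {
  switch(node$type,
    var = node$name,
    num = format(node$value),
    str = sprintf("'%s'", node$value),
    "expression"
  )
}

# Completed calendar years from `from` to `to`, truncated toward zero.
years_between <- function(to, from) {
  lt_to <- as.POSIXlt(to)
  lt_from <- as.POSIXlt(from)
  years <- lt_to$year - lt_from$year
  anniv_not_reached <- (lt_to$mon < lt_from$mon) ||
    (lt_to$mon == lt_from$mon && lt_to$mday < lt_from$mday)
  if (years > 0 && anniv_not_reached) years <- years - 1L
  if (years < 0) {
    # symmetric: completed years in the other direction, negated
    years <- -years_between(from, to)
  }
  as.integer(years)
}
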