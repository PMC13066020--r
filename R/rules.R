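# Boolean rule expressions, the plain-text rule dialect, and its parser/writer.
#
# Dialect (modeled on BoolNet-style target/factor files):
#   NODE = expr          one rule line per node; & = AND, | = OR, ! = NOT
#   polymorphism(NODE) = p   optional activation probability in [0,1]
#   # comment            comments and blank lines are ignored

#' Construct rule-expression trees
#'
#' Rule expressions are finite trees over the operators AND, OR, NOT with
#' node-name leaves and TRUE/FALSE literals. `rule_and()`/`rule_or()` are
#' n-ary, `rule_not()` unary.
#'
#' @param ... child expressions (for `rule_and`/`rule_or`).
#' @param x a child expression (for `rule_not`).
#' @param name a node name (for `rule_var`).
#' @param value logical literal (for `rule_const`).
#' @return a `rule_expr` object.
#' @export
rule_and <- function(...) structure(list(op = "and", args = list(...)), class = "rule_expr")

#' @rdname rule_and
#' @export
rule_or <- function(...) structure(list(op = "or", args = list(...)), class = "rule_expr")

#' @rdname rule_and
#' @export
rule_not <- function(x) structure(list(op = "not", args = list(x)), class = "rule_expr")

#' @rdname rule_and
#' @export
rule_var <- function(name) structure(list(op = "var", name = name), class = "rule_expr")

#' @rdname rule_and
#' @export
rule_const <- function(value) structure(list(op = "const", value = isTRUE(value)), class = "rule_expr")

#' Evaluate a rule expression on a complete network state
#'
#' Standard Boolean semantics; pure. For example the rule
#' `AKT = PDK1 & !(CASP3 | PP2A)` evaluates ON exactly when PDK1 is ON and
#' neither CASP3 nor PP2A is ON.
#'
#' @param rule a `rule_expr`.
#' @param state named logical vector assigning ON (`TRUE`) / OFF (`FALSE`) to
#'   every node the rule mentions.
#' @return `TRUE` (ON) or `FALSE` (OFF).
#' @export
evaluate_rule <- function(rule, state) {
  switch(rule$op,
    const = rule$value,
    var = {
      idx <- match(rule$name, names(state))
      if (is.na(idx)) stop("state is missing node '", rule$name, "'")
      v <- state[[idx]]
      if (is.na(v)) stop("state is missing node '", rule$name, "'")
      v
    },
    not = !evaluate_rule(rule$args[[1L]], state),
    and = {
      for (a in rule$args) if (!evaluate_rule(a, state)) return(FALSE)
      TRUE
    },
    or = {
      for (a in rule$args) if (evaluate_rule(a, state)) return(TRUE)
      FALSE
    },
    stop("unknown rule operator: ", rule$op)
  )
}

#' Node names referenced by a rule expression
#' @param rule a `rule_expr`.
#' @return character vector of distinct leaf node names.
#' @export
rule_leaves <- function(rule) {
  switch(rule$op,
    const = character(),
    var = rule$name,
    unique(unlist(lapply(rule$args, rule_leaves)))
  )
}

# ---- tokenizer -------------------------------------------------------------

tokenize_line <- function(line, lineno) {
  toks <- list()
  i <- 1L
  n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "#") break
    if (ch %in% c("&", "|", "!", "(", ")", "=")) {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch, col = i)
      i <- i + 1L
      next
    }
    if (grepl("[A-Za-z0-9_.]", ch)) {
      j <- i
      while (j <= n && grepl("[A-Za-z0-9_.]", substr(line, j, j))) j <- j + 1L
      toks[[length(toks) + 1L]] <- list(type = "word", text = substr(line, i, j - 1L), col = i)
      i <- j
      next
    }
    stop(sprintf("rule syntax error at line %d, column %d: unexpected character '%s'",
                 lineno, i, ch), call. = FALSE)
  }
  toks
}

# recursive-descent parser over one line's tokens
# expr := term ('|' term)* ; term := factor ('&' factor)* ;
# factor := '!' factor | '(' expr ')' | IDENT | TRUE | FALSE | 1 | 0
parse_expr_tokens <- function(toks, lineno) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  fail <- function(t, what) {
    col <- if (is.null(t)) NA_integer_ else t$col
    stop(sprintf("rule syntax error at line %d, column %s: expected %s",
                 lineno, ifelse(is.na(col), "end", col), what), call. = FALSE)
  }
  parse_or <- function() {
    x <- parse_and()
    args <- list(x)
    while (!is.null(peek()) && peek()$type == "|") {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) x else structure(list(op = "or", args = args), class = "rule_expr")
  }
  parse_and <- function() {
    x <- parse_factor()
    args <- list(x)
    while (!is.null(peek()) && peek()$type == "&") {
      advance()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) x else structure(list(op = "and", args = args), class = "rule_expr")
  }
  parse_factor <- function() {
    t <- peek()
    if (is.null(t)) fail(t, "an expression")
    if (t$type == "!") { advance(); return(rule_not(parse_factor())) }
    if (t$type == "(") {
      advance()
      x <- parse_or()
      t2 <- peek()
      if (is.null(t2) || t2$type != ")") fail(t2, "')'")
      advance()
      return(x)
    }
    if (t$type == "word") {
      advance()
      up <- toupper(t$text)
      if (up == "TRUE" || t$text == "1") return(rule_const(TRUE))
      if (up == "FALSE" || t$text == "0") return(rule_const(FALSE))
      return(rule_var(t$text))
    }
    fail(t, "a node name, literal, '!' or '('")
  }
  out <- parse_or()
  if (!is.null(peek())) fail(peek(), "end of line")
  out
}

# ---- rule file parser ------------------------------------------------------

#' Parse a rule file into a Boolean network
#'
#' Accepts either the text of a rule file or a path to one. One
#' `target = expression` line per node (`&` AND, `|` OR, `!` NOT,
#' parentheses, literals TRUE/FALSE/1/0), optional
#' `polymorphism(NODE) = p` directives and `#` comments.
#'
#' Validation errors are raised for: syntax errors (with line and column),
#' references to undeclared nodes (all offenders listed), duplicate rules for
#' a node, and polymorphisms outside \[0,1\].
#'
#' @param text character: rule-file content (single string or vector of lines),
#'   or a path to a file when `is_path = TRUE`.
#' @param is_path interpret `text` as a file path.
#' @return a [boolean_network()] object.
#' @seealso [write_rule_file()]
#' @export
parse_rule_file <- function(text, is_path = FALSE) {
  if (is_path) text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  rules <- list()
  order <- character()
  polys <- numeric()
  for (k in seq_along(lines)) {
    toks <- tokenize_line(lines[[k]], k)
    if (length(toks) == 0L) next
    # polymorphism(NODE) = p
    if (toks[[1L]]$type == "word" && tolower(toks[[1L]]$text) == "polymorphism" &&
        length(toks) >= 2L && toks[[2L]]$type == "(") {
      if (length(toks) != 6L || toks[[3L]]$type != "word" || toks[[4L]]$type != ")" ||
          toks[[5L]]$type != "=" || toks[[6L]]$type != "word") {
        stop(sprintf("rule syntax error at line %d: malformed polymorphism directive", k),
             call. = FALSE)
      }
      node <- toks[[3L]]$text
      p <- suppressWarnings(as.numeric(toks[[6L]]$text))
      if (is.na(p)) stop(sprintf("rule syntax error at line %d: polymorphism value is not a number", k),
                         call. = FALSE)
      if (p < 0 || p > 1) stop(sprintf("polymorphism for node '%s' is %g, outside [0,1]", node, p),
                               call. = FALSE)
      polys[[node]] <- p
      next
    }
    if (length(toks) < 3L || toks[[1L]]$type != "word" || toks[[2L]]$type != "=") {
      stop(sprintf("rule syntax error at line %d, column %d: expected 'NODE = expression'",
                   k, toks[[1L]]$col), call. = FALSE)
    }
    name <- toks[[1L]]$text
    if (name %in% order) stop("duplicate rule for node '", name, "'", call. = FALSE)
    rules[[name]] <- parse_expr_tokens(toks[-(1:2)], k)
    order <- c(order, name)
  }
  if (length(order) == 0L) stop("rule file declares no nodes", call. = FALSE)
  refs <- unique(unlist(lapply(rules, rule_leaves)))
  unknown <- setdiff(refs, order)
  if (length(unknown) > 0L) {
    stop("rules reference undeclared node(s): ", paste(sort(unknown), collapse = ", "),
         call. = FALSE)
  }
  unknown_poly <- setdiff(names(polys), order)
  if (length(unknown_poly) > 0L) {
    stop("polymorphism directive for undeclared node(s): ",
         paste(sort(unknown_poly), collapse = ", "), call. = FALSE)
  }
  p <- rep(1, length(order))
  names(p) <- order
  p[names(polys)] <- polys
  boolean_network(rules = rules[order], polymorphisms = p)
}

# ---- writer ----------------------------------------------------------------

#' Deparse a rule expression to the rule dialect
#' @param rule a `rule_expr`.
#' @return a single string.
#' @export
format_rule <- function(rule) {
  prec <- function(op) switch(op, or = 1L, and = 2L, not = 3L, 4L)
  go <- function(r, parent_prec) {
    s <- switch(r$op,
      const = if (r$value) "TRUE" else "FALSE",
      var = r$name,
      not = paste0("!", go(r$args[[1L]], prec("not"))),
      and = paste(vapply(r$args, go, "", parent_prec = prec("and")), collapse = " & "),
      or = paste(vapply(r$args, go, "", parent_prec = prec("or")), collapse = " | ")
    )
    if (prec(r$op) < parent_prec) paste0("(", s, ")") else s
  }
  go(rule, 0L)
}

#' Write a Boolean network in the rule dialect
#'
#' Produces one `NODE = expression` line per node in declaration order, then
#' one `polymorphism(NODE) = p` directive per node with activation probability
#' below 1. `parse_rule_file(write_rule_file(net))` reproduces the network.
#'
#' @param network a [boolean_network()].
#' @param path optional file path; when `NULL` the text is returned invisibly.
#' @return the file content as a character vector of lines (invisibly when
#'   written to `path`).
#' @export
write_rule_file <- function(network, path = NULL) {
  stopifnot(inherits(network, "boolean_network"))
  lines <- vapply(network$node_names, function(nm) {
    paste(nm, "=", format_rule(network$rules[[nm]]))
  }, "")
  pl <- network$polymorphisms[network$polymorphisms < 1]
  if (length(pl) > 0L) {
    lines <- c(lines, vapply(names(pl), function(nm) {
      sprintf("polymorphism(%s) = %s", nm, format(unname(pl[[nm]]), digits = 15))
    }, ""))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
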