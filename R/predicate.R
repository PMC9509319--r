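# Restricted predicate language for annotation properties. Expressions are
# parsed with the R parser and then validated against a small whitelist
# before any evaluation -- anything outside the grammar is rejected up
# front, never partially evaluated. The same expression can be compiled to
# an SQLite WHERE clause (json_extract on the properties column) when every
# node is translatable; the interpreted path and the SQL path must return
# identical sets, which the test-suite asserts.

PREDICATE_CALLS <- c("==", "!=", "<", ">", "<=", ">=",
                     "&", "|", "&&", "||", "!",
                     "+", "-", "*", "/", "%in%",
                     "[[", "[", "$", "(", "c",
                     "abs", "min", "max", "length", "is.null")

#' Compile a property predicate
#'
#' Parses and validates an expression over `props` (the annotation property
#' map) in a restricted grammar: literals, comparisons, boolean connectives,
#' arithmetic, membership (`%in%`), subscript/`$` access on `props`, and the
#' functions `abs`, `min`, `max`, `length`, `is.null`. Anything else is
#' rejected before evaluation.
#'
#' @param expr predicate source string, e.g. `'props[["class"]] == 2'`.
#' @return a `wsi_predicate` (callable on a property list).
#' @export
predicate <- function(expr) {
  assert_that(is.character(expr) && length(expr) == 1,
              "predicate must be a single string")
  parsed <- tryCatch(parse(text = expr, keep.source = FALSE),
                     error = function(e)
                       abort(sprintf("predicate does not parse: %s",
                                     conditionMessage(e)),
                             "wsikit_predicate_error"))
  assert_that(length(parsed) == 1, "predicate must be a single expression",
              "wsikit_predicate_error")
  ast <- parsed[[1]]
  check_predicate_ast(ast)
  structure(list(expr = expr, ast = ast), class = "wsi_predicate")
}

check_predicate_ast <- function(node) {
  if (is.atomic(node) || is.null(node)) return(invisible(TRUE))
  if (is.symbol(node)) {
    nm <- as.character(node)
    if (nm %in% c("props", "TRUE", "FALSE", "T", "F")) return(invisible(TRUE))
    abort(sprintf("predicate references forbidden name '%s'", nm),
          "wsikit_predicate_error")
  }
  if (is.call(node)) {
    fn <- node[[1]]
    if (!is.symbol(fn) || !(as.character(fn) %in% PREDICATE_CALLS)) {
      abort(sprintf("predicate uses forbidden call '%s'",
                    paste(deparse(fn), collapse = "")),
            "wsikit_predicate_error")
    }
    if (as.character(fn) == "$") {
      # props$name: the rhs symbol is a field name, not a variable
      check_predicate_ast(node[[2]])
      assert_that(is.symbol(node[[3]]) || is.character(node[[3]]),
                  "invalid $ access", "wsikit_predicate_error")
      return(invisible(TRUE))
    }
    for (i in seq_along(node)[-1]) check_predicate_ast(node[[i]])
    return(invisible(TRUE))
  }
  abort("unsupported syntax in predicate", "wsikit_predicate_error")
}

as_predicate <- function(x) {
  if (is.null(x) || inherits(x, "wsi_predicate")) return(x)
  predicate(x)
}

# interpreted path: evaluate in a sealed environment; missing properties
# come back NULL and any non-TRUE result (including logical(0)) is FALSE
eval_predicate <- function(pred, props) {
  env <- new.env(parent = baseenv())
  for (fn in c("abs", "min", "max", "length", "is.null", "c", "%in%")) {
    assign(fn, get(fn, baseenv()), envir = env)
  }
  env$props <- props
  res <- tryCatch(eval(pred$ast, env), error = function(e) FALSE)
  isTRUE(res)
}

# SQL path: returns a WHERE fragment or NULL when untranslatable
predicate_to_sql <- function(pred) {
  tryCatch(sql_node(pred$ast), wsikit_untranslatable = function(e) NULL)
}

sql_bail <- function() {
  stop(structure(class = c("wsikit_untranslatable", "condition"),
                 list(message = "untranslatable", call = NULL)))
}

sql_quote <- function(x) paste0("'", gsub("'", "''", x), "'")

sql_node <- function(node) {
  if (is.character(node)) return(sql_quote(node))
  if (is.logical(node)) return(if (isTRUE(node)) "1" else "0")
  if (is.numeric(node)) return(format(node, digits = 17))
  if (is.symbol(node)) {
    nm <- as.character(node)
    if (nm %in% c("TRUE", "T")) return("1")
    if (nm %in% c("FALSE", "F")) return("0")
    sql_bail()
  }
  if (!is.call(node)) sql_bail()
  fn <- as.character(node[[1]])
  if (fn %in% c("[[", "[", "$")) {
    if (!is.symbol(node[[2]]) || as.character(node[[2]]) != "props") sql_bail()
    key <- if (fn == "$") as.character(node[[3]]) else {
      if (!is.character(node[[3]])) sql_bail()
      node[[3]]
    }
    return(sprintf("json_extract(properties, '$.%s')", key))
  }
  op_map <- c("==" = "=", "!=" = "<>", "<" = "<", ">" = ">", "<=" = "<=",
              ">=" = ">=", "+" = "+", "-" = "-", "*" = "*", "/" = "/")
  if (fn %in% names(op_map) && length(node) == 3) {
    return(sprintf("(%s %s %s)", sql_node(node[[2]]), op_map[[fn]],
                   sql_node(node[[3]])))
  }
  if (fn == "-" && length(node) == 2) {
    return(sprintf("(-%s)", sql_node(node[[2]])))
  }
  if (fn %in% c("&", "&&") && length(node) == 3) {
    return(sprintf("(%s AND %s)", sql_node(node[[2]]), sql_node(node[[3]])))
  }
  if (fn %in% c("|", "||") && length(node) == 3) {
    return(sprintf("(%s OR %s)", sql_node(node[[2]]), sql_node(node[[3]])))
  }
  if (fn == "!" && length(node) == 2) {
    return(sprintf("(NOT %s)", sql_node(node[[2]])))
  }
  if (fn == "(") return(sql_node(node[[2]]))
  if (fn == "%in%" && length(node) == 3) {
    rhs <- node[[3]]
    items <- if (is.call(rhs) && is.symbol(rhs[[1]]) &&
                 as.character(rhs[[1]]) == "c") {
      lapply(seq_along(rhs)[-1], function(i) rhs[[i]])
    } else {
      list(rhs)
    }
    vals <- vapply(items, function(it) {
      if (is.character(it)) sql_quote(it)
      else if (is.numeric(it)) format(it, digits = 17)
      else sql_bail()
    }, character(1))
    return(sprintf("(%s IN (%s))", sql_node(node[[2]]),
                   paste(vals, collapse = ", ")))
  }
  if (fn == "abs" && length(node) == 2) {
    return(sprintf("abs(%s)", sql_node(node[[2]])))
  }
  sql_bail()
}
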