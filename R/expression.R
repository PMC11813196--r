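#' Boolean rule expressions
#'
#' The knowledge base expresses both item-enabling conditions and diagnosis
#' rules as finite Boolean trees over recorded findings. A tree node is one
#' of `atom` (a required `(item, response)` pair), `and`, `or`, `not`, or
#' the constant `true`. An atom is satisfied iff the findings map records
#' exactly the required response for the item; an unanswered item never
#' satisfies an atom ("absence of evidence"), which means negated atoms are
#' satisfied by unanswered items -- a deliberate modelling convention (see
#' the package vignette).
#'
#' @param item Item identifier the atom refers to.
#' @param response Required response (default `"present"`).
#' @param ... Child expressions for `expr_and()` / `expr_or()`.
#' @param x A child expression for `expr_not()`.
#' @return An object of class `lbp_expr`.
#' @examples
#' e <- expr_or(expr_atom("buttock_pain"), expr_atom("radiating_leg_pain"))
#' evaluate_expression(e, c(buttock_pain = "present"))
#' @name lbp_expr
NULL

new_expr <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "lbp_expr")
}

#' @rdname lbp_expr
#' @export
expr_true <- function() new_expr("true")

#' @rdname lbp_expr
#' @export
expr_atom <- function(item, response = "present") {
  stopifnot(is.character(item), length(item) == 1L,
            is.character(response), length(response) == 1L)
  new_expr("atom", item = item, response = response)
}

#' @rdname lbp_expr
#' @export
expr_and <- function(...) {
  kids <- lapply(list(...), as_expr)
  if (length(kids) == 0L) lbp_format_error("`and` requires at least one child")
  new_expr("and", children = kids)
}

#' @rdname lbp_expr
#' @export
expr_or <- function(...) {
  kids <- lapply(list(...), as_expr)
  if (length(kids) == 0L) lbp_format_error("`or` requires at least one child")
  new_expr("or", children = kids)
}

#' @rdname lbp_expr
#' @export
expr_not <- function(x) new_expr("not", child = as_expr(x))

as_expr <- function(x) {
  if (inherits(x, "lbp_expr")) return(x)
  lbp_format_error("not an expression object")
}

#' @export
print.lbp_expr <- function(x, ...) {
  cat(deparse_expr(x), "\n")
  invisible(x)
}

deparse_expr <- function(e) {
  switch(e$kind,
    true = "TRUE",
    atom = sprintf("[%s=%s]", e$item, e$response),
    not  = paste0("NOT ", deparse_expr(e$child)),
    and  = paste0("(", paste(vapply(e$children, deparse_expr, ""),
                             collapse = " AND "), ")"),
    or   = paste0("(", paste(vapply(e$children, deparse_expr, ""),
                             collapse = " OR "), ")")
  )
}

#' Atoms referenced by an expression
#'
#' Returns the set (no duplicates) of `(item, response)` pairs an
#' expression refers to, in first-mention order.
#'
#' @param expr An `lbp_expr`.
#' @return A data frame with columns `item` and `response`.
#' @export
expr_atoms <- function(expr) {
  acc <- list()
  walk <- function(e) {
    switch(e$kind,
      atom = acc[[length(acc) + 1L]] <<- c(e$item, e$response),
      not  = walk(e$child),
      and  = ,
      or   = for (k in e$children) walk(k),
      true = invisible(NULL)
    )
  }
  walk(as_expr(expr))
  if (length(acc) == 0L) {
    return(data.frame(item = character(), response = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, acc)
  df <- data.frame(item = m[, 1L], response = m[, 2L],
                   stringsAsFactors = FALSE)
  df[!duplicated(paste(df$item, df$response, sep = "\r")), , drop = FALSE]
}

expr_is_true <- function(expr) identical(expr$kind, "true")

expr_negation_free <- function(expr) {
  switch(expr$kind,
    true = TRUE,
    atom = TRUE,
    not  = FALSE,
    and  = ,
    or   = all(vapply(expr$children, expr_negation_free, logical(1L)))
  )
}

#' Evaluate a Boolean rule expression against findings
#'
#' Standard Boolean semantics. An atom is true iff `findings` records
#' exactly the required response for its item; items absent from
#' `findings` (unanswered) make their atoms false.
#'
#' @param expr An `lbp_expr`.
#' @param findings Named character vector (or named list / data frame with
#'   columns `item`, `response`) mapping item ids to responses.
#' @param kb Optional knowledge base; when supplied, atoms are checked to
#'   resolve against its items (integrity error otherwise).
#' @return Logical scalar.
#' @export
evaluate_expression <- function(expr, findings, kb = NULL) {
  f <- as_findings(findings)
  e <- as_expr(expr)
  if (!is.null(kb)) {
    at <- expr_atoms(e)
    bad <- setdiff(at$item, names(kb$items))
    if (length(bad) > 0L) {
      lbp_integrity_error(sprintf(
        "expression references unknown item(s): %s",
        paste(bad, collapse = ", ")))
    }
  }
  eval_expr_(e, f)
}

eval_expr_ <- function(e, findings) {
  switch(e$kind,
    true = TRUE,
    atom = !is.na(findings[e$item]) &&
           identical(unname(findings[e$item]), e$response),
    not  = !eval_expr_(e$child, findings),
    and  = all(vapply(e$children, eval_expr_, logical(1L), findings = findings)),
    or   = any(vapply(e$children, eval_expr_, logical(1L), findings = findings))
  )
}

# Normalise the accepted findings representations to a named character vector.
as_findings <- function(findings) {
  if (is.null(findings)) return(stats::setNames(character(), character()))
  if (is.data.frame(findings)) {
    return(stats::setNames(as.character(findings$response),
                           as.character(findings$item)))
  }
  if (is.list(findings)) {
    return(stats::setNames(vapply(findings, as.character, ""), names(findings)))
  }
  if (is.character(findings)) {
    if (length(findings) > 0L && is.null(names(findings))) {
      lbp_format_error("findings vector must be named by item id")
    }
    return(findings)
  }
  lbp_format_error("unsupported findings representation")
}

# --- (de)serialisation to the KB file dialect ------------------------------

# {"or":[{"atom":{"item":"x","response":"present"}}, ...]} etc.
parse_expr <- function(x) {
  if (is.null(x)) return(expr_true())
  if (identical(x, "true") || isTRUE(x)) return(expr_true())
  if (!is.list(x) || length(x) != 1L || is.null(names(x))) {
    lbp_format_error("malformed expression node: expected single-key object")
  }
  key <- names(x)
  val <- x[[1L]]
  switch(key,
    true = expr_true(),
    atom = {
      if (is.null(val$item)) lbp_format_error("atom missing `item` field")
      expr_atom(as.character(val$item),
                if (is.null(val$response)) "present" else as.character(val$response))
    },
    and = do.call(expr_and, lapply(val, parse_expr)),
    or  = do.call(expr_or, lapply(val, parse_expr)),
    not = expr_not(parse_expr(if (is.list(val) && is.null(names(val)) &&
                                  length(val) == 1L) val[[1L]] else val)),
    lbp_format_error(sprintf("unknown expression node kind `%s`", key))
  )
}

unparse_expr <- function(e) {
  switch(e$kind,
    true = list(true = TRUE),
    atom = list(atom = list(item = e$item, response = e$response)),
    not  = list(not = unparse_expr(e$child)),
    and  = list(and = lapply(e$children, unparse_expr)),
    or   = list(or = lapply(e$children, unparse_expr))
  )
}
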