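# Atom selection mini-language.
#
# Grammar:  expr   := and_expr ('or' and_expr)*
#           and_expr := unary ('and' unary)*
#           unary  := 'not' unary | '(' expr ')' | predicate
#           pred   := field ('==' | '!=') value
# Fields: residue_name, residue_id, chain, element, group, name.
# Values are bare tokens (PHE, 228, NZ); matching on string fields is
# case-sensitive except element, which is normalised.

tokenize_selection <- function(expression) {
  tokens <- list()
  i <- 1L
  n <- nchar(expression)
  while (i <= n) {
    rest <- substr(expression, i, n)
    ws <- regmatches(rest, regexpr("^\\s+", rest))
    if (length(ws) == 1) { i <- i + nchar(ws); next }
    rest <- substr(expression, i, n)
    m <- regmatches(rest, regexpr("^(==|!=|\\(|\\)|[A-Za-z0-9_*'+-]+)", rest))
    if (length(m) == 0) {
      stop("selection syntax error at position ", i, ": unexpected character '",
           substr(expression, i, i), "'")
    }
    tokens[[length(tokens) + 1L]] <- list(text = m, pos = i)
    i <- i + nchar(m)
  }
  tokens
}

selection_parser <- function(tokens, structure) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { tok <- peek(); pos <<- pos + 1L; tok }
  expect <- function(text) {
    tok <- advance()
    if (is.null(tok) || tok$text != text) {
      stop("selection syntax error at position ",
           if (is.null(tok)) nchar_end else tok$pos, ": expected '", text, "'")
    }
    tok
  }
  nchar_end <- if (length(tokens) > 0) {
    last <- tokens[[length(tokens)]]; last$pos + nchar(last$text)
  } else 1L
  natoms <- n_atoms(structure)
  a <- structure$atoms

  eval_predicate <- function(field_tok, op, value_tok) {
    field <- field_tok$text
    value <- value_tok$text
    mask <- switch(field,
      residue_name = a$residue_name == value,
      residue_id = a$residue_id == suppressWarnings(as.integer(value)),
      chain = , chain_id = a$chain_id == value,
      element = toupper(a$element) == toupper(value),
      name = a$name == value,
      group = {
        if (!(value %in% names(structure$groups))) {
          stop("unknown group '", value, "' in selection (position ",
               value_tok$pos, ")")
        }
        seq_len(natoms) %in% structure$groups[[value]]
      },
      stop("selection syntax error at position ", field_tok$pos,
           ": unknown field '", field, "'"))
    mask[is.na(mask)] <- FALSE
    if (op == "!=") mask <- !mask
    mask
  }

  parse_unary <- function() {
    tok <- peek()
    if (is.null(tok)) {
      stop("selection syntax error at position ", nchar_end,
           ": unexpected end of expression")
    }
    if (tolower(tok$text) == "not") { advance(); return(!parse_unary()) }
    if (tok$text == "(") {
      advance()
      out <- parse_or()
      expect(")")
      return(out)
    }
    field_tok <- advance()
    op_tok <- advance()
    if (is.null(op_tok) || !(op_tok$text %in% c("==", "!="))) {
      stop("selection syntax error at position ",
           if (is.null(op_tok)) nchar_end else op_tok$pos,
           ": expected '==' or '!=' after field '", field_tok$text, "'")
    }
    value_tok <- advance()
    if (is.null(value_tok)) {
      stop("selection syntax error at position ", nchar_end,
           ": expected a value")
    }
    eval_predicate(field_tok, op_tok$text, value_tok)
  }

  parse_and <- function() {
    out <- parse_unary()
    while (!is.null(peek()) && tolower(peek()$text) == "and") {
      advance()
      out <- out & parse_unary()
    }
    out
  }

  parse_or <- function() {
    out <- parse_and()
    while (!is.null(peek()) && tolower(peek()$text) == "or") {
      advance()
      out <- out | parse_and()
    }
    out
  }

  mask <- parse_or()
  if (pos <= length(tokens)) {
    stop("selection syntax error at position ", tokens[[pos]]$pos,
         ": unexpected token '", tokens[[pos]]$text, "'")
  }
  mask
}

#' Resolve an atom selection expression
#'
#' Deterministically evaluates a boolean combination of field predicates
#' (with `and`, `or`, `not`, parentheses) against a structure. An empty
#' resolution is a valid `md_selection`, distinguishable from a syntax or
#' unknown-group error.
#'
#' @param structure an `md_structure`.
#' @param expression selection string, e.g.
#'   `"residue_name == PHE and residue_id == 228"` or `"group == cnt"`.
#' @return an `md_selection` with fields `expression` and `resolved`
#'   (sorted integer atom indices, 1-based).
#' @export
resolve_selection <- function(structure, expression) {
  if (!nzchar(trimws(expression))) {
    stop("selection syntax error at position 1: empty expression")
  }
  tokens <- tokenize_selection(expression)
  mask <- selection_parser(tokens, structure)
  structure(list(expression = expression, resolved = which(mask)),
            class = "md_selection")
}

#' Build a selection directly from atom indices
#' @param structure an `md_structure`.
#' @param indices 1-based atom indices.
#' @param label optional expression label.
#' @return an `md_selection`.
#' @export
selection_from_indices <- function(structure, indices, label = "<indices>") {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) > 0 &&
      (min(indices) < 1L || max(indices) > n_atoms(structure))) {
    stop("selection indices out of range")
  }
  structure(list(expression = label, resolved = indices),
            class = "md_selection")
}

#' @export
print.md_selection <- function(x, ...) {
  cat("md_selection:", length(x$resolved), "atoms <-", x$expression, "\n")
  invisible(x)
}

# internal: accept either an md_selection or a raw index vector
selection_indices <- function(sel) {
  if (inherits(sel, "md_selection")) sel$resolved else as.integer(sel)
}

#' Split a selection by residue
#'
#' @param structure an `md_structure`.
#' @param selection an `md_selection` (or index vector).
#' @return named list of `md_selection`s, one per residue, named
#'   `"<residue_name><residue_id>:<chain>"`.
#' @export
split_by_residue <- function(structure, selection) {
  idx <- selection_indices(selection)
  a <- structure$atoms[idx, , drop = FALSE]
  key <- paste0(a$residue_name, a$residue_id, ":", a$chain_id)
  out <- lapply(split(idx, key), function(ii) {
    selection_from_indices(structure, ii)
  })
  out[unique(key)]
}
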