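# Typed tabular metadata. An em_table is a tibble carrying a "ctypes"
# attribute that pins each column to one of the four metadata column types
# (int, float, string, bool); missing values are plain NA. All verbs take
# the table first and return a new em_table, so they compose with the pipe.

.CTYPES <- c("int", "float", "string", "bool")

.ctype_of_vector <- function(x) {
  if (is.integer(x)) "int"
  else if (is.double(x)) "float"
  else if (is.character(x)) "string"
  else if (is.logical(x)) "bool"
  else stop("unsupported column class: ", class(x)[1], call. = FALSE)
}

.vector_of_ctype <- function(ctype, n) {
  switch(ctype,
         int = integer(n), float = double(n), string = character(n),
         bool = logical(n))
}

.check_col_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name) ||
      grepl("[[:space:]]", name)) {
    stop("column name must be a non-empty string without whitespace",
         call. = FALSE)
  }
  name
}

#' Construct a typed metadata table
#'
#' Wraps a data frame / tibble as an `em_table`, recording each column's
#' metadata type: `int`, `float`, `string` or `bool`. Column names must be
#' non-empty, unique and free of whitespace. Missing values are `NA`.
#'
#' @param x A data frame or tibble.
#' @param ctypes Optional character vector of column types; by default they
#'   are taken from the R column classes (integer, double, character,
#'   logical).
#' @return An `em_table` (a tibble subclass).
#' @examples
#' em_table(tibble::tibble(id = 1:3, defocus = c(1.2, 2.5, 1.8)))
#' @export
em_table <- function(x = NULL, ctypes = NULL) {
  if (is.null(x)) x <- tibble::tibble()
  tbl <- tibble::as_tibble(x)
  nm <- names(tbl)
  if (anyDuplicated(nm)) {
    stop("duplicate column names", call. = FALSE)
  }
  for (n in nm) .check_col_name(n)
  if (is.null(ctypes)) {
    ctypes <- vapply(tbl, .ctype_of_vector, character(1))
  } else {
    ctypes <- stats::setNames(as.character(ctypes), nm)
    if (!all(ctypes %in% .CTYPES)) {
      stop("ctypes must be in {", paste(.CTYPES, collapse = ", "), "}",
           call. = FALSE)
    }
  }
  attr(tbl, "ctypes") <- ctypes
  class(tbl) <- c("em_table", class(tibble::tibble()))
  tbl
}

#' @export
is_em_table <- function(x) inherits(x, "em_table")

#' Column types of a table
#'
#' @param t An `em_table`.
#' @return Named character vector of column ctypes.
#' @export
table_ctypes <- function(t) {
  stopifnot(is_em_table(t))
  ct <- attr(t, "ctypes")
  if (is.null(ct)) ct <- vapply(t, .ctype_of_vector, character(1))
  ct
}

.retype <- function(t, ctypes) {
  attr(t, "ctypes") <- ctypes
  class(t) <- c("em_table", class(tibble::tibble()))
  t
}

#' Append a typed column
#'
#' Adds a new column at the end of the table, filling existing rows with a
#' default value.
#'
#' @param t An `em_table`.
#' @param name New column name (unique, no whitespace).
#' @param ctype One of `"int"`, `"float"`, `"string"`, `"bool"`.
#' @param default Fill value for existing rows; must be valid for `ctype`
#'   (`NA` marks missing).
#' @return The extended `em_table`.
#' @export
table_add_column <- function(t, name, ctype, default = NA) {
  stopifnot(is_em_table(t))
  .check_col_name(name)
  if (name %in% names(t)) {
    stop("column '", name, "' already exists", call. = FALSE)
  }
  if (!ctype %in% .CTYPES) {
    stop("unknown ctype: ", ctype, call. = FALSE)
  }
  if (length(default) != 1L) {
    stop("default must be a single value", call. = FALSE)
  }
  col <- .vector_of_ctype(ctype, nrow(t))
  if (is.na(default)) {
    col[] <- NA
  } else {
    ok <- switch(ctype,
                 int = is.numeric(default) && default == as.integer(default),
                 float = is.numeric(default),
                 string = is.character(default),
                 bool = is.logical(default))
    if (!isTRUE(ok)) {
      stop("default value is not valid for ctype ", ctype, call. = FALSE)
    }
    col[] <- switch(ctype, int = as.integer(default),
                    float = as.double(default), string = default,
                    bool = default)
  }
  out <- t
  out[[name]] <- col
  .retype(out, c(table_ctypes(t), stats::setNames(ctype, name)))
}

#' Drop a column
#'
#' @param t An `em_table`.
#' @param name Column to remove.
#' @return The reduced `em_table`.
#' @export
table_remove_column <- function(t, name) {
  stopifnot(is_em_table(t))
  if (!name %in% names(t)) {
    stop("unknown column: ", name, call. = FALSE)
  }
  ct <- table_ctypes(t)
  out <- t[setdiff(names(t), name)]
  .retype(out, ct[setdiff(names(t), name)])
}

#' Select columns, preserving table typing
#'
#' @param t An `em_table`.
#' @param cols Character vector of column names, in the desired order.
#' @return An `em_table` with only those columns.
#' @export
table_select <- function(t, cols) {
  stopifnot(is_em_table(t))
  missing <- setdiff(cols, names(t))
  if (length(missing)) {
    stop("unknown column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  .retype(t[cols], table_ctypes(t)[cols])
}

# --- filter ----------------------------------------------------------------

# Rewrite the word operators and/or/not to &/|/! outside quoted strings.
.rewrite_filter_words <- function(expr) {
  pat <- "\"[^\"]*\"|'[^']*'"
  m <- gregexpr(pat, expr)[[1]]
  if (m[1] == -1) {
    quoted <- character(0)
    parts <- expr
  } else {
    quoted <- regmatches(expr, gregexpr(pat, expr))[[1]]
    parts <- strsplit(expr, pat)[[1]]
    if (length(parts) < length(quoted) + 1L) {
      parts <- c(parts, rep("", length(quoted) + 1L - length(parts)))
    }
  }
  fix <- function(s) {
    s <- gsub("\\band\\b", "&", s)
    s <- gsub("\\bor\\b", "|", s)
    gsub("\\bnot\\b", "!", s)
  }
  parts <- vapply(parts, fix, character(1))
  out <- parts[1]
  for (i in seq_along(quoted)) out <- paste0(out, quoted[i], parts[i + 1L])
  out
}

.CMP_OPS <- c("==", "!=", "<", "<=", ">", ">=")

# Validate the parsed filter AST: only comparisons, &/|/!, parentheses,
# column symbols and literals. Returns "num" / "chr" / "lgl" for value
# nodes and "cond" for boolean subexpressions.
.check_filter_node <- function(node, ctypes) {
  if (is.name(node)) {
    nm <- as.character(node)
    if (nm %in% c("TRUE", "FALSE")) return("lgl")
    if (!nm %in% names(ctypes)) {
      stop("unknown column in filter expression: ", nm, call. = FALSE)
    }
    return(switch(ctypes[[nm]], int = "num", float = "num",
                  string = "chr", bool = "lgl"))
  }
  if (is.numeric(node)) return("num")
  if (is.character(node)) return("chr")
  if (is.logical(node)) return("lgl")
  if (is.call(node)) {
    op <- as.character(node[[1]])
    if (op == "(") return(.check_filter_node(node[[2]], ctypes))
    if (op == "!") {
      t1 <- .check_filter_node(node[[2]], ctypes)
      if (!t1 %in% c("cond", "lgl")) {
        stop("'not' applied to a non-boolean expression", call. = FALSE)
      }
      return("cond")
    }
    if (op %in% c("&", "|")) {
      t1 <- .check_filter_node(node[[2]], ctypes)
      t2 <- .check_filter_node(node[[3]], ctypes)
      if (!all(c(t1, t2) %in% c("cond", "lgl"))) {
        stop("'", op, "' applied to non-boolean operands", call. = FALSE)
      }
      return("cond")
    }
    if (op %in% .CMP_OPS) {
      t1 <- .check_filter_node(node[[2]], ctypes)
      t2 <- .check_filter_node(node[[3]], ctypes)
      if (t1 == "cond" || t2 == "cond") {
        stop("comparison of boolean subexpressions is not supported",
             call. = FALSE)
      }
      if (t1 != t2) {
        stop("type mismatch in comparison: ", deparse(node), call. = FALSE)
      }
      if (op %in% c("<", "<=", ">", ">=") && t1 == "lgl") {
        stop("ordering comparison on boolean values", call. = FALSE)
      }
      return("cond")
    }
    stop("unsupported operator in filter expression: ", op, call. = FALSE)
  }
  stop("unsupported token in filter expression", call. = FALSE)
}

#' Filter rows with a comparison expression
#'
#' Keeps the rows satisfying a small boolean expression over the table's
#' columns: the six comparison operators combined with `and` / `or` / `not`
#' (or `&` / `|` / `!`) and parentheses. String literals are quoted. Rows
#' where the expression is missing (because a compared value is missing) are
#' dropped. Original row order is preserved.
#'
#' @param t An `em_table`.
#' @param expr Filter expression as a string, e.g.
#'   `"defocus < 2.0 and id > 1"`.
#' @return The filtered `em_table`.
#' @export
table_filter <- function(t, expr) {
  stopifnot(is_em_table(t))
  if (!is.character(expr) || length(expr) != 1L) {
    stop("expr must be a single string", call. = FALSE)
  }
  code <- .rewrite_filter_words(expr)
  parsed <- tryCatch(parse(text = code, keep.source = FALSE),
                     error = function(e) {
                       stop("cannot parse filter expression: ", expr,
                            call. = FALSE)
                     })
  if (length(parsed) != 1L) {
    stop("filter expression must be a single expression", call. = FALSE)
  }
  node <- parsed[[1]]
  .check_filter_node(node, table_ctypes(t))
  keep <- eval(node, envir = as.list(t), enclos = baseenv())
  keep <- rep_len(keep, nrow(t))
  .retype(t[which(keep %in% TRUE), ], table_ctypes(t))
}

#' Sort rows by one column
#'
#' Stable sort: rows with equal keys keep their input order, so sorting is
#' idempotent and a descending sort is the exact reverse of ascending over
#' distinct keys.
#'
#' @param t An `em_table`.
#' @param key Column to sort by (int, float, string or bool).
#' @param ascending Sort direction (default `TRUE`). Missing values go last.
#' @return The sorted `em_table`.
#' @export
table_sort <- function(t, key, ascending = TRUE) {
  stopifnot(is_em_table(t))
  if (!key %in% names(t)) {
    stop("unknown column: ", key, call. = FALSE)
  }
  ord <- order(t[[key]], method = "radix", decreasing = !ascending,
               na.last = TRUE)
  .retype(t[ord, ], table_ctypes(t))
}

#' Column summary statistics
#'
#' Count, range and moments of a numeric column, excluding missing values.
#' The standard deviation uses the population formula (divide by N),
#' consistent with [image_stats()].
#'
#' @param t An `em_table`.
#' @param key Numeric (int or float) column name.
#' @return A one-row tibble with `count`, `min`, `max`, `mean`, `sd`.
#' @examples
#' t <- em_table(tibble::tibble(defocus = c(1.2, 2.5, 1.8, 3.0)))
#' table_stats(t, "defocus")
#' @export
table_stats <- function(t, key) {
  stopifnot(is_em_table(t))
  if (!key %in% names(t)) {
    stop("unknown column: ", key, call. = FALSE)
  }
  if (!table_ctypes(t)[[key]] %in% c("int", "float")) {
    stop("column '", key, "' is not numeric", call. = FALSE)
  }
  x <- t[[key]]
  x <- as.double(x[!is.na(x)])
  if (length(x) == 0L) {
    return(tibble::tibble(count = 0L, min = NA_real_, max = NA_real_,
                          mean = NA_real_, sd = NA_real_))
  }
  m <- .buffer_moments(x)
  tibble::tibble(count = length(x), min = m[1], max = m[2], mean = m[3],
                 sd = m[4])
}
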