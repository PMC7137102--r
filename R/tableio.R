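# STAR (RELION dialect) and delimited-text table serialization. A STAR
# document is an ordered named list of em_table blocks. Loops become
# multi-row tables; key-value blocks become single-row tables. Missing
# values are the STAR tokens "." and "?" on read and "." on write.

.STAR_MISSING <- c(".", "?")

# Split one data line into tokens, honouring single/double quotes.
.star_tokens <- function(line) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  tokens <- character(0)
  buf <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) {
      if (length(buf)) {
        tokens <- c(tokens, paste(buf, collapse = ""))
        buf <- character(0)
      }
      i <- i + 1L
    } else if (ch %in% c("\"", "'") && !length(buf)) {
      q <- ch
      j <- i + 1L
      while (j <= n && chars[j] != q) j <- j + 1L
      if (j > n) {
        stop("unterminated quote in line: ", line, call. = FALSE)
      }
      tokens <- c(tokens, paste(chars[seq(i + 1L, length.out = j - i - 1L)],
                                collapse = ""))
      i <- j + 1L
      if (i <= n && !chars[i] %in% c(" ", "\t")) {
        stop("malformed quoted token in line: ", line, call. = FALSE)
      }
    } else {
      buf <- c(buf, ch)
      i <- i + 1L
    }
  }
  if (length(buf)) tokens <- c(tokens, paste(buf, collapse = ""))
  tokens
}

# Deterministic column typing shared by the STAR and TSV readers: int if
# every non-missing token is an integer literal, else float if every token
# parses as a number, else string.
.infer_column <- function(tokens, missing_tokens = .STAR_MISSING) {
  miss <- tokens %in% missing_tokens
  vals <- tokens[!miss]
  if (length(vals) && all(grepl("^[+-]?[0-9]+$", vals)) &&
      !anyNA(suppressWarnings(as.integer(vals)))) {
    out <- rep(NA_integer_, length(tokens))
    out[!miss] <- as.integer(vals)
    return(out)
  }
  num <- suppressWarnings(as.numeric(vals))
  if (length(vals) && !anyNA(num)) {
    out <- rep(NA_real_, length(tokens))
    out[!miss] <- num
    return(out)
  }
  out <- rep(NA_character_, length(tokens))
  out[!miss] <- vals
  out
}

.columns_to_table <- function(colnames, token_matrix) {
  cols <- lapply(seq_along(colnames), function(j) {
    .infer_column(token_matrix[, j])
  })
  names(cols) <- colnames
  em_table(tibble::as_tibble(cols, .name_repair = "minimal"))
}

#' Read a STAR metadata file
#'
#' Parses a RELION-dialect STAR file into an ordered, named list of
#' [em_table()] blocks (one per `data_<name>` block). `loop_` blocks become
#' multi-row tables with column order taken from the `_label #N` ordinals
#' when present; bare key-value blocks become single-row tables. Full-line
#' `#` comments and blank lines are ignored; quoted tokens keep embedded
#' whitespace; multi-line semicolon-delimited text fields are read as single
#' string values. Column types are inferred deterministically: int, else
#' float, else string.
#'
#' @param path Path to the STAR file.
#' @return A named list of `em_table` objects (class `star_document`).
#' @export
read_star <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  doc <- list()
  i <- 1L
  nline <- length(lines)
  trim <- function(s) sub("[[:space:]]+$", "", sub("^[[:space:]]+", "", s))

  skip_blank <- function(i) {
    while (i <= nline) {
      l <- trim(lines[i])
      if (nzchar(l) && !startsWith(l, "#")) break
      i <- i + 1L
    }
    i
  }

  # read one (possibly multi-line ;-delimited) sequence of tokens
  line_tokens <- function(i) {
    l <- trim(lines[i])
    if (startsWith(l, ";")) {
      txt <- character(0)
      first <- sub("^;", "", l)
      if (nzchar(first)) txt <- first
      j <- i + 1L
      while (j <= nline && !startsWith(trim(lines[j]), ";")) {
        txt <- c(txt, lines[j])
        j <- j + 1L
      }
      if (j > nline) {
        stop("unterminated semicolon text field", call. = FALSE)
      }
      return(list(tokens = paste(txt, collapse = "\n"), nexti = j + 1L))
    }
    list(tokens = .star_tokens(l), nexti = i + 1L)
  }

  while (TRUE) {
    i <- skip_blank(i)
    if (i > nline) break
    l <- trim(lines[i])
    if (!startsWith(l, "data_")) {
      stop("expected a data_ block, found: ", l, call. = FALSE)
    }
    block_name <- sub("^data_", "", l)
    if (block_name %in% names(doc)) {
      stop("duplicate block name: ", block_name, call. = FALSE)
    }
    i <- skip_blank(i + 1L)
    if (i > nline) {
      doc[[block_name]] <- em_table()
      break
    }
    l <- trim(lines[i])
    if (startsWith(l, "loop_")) {
      i <- skip_blank(i + 1L)
      labels <- character(0)
      ordinals <- integer(0)
      while (i <= nline) {
        l <- trim(lines[i])
        if (!startsWith(l, "_")) break
        parts <- .star_tokens(l)
        lab <- sub("^_", "", parts[1])
        ord <- NA_integer_
        if (length(parts) >= 2L && grepl("^#[0-9]+$", parts[2])) {
          ord <- as.integer(sub("^#", "", parts[2]))
        }
        labels <- c(labels, lab)
        ordinals <- c(ordinals, ord)
        i <- skip_blank(i + 1L)
      }
      if (anyDuplicated(labels)) {
        stop("duplicate labels in loop of block ", block_name, call. = FALSE)
      }
      if (!length(labels)) {
        stop("loop_ with no labels in block ", block_name, call. = FALSE)
      }
      if (all(!is.na(ordinals))) {
        ord <- order(ordinals)
        labels <- labels[ord]
      }
      tokens <- character(0)
      while (i <= nline) {
        l <- trim(lines[i])
        if (!nzchar(l) || startsWith(l, "#")) { i <- i + 1L; next }
        if (startsWith(l, "data_") || startsWith(l, "loop_") ||
            startsWith(l, "_")) break
        lt <- line_tokens(i)
        tokens <- c(tokens, lt$tokens)
        i <- lt$nexti
      }
      nc <- length(labels)
      if (length(tokens) %% nc != 0L) {
        stop("loop in block '", block_name, "' has ", length(tokens),
             " values for ", nc, " columns", call. = FALSE)
      }
      mat <- matrix(tokens, ncol = nc, byrow = TRUE)
      doc[[block_name]] <- .columns_to_table(labels, mat)
    } else {
      # key-value block: one-row table
      labels <- character(0)
      values <- character(0)
      while (i <= nline) {
        l <- trim(lines[i])
        if (!nzchar(l) || startsWith(l, "#")) { i <- i + 1L; next }
        if (startsWith(l, "data_") || startsWith(l, "loop_")) break
        if (!startsWith(l, "_")) {
          stop("unexpected line in key-value block '", block_name, "': ", l,
               call. = FALSE)
        }
        parts <- .star_tokens(l)
        if (length(parts) != 2L) {
          stop("key-value line must hold exactly one value: ", l,
               call. = FALSE)
        }
        lab <- sub("^_", "", parts[1])
        if (lab %in% labels) {
          stop("duplicate labels in block ", block_name, call. = FALSE)
        }
        labels <- c(labels, lab)
        values <- c(values, parts[2])
        i <- i + 1L
      }
      doc[[block_name]] <- .columns_to_table(
        labels, matrix(values, nrow = 1L))
    }
  }
  structure(doc, class = "star_document")
}

# shortest decimal representation that round-trips through as.numeric
.format_double <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    for (d in 1:17) {
      s <- trimws(formatC(v, digits = d, format = "g"))
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

.star_format_column <- function(x, ctype) {
  out <- switch(ctype,
    int = ifelse(is.na(x), NA_character_, sprintf("%d", as.integer(x))),
    float = .format_double(as.double(x)),
    bool = ifelse(is.na(x), NA_character_, ifelse(x, "1", "0")),
    string = {
      s <- as.character(x)
      needs_quote <- !is.na(s) &
        (grepl("[[:space:]]", s) | s %in% .STAR_MISSING | !nzchar(s) |
           grepl("^[_#;]", s) | grepl("['\"]", s))
      if (any(needs_quote & grepl("\"", s) & grepl("'", s), na.rm = TRUE)) {
        stop("cannot serialize a string containing both quote characters",
             call. = FALSE)
      }
      q <- ifelse(grepl("\"", s), "'", "\"")
      ifelse(needs_quote, paste0(q, s, q), s)
    })
  out[is.na(out)] <- "."
  out
}

#' Write a STAR metadata file
#'
#' Serializes a document (named list of [em_table()]s, or a single table) in
#' the RELION STAR dialect: `data_<name>` blocks with `loop_` tables and
#' `_label #N` ordinal suffixes. Floats use the shortest decimal
#' representation that round-trips, strings with embedded whitespace are
#' quoted, and missing values are written as `"."`, so
#' `read_star(write_star(doc))` reproduces block names, columns, row counts
#' and values.
#'
#' @param doc A named list of `em_table`s, or one `em_table` (written as a
#'   block named `"table"`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_star <- function(doc, path) {
  if (is_em_table(doc)) doc <- list(table = doc)
  if (!length(doc) || is.null(names(doc)) || any(!nzchar(names(doc)))) {
    stop("doc must be a named list of em_table blocks", call. = FALSE)
  }
  if (anyDuplicated(names(doc))) {
    stop("duplicate block names", call. = FALSE)
  }
  out <- character(0)
  for (bn in names(doc)) {
    t <- doc[[bn]]
    stopifnot(is_em_table(t))
    ct <- table_ctypes(t)
    out <- c(out, paste0("data_", bn), "", "loop_")
    out <- c(out, sprintf("_%s #%d", names(t), seq_along(t)))
    if (nrow(t) > 0L) {
      cols <- lapply(names(t), function(nm) {
        .star_format_column(t[[nm]], ct[[nm]])
      })
      out <- c(out, do.call(paste, cols))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a delimited text table
#'
#' Reads a header-row delimited file (TSV by default) with the same
#' deterministic column-type inference as the STAR reader. Empty fields and
#' `NA` tokens are missing values. Ragged rows are an error.
#'
#' @param path Input path.
#' @param delimiter Field separator (default tab).
#' @return An `em_table`.
#' @export
read_tsv_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    stop("delimited file has no header row: ", path, call. = FALSE)
  }
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  header <- parts[[1]]
  nc <- length(header)
  body <- parts[-1]
  # strsplit drops a trailing empty field; restore it
  body <- lapply(seq_along(body), function(k) {
    p <- body[[k]]
    if (length(p) == nc - 1L && endsWith(lines[k + 1L], delimiter)) {
      p <- c(p, "")
    }
    p
  })
  bad <- which(lengths(body) != nc)
  if (length(bad)) {
    stop("ragged row ", bad[1] + 1L, ": expected ", nc, " fields, found ",
         lengths(body)[bad[1]], call. = FALSE)
  }
  mat <- if (length(body)) do.call(rbind, body) else
    matrix(character(0), ncol = nc)
  cols <- lapply(seq_len(nc), function(j) {
    .infer_column(mat[, j], missing_tokens = c("", "NA"))
  })
  names(cols) <- header
  em_table(tibble::as_tibble(cols, .name_repair = "minimal"))
}

#' Write a delimited text table
#'
#' Writes a header row plus one line per row. Numeric values use the
#' shortest round-trip decimal representation; missing values are written as
#' empty fields. Values containing the delimiter or a newline are an error
#' (the format has no quoting).
#'
#' @param t An `em_table`.
#' @param path Output path.
#' @param delimiter Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(t, path, delimiter = "\t") {
  stopifnot(is_em_table(t))
  ct <- table_ctypes(t)
  cols <- lapply(names(t), function(nm) {
    x <- t[[nm]]
    s <- switch(ct[[nm]],
                int = ifelse(is.na(x), "", sprintf("%d", as.integer(x))),
                float = { v <- .format_double(as.double(x))
                          ifelse(is.na(v), "", v) },
                bool = ifelse(is.na(x), "", ifelse(x, "1", "0")),
                string = ifelse(is.na(x), "", as.character(x)))
    if (any(grepl(delimiter, s, fixed = TRUE)) || any(grepl("\n", s))) {
      stop("value in column '", nm, "' contains the delimiter or a newline",
           call. = FALSE)
    }
    s
  })
  header <- paste(names(t), collapse = delimiter)
  rows <- if (nrow(t)) do.call(paste, c(cols, sep = delimiter)) else
    character(0)
  writeLines(c(header, rows), path)
  invisible(path)
}
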