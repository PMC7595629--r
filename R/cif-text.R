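# Text CIF 1.1 reader and writer (PDBx/mmCIF dialect).
#
# The tokenizer is line-oriented: semicolon-delimited text fields are
# assembled first, then each remaining line is split with a single regular
# expression.  Quoted strings follow the CIF 1.1 rule that a closing quote
# must be followed by whitespace or end of line, so embedded quote
# characters (as in 'it's') survive.  `#` starts a comment only at a token
# boundary; a quote character inside an unquoted token (C1') is ordinary.

# Alternatives are ordered: quoted forms, comment, bare token.
.cif_token_re <- "('.*?'(?=[ \t]|$))|(\".*?\"(?=[ \t]|$))|(#.*$)|([^ \t]+)"

# Tokenize CIF text into a data.frame of tokens with line numbers.
# kind: "value" (bare), "squoted", "dquoted", "multiline", later refined by
# the parser into headers/tags/keywords.
tokenize_cif <- function(text) {
  text <- paste(text, collapse = "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (!length(lines)) lines <- ""
  n <- length(lines)
  tok_text <- vector("list", n)
  tok_kind <- vector("list", n)
  tok_line <- vector("list", n)
  i <- 1L
  while (i <= n) {
    line <- lines[[i]]
    if (startsWith(line, ";")) {
      # semicolon-delimited text field: runs to the next line starting ';'
      start <- i
      body <- substring(line, 2L)
      i <- i + 1L
      closed <- FALSE
      while (i <= n) {
        if (startsWith(lines[[i]], ";")) {
          closed <- TRUE
          break
        }
        body <- c(body, lines[[i]])
        i <- i + 1L
      }
      if (!closed) {
        cif_stop("cif_parse_error",
                 "unterminated semicolon text field starting at line ", start)
      }
      # the opening ';' line's remainder is the first value line; when it is
      # empty the value starts at the next line (the usual mmCIF layout)
      if (length(body) > 1L && body[[1]] == "") body <- body[-1]
      tok_text[[start]] <- paste(body, collapse = "\n")
      tok_kind[[start]] <- "multiline"
      tok_line[[start]] <- start
      # anything after the closing ';' on the same line is tokenized normally
      rest <- substring(lines[[i]], 2L)
      if (nzchar(trimws(rest))) {
        got <- tokenize_line(rest, i)
        tok_text[[i]] <- got$text
        tok_kind[[i]] <- got$kind
        tok_line[[i]] <- got$line
      }
      i <- i + 1L
    } else {
      if (nzchar(line)) {
        got <- tokenize_line(line, i)
        tok_text[[i]] <- got$text
        tok_kind[[i]] <- got$kind
        tok_line[[i]] <- got$line
      }
      i <- i + 1L
    }
  }
  list(text = unlist(tok_text, use.names = FALSE) %||% character(0),
       kind = unlist(tok_kind, use.names = FALSE) %||% character(0),
       line = unlist(tok_line, use.names = FALSE) %||% integer(0))
}

tokenize_line <- function(line, lineno) {
  m <- gregexpr(.cif_token_re, line, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list(text = character(0), kind = character(0),
                               line = integer(0)))
  toks <- regmatches(line, list(m))[[1]]
  first <- substring(toks, 1L, 1L)
  keep <- first != "#"
  toks <- toks[keep]
  first <- first[keep]
  if (!length(toks)) return(list(text = character(0), kind = character(0),
                                 line = integer(0)))
  kind <- rep("value", length(toks))
  sq <- first == "'"
  dq <- first == "\""
  # a bare token starting with a quote is an unterminated quoted value
  bad <- (sq & !grepl("'$", toks)) | (dq & !grepl("\"$", toks)) |
    ((sq | dq) & nchar(toks) < 2L)
  if (any(bad)) {
    cif_stop("cif_parse_error", "unterminated quoted value at line ", lineno,
             ": ", toks[bad][1])
  }
  kind[sq] <- "squoted"
  kind[dq] <- "dquoted"
  txt <- toks
  txt[sq | dq] <- substring(toks[sq | dq], 2L, nchar(toks[sq | dq]) - 1L)
  list(text = txt, kind = kind, line = rep(lineno, length(toks)))
}

#' Parse text CIF into the generic data model
#'
#' Accepts the CIF 1.1 / STAR-derived syntax used by PDBx/mmCIF: `data_`
#' blocks, key-value items, `loop_` tables, single/double-quoted values,
#' semicolon-delimited multiline text fields and `#` comments.  Bare `?` and
#' `.` tokens become cells of kind `"unknown"` and `"not_present"`; quoted
#' `'?'` / `'.'` are ordinary strings.  `save_` frames and `global_` sections
#' (dictionary syntax) are tolerated and skipped.
#'
#' @param text CIF source: a single string or a character vector of lines.
#' @return A [cif_file].
#' @export
parse_cif <- function(text) {
  tk <- tokenize_cif(text)
  n <- length(tk$text)
  blocks <- list()
  # accumulate per block: categories as env name -> list(cols = named list of
  # list(values, kinds), order = character())
  cur_header <- NULL
  cur_cats <- NULL
  cat_order <- character(0)
  in_save <- FALSE

  flush_block <- function() {
    if (is.null(cur_header)) return()
    cats <- lapply(cat_order, function(cn) {
      cc <- cur_cats[[cn]]
      cols <- lapply(cc$order, function(coln) {
        cif_column(coln, cc$cols[[coln]]$values, cc$cols[[coln]]$kinds)
      })
      cif_category(cn, cols)
    })
    blocks[[length(blocks) + 1L]] <<- cif_block(cur_header, cats)
  }

  add_column <- function(cat, col, values, kinds, lineno) {
    if (is.null(cur_cats[[cat]])) {
      cur_cats[[cat]] <<- list(cols = list(), order = character(0))
      cat_order <<- c(cat_order, cat)
    }
    cc <- cur_cats[[cat]]
    if (!is.null(cc$cols[[col]])) {
      cif_stop("cif_parse_error", "duplicate tag _", cat, ".", col,
               " at line ", lineno)
    }
    nexist <- if (length(cc$cols)) length(cc$cols[[1]]$values) else NULL
    if (!is.null(nexist) && nexist != length(values)) {
      cif_stop("cif_parse_error", "category '", cat,
               "' given conflicting row counts (", nexist, " vs ",
               length(values), ") near line ", lineno)
    }
    cc$cols[[col]] <- list(values = values, kinds = kinds)
    cc$order <- c(cc$order, col)
    cur_cats[[cat]] <<- cc
  }

  # structural tokens: tags and keywords terminate a run of loop values
  bare_all <- tk$kind == "value"
  is_tag_all <- bare_all & startsWith(tk$text, "_")
  is_kw_all <- bare_all & grepl("^(data_|loop_$|save_|global_$)", tk$text,
                                ignore.case = TRUE)
  stop_idx <- which(is_tag_all | is_kw_all)

  values_of <- function(idx) {
    txt <- tk$text[idx]
    kinds <- rep(KIND_PRESENT, length(idx))
    bare <- bare_all[idx]
    kinds[bare & txt == "?"] <- KIND_UNKNOWN
    kinds[bare & txt == "."] <- KIND_NOT_PRESENT
    txt[kinds != KIND_PRESENT] <- ""
    list(payloads = txt, kinds = kinds)
  }
  split_tag <- function(tag, lineno) {
    body <- substring(tag, 2L)
    dot <- regexpr(".", body, fixed = TRUE)
    if (dot == -1L) return(c(body, body))
    c(substring(body, 1L, dot - 1L), substring(body, dot + 1L))
  }

  i <- 1L
  while (i <= n) {
    txt <- tk$text[[i]]
    kd <- tk$kind[[i]]
    bare <- kd == "value"
    if (bare && grepl("^data_", txt, ignore.case = TRUE)) {
      flush_block()
      cur_header <- substring(txt, 6L)
      if (!nzchar(cur_header)) {
        cif_stop("cif_parse_error", "empty data block header at line ",
                 tk$line[[i]])
      }
      cur_cats <- list()
      cat_order <- character(0)
      in_save <- FALSE
      i <- i + 1L
    } else if (bare && grepl("^save_", txt, ignore.case = TRUE)) {
      # dictionary save frames are skipped wholesale; bare save_ closes one
      in_save <- nchar(txt) > 5L
      i <- i + 1L
    } else if (bare && grepl("^global_$", txt, ignore.case = TRUE)) {
      i <- i + 1L
    } else if (in_save) {
      i <- i + 1L
    } else if (bare && grepl("^loop_$", txt, ignore.case = TRUE)) {
      lineno <- tk$line[[i]]
      if (is.null(cur_header)) {
        cif_stop("cif_parse_error", "loop_ outside any data block at line ",
                 lineno)
      }
      i <- i + 1L
      tags <- character(0)
      while (i <= n && tk$kind[[i]] == "value" &&
             startsWith(tk$text[[i]], "_")) {
        tags <- c(tags, tk$text[[i]])
        i <- i + 1L
      }
      if (!length(tags)) {
        cif_stop("cif_parse_error", "loop_ without tags at line ", lineno)
      }
      nxt <- stop_idx[stop_idx >= i]
      end <- if (length(nxt)) nxt[[1]] - 1L else n
      vals_idx <- if (end >= i) i:end else integer(0)
      i <- end + 1L
      nt <- length(tags)
      if (length(vals_idx) %% nt != 0L) {
        cif_stop("cif_parse_error", "loop_ starting at line ", lineno,
                 " has ", length(vals_idx),
                 " values, not a multiple of its ", nt, " tags")
      }
      cells <- values_of(vals_idx)
      for (j in seq_len(nt)) {
        sel <- if (length(vals_idx)) seq(j, length(vals_idx), by = nt)
          else integer(0)
        cc <- split_tag(tags[[j]], lineno)
        add_column(cc[[1]], cc[[2]], cells$payloads[sel], cells$kinds[sel],
                   lineno)
      }
    } else if (bare && startsWith(txt, "_")) {
      lineno <- tk$line[[i]]
      if (is.null(cur_header)) {
        cif_stop("cif_parse_error", "tag ", txt,
                 " outside any data block at line ", lineno)
      }
      if (i + 1L > n || is_tag_all[[i + 1L]] || is_kw_all[[i + 1L]]) {
        cif_stop("cif_parse_error", "tag ", txt, " at line ", lineno,
                 " has no value")
      }
      v <- values_of(i + 1L)
      cc <- split_tag(txt, lineno)
      add_column(cc[[1]], cc[[2]], v$payloads, v$kinds, lineno)
      i <- i + 2L
    } else {
      cif_stop("cif_parse_error", "unexpected value '", txt,
               "' at line ", tk$line[[i]],
               if (is.null(cur_header)) " (outside any data block)" else "")
    }
  }
  flush_block()
  cif_file(blocks)
}

# ---------------------------------------------------------------------------
# Writer

# Quote a present value minimally: bare when safe, then single quotes, then
# double quotes, then a semicolon block (required when the value contains a
# newline or both quote kinds).
quote_cif_value <- function(x) {
  if (grepl("\n", x, fixed = TRUE)) return(semicolon_block(x))
  if (nzchar(x) &&
      !grepl("[ \t']", x) &&
      !substring(x, 1L, 1L) %in% c("\"", "_", "#", "$", ";", "[", "]") &&
      !x %in% c("?", ".") &&
      !grepl("^(data_|loop_$|save_|global_$|stop_$)", x, ignore.case = TRUE)) {
    return(x)
  }
  if (!grepl("'", x, fixed = TRUE)) return(paste0("'", x, "'"))
  if (!grepl("\"", x, fixed = TRUE)) return(paste0("\"", x, "\""))
  semicolon_block(x)
}

semicolon_block <- function(x) {
  if (grepl("(^|\n);", x)) {
    cif_stop("cif_parse_error",
             "value contains a line starting with ';' and cannot be ",
             "represented as a CIF semicolon text field")
  }
  # a value starting with a newline needs an explicit empty first line so
  # the reader's leading-line rule restores it exactly
  paste0("\n;", if (startsWith(x, "\n")) "\n" else "", x, "\n;\n")
}

format_cell <- function(payload, kind) {
  if (kind == KIND_UNKNOWN) return("?")
  if (kind == KIND_NOT_PRESENT) return(".")
  quote_cif_value(payload)
}

#' Serialize the generic model to text CIF
#'
#' Single-row categories are written as aligned key-value pairs, multi-row
#' categories as `loop_` tables.  Values are quoted minimally; unknown and
#' not-present cells are written as `?` and `.`.  `parse_cif(format_cif(f))`
#' is semantically equal to `f`.
#'
#' @param file A [cif_file].
#' @return A single string of CIF text.
#' @export
format_cif <- function(file) {
  stopifnot(inherits(file, "cif_file"))
  out <- character(0)
  for (block in file$blocks) {
    out <- c(out, paste0("data_", block$header, "\n"))
    for (cat in block$categories) {
      out <- c(out, "#\n", format_category(cat))
    }
  }
  paste(out, collapse = "")
}

pad_right <- function(x, width) {
  paste0(x, strrep(" ", pmax(0L, width - nchar(x, type = "bytes"))))
}

format_category <- function(cat) {
  tags <- paste0("_", cat$name, ".",
                 vapply(cat$columns, `[[`, character(1), "name"))
  if (cat$row_count == 1L && length(cat$columns)) {
    width <- max(nchar(tags))
    lines <- vapply(seq_along(cat$columns), function(j) {
      col <- cat$columns[[j]]
      cell <- format_cell(col$values[[1]], col$kinds[[1]])
      if (startsWith(cell, "\n;")) {
        paste0(tags[[j]], cell)
      } else {
        paste0(formatC(tags[[j]], width = -width), " ", cell, "\n")
      }
    }, character(1))
    return(paste(lines, collapse = ""))
  }
  # loop_ form (also used for 0-row categories so that the tags survive)
  head <- paste0("loop_\n", paste0(tags, "\n", collapse = ""))
  if (cat$row_count == 0L) return(head)
  ncol <- length(cat$columns)
  cells <- matrix("", nrow = cat$row_count, ncol = ncol)
  for (j in seq_len(ncol)) {
    col <- cat$columns[[j]]
    v <- col$values
    k <- col$kinds
    simple <- k == KIND_PRESENT & nzchar(v) &
      !grepl("[ \t'\"\n]", v) &
      !substring(v, 1L, 1L) %in% c("_", "#", "$", ";", "[", "]") &
      !v %in% c("?", ".") &
      !grepl("^(data_|loop_$|save_|global_$|stop_$)", v, ignore.case = TRUE)
    cells[simple, j] <- v[simple]
    idx <- which(!simple)
    for (i in idx) cells[i, j] <- format_cell(v[[i]], k[[i]])
  }
  widths <- pmax(nchar(tags) * 0L + 1L,
                 apply(cells, 2, function(x)
                   max(nchar(x[!startsWith(x, "\n;")], type = "bytes"), 1L)))
  rows <- character(cat$row_count)
  has_block <- grepl("^\n;", cells)
  dim(has_block) <- dim(cells)
  for (i in seq_len(cat$row_count)) {
    if (ncol && any(has_block[i, ])) {
      # semicolon blocks break column alignment; emit token-wise
      parts <- character(0)
      pending <- character(0)
      for (j in seq_len(ncol)) {
        cell <- cells[i, j]
        if (has_block[i, j]) {
          parts <- c(parts,
                     if (length(pending)) paste(pending, collapse = " "),
                     sub("^\n", "", cell))
          pending <- character(0)
        } else {
          pending <- c(pending, cell)
        }
      }
      if (length(pending)) parts <- c(parts, paste0(paste(pending,
                                                          collapse = " "),
                                                    "\n"))
      rows[[i]] <- paste(parts, collapse = "")
    } else {
      rows[[i]] <- paste0(paste(pad_right(cells[i, ], widths),
                                collapse = " "), "\n")
    }
  }
  rows <- sub("[ \t]+\n$", "\n", rows)
  paste0(head, paste(rows, collapse = ""))
}
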