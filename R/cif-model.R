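# In-memory CIF data model shared by the text and binary readers/writers.
#
# The hierarchy is File -> Block -> Category -> Column -> Value.  Columns are
# stored column-oriented: a character vector of raw payload text plus an
# integer kind code per row.  Payload text is kept verbatim so that a text
# round trip is lossless; numeric interpretation is deferred to the typed
# access layer or the binary encoder.

# Per-row kind codes; these double as the BinaryCIF mask codes.
KIND_PRESENT <- 0L
KIND_NOT_PRESENT <- 1L # the "." CIF token
KIND_UNKNOWN <- 2L # the "?" CIF token

kind_label <- function(code) {
  c("present", "not_present", "unknown")[match(code, c(0L, 1L, 2L))]
}

#' Construct a CIF column
#'
#' A column is an ordered sequence of cells.  Each cell has a kind:
#' `"present"` (carrying a text payload), `"unknown"` (the CIF `?` token) or
#' `"not_present"` (the CIF `.` token).  Masked cells carry an empty payload.
#'
#' @param name Column name (case-sensitive, e.g. `"Cartn_x"`).
#' @param values Character vector of cell payloads (`""` for masked cells).
#' @param kinds Integer vector the same length as `values`: 0 = present,
#'   1 = not present (`.`), 2 = unknown (`?`).  Defaults to all present.
#' @return An object of class `cif_column`.
#' @export
cif_column <- function(name, values, kinds = NULL) {
  values <- as.character(values)
  if (is.null(kinds)) kinds <- rep(KIND_PRESENT, length(values))
  kinds <- as.integer(kinds)
  stopifnot(length(kinds) == length(values), all(kinds %in% 0:2))
  values[kinds != KIND_PRESENT] <- ""
  structure(list(name = as.character(name), values = values, kinds = kinds),
            class = "cif_column")
}

#' Construct a CIF category
#'
#' @param name Category name; a leading underscore, if given, is stripped so
#'   the canonical stored form is e.g. `"atom_site"`.
#' @param columns List of [cif_column] objects with equal lengths and unique
#'   names.
#' @return An object of class `cif_category`.
#' @export
cif_category <- function(name, columns = list()) {
  name <- canonical_category_name(name)
  nm <- vapply(columns, function(c) c$name, character(1))
  if (anyDuplicated(nm)) {
    stop("duplicate column name(s) in category '", name, "': ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  lens <- vapply(columns, function(c) length(c$values), integer(1))
  if (length(lens) && length(unique(lens)) != 1L) {
    stop("columns of category '", name, "' have differing lengths")
  }
  names(columns) <- nm
  structure(list(name = name,
                 row_count = if (length(lens)) lens[[1]] else 0L,
                 columns = columns),
            class = "cif_category")
}

#' Construct a CIF data block
#'
#' @param header Block header text (the part after `data_`); must be nonempty.
#' @param categories List of [cif_category] objects with unique names.
#' @return An object of class `cif_block`.
#' @export
cif_block <- function(header, categories = list()) {
  header <- as.character(header)
  if (!nzchar(header)) stop("block header must be nonempty")
  nm <- vapply(categories, function(x) x$name, character(1))
  if (anyDuplicated(nm)) {
    stop("duplicate category name(s) in block '", header, "'")
  }
  names(categories) <- nm
  structure(list(header = header, categories = categories),
            class = "cif_block")
}

#' Construct a CIF file object
#'
#' @param blocks List of [cif_block] objects; order is preserved across
#'   read/write round trips.
#' @return An object of class `cif_file`.
#' @export
cif_file <- function(blocks = list()) {
  structure(list(blocks = blocks), class = "cif_file")
}

canonical_category_name <- function(name) {
  sub("^_", "", as.character(name))
}

#' Access a data block by index
#'
#' @param file A [cif_file].
#' @param index 1-based block index.
#' @return The [cif_block] at that position.
#' @export
get_block <- function(file, index) {
  stopifnot(inherits(file, "cif_file"))
  n <- length(file$blocks)
  if (length(index) != 1L || is.na(index) || index < 1L || index > n) {
    stop("block index ", index, " out of range [1, ", n, "]")
  }
  file$blocks[[index]]
}

#' Look up a category by name
#'
#' The name may be given with or without the leading underscore
#' (`"_atom_site"` and `"atom_site"` address the same category).  Lookup is
#' exact on the canonical name; a missing category yields `NULL` rather than
#' an error.
#'
#' @param block A [cif_block].
#' @param name Category name.
#' @return The [cif_category], or `NULL` when absent.
#' @export
get_category <- function(block, name) {
  stopifnot(inherits(block, "cif_block"))
  block$categories[[canonical_category_name(name)]]
}

#' Look up a column by name
#'
#' Column names are compared case-sensitively; a missing column yields
#' `NULL`.
#'
#' @param category A [cif_category].
#' @param name Column name.
#' @return The [cif_column], or `NULL` when absent.
#' @export
get_column <- function(category, name) {
  stopifnot(inherits(category, "cif_category"))
  category$columns[[as.character(name)]]
}

#' Read one cell of a column
#'
#' @param column A [cif_column].
#' @param row 1-based row index; out-of-range indices raise an error.
#' @return A list with elements `kind` (`"present"`, `"unknown"` or
#'   `"not_present"`) and `payload` (cell text; `NA` unless present).
#' @export
get_value <- function(column, row) {
  stopifnot(inherits(column, "cif_column"))
  n <- length(column$values)
  if (length(row) != 1L || is.na(row) || row < 1L || row > n) {
    stop("row index ", row, " out of range [1, ", n, "]")
  }
  k <- column$kinds[[row]]
  list(kind = kind_label(k),
       payload = if (k == KIND_PRESENT) column$values[[row]] else NA_character_)
}

#' @export
print.cif_file <- function(x, ...) {
  cat("<cif_file> ", length(x$blocks), " block(s)\n", sep = "")
  for (b in x$blocks) {
    cat("  data_", b$header, ": ", length(b$categories), " categories\n",
        sep = "")
  }
  invisible(x)
}

#' @export
print.cif_category <- function(x, ...) {
  cat("<cif_category> ", x$name, ": ", x$row_count, " row(s), ",
      length(x$columns), " column(s)\n", sep = "")
  invisible(x)
}
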