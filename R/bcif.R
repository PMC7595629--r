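# BinaryCIF container: serialize the generic model to the MessagePack
# map hierarchy of the BinaryCIF 1.0 layout and back.
#
# File level:  { version, encoder, dataBlocks: [ { header, categories } ] }
# Category:    { name, rowCount, columns }
# Column:      { name, data: { encoding: [steps], data: bytes },
#                mask: <encoded data> | nil }
# Mask codes:  0 = present, 1 = not present ("."), 2 = unknown ("?").
# Category names are stored without the leading underscore; the reader
# accepts either form.

BCIF_VERSION <- "1.0.0"
BCIF_ENCODER <- "bcif (R) 1.0.0"

#' Encode the mask of a column
#'
#' Produces the per-row 0/1/2 present/not-present/unknown code array, itself
#' compressed through the integer classifier (an almost-uniform mask
#' collapses to a short run-length chain).  Returns `NULL` when every row is
#' present, in which case the mask is omitted from the container.
#'
#' @param column A [cif_column].
#' @return An encoded-data object or `NULL`.
#' @export
encode_mask <- function(column) {
  if (all(column$kinds == KIND_PRESENT)) return(NULL)
  choose_int_chain(as.numeric(column$kinds))
}

# ---- container <-> R conversion --------------------------------------------

encoded_to_msg <- function(encoded) {
  steps <- lapply(encoded$encoding, step_to_msg)
  data <- encoded$data
  if (!is.raw(data)) {
    cif_stop("cif_format_error", "encoded payload must be raw bytes")
  }
  list(encoding = steps, data = data)
}

step_to_msg <- function(step) {
  if (identical(step$kind, "StringArray")) {
    return(list(kind = "StringArray",
                dataEncoding = lapply(step$dataEncoding, step_to_msg),
                stringData = step$stringData,
                offsetEncoding = lapply(step$offsetEncoding, step_to_msg),
                offsets = step$offsets))
  }
  step
}

msg_to_encoded <- function(msg) {
  if (is.null(msg$encoding) || is.null(msg$data)) {
    cif_stop("cif_format_error", "encoded column entry lacks encoding/data")
  }
  list(encoding = lapply(msg$encoding, msg_to_step), data = msg$data)
}

msg_to_step <- function(msg) {
  if (is.null(msg$kind)) {
    cif_stop("cif_format_error", "encoding step without kind tag")
  }
  if (identical(msg$kind, "StringArray")) {
    msg$dataEncoding <- lapply(msg$dataEncoding, msg_to_step)
    msg$offsetEncoding <- lapply(msg$offsetEncoding, msg_to_step)
  }
  msg
}

#' Serialize a CIF file to BinaryCIF bytes
#'
#' Every column is classified and encoded with the size-minimizing chain
#' (see [choose_encoding_chain()]); `?`/`.` cells go into a dedicated
#' compressed mask.  The resulting MessagePack container is fully
#' self-descriptive: the decoder uses only the embedded encoding steps.
#'
#' @param file A [cif_file].
#' @param hints Optional named list of encoding hints keyed by
#'   `"category.column"`; each entry as in [choose_encoding_chain()].
#'   Duplicate selectors are a configuration error.
#' @param encoder Encoder identification string embedded in the container.
#' @return A raw vector of BinaryCIF bytes.
#' @export
encode_bcif <- function(file, hints = NULL, encoder = BCIF_ENCODER) {
  stopifnot(inherits(file, "cif_file"))
  if (!is.null(hints)) {
    if (is.null(names(hints)) || anyDuplicated(names(hints))) {
      cif_stop("cif_usage_error",
               "encoding hints must be uniquely named by category.column")
    }
  }
  blocks <- lapply(file$blocks, function(block) {
    cats <- lapply(unname(block$categories), function(cat) {
      cols <- lapply(unname(cat$columns), function(col) {
        hint <- hints[[paste0(cat$name, ".", col$name)]]
        encoded <- choose_encoding_chain(col, hint)
        mask <- encode_mask(col)
        list(name = col$name,
             data = encoded_to_msg(encoded),
             mask = if (is.null(mask)) NULL else encoded_to_msg(mask))
      })
      list(name = cat$name, rowCount = cat$row_count, columns = cols)
    })
    list(header = block$header, categories = cats)
  })
  msgpack_pack(list(version = BCIF_VERSION, encoder = encoder,
                    dataBlocks = blocks))
}

#' Decode BinaryCIF bytes into the generic model
#'
#' Reconstruction is driven entirely by the encoding steps stored in the
#' container.  Numeric columns re-materialize as canonical decimal text:
#' fixed-point columns print the number of decimals implied by their factor,
#' so a text -> binary -> text round trip is idempotent.
#'
#' @param bytes Raw vector of BinaryCIF (MessagePack) data.
#' @return A [cif_file].
#' @export
decode_bcif <- function(bytes) {
  msg <- msgpack_unpack(bytes)
  if (is.null(msg$dataBlocks)) {
    cif_stop("cif_format_error", "not a BinaryCIF container: no dataBlocks")
  }
  blocks <- lapply(msg$dataBlocks, function(bmsg) {
    cats <- lapply(bmsg$categories, function(cmsg) {
      row_count <- as.integer(cmsg$rowCount)
      cols <- lapply(cmsg$columns, function(colmsg) {
        decode_bcif_column(colmsg, row_count)
      })
      cif_category(cmsg$name, cols)
    })
    cif_block(bmsg$header, cats)
  })
  cif_file(blocks)
}

decode_bcif_column <- function(colmsg, row_count) {
  encoded <- msg_to_encoded(colmsg$data)
  values <- withCallingHandlers(
    decode_chain(encoded),
    cif_format_error = function(e) {
      cif_stop("cif_format_error", "column ", colmsg$name, ": ",
               conditionMessage(e))
    })
  kinds <- rep(KIND_PRESENT, row_count)
  if (!is.null(colmsg$mask)) {
    kinds <- as.integer(decode_chain(msg_to_encoded(colmsg$mask)))
    if (length(kinds) != row_count) {
      cif_stop("cif_format_error", "mask length ", length(kinds),
               " != rowCount ", row_count, " in column ", colmsg$name)
    }
    if (any(!kinds %in% 0:2)) {
      cif_stop("cif_format_error", "invalid mask code in column ",
               colmsg$name)
    }
  }
  if (length(values) != row_count) {
    cif_stop("cif_format_error", "column ", colmsg$name, " decoded to ",
             length(values), " values, expected ", row_count)
  }
  if (is.character(values)) {
    text <- values
  } else {
    text <- materialize_numeric_text(values, encoded$encoding)
  }
  text[kinds != KIND_PRESENT] <- ""
  cif_column(colmsg$name, text, kinds)
}

# Canonical decimal text for decoded numeric columns.
materialize_numeric_text <- function(values, encoding) {
  kinds <- vapply(encoding, `[[`, character(1), "kind")
  fp <- match("FixedPoint", kinds)
  if (!is.na(fp)) {
    factor <- encoding[[fp]]$factor
    digits <- max(0L, as.integer(round(log10(factor))))
    return(formatC(values, format = "f", digits = digits))
  }
  if ("IntervalQuantization" %in% kinds ||
      any(vapply(encoding, function(s)
        identical(s$kind, "ByteArray") && type_info(s$type)$float,
        logical(1)))) {
    return(format_float_text(values))
  }
  # pure integer chain
  formatC(values, format = "d")
}

# Shortest decimal text that parses back to the same double.
format_float_text <- function(v) {
  out <- sprintf("%.15g", v)
  bad <- as.numeric(out) != v
  out[bad] <- sprintf("%.17g", v[bad])
  out
}
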