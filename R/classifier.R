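# Automatic per-column encoding selection.
#
# For integer data five candidate chains are measured and the one whose
# serialized container entry (payload + step metadata, sized by the actual
# MessagePack writer) is smallest wins; ties go to the earlier candidate:
#   1. ByteArray at the narrowest lossless width
#   2. IntegerPacking
#   3. RunLength -> packed
#   4. Delta -> packed
#   5. Delta -> RunLength -> packed
# ("packed" means whichever of IntegerPacking or a narrowest ByteArray is
# smaller for the transformed array.)  Floats go through FixedPoint into
# the integer machinery when a lossless power-of-ten factor exists, else
# Float64 ByteArray.  Strings use StringArray with offsets and indices
# routed back through the integer classifier.

#' Classify the payloads of a column
#'
#' Masked rows are ignored: a column is `integer` when every present payload
#' is a decimal integer literal, `float` when every present payload is a
#' decimal number, and `string` otherwise.  Integer columns whose values
#' exceed 32-bit range fall back to `string` (the codec family is 32-bit).
#'
#' @param column A [cif_column].
#' @return A list with `base` (`"integer"`, `"float"` or `"string"`),
#'   `has_masked_rows`, and `max_decimal_digits` (floats only, else `NA`).
#' @export
detect_column_kind <- function(column) {
  present <- column$kinds == KIND_PRESENT
  v <- column$values[present]
  has_masked <- any(!present)
  if (!length(v)) {
    return(list(base = "integer", has_masked_rows = has_masked,
                max_decimal_digits = NA_integer_))
  }
  if (all(is_integer_literal(v))) {
    num <- as.numeric(v)
    if (all(num >= -2147483648 & num <= 2147483647)) {
      return(list(base = "integer", has_masked_rows = has_masked,
                  max_decimal_digits = NA_integer_))
    }
    return(list(base = "string", has_masked_rows = has_masked,
                max_decimal_digits = NA_integer_))
  }
  if (all(is_numeric_literal(v))) {
    return(list(base = "float", has_masked_rows = has_masked,
                max_decimal_digits = max(decimal_digits(v))))
  }
  list(base = "string", has_masked_rows = has_masked,
       max_decimal_digits = NA_integer_)
}

#' Infer a lossless fixed-point factor
#'
#' Returns the smallest factor `10^k`, `k <= min(max_digits, 6)`, that
#' represents every value to within `1e-9 * max(1, |v|)` and keeps
#' `round(v * 10^k)` inside signed 32-bit range; `NULL` when none qualifies
#' (the column then stays as Float64).
#'
#' @param values Finite numeric vector.
#' @param max_digits Cap on the decimal exponent, e.g. the maximum number of
#'   printed decimals observed in the column.
#' @return The factor, or `NULL`.
#' @export
infer_fixed_point_factor <- function(values, max_digits = 6L) {
  v <- values[is.finite(values)]
  if (!length(v)) return(1)
  cap <- min(max_digits, 6L)
  if (is.na(cap)) cap <- 6L
  tol <- 1e-9 * pmax(1, abs(v))
  for (k in 0:cap) {
    f <- 10^k
    r <- round_half_away(v * f)
    if (any(abs(r) > 2147483647)) next
    if (all(abs(v - r / f) <= tol)) return(f)
  }
  NULL
}

# Serialized size (bytes) of an encoded-data object inside the container:
# the MessagePack writer itself is the size metric, so metadata verbosity
# counts against a candidate.
encoded_size <- function(encoded) {
  length(msgpack_pack(encoded_to_msg(encoded)))
}

# Best of {IntegerPacking, narrowest ByteArray} terminal for an integer
# array (both measured, smaller kept; tie -> ByteArray).
pack_terminal <- function(v) {
  plain <- apply_chain(v, list(list(kind = "ByteArray",
                                    type = narrowest_int_type(v))))
  best <- plain
  best_size <- encoded_size(plain)
  pp <- best_packing_params(v)
  if (!is.null(pp)) {
    packed <- apply_chain(v, list(list(kind = "IntegerPacking",
                                       byteCount = pp$byte_count,
                                       isUnsigned = pp$is_unsigned)))
    sz <- encoded_size(packed)
    if (sz < best_size) {
      best <- packed
      best_size <- sz
    }
  }
  best
}

# Packing parameters minimizing payload bytes; NULL when the values already
# fit the candidate widths so packing cannot beat a plain ByteArray.
best_packing_params <- function(v) {
  if (!length(v)) return(NULL)
  unsigned_ok <- all(v >= 0)
  cands <- list(list(byte_count = 1L, is_unsigned = FALSE),
                list(byte_count = 2L, is_unsigned = FALSE))
  if (unsigned_ok) {
    cands <- c(list(list(byte_count = 1L, is_unsigned = TRUE),
                    list(byte_count = 2L, is_unsigned = TRUE)), cands)
  }
  best <- NULL
  best_bytes <- Inf
  for (cd in cands) {
    k <- packing_runs(v, cd$byte_count, cd$is_unsigned)
    bytes <- (sum(k) + length(v)) * cd$byte_count
    if (bytes < best_bytes) {
      best <- cd
      best_bytes <- bytes
    }
  }
  best
}

# The five integer candidate chains, in tie-break order.  Delta candidates
# drop out when a consecutive difference would overflow 32 bits (its
# precondition).
int_candidate_chains <- function(v) {
  rle_pairs <- encode_run_length(v)
  delta_ok <- length(v) < 2L || all(abs(diff(v)) <= 2147483647)
  delta <- if (delta_ok) encode_delta(v) else NULL
  delta_rle <- if (delta_ok) encode_run_length(delta$data) else NULL
  list(
    apply_chain(v, list(list(kind = "ByteArray",
                             type = narrowest_int_type(v)))),
    {
      pp <- best_packing_params(v)
      if (is.null(pp)) NULL else
        apply_chain(v, list(list(kind = "IntegerPacking",
                                 byteCount = pp$byte_count,
                                 isUnsigned = pp$is_unsigned)))
    },
    prepend_step(rle_pairs$step, pack_terminal(rle_pairs$data)),
    if (delta_ok) prepend_step(delta$step, pack_terminal(delta$data)),
    if (delta_ok)
      prepend_step(delta$step,
                   prepend_step(delta_rle$step, pack_terminal(delta_rle$data)))
  )
}

prepend_step <- function(step, encoded) {
  list(encoding = c(list(step), encoded$encoding), data = encoded$data)
}

#' Choose the smallest encoding chain for an integer array
#'
#' Measures the five candidate chains and returns the one with the minimal
#' serialized size; ties break in candidate-list order (plain ByteArray,
#' IntegerPacking, RunLength, Delta, Delta+RunLength).
#'
#' @param values Integer-valued numeric vector.
#' @return An encoded-data object.
#' @export
choose_int_chain <- function(values) {
  v <- check_int32(as.numeric(values), "value")
  cands <- int_candidate_chains(v)
  sizes <- vapply(cands, function(c)
    if (is.null(c)) Inf else encoded_size(c), numeric(1))
  cands[[which.min(sizes)]]
}

#' Choose and apply the best encoding chain for a column
#'
#' The single entry point used by the BinaryCIF writer: classifies the
#' column, fills masked rows with a filler (0 for numeric, index -1 for
#' strings; the mask carries the truth), and picks the size-minimal chain.
#' A hint can force a chain or a lossy fixed-point precision for a specific
#' column.
#'
#' @param column A [cif_column].
#' @param hint Optional hint: `list(chain = <chain spec for apply_chain>)`
#'   or `list(precision = <digits>)` (floats only, lossy when below the
#'   column's printed precision).
#' @return An encoded-data object.
#' @export
choose_encoding_chain <- function(column, hint = NULL) {
  if (!is.null(hint$chain)) {
    return(apply_chain(column_numeric_filled(column), hint$chain))
  }
  kind <- detect_column_kind(column)
  present <- column$kinds == KIND_PRESENT
  if (kind$base == "string") {
    return(encode_string_array(column$values, column$kinds))
  }
  v <- numeric(length(column$values))
  v[present] <- as.numeric(column$values[present])
  if (kind$base == "integer") {
    return(choose_int_chain(v))
  }
  # float column
  if (!is.null(hint$precision)) {
    factor <- 10^hint$precision
    v[present] <- round_half_away(v[present] * factor) / factor
  } else {
    factor <- infer_fixed_point_factor(v[present],
                                       kind$max_decimal_digits %||% 6L)
  }
  if (is.null(factor)) {
    return(apply_chain(v, list(list(kind = "ByteArray",
                                    type = type_code("Float64")))))
  }
  fp <- encode_fixed_point(v, factor)
  prepend_step(fp$step, choose_int_chain(fp$data))
}

column_numeric_filled <- function(column) {
  present <- column$kinds == KIND_PRESENT
  v <- numeric(length(column$values))
  v[present] <- as.numeric(column$values[present])
  v
}
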