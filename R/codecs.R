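# The seven BinaryCIF column codecs.
#
# Every encoder returns a self-descriptive step (a named list carrying the
# codec kind plus the parameters needed to invert it) together with the
# transformed data.  Chains compose left-to-right on encode and are
# inverted right-to-left by decode_chain(); the decoder needs nothing
# beyond the stored steps.  Numeric payloads travel as R numeric vectors
# between steps; the terminal ByteArray step turns them into little-endian
# bytes.

# Array type codes of the BinaryCIF 1.0 specification.
ARRAY_TYPES <- data.frame(
  name = c("Int8", "Int16", "Int32", "Uint8", "Uint16", "Uint32",
           "Float32", "Float64"),
  code = c(1L, 2L, 3L, 4L, 5L, 6L, 32L, 33L),
  width = c(1L, 2L, 4L, 1L, 2L, 4L, 4L, 8L),
  signed = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
  float = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
  min = c(-128, -32768, -2147483648, 0, 0, 0, -Inf, -Inf),
  max = c(127, 32767, 2147483647, 255, 65535, 4294967295, Inf, Inf),
  stringsAsFactors = FALSE
)

type_info <- function(code) {
  i <- match(code, ARRAY_TYPES$code)
  if (is.na(i)) {
    cif_stop("cif_format_error", "unknown array type code ", code)
  }
  ARRAY_TYPES[i, ]
}

type_code <- function(name) {
  ARRAY_TYPES$code[match(name, ARRAY_TYPES$name)]
}

# Narrowest integer array type able to hold all values losslessly.
narrowest_int_type <- function(v) {
  if (!length(v)) return(type_code("Int8"))
  lo <- min(v)
  hi <- max(v)
  for (nm in c("Int8", "Uint8", "Int16", "Uint16", "Int32", "Uint32")) {
    ti <- ARRAY_TYPES[ARRAY_TYPES$name == nm, ]
    if (lo >= ti$min && hi <= ti$max) return(ti$code)
  }
  cif_stop("cif_format_error", "integer values exceed 32-bit range")
}

check_int32 <- function(v, what) {
  bad <- which(!is.finite(v) | v != trunc(v) | v < -2147483648 |
                 v > 2147483647)
  if (length(bad)) {
    cif_stop("cif_format_error", what, " not a signed 32-bit integer at ",
             "index ", bad[1], " (value ", v[bad[1]], ")")
  }
  invisible(v)
}

# --- ByteArray --------------------------------------------------------------

#' Pack a numeric array into little-endian bytes
#'
#' The terminal step of every encoding chain: stores the array directly at a
#' declared element type (`Int8`/`Int16`/`Int32`, unsigned variants,
#' `Float32`/`Float64`), little-endian.
#'
#' @param values Numeric vector.
#' @param type Array type code (1,2,3 = Int8/16/32; 4,5,6 = Uint8/16/32;
#'   32, 33 = Float32/64).
#' @return A list with elements `step` (the self-descriptive encoding step)
#'   and `data` (raw payload).
#' @export
encode_byte_array <- function(values, type = 3L) {
  ti <- type_info(type)
  v <- as.numeric(values)
  if (!ti$float) {
    bad <- which(!is.finite(v) | v != trunc(v) | v < ti$min | v > ti$max)
    if (length(bad)) {
      cif_stop("cif_format_error", "value ", v[bad[1]], " at index ", bad[1],
               " does not fit array type ", ti$name)
    }
    # writeBin stores the low bytes two's-complement, which is exactly the
    # unsigned representation for the Uint types
    if (ti$width == 4L) v <- ifelse(v > 2147483647, v - 4294967296, v)
    data <- writeBin(as.integer(v), raw(), size = ti$width,
                     endian = "little")
  } else {
    bad <- which(!is.finite(v))
    if (length(bad)) {
      cif_stop("cif_format_error", "non-finite value at index ", bad[1])
    }
    data <- writeBin(v, raw(), size = ti$width, endian = "little")
  }
  list(step = list(kind = "ByteArray", type = as.integer(ti$code)),
       data = data)
}

decode_byte_array <- function(step, data) {
  if (!is.raw(data)) {
    cif_stop("cif_format_error", "ByteArray payload is not raw bytes")
  }
  ti <- type_info(step$type)
  if (length(data) %% ti$width != 0L) {
    cif_stop("cif_format_error", "payload length ", length(data),
             " not divisible by ", ti$name, " width ", ti$width)
  }
  n <- length(data) %/% ti$width
  if (ti$float) {
    return(readBin(data, "numeric", n = n, size = ti$width,
                   endian = "little"))
  }
  if (ti$width < 4L) {
    v <- readBin(data, "integer", n = n, size = ti$width, signed = ti$signed,
                 endian = "little")
    as.numeric(v)
  } else {
    v <- as.numeric(readBin(data, "integer", n = n, size = 4L,
                            endian = "little"))
    if (!ti$signed) v <- ifelse(v < 0, v + 4294967296, v)
    v
  }
}

# --- FixedPoint -------------------------------------------------------------

#' Fixed-point encode a float array
#'
#' Multiplies each value by `factor` and rounds half away from zero to an
#' integer; with factor 10^k this is lossless for values printed with k
#' decimals (mmCIF coordinates use factor 1000).
#'
#' @param values Finite numeric vector.
#' @param factor Positive multiplier, typically a power of ten.
#' @param src_type Array type code of the source floats (32 or 33).
#' @return List of `step` and integer `data`.
#' @export
encode_fixed_point <- function(values, factor, src_type = 33L) {
  stopifnot(factor > 0)
  v <- as.numeric(values)
  bad <- which(!is.finite(v))
  if (length(bad)) {
    cif_stop("cif_format_error", "non-finite value at index ", bad[1])
  }
  r <- round_half_away(v * factor)
  over <- which(abs(r) > 2147483647)
  if (length(over)) {
    cif_stop("cif_format_error", "fixed-point value overflows 32 bits at ",
             "index ", over[1])
  }
  list(step = list(kind = "FixedPoint", factor = factor,
                   srcType = as.integer(src_type)),
       data = r)
}

decode_fixed_point <- function(step, data) {
  as.numeric(data) / step$factor
}

# --- RunLength --------------------------------------------------------------

#' Run-length encode an integer array
#'
#' Collapses repeats into flattened (value, count) pairs.
#'
#' @param values Integer-valued numeric vector (signed 32-bit range).
#' @return List of `step` (carrying the original length as `srcSize`) and
#'   paired `data`.
#' @export
encode_run_length <- function(values) {
  v <- check_int32(as.numeric(values), "value")
  r <- rle(v)
  list(step = list(kind = "RunLength", srcType = 3L,
                   srcSize = length(v)),
       data = as.numeric(rbind(r$values, r$lengths)))
}

decode_run_length <- function(step, data) {
  if (length(data) %% 2L != 0L) {
    cif_stop("cif_format_error", "RunLength payload has odd length")
  }
  vals <- data[seq_along(data) %% 2L == 1L]
  counts <- data[seq_along(data) %% 2L == 0L]
  if (any(counts < 0)) {
    cif_stop("cif_format_error", "negative RunLength count")
  }
  if (sum(counts) != step$srcSize) {
    cif_stop("cif_format_error", "RunLength counts sum to ", sum(counts),
             ", expected srcSize ", step$srcSize)
  }
  rep(vals, counts)
}

# --- Delta ------------------------------------------------------------------

#' Delta encode an integer array
#'
#' Stores the first value as the step's `origin` and consecutive differences
#' in the payload (whose first slot is 0).
#'
#' @param values Integer-valued numeric vector.
#' @return List of `step` and `data`.
#' @export
encode_delta <- function(values) {
  v <- check_int32(as.numeric(values), "value")
  if (!length(v)) {
    return(list(step = list(kind = "Delta", origin = 0, srcType = 3L),
                data = numeric(0)))
  }
  d <- c(0, diff(v))
  check_int32(d, "consecutive difference")
  list(step = list(kind = "Delta", origin = v[[1]], srcType = 3L),
       data = d)
}

decode_delta <- function(step, data) {
  if (!length(data)) return(numeric(0))
  step$origin + cumsum(as.numeric(data))
}

# --- IntervalQuantization ---------------------------------------------------

#' Interval-quantize a float array (lossy)
#'
#' Maps floats onto `num_steps` uniformly spaced levels between `min` and
#' `max` (256 or 65,536 levels fill one or two bytes).  Values outside the
#' interval clamp to the boundary bins, which is how outliers are discarded
#' when min/max are chosen tighter than the data range.  Reconstruction
#' error for in-range values is at most `(max-min)/(2*(num_steps-1))`.
#'
#' @param values Finite numeric vector.
#' @param min,max Interval bounds, `min < max`.
#' @param num_steps Number of levels (>= 2); 256 and 65536 are the standard
#'   choices.
#' @param src_type Array type code of the source floats.
#' @return List of `step` and integer bin indices in `[0, num_steps)`.
#' @export
encode_interval_quantization <- function(values, min, max,
                                         num_steps = 256L, src_type = 33L) {
  if (!(min < max)) {
    cif_stop("cif_format_error", "interval quantization requires min < max")
  }
  if (num_steps < 2L) {
    cif_stop("cif_format_error", "interval quantization requires >= 2 steps")
  }
  v <- as.numeric(values)
  bad <- which(!is.finite(v))
  if (length(bad)) {
    cif_stop("cif_format_error", "non-finite value at index ", bad[1])
  }
  delta <- (max - min) / (num_steps - 1)
  idx <- round_half_away((v - min) / delta)
  idx <- pmax(0, pmin(num_steps - 1, idx))
  list(step = list(kind = "IntervalQuantization", min = min, max = max,
                   numSteps = as.integer(num_steps),
                   srcType = as.integer(src_type)),
       data = idx)
}

decode_interval_quantization <- function(step, data) {
  delta <- (step$max - step$min) / (step$numSteps - 1)
  step$min + as.numeric(data) * delta
}

# --- IntegerPacking ---------------------------------------------------------

packing_bounds <- function(byte_count, is_unsigned) {
  if (is_unsigned) {
    list(upper = 2^(8 * byte_count) - 1, lower = NULL)
  } else {
    list(upper = 2^(8 * byte_count - 1) - 1, lower = -2^(8 * byte_count - 1))
  }
}

# Number of packed elements each value expands to, minus one (the count of
# saturated bound markers preceding the terminal residue).
packing_runs <- function(v, byte_count, is_unsigned) {
  b <- packing_bounds(byte_count, is_unsigned)
  k <- numeric(length(v))
  pos <- v > 0
  k[pos] <- v[pos] %/% b$upper
  if (!is_unsigned) {
    neg <- v < 0
    k[neg] <- v[neg] %/% b$lower
  }
  k
}

#' Pack 32-bit integers into 8- or 16-bit values
#'
#' Each value becomes zero or more saturated bound markers (the byte width's
#' extreme value) followed by a residue; the decoder sums runs.  Values that
#' equal a bound exactly therefore need an explicit 0 terminator
#' (`127 -> [127, 0]` at signed byte width).
#'
#' @param values Integer-valued numeric vector.
#' @param byte_count 1 or 2.
#' @param is_unsigned If `TRUE` all values must be non-negative and the
#'   packed array is unsigned.
#' @return List of `step` and the packed array.
#' @export
encode_integer_packing <- function(values, byte_count = 1L,
                                   is_unsigned = FALSE) {
  stopifnot(byte_count %in% c(1L, 2L))
  v <- check_int32(as.numeric(values), "value")
  if (is_unsigned && any(v < 0)) {
    cif_stop("cif_format_error",
             "negative value at index ", which(v < 0)[1],
             " cannot be packed unsigned")
  }
  b <- packing_bounds(byte_count, is_unsigned)
  k <- packing_runs(v, byte_count, is_unsigned)
  res <- v - k * ifelse(v >= 0, b$upper, if (is_unsigned) b$upper else b$lower)
  if (sum(k) == 0) {
    out <- v
  } else {
    out <- unlist(mapply(function(ki, vi, ri) {
      c(rep(if (vi >= 0) b$upper else b$lower, ki), ri)
    }, k, v, res, SIMPLIFY = FALSE), use.names = FALSE)
  }
  list(step = list(kind = "IntegerPacking", byteCount = as.integer(byte_count),
                   isUnsigned = isTRUE(is_unsigned), srcSize = length(v)),
       data = as.numeric(out))
}

decode_integer_packing <- function(step, data) {
  b <- packing_bounds(step$byteCount, isTRUE(step$isUnsigned))
  v <- as.numeric(data)
  lo <- if (is.null(b$lower)) 0 else b$lower
  if (length(v) && (max(v) > b$upper || min(v) < lo)) {
    cif_stop("cif_format_error", "packed value outside declared ",
             step$byteCount, "-byte bounds")
  }
  terminal <- v != b$upper
  if (!is.null(b$lower)) terminal <- terminal & v != b$lower
  if (!length(v)) {
    if (step$srcSize != 0L) {
      cif_stop("cif_format_error", "empty packing payload for srcSize ",
               step$srcSize)
    }
    return(numeric(0))
  }
  if (!terminal[length(v)]) {
    cif_stop("cif_format_error", "integer packing payload ends inside a run")
  }
  grp <- c(1, 1 + cumsum(terminal)[-length(v)])
  out <- as.numeric(rowsum(v, grp))
  if (length(out) != step$srcSize) {
    cif_stop("cif_format_error", "integer packing yielded ", length(out),
             " values, expected ", step$srcSize)
  }
  out
}

# --- StringArray ------------------------------------------------------------

#' Encode a string column as unique substrings + offsets + indices
#'
#' Unique strings are concatenated in first-occurrence order; byte offsets
#' delimit them and a per-row index array references them (-1 for masked
#' rows, whose truth lives in the column mask).  Offsets and indices are
#' themselves encoded as ordinary integer arrays via `int_encoder`.
#'
#' @param values Character vector of payloads.
#' @param kinds Optional integer kind codes (0 present, 1 `.`, 2 `?`);
#'   non-present rows get index -1.
#' @param int_encoder Function mapping an integer vector to an encoded-data
#'   object (defaults to the size-minimizing classifier chain).
#' @return An encoded-data object: `list(encoding = list(<StringArray
#'   step>), data = <raw payload of the encoded indices>)`.
#' @export
encode_string_array <- function(values, kinds = NULL,
                                int_encoder = choose_int_chain) {
  values <- as.character(values)
  if (is.null(kinds)) kinds <- rep(KIND_PRESENT, length(values))
  present <- kinds == KIND_PRESENT
  uniq <- unique(values[present])
  indices <- rep(-1, length(values))
  indices[present] <- match(values[present], uniq) - 1
  offsets <- c(0, cumsum(vapply(uniq, function(s)
    length(charToRaw(enc2utf8(s))), numeric(1), USE.NAMES = FALSE)))
  string_data <- paste(uniq, collapse = "")
  enc_offsets <- int_encoder(offsets)
  enc_indices <- int_encoder(indices)
  step <- list(kind = "StringArray",
               dataEncoding = enc_indices$encoding,
               stringData = string_data,
               offsetEncoding = enc_offsets$encoding,
               offsets = enc_offsets$data)
  list(encoding = list(step), data = enc_indices$data)
}

decode_string_array <- function(step, data) {
  indices <- decode_chain(list(encoding = step$dataEncoding, data = data))
  offsets <- decode_chain(list(encoding = step$offsetEncoding,
                               data = step$offsets))
  sbytes <- charToRaw(enc2utf8(step$stringData))
  nu <- length(offsets) - 1L
  if (length(offsets) && offsets[length(offsets)] != length(sbytes)) {
    cif_stop("cif_format_error", "StringArray offsets inconsistent with ",
             "stringData length")
  }
  uniq <- vapply(seq_len(nu), function(i) {
    if (offsets[i + 1L] == offsets[i]) return("")
    rawToChar(sbytes[(offsets[i] + 1L):offsets[i + 1L]])
  }, character(1))
  if (length(indices) && nu &&
      (max(indices) >= nu || min(indices) < -1)) {
    cif_stop("cif_format_error", "StringArray index out of range")
  }
  out <- character(length(indices))
  hit <- indices >= 0
  out[hit] <- uniq[indices[hit] + 1L]
  out
}

# --- Generic chain machinery ------------------------------------------------

#' Decode a single encoding step
#'
#' Dispatches on the step's `kind` tag; the step is fully self-descriptive,
#' so no information beyond its parameters and the payload is needed.
#'
#' @param step A step list as produced by the `encode_*` functions (or read
#'   from a BinaryCIF container).
#' @param data The downstream payload (raw bytes for `ByteArray`, numeric
#'   otherwise).
#' @return The recovered upstream array (numeric, or character for
#'   `StringArray`).
#' @export
decode_step <- function(step, data) {
  switch(step$kind,
    ByteArray = decode_byte_array(step, data),
    FixedPoint = decode_fixed_point(step, data),
    RunLength = decode_run_length(step, data),
    Delta = decode_delta(step, data),
    IntervalQuantization = decode_interval_quantization(step, data),
    IntegerPacking = decode_integer_packing(step, data),
    StringArray = decode_string_array(step, data),
    cif_stop("cif_format_error", "unknown encoding kind '", step$kind, "'")
  )
}

#' Apply a chain of encodings to an array
#'
#' Steps are applied left to right; when the chain does not end in
#' `ByteArray`, a terminal `ByteArray` step at the narrowest lossless
#' integer width (or the width implied by a preceding `IntegerPacking`
#' step) is appended so the result is always a byte payload.
#'
#' @param values Numeric vector (or anything coercible).
#' @param chain A list whose elements are either a codec kind name
#'   (`"Delta"`, `"RunLength"`, ...) or a list with element `kind` plus
#'   parameters (`list(kind = "FixedPoint", factor = 1000)`).
#' @return An encoded-data object `list(encoding = <steps>, data = <raw>)`.
#' @export
apply_chain <- function(values, chain) {
  data <- as.numeric(values)
  steps <- list()
  done <- FALSE
  for (el in chain) {
    if (done) cif_stop("cif_format_error", "no step may follow ByteArray")
    spec <- if (is.character(el)) list(kind = el) else el
    enc <- switch(spec$kind,
      ByteArray = {
        done <- TRUE
        encode_byte_array(data, spec$type %||% auto_terminal_type(data, steps))
      },
      FixedPoint = encode_fixed_point(data, spec$factor,
                                      spec$srcType %||% 33L),
      RunLength = encode_run_length(data),
      Delta = encode_delta(data),
      IntervalQuantization = encode_interval_quantization(
        data, spec$min, spec$max, spec$numSteps %||% 256L,
        spec$srcType %||% 33L),
      IntegerPacking = encode_integer_packing(
        data, spec$byteCount %||% 1L, isTRUE(spec$isUnsigned)),
      cif_stop("cif_format_error", "unknown encoding kind '", spec$kind, "'")
    )
    steps[[length(steps) + 1L]] <- enc$step
    data <- enc$data
  }
  if (!done) {
    enc <- encode_byte_array(data, auto_terminal_type(data, steps))
    steps[[length(steps) + 1L]] <- enc$step
    data <- enc$data
  }
  list(encoding = steps, data = data)
}

# Terminal byte-array type: the width/signedness implied by an immediately
# preceding IntegerPacking step, else the narrowest lossless integer type.
auto_terminal_type <- function(data, steps) {
  if (length(steps)) {
    last <- steps[[length(steps)]]
    if (identical(last$kind, "IntegerPacking")) {
      nm <- paste0(if (isTRUE(last$isUnsigned)) "Uint" else "Int",
                   8L * last$byteCount)
      return(type_code(nm))
    }
  }
  narrowest_int_type(data)
}

#' Invert an encoding chain
#'
#' Applies the inverse of every stored step right-to-left, starting from the
#' byte payload.
#'
#' @param encoded An encoded-data object (`encoding` steps + `data` bytes).
#' @return The decoded array (numeric, or character for string columns).
#' @export
decode_chain <- function(encoded) {
  data <- encoded$data
  for (step in rev(encoded$encoding)) {
    data <- decode_step(step, data)
  }
  data
}

# Human-readable chain description, e.g. "Delta->RunLength->ByteArray".
describe_chain <- function(encoding) {
  paste(vapply(encoding, `[[`, character(1), "kind"), collapse = "->")
}
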