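# Minimal MessagePack implementation covering the types the BinaryCIF
# container uses: nil, booleans, integers (up to 32-bit), float32/float64,
# UTF-8 strings, raw binary, arrays and string-keyed maps.
#
# Mapping on encode: NULL -> nil, length-1 logical -> bool, raw -> bin,
# length-1 character -> str, length-1 whole numeric within 32-bit -> int,
# other length-1 numeric -> float64, named list -> map, unnamed list ->
# array.  Decode inverts this (maps become named lists, bin stays raw).
# Multi-byte values are big-endian per the msgpack spec.

#' Serialize an R object to MessagePack bytes
#'
#' @param x `NULL`, a length-1 logical/character/numeric, a raw vector, or a
#'   (possibly nested) list; named lists become maps, unnamed lists arrays.
#' @return A raw vector.
#' @export
msgpack_pack <- function(x) {
  acc <- new.env(parent = emptyenv())
  acc$parts <- vector("list", 64L)
  acc$n <- 0L
  pack_one(x, acc)
  unlist(acc$parts[seq_len(acc$n)], use.names = FALSE)
}

emit <- function(acc, bytes) {
  n <- acc$n + 1L
  if (n > length(acc$parts)) {
    acc$parts <- c(acc$parts, vector("list", length(acc$parts)))
  }
  acc$parts[[n]] <- bytes
  acc$n <- n
}

be_bytes <- function(x, size) {
  writeBin(as.integer(x), raw(), size = size, endian = "big")
}

pack_uint <- function(acc, x) {
  if (x < 128) {
    emit(acc, as.raw(x))
  } else if (x < 256) {
    emit(acc, c(as.raw(0xcc), as.raw(x)))
  } else if (x < 65536) {
    emit(acc, c(as.raw(0xcd), be_bytes(x, 2L)))
  } else {
    y <- if (x > .Machine$integer.max) x - 4294967296 else x
    emit(acc, c(as.raw(0xce), be_bytes(y, 4L)))
  }
}

pack_one <- function(x, acc) {
  if (is.null(x)) {
    emit(acc, as.raw(0xc0))
  } else if (is.raw(x)) {
    n <- length(x)
    if (n < 256) {
      emit(acc, c(as.raw(0xc4), as.raw(n)))
    } else if (n < 65536) {
      emit(acc, c(as.raw(0xc5), be_bytes(n, 2L)))
    } else {
      emit(acc, c(as.raw(0xc6), be_bytes(n, 4L)))
    }
    emit(acc, x)
  } else if (is.list(x)) {
    nm <- names(x)
    n <- length(x)
    if (!is.null(nm)) {
      if (anyNA(nm) || any(!nzchar(nm))) {
        stop("map keys must all be nonempty strings")
      }
      if (n < 16) {
        emit(acc, as.raw(bitwOr(0x80L, n)))
      } else if (n < 65536) {
        emit(acc, c(as.raw(0xde), be_bytes(n, 2L)))
      } else {
        emit(acc, c(as.raw(0xdf), be_bytes(n, 4L)))
      }
      for (i in seq_len(n)) {
        pack_str(acc, nm[[i]])
        pack_one(x[[i]], acc)
      }
    } else {
      if (n < 16) {
        emit(acc, as.raw(bitwOr(0x90L, n)))
      } else if (n < 65536) {
        emit(acc, c(as.raw(0xdc), be_bytes(n, 2L)))
      } else {
        emit(acc, c(as.raw(0xdd), be_bytes(n, 4L)))
      }
      for (el in x) pack_one(el, acc)
    }
  } else if (is.logical(x) && length(x) == 1L) {
    if (is.na(x)) stop("cannot pack NA")
    emit(acc, as.raw(if (x) 0xc3 else 0xc2))
  } else if (is.character(x) && length(x) == 1L) {
    pack_str(acc, x)
  } else if (is.numeric(x) && length(x) == 1L) {
    if (!is.finite(x) || x != trunc(x) || x < -2147483648 || x > 4294967295) {
      emit(acc, c(as.raw(0xcb), writeBin(as.double(x), raw(), size = 8L,
                                         endian = "big")))
    } else if (x >= 0) {
      pack_uint(acc, x)
    } else if (x >= -32) {
      emit(acc, as.raw(256 + x))
    } else if (x >= -128) {
      emit(acc, c(as.raw(0xd0), as.raw(256 + x)))
    } else if (x >= -32768) {
      emit(acc, c(as.raw(0xd1), be_bytes(x, 2L)))
    } else {
      emit(acc, c(as.raw(0xd2), be_bytes(x, 4L)))
    }
  } else {
    stop("cannot pack object of class ", paste(class(x), collapse = "/"),
         " and length ", length(x))
  }
}

pack_str <- function(acc, s) {
  b <- charToRaw(enc2utf8(s))
  n <- length(b)
  if (n < 32) {
    emit(acc, as.raw(bitwOr(0xa0L, n)))
  } else if (n < 256) {
    emit(acc, c(as.raw(0xd9), as.raw(n)))
  } else if (n < 65536) {
    emit(acc, c(as.raw(0xda), be_bytes(n, 2L)))
  } else {
    emit(acc, c(as.raw(0xdb), be_bytes(n, 4L)))
  }
  emit(acc, b)
}

#' Deserialize MessagePack bytes
#'
#' @param bytes A raw vector produced by [msgpack_pack()] or any
#'   interoperable encoder, containing a single object.
#' @return The decoded R object; maps become named lists, arrays unnamed
#'   lists, bin payloads raw vectors.
#' @export
msgpack_unpack <- function(bytes) {
  stopifnot(is.raw(bytes))
  st <- new.env(parent = emptyenv())
  st$pos <- 1L
  st$bytes <- bytes
  out <- unpack_one(st)
  if (st$pos != length(bytes) + 1L) {
    cif_stop("cif_format_error", "trailing bytes after MessagePack object")
  }
  out
}

take <- function(st, n) {
  if (st$pos + n - 1L > length(st$bytes)) {
    cif_stop("cif_format_error", "truncated MessagePack input")
  }
  b <- st$bytes[st$pos:(st$pos + n - 1L)]
  st$pos <- st$pos + n
  b
}

read_be_uint <- function(st, size) {
  b <- take(st, size)
  x <- sum(as.numeric(b) * 256^((size - 1):0))
  x
}

read_be_int <- function(st, size) {
  x <- read_be_uint(st, size)
  half <- 256^size / 2
  if (x >= half) x - 256^size else x
}

unpack_one <- function(st) {
  b <- as.integer(take(st, 1L))
  if (b < 0x80) return(b)
  if (b >= 0xe0) return(b - 256L)
  if (b >= 0xa0 && b <= 0xbf) return(rawToChar(take(st, b - 0xa0L)))
  if (b >= 0x90 && b <= 0x9f) return(unpack_array(st, b - 0x90L))
  if (b >= 0x80 && b <= 0x8f) return(unpack_map(st, b - 0x80L))
  switch(as.character(b),
    "192" = NULL,                                   # nil
    "194" = FALSE,
    "195" = TRUE,
    "196" = take(st, read_be_uint(st, 1L)),         # bin8/16/32
    "197" = take(st, read_be_uint(st, 2L)),
    "198" = take(st, read_be_uint(st, 4L)),
    "202" = readBin(take(st, 4L), "numeric", size = 4L, endian = "big"),
    "203" = readBin(take(st, 8L), "numeric", size = 8L, endian = "big"),
    "204" = read_be_uint(st, 1L),                   # uint8/16/32
    "205" = read_be_uint(st, 2L),
    "206" = read_be_uint(st, 4L),
    "208" = read_be_int(st, 1L),                    # int8/16/32
    "209" = read_be_int(st, 2L),
    "210" = read_be_int(st, 4L),
    "217" = rawToChar(take(st, read_be_uint(st, 1L))),  # str8/16/32
    "218" = rawToChar(take(st, read_be_uint(st, 2L))),
    "219" = rawToChar(take(st, read_be_uint(st, 4L))),
    "220" = unpack_array(st, read_be_uint(st, 2L)),
    "221" = unpack_array(st, read_be_uint(st, 4L)),
    "222" = unpack_map(st, read_be_uint(st, 2L)),
    "223" = unpack_map(st, read_be_uint(st, 4L)),
    cif_stop("cif_format_error", "unsupported MessagePack type byte 0x",
             sprintf("%02x", b))
  )
}

unpack_array <- function(st, n) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    v <- unpack_one(st)
    out[i] <- list(v)
  }
  out
}

unpack_map <- function(st, n) {
  out <- vector("list", n)
  nm <- character(n)
  for (i in seq_len(n)) {
    k <- unpack_one(st)
    if (!is.character(k)) {
      cif_stop("cif_format_error", "non-string MessagePack map key")
    }
    nm[[i]] <- k
    v <- unpack_one(st)
    out[i] <- list(v)
  }
  names(out) <- nm
  out
}
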