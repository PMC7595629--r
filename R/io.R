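# File-level input/output with format sniffing and transparent gzip.

#' Read a CIF or BinaryCIF file
#'
#' The format is sniffed from the extension first (`.cif`, `.bcif`, plus
#' `.gz` wrappings), then from content: a gzip magic number triggers
#' decompression, and a MessagePack map byte distinguishes BinaryCIF from
#' text.
#'
#' @param path Path to a `.cif`, `.cif.gz`, `.bcif` or `.bcif.gz` file (any
#'   other extension is sniffed by content).
#' @return A [cif_file].
#' @export
read_cif <- function(path) {
  if (!file.exists(path)) {
    cif_stop("cif_usage_error", "input file not found: ", path)
  }
  fmt <- sniff_format(path)
  if (fmt == "bcif") {
    decode_bcif(read_raw_file(path))
  } else {
    parse_cif(read_text_file(path))
  }
}

sniff_format <- function(path) {
  base <- sub("\\.gz$", "", path)
  if (grepl("\\.bcif$", base, ignore.case = TRUE)) return("bcif")
  if (grepl("\\.cif$", base, ignore.case = TRUE)) return("cif")
  head <- read_head_bytes(path, 1L)
  if (!length(head)) return("cif")
  b <- as.integer(head[1])
  if ((b >= 0x80 && b <= 0x8f) || b == 0xde || b == 0xdf) "bcif" else "cif"
}

read_head_bytes <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, raw(), n = 2L)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) &&
      magic[2] == as.raw(0x8b)) {
    close(con)
    on.exit()
    con <- gzfile(path, "rb")
    on.exit(close(con))
    return(readBin(con, raw(), n = n))
  }
  magic[seq_len(min(n, length(magic)))]
}

#' Write a CIF file to disk in text or binary form
#'
#' @param file A [cif_file].
#' @param path Output path; `.gz` suffixes are written gzip-compressed
#'   (default compression level).
#' @param format `"auto"` (from the extension; text when ambiguous),
#'   `"cif"` or `"bcif"`.
#' @param hints Encoding hints forwarded to [encode_bcif()].
#' @param encoder Encoder string for binary output.
#' @return The path, invisibly.
#' @export
write_cif <- function(file, path, format = c("auto", "cif", "bcif"),
                      hints = NULL, encoder = BCIF_ENCODER) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bcif(\\.gz)?$", path, ignore.case = TRUE))
      "bcif" else "cif"
  }
  if (format == "bcif") {
    write_raw_file(encode_bcif(file, hints = hints, encoder = encoder), path)
  } else {
    write_text_file(format_cif(file), path)
  }
  invisible(path)
}
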