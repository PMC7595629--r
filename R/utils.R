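# Shared internal helpers.

# Classed errors so the CLI can map failures onto exit codes:
#   cif_usage_error  -> 1, cif_parse_error / cif_format_error -> 2,
#   cif_verify_error -> 3.
cif_stop <- function(class, ...) {
  stop(structure(class = c(class, "cif_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Round half away from zero (deterministic, symmetric; base round() rounds
# half to even).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

is_integer_literal <- function(x) {
  grepl("^[+-]?[0-9]+$", x)
}

is_numeric_literal <- function(x) {
  grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", x)
}

# Digits after the decimal point in a plain decimal literal (0 when none or
# when in exponent form, where printed decimals are not meaningful).
decimal_digits <- function(x) {
  out <- integer(length(x))
  plain <- grepl("^[+-]?[0-9]*\\.[0-9]+$", x)
  out[plain] <- nchar(sub("^[+-]?[0-9]*\\.", "", x[plain]))
  out
}

# Read an entire file (optionally gzipped) as a raw vector.
read_raw_file <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  chunks <- list()
  repeat {
    b <- readBin(con, raw(), n = 1048576L)
    if (!length(b)) break
    chunks[[length(chunks) + 1L]] <- b
  }
  unlist(chunks, use.names = FALSE) %||% raw(0)
}

write_raw_file <- function(bytes, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(bytes, con)
  invisible(path)
}

write_text_file <- function(text, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(text, con, sep = "")
  invisible(path)
}

read_text_file <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  paste(readLines(con, warn = FALSE), collapse = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
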