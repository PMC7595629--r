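# BinaryCIF container: masks, serialization, self-description, sizes.

test_that("masks code present/not-present/unknown as 0/1/2 and compress", {
  col <- cif_column("c", c("A", "", ""), c(0L, 2L, 1L))
  m <- encode_mask(col)
  expect_equal(decode_chain(m), c(0, 2, 1))
  # all-present columns omit the mask entirely
  expect_null(encode_mask(cif_column("c", c("A", "B"))))
  # one unknown among 10000 present rows: run-length dominates the chain
  big <- cif_column("c", c(rep("1", 5000), "", rep("1", 5000)),
                    c(rep(0L, 5000), 2L, rep(0L, 5000)))
  m <- encode_mask(big)
  expect_match(describe_chain(m$encoding), "RunLength")
  expect_lt(encoded_size(m), 100)
})

test_that("an empty file encodes to a valid container", {
  bytes <- encode_bcif(cif_file())
  msg <- msgpack_unpack(bytes)
  expect_equal(length(msg$dataBlocks), 0L)
  expect_true(is.character(msg$encoder))
  expect_true(is.character(msg$version))
  expect_equal(length(decode_bcif(bytes)$blocks), 0L)
})

test_that("binary round trip preserves kinds, strings and numbers", {
  f <- small_structure()
  f2 <- decode_bcif(encode_bcif(f))
  cmp <- semantically_equal(f, f2)
  expect_true(cmp$equal, info = paste(cmp$differences, collapse = "; "))
})

test_that("coordinate columns default to fixed-point factor 1000", {
  f <- small_structure()
  msg <- msgpack_unpack(encode_bcif(f))
  cats <- msg$dataBlocks[[1]]$categories
  atom <- cats[[which(vapply(cats, `[[`, character(1), "name") ==
                        "atom_site")]]
  cols <- vapply(atom$columns, `[[`, character(1), "name")
  for (ax in c("Cartn_x", "Cartn_y", "Cartn_z")) {
    enc <- atom$columns[[which(cols == ax)]]$data$encoding
    expect_equal(enc[[1]]$kind, "FixedPoint")
    expect_equal(enc[[1]]$factor, 1000)
  }
})

test_that("the decoder is driven purely by the stored chain", {
  # hand-assemble a container with a nonstandard-but-legal chain: double
  # Delta plus 2-byte packing for a column the classifier would encode
  # differently
  v <- c(5, 6, 8, 11, 15, 20)
  d1 <- encode_delta(v)
  d2 <- encode_delta(d1$data)
  packed <- encode_integer_packing(d2$data, 2L, FALSE)
  term <- encode_byte_array(packed$data, 2L)
  column <- list(name = "odd",
                 data = list(encoding = list(d1$step, d2$step, packed$step,
                                             term$step),
                             data = term$data),
                 mask = NULL)
  container <- msgpack_pack(list(
    version = "1.0.0", encoder = "hand-assembled",
    dataBlocks = list(list(header = "H", categories = list(
      list(name = "weird", rowCount = 6L, columns = list(column)))))))
  f <- decode_bcif(container)
  col <- get_column(get_category(get_block(f, 1), "weird"), "odd")
  expect_equal(col$values, as.character(v))
})

test_that("containers with underscored category names still resolve", {
  f <- small_structure()
  msg <- msgpack_unpack(encode_bcif(f))
  msg$dataBlocks[[1]]$categories[[1]]$name <-
    paste0("_", msg$dataBlocks[[1]]$categories[[1]]$name)
  f2 <- decode_bcif(msgpack_pack(msg))
  expect_true(semantically_equal(f, f2)$equal)
})

test_that("format errors cite the offending construct", {
  f <- small_structure()
  msg <- msgpack_unpack(encode_bcif(f))
  msg$dataBlocks[[1]]$categories[[1]]$columns[[1]]$data$encoding[[1]]$kind <-
    "NotACodec"
  expect_error(decode_bcif(msgpack_pack(msg)), "NotACodec")
  expect_error(decode_bcif(msgpack_pack(list(hello = 1))), "dataBlocks")
  # truncated payload
  msg2 <- msgpack_unpack(encode_bcif(f))
  col <- msg2$dataBlocks[[1]]$categories[[6]]$columns[[2]]
  col$data$data <- col$data$data[1:3]
  msg2$dataBlocks[[1]]$categories[[6]]$columns[[2]] <- col
  expect_error(decode_bcif(msgpack_pack(msg2)), class = "cif_format_error")
})

test_that("semantic comparison applies per-column numeric tolerances", {
  f <- small_structure()
  g <- f
  x <- g$blocks[[1]]$categories$atom_site$columns$Cartn_x
  v <- as.numeric(x$values)
  v[10] <- v[10] + 0.0004
  g$blocks[[1]]$categories$atom_site$columns$Cartn_x <-
    cif_column("Cartn_x", formatC(v, format = "f", digits = 4), x$kinds)
  tol <- c("atom_site.Cartn_x" = 0.0005)
  expect_true(semantically_equal(f, g, tolerances = tol)$equal)
  v[10] <- v[10] - 0.0004 + 0.001
  g$blocks[[1]]$categories$atom_site$columns$Cartn_x <-
    cif_column("Cartn_x", formatC(v, format = "f", digits = 4), x$kinds)
  cmp <- semantically_equal(f, g, tolerances = tol)
  expect_false(cmp$equal)
  expect_match(cmp$differences[1], "Cartn_x row 10")
  # kind mismatches are divergences with a citation
  h <- f
  ch <- h$blocks[[1]]$categories$atom_site$columns$pdbx_formal_charge
  k <- ch$kinds
  k[which(k == 2L)[1]] <- 1L
  h$blocks[[1]]$categories$atom_site$columns$pdbx_formal_charge <-
    cif_column("pdbx_formal_charge", ch$values, k)
  cmp <- semantically_equal(f, h)
  expect_false(cmp$equal)
  expect_match(cmp$differences[1], "kind")
})

test_that("binary is smaller than text, also after gzip, also pruned", {
  f <- generate_structure_cif(synthetic_structure_spec(
    n_chains = 2L, residues_per_chain = 50L, seed = 5L))
  txt <- charToRaw(format_cif(f))
  bin <- encode_bcif(f)
  expect_lt(length(bin), length(txt))
  expect_lte(length(memCompress(bin, "gzip")),
             length(memCompress(txt, "gzip")))
  pruned <- prune_cif(f, "atom_site")
  expect_lt(length(encode_bcif(pruned)), length(bin))
  expect_lt(nchar(format_cif(pruned)), length(txt))
})
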