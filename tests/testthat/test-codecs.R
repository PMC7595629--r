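# The seven column codecs: worked examples, error contracts, chain
# composition and the lossless round-trip property.

test_that("byte array packs little-endian and checks ranges", {
  e <- encode_byte_array(numeric(0), 3L)
  expect_identical(e$data, raw(0))
  expect_error(encode_byte_array(c(1, 256), 4L), "index 2")
  # two's-complement Int8: -1 -> 0xff
  e <- encode_byte_array(c(-1, 2), 1L)
  expect_identical(e$data, as.raw(c(0xff, 0x02)))
  expect_equal(decode_step(e$step, e$data), c(-1, 2))
  # little-endian Int32: 1 -> 01 00 00 00
  e <- encode_byte_array(1, 3L)
  expect_identical(e$data, as.raw(c(1, 0, 0, 0)))
  # unsigned widths and floats round trip
  for (tc in c(1L, 2L, 3L, 4L, 5L, 6L)) {
    v <- c(0, 1, 100)
    e <- encode_byte_array(v, tc)
    expect_equal(decode_step(e$step, e$data), v)
  }
  e <- encode_byte_array(c(-1.25, 3e100), 33L)
  expect_identical(decode_step(e$step, e$data), c(-1.25, 3e100))
  expect_error(decode_step(list(kind = "ByteArray", type = 3L),
                           as.raw(1:5)), "not divisible")
})

test_that("fixed point multiplies, rounds half away from zero, inverts", {
  e <- encode_fixed_point(1.2345, 1000)
  expect_equal(e$data, 1235)
  expect_true(abs(decode_step(e$step, e$data) - 1.2345) <= 0.0005 + 1e-12)
  expect_equal(encode_fixed_point(0, 10)$data, 0)
  expect_equal(encode_fixed_point(-1.2345, 1000)$data, -1235)
  # three-decimal coordinates at factor 1000 are exact
  v <- round(runif(50, -99, 99), 3)
  e <- encode_fixed_point(v, 1000)
  expect_identical(decode_step(e$step, e$data), v)
  expect_error(encode_fixed_point(c(1, Inf), 1000), "non-finite")
  expect_error(encode_fixed_point(1e8, 1e6), "overflow")
})

test_that("run length collapses repeats into value,count pairs", {
  expect_equal(encode_run_length(c(1, 1, 1, 1))$data, c(1, 4))
  expect_equal(encode_run_length(c(5, 5, 7))$data, c(5, 2, 7, 1))
  e <- encode_run_length(numeric(0))
  expect_equal(e$data, numeric(0))
  expect_equal(e$step$srcSize, 0L)
  expect_equal(decode_step(e$step, e$data), numeric(0))
  # counts must sum to srcSize
  expect_error(decode_step(list(kind = "RunLength", srcSize = 5L),
                           c(1, 4)), "srcSize")
})

test_that("delta stores origin plus consecutive differences", {
  e <- encode_delta(1:10)
  expect_equal(e$step$origin, 1)
  expect_equal(e$data, c(0, rep(1, 9)))
  expect_equal(decode_step(e$step, e$data), as.numeric(1:10))
  e <- encode_delta(42)
  expect_equal(e$step$origin, 42)
  expect_equal(e$data, 0)
  e <- encode_delta(c(10, 11, 12))
  expect_equal(e$data, c(0, 1, 1))
  expect_equal(decode_step(e$step, e$data), c(10, 11, 12))
  expect_error(encode_delta(c(-2e9, 2e9)), "difference")
})

test_that("interval quantization bins, clamps and bounds the error", {
  e <- encode_interval_quantization(c(0, 1, 0.5), 0, 1, 256L)
  expect_equal(e$data, c(0, 255, 128)) # 127.5 rounds away from zero
  dec <- decode_step(e$step, e$data)
  expect_equal(dec[3], 128 / 255)
  # outliers clamp to the boundary bins
  e <- encode_interval_quantization(c(-5, 7), 0, 1, 256L)
  expect_equal(e$data, c(0, 255))
  expect_error(encode_interval_quantization(1, 2, 2, 256L), "min < max")
  for (steps in c(256L, 65536L)) {
    v <- runif(500, -3, 3)
    e <- encode_interval_quantization(v, -3, 3, steps)
    err <- abs(decode_step(e$step, e$data) - v)
    expect_lte(max(err), 6 / (2 * (steps - 1)) + 1e-12)
  }
})

test_that("integer packing emits saturated runs plus residues", {
  expect_equal(encode_integer_packing(300, 1L, FALSE)$data, c(127, 127, 46))
  expect_equal(encode_integer_packing(127, 1L, FALSE)$data, c(127, 0))
  expect_equal(encode_integer_packing(5, 1L, FALSE)$data, 5)
  expect_equal(encode_integer_packing(-300, 1L, FALSE)$data,
               c(-128, -128, -44))
  expect_equal(encode_integer_packing(255, 1L, TRUE)$data, c(255, 0))
  expect_error(encode_integer_packing(-1, 1L, TRUE), "unsigned")
  for (bc in c(1L, 2L)) {
    for (uns in c(TRUE, FALSE)) {
      v <- if (uns) c(0, 1, 2^20, 255, 65535) else
        c(0, -1, 2^20, -2^20, 127, -128)
      e <- encode_integer_packing(v, bc, uns)
      expect_equal(decode_step(e$step, e$data), v,
                   info = paste(bc, uns))
      b <- if (uns) 2^(8 * bc) - 1 else 2^(8 * bc - 1) - 1
      expect_true(all(e$data <= b))
    }
  }
  # a payload ending inside a run is malformed
  expect_error(decode_step(list(kind = "IntegerPacking", byteCount = 1L,
                                isUnsigned = FALSE, srcSize = 1L),
                           c(127)), "ends inside a run")
})

test_that("string array concatenates uniques in first-occurrence order", {
  e <- encode_string_array(c("ALA", "GLY", "ALA"))
  step <- e$encoding[[1]]
  expect_equal(step$stringData, "ALAGLY")
  expect_equal(decode_chain(list(encoding = step$offsetEncoding,
                                 data = step$offsets)), c(0, 3, 6))
  expect_equal(decode_chain(list(encoding = step$dataEncoding,
                                 data = e$data)), c(0, 1, 0))
  expect_equal(decode_chain(e), c("ALA", "GLY", "ALA"))
  # all rows identical -> one unique string
  e <- encode_string_array(rep("HOH", 50))
  expect_equal(e$encoding[[1]]$stringData, "HOH")
  expect_equal(decode_chain(e), rep("HOH", 50))
  # empty column
  e <- encode_string_array(character(0))
  expect_equal(e$encoding[[1]]$stringData, "")
  expect_equal(decode_chain(e), character(0))
  # masked rows carry index -1 and decode to empty payloads
  e <- encode_string_array(c("A", "", "B"), kinds = c(0L, 2L, 0L))
  expect_equal(decode_chain(list(encoding = e$encoding[[1]]$dataEncoding,
                                 data = e$data)), c(0, -1, 1))
  expect_equal(decode_chain(e), c("A", "", "B"))
})

test_that("string array invariants hold on random columns", {
  for (i in 1:30) {
    col <- random_string_column(i)
    e <- encode_string_array(col$values, col$kinds)
    step <- e$encoding[[1]]
    offs <- decode_chain(list(encoding = step$offsetEncoding,
                              data = step$offsets))
    idx <- decode_chain(list(encoding = step$dataEncoding, data = e$data))
    expect_true(all(diff(offs) >= 0))
    expect_true(all(idx >= -1 & idx < length(offs)))
    expect_equal(decode_chain(e), col$values)
  }
})

test_that("chains compose left-to-right and decode right-to-left", {
  ids <- 1:50
  e <- apply_chain(ids, list("Delta", "RunLength"))
  kinds <- vapply(e$encoding, `[[`, character(1), "kind")
  expect_equal(kinds, c("Delta", "RunLength", "ByteArray"))
  # intermediate integer stream before terminal packing: [0,1,1,49]
  pre <- decode_step(e$encoding[[3]], e$data)
  expect_equal(pre, c(0, 1, 1, 49))
  expect_equal(decode_chain(e), as.numeric(ids))
  # a single ByteArray step is the identity chain
  e <- apply_chain(c(3, 1, 2), list("ByteArray"))
  expect_equal(length(e$encoding), 1L)
  expect_equal(decode_chain(e), c(3, 1, 2))
  # FixedPoint -> Delta -> IntegerPacking round trips within 0.5/factor
  v <- round(cumsum(rnorm(200, 0, 2)), 3)
  e <- apply_chain(v, list(list(kind = "FixedPoint", factor = 1000),
                           "Delta",
                           list(kind = "IntegerPacking", byteCount = 2L)))
  expect_true(max(abs(decode_chain(e) - v)) <= 0.5 / 1000)
  # incompatible composition: integers cannot feed FixedPoint after packing
  expect_error(apply_chain(1:3, list("ByteArray", "Delta")),
               "no step may follow ByteArray")
  expect_error(decode_step(list(kind = "Bogus"), 1), "unknown encoding kind")
})

test_that("every lossless codec inverts exactly on randomized arrays", {
  for (i in 1:120) {
    v <- random_int_array(i)
    chains <- list(list("RunLength"),
                   list(list(kind = "ByteArray",
                             type = narrowest_int_type(v))))
    # delta requires consecutive differences within 32 bits
    if (length(v) < 2 || all(abs(diff(v)) <= 2147483647)) {
      chains <- c(chains, list(list("Delta"), list("Delta", "RunLength")))
    }
    for (chain in chains) {
      e <- apply_chain(v, chain)
      expect_identical(decode_chain(e), v,
                       info = paste("case", i, describe_chain(e$encoding)))
    }
    if (all(abs(v) < 2^30)) {
      e <- apply_chain(v, list(list(kind = "IntegerPacking",
                                    byteCount = sample(1:2, 1))))
      expect_identical(decode_chain(e), v, info = paste("packing case", i))
    }
    f <- random_float_array(i)
    e <- apply_chain(f, list(list(kind = "FixedPoint", factor = 10000)))
    expect_equal(decode_chain(e), f, tolerance = 1e-12,
                 info = paste("fixed point case", i))
  }
})
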