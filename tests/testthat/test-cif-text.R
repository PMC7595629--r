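# Text CIF tokenizer, parser and writer.

test_that("key-value items, loops and masked tokens parse correctly", {
  f <- parse_cif(tiny_mmcif_text())
  b <- get_block(f, 1)
  expect_equal(b$header, "1ABC")
  cell <- get_category(b, "cell")
  expect_equal(cell$row_count, 1L)
  expect_equal(get_value(get_column(cell, "length_a"), 1)$payload, "10.0")
  # a two-column loop with 6 values has rowCount 3
  atom <- get_category(b, "atom_site")
  expect_equal(atom$row_count, 3L)
  expect_equal(get_column(atom, "label_atom_id")$values,
               c("N", "CA", "C1'"))
  # key-value and looped categories coexist in one block
  expect_setequal(names(b$categories),
                  c("cell", "struct", "atom_site", "atom_sites"))
})

test_that("semicolon text fields and quoted special tokens tokenize", {
  txt <- paste("data_X",
               "_a.multi",
               ";", "multi", "line", ";",
               "_a.q '?'",
               "_a.d '.'",
               sep = "\n")
  f <- parse_cif(txt)
  a <- get_category(get_block(f, 1), "a")
  expect_equal(get_value(get_column(a, "multi"), 1)$payload, "multi\nline")
  # quoting suppresses the special meaning of ? and .
  expect_equal(get_value(get_column(a, "q"), 1),
               list(kind = "present", payload = "?"))
  expect_equal(get_value(get_column(a, "d"), 1)$kind, "present")
})

test_that("parse errors carry line numbers and describe the fault", {
  expect_error(parse_cif("data_X\n_a.b 'unterminated\n"),
               "unterminated quoted value at line 2")
  expect_error(parse_cif("data_X\n_a.b\n;\nnever closed\n"),
               "unterminated semicolon")
  expect_error(parse_cif("_a.b 1\n"), "outside any data block")
  expect_error(
    parse_cif("data_X\nloop_\n_a.x\n_a.y\n1 2 3\n"),
    "not a multiple")
})

test_that("save_ frames and global_ are tolerated and skipped", {
  txt <- paste("data_D",
               "global_",
               "save_frame1",
               "_ignored.tag 1",
               "save_",
               "_kept.tag 2",
               sep = "\n")
  f <- parse_cif(txt)
  b <- get_block(f, 1)
  expect_null(get_category(b, "ignored"))
  expect_equal(get_value(get_column(get_category(b, "kept"), "tag"),
                         1)$payload, "2")
})

test_that("writer quotes minimally and round trips hostile values", {
  col_vals <- c("plain", "C1'", "has space", "it's", "a\"b", "?", ".",
                "_tag", "multi\nline", "", "data_x", "loop_")
  f <- cif_file(list(cif_block("Q", list(
    cif_category("t", list(cif_column("v", col_vals)))))))
  txt <- format_cif(f)
  # a value containing a single quote takes double quotes
  expect_match(txt, "\"C1'\"", fixed = TRUE)
  expect_match(txt, "'?'", fixed = TRUE)
  back <- parse_cif(txt)
  expect_true(semantically_equal(f, back)$equal)
  expect_equal(get_column(get_category(get_block(back, 1), "t"), "v")$values,
               col_vals)
})

test_that("a value with a line starting ';' cannot be written", {
  f <- cif_file(list(cif_block("Q", list(
    cif_category("t", list(cif_column("v", "bad\n;payload")))))))
  expect_error(format_cif(f), "semicolon")
})

test_that("empty blocks and zero-row categories survive a round trip", {
  f <- cif_file(list(cif_block("EMPTY", list()),
                     cif_block("Z", list(cif_category("zero", list(
                       cif_column("a", character(0))))))))
  txt <- format_cif(f)
  expect_match(txt, "data_EMPTY\n", fixed = TRUE)
  back <- parse_cif(txt)
  expect_equal(length(back$blocks), 2L)
  expect_equal(get_category(get_block(back, 2), "zero")$row_count, 0L)
  expect_true(semantically_equal(f, back)$equal)
})

test_that("random columns round trip through text exactly", {
  for (i in 1:25) {
    col <- random_string_column(i)
    f <- cif_file(list(cif_block("R", list(cif_category("c", list(col))))))
    back <- parse_cif(format_cif(f))
    cmp <- semantically_equal(f, back)
    expect_true(cmp$equal, info = paste("case", i, ":",
                                        paste(cmp$differences,
                                              collapse = "; ")))
  }
})

test_that("multi-block files preserve order through write/parse", {
  f <- cif_file(lapply(c("A", "B", "C"), function(h) {
    cif_block(h, list(cif_category("t", list(cif_column("v", h)))))
  }))
  back <- parse_cif(format_cif(f))
  expect_equal(vapply(back$blocks, `[[`, character(1), "header"),
               c("A", "B", "C"))
})

test_that("gemmi independently agrees with the parser on a fixture", {
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(tiny_mmcif_text(), path)
  script <- paste(
    "import sys, json, gemmi",
    "doc = gemmi.cif.read(sys.argv[1])",
    "b = doc.sole_block()",
    "out = {",
    " 'x': [gemmi.cif.as_string(v) for v in",
    "       b.find_values('_atom_site.Cartn_x')],",
    " 'atoms': [gemmi.cif.as_string(v) for v in",
    "       b.find_values('_atom_site.label_atom_id')],",
    " 'a': gemmi.cif.as_string(b.find_value('_cell.length_a'))}",
    "print(json.dumps(out))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), path), stdout = TRUE)
  got <- jsonlite::fromJSON(paste(out, collapse = ""))
  atom <- get_category(get_block(parse_cif(tiny_mmcif_text()), 1),
                       "atom_site")
  expect_equal(got$x, get_column(atom, "Cartn_x")$values)
  expect_equal(got$atoms, get_column(atom, "label_atom_id")$values)
  expect_equal(got$a, "10.0")
})
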