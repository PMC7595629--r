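# Shared fixtures built in code.

# A small hand-written mmCIF snippet exercising key-value items, a loop,
# masked cells, quoting and an adversarial category-name pair.
tiny_mmcif_text <- function() {
  paste(
    "data_1ABC",
    "# a comment",
    "_cell.length_a 10.0",
    "_cell.length_b 12.5",
    "_struct.title 'A synthetic entry'",
    "loop_",
    "_atom_site.id",
    "_atom_site.label_atom_id",
    "_atom_site.Cartn_x",
    "_atom_site.pdbx_formal_charge",
    "1 N   1.000 ?",
    "2 CA  2.500 .",
    "3 C1' 3.250 0",
    "loop_",
    "_atom_sites.entry_id",
    "_atom_sites.fract_transf_matrix11",
    "1ABC 0.1",
    sep = "\n")
}

# Random integer arrays spanning widths, signs, repeats and empties; i
# indexes a deterministic case.
random_int_array <- function(i) {
  set.seed(1000L + i)
  n <- sample(c(0L, 1L, 2L, sample(3:200, 1L)), 1L,
              prob = c(.05, .1, .1, .75))
  style <- sample(1:5, 1L)
  v <- switch(style,
    sample(-5:5, n, replace = TRUE),                       # tiny, signed
    rep(sample(-1000:1000, 1L), n),                        # constant
    seq_len(n) + sample(-50:50, 1L),                       # sequential
    sample(c(-2147483647L, -32768L, -128L, 0L, 127L, 128L, # bounds
             32767L, 65535L, 2147483647L), n, replace = TRUE),
    as.integer(round(cumsum(stats::rnorm(n, 0, 300))))     # walk
  )
  as.numeric(v)
}

random_float_array <- function(i) {
  set.seed(2000L + i)
  n <- sample(0:150, 1L)
  digits <- sample(0:4, 1L)
  round(stats::rnorm(n, 0, 50), digits)
}

# Column with randomized payloads and mask codes.
random_string_column <- function(i) {
  set.seed(3000L + i)
  n <- sample(0:100, 1L)
  pool <- c("ALA", "GLY", "it's", "a\"b", "x y", "?", ".", "_tag", "",
            "loop_", "C1'", "multi\nline", "\nleads with newline",
            strrep("Z", 40))
  kinds <- sample(0:2, n, replace = TRUE, prob = c(.8, .1, .1))
  vals <- sample(pool, n, replace = TRUE)
  vals[kinds != 0L] <- ""
  cif_column(paste0("col", i), vals, kinds)
}

small_structure <- function(seed = 11L) {
  generate_structure_cif(synthetic_structure_spec(
    n_chains = 2L, residues_per_chain = 10L, seed = seed))
}
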