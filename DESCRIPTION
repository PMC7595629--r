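Package: bcif
Title: Reading, Writing and Compressing Macromolecular CIF Files with
    BinaryCIF
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for macromolecular structure data in the CIF family of
    formats. Parses and writes text CIF 1.1 (PDBx/mmCIF dialect), encodes
    and decodes the column-oriented BinaryCIF serialization (MessagePack
    container with delta, run-length, integer-packing, fixed-point,
    interval-quantization, byte-array and string-array column codecs), and
    selects per-column encoding chains automatically to minimize encoded
    size. Provides a unified generic data-access model shared by both
    formats, schema-typed access and validation for common mmCIF
    categories, category pruning, deterministic synthetic-structure
    generators for testing, and a command-line front end for conversion,
    statistics, pruning and round-trip checking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
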