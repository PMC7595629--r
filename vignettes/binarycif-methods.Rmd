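---
title: "Column codecs, encoding selection and the BinaryCIF container"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Column codecs, encoding selection and the BinaryCIF container}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcif)
```

## The data model and why it is column-oriented

A CIF file is a list of data blocks; a block is a set of categories; a
category is a table whose columns share one row count; a cell is either a
present value (kept as its verbatim text payload), unknown (`?`) or not
applicable (`.`). `bcif` keeps this model identical for text and binary
sources, so code written against `get_block()` / `get_category()` /
`get_column()` / `get_value()` cannot tell where the data came from.

Two representation choices matter downstream:

- **Payloads stay text in the generic model.** Numbers are only parsed on
  demand (by the typed layer or the binary encoder). This makes the text
  round trip `parse_cif(format_cif(f))` exactly lossless and defers all
  typing decisions to the point where a type is actually declared.
- **Category names are canonicalized without the leading underscore**
  (`atom_site`, not `_atom_site`); both spellings are accepted on lookup
  and in containers. Readers strip the underscore once, writers re-add it.

## The seven codecs

Each encoder emits a *step*: a small named list carrying the codec kind
and every parameter needed to invert it. Chains apply left to right and
decode right to left; the terminal step is always a ByteArray that fixes
the element type (type codes 1–6 for Int8…Uint32, 32/33 for floats,
little-endian) so the payload is a plain byte string.

| Codec | Parameters | Lossy? |
|---|---|---|
| ByteArray | element type | no |
| FixedPoint | factor, source float type | no, at the printed precision |
| RunLength | source length | no |
| Delta | origin, source type | no |
| IntervalQuantization | min, max, numSteps | yes, ≤ half a bin |
| IntegerPacking | byteCount, isUnsigned, source length | no |
| StringArray | stringData, offsets + two nested chains | no |

Numerical conventions worth stating explicitly:

- **Rounding is half away from zero** in FixedPoint and
  IntervalQuantization (`floor(|x| + 0.5) * sign(x)`). Base R's round
  halves to even, which would make encodings depend on parity;
  half-away-from-zero is deterministic and symmetric. Cross-implementation
  byte identity with other BinaryCIF encoders is *not* promised for exact
  `.5` cases, only semantic round-trip fidelity.
- **Delta stores the first element as `origin` and emits a leading 0** in
  the payload, so decode is `origin + cumsum(payload)`. An empty array has
  origin 0 and an empty payload.
- **IntegerPacking** represents a value as zero or more saturated bound
  markers (e.g. 127 at signed byte width) followed by a residue; a value
  equal to the bound therefore needs an explicit 0 terminator
  (`127 → [127, 0]`). The decoder validates that payload values respect
  the declared width and that the payload does not end inside a run.
- **IntervalQuantization** with `numSteps` levels uses bin width
  `(max − min)/(numSteps − 1)`; in-range values reconstruct to within half
  a bin, and out-of-range values clamp to the boundary bins, which is how
  outliers are deliberately discarded when `min`/`max` are chosen tighter
  than the data. 256 and 65,536 steps fill exactly one and two bytes.
- **StringArray offsets are byte offsets** into the UTF-8 concatenation of
  unique strings (first-occurrence order); extraction slices the raw
  bytes, so multi-byte characters are safe. Masked rows carry index −1 in
  the index array, but the column mask remains the authority on which rows
  are absent; the decoder accepts both −1 and mask-only conventions.
- **All encoders accept length 0** and produce empty payloads with
  consistent parameters.

## Automatic encoding selection

`detect_column_kind()` classifies a column by inspecting *present*
payloads only: integer if all are integer literals (within 32-bit range —
larger integers fall back to string, since the codec family is 32-bit),
float if all are decimal numbers, string otherwise.

For floats, `infer_fixed_point_factor()` finds the smallest `10^k`
(`k ≤ min(printed decimals, 6)`) reproducing every value within a relative
tolerance of `1e-9 · max(1, |v|)` without overflowing 32 bits; if none
exists the column is stored as Float64. Note one consequence of the
relative tolerance: very large magnitudes can legitimately select a factor
smaller than their printed decimals (the error is still below a part in
10⁹). Coordinates at usual magnitudes always get their exact factor, 1000
for the three decimals mmCIF prints. Lossy precision is strictly opt-in
via hints or `--coord-precision`/`--allow-lossy`; nothing lossy ever
happens by default.

For integers, five candidate chains are built — plain ByteArray at the
narrowest width, IntegerPacking, RunLength, Delta, Delta→RunLength, the
latter three finished by whichever of packing or plain bytes is smaller —
and the winner is the one whose **actual serialized container entry**
(payload plus step metadata, measured by running the MessagePack writer)
is smallest, ties resolved in the order above. Measuring real serialized
bytes rather than payload length means verbose step metadata counts
against a candidate, which is the honest reading of "minimal number of
bytes". Delta candidates drop out when a consecutive difference would
overflow 32 bits. Masked rows contribute a filler 0 to numeric streams;
the mask carries the truth.

The exact candidate family and tie-break order used by other BinaryCIF
encoders is unpublished, so byte-identical output with them is a non-goal;
self-descriptive decoding makes that unnecessary.

## The container and masks

The MessagePack layout is
`{version, encoder, dataBlocks: [{header, categories: [{name, rowCount,
columns: [{name, data: {encoding, data}, mask}]}]}]}` with mask codes
0 = present, 1 = not present (`.`), 2 = unknown (`?`). Masks are omitted
when every row is present and are otherwise compressed through the same
integer classifier (a single `?` among thousands of present rows collapses
to a three-pair run-length chain). MessagePack itself is implemented in
the package (the stack has no R MessagePack library): the subset of
types the container needs, with hand-computed byte oracles from the format
specification frozen in the tests.

On decode, fixed-point columns re-materialize as text with exactly the
`k = log10(factor)` decimals, making text → binary → text idempotent for
fixed-decimal data; plain float columns print the shortest decimal text
that parses back to the same double; integers print as integers. The
decoder never consults the classifier — containers assembled by hand with
nonstandard-but-legal chains (tested: RunLength→Delta, double Delta with
2-byte packing) decode identically.

## Text syntax decisions

Input is read permissively: UTF-8, no line-length enforcement, keywords
case-insensitive, tags case-sensitive, `save_`/`global_` dictionary frames
skipped. Quoted `'?'`/`'.'` are ordinary strings; only bare tokens are
masks. The writer quotes minimally (bare, `'…'`, `"…"`, then a semicolon
block when a value contains a newline or both quote kinds) and errors on
the one value class CIF 1.1 cannot represent: text containing a line that
itself starts with `;`. In semicolon fields, the remainder of the opening
`;` line is the first value line; when it is empty the value starts on the
next line, and the writer inserts an explicit empty first line for values
that genuinely begin with a newline so the convention round-trips.

CIF 2.0 syntax (list/table values, triple quotes) is out of scope; such
values pass through as plain text.

## What the synthetic generators emulate — and what they do not

`generate_structure_cif()` reproduces the statistical shapes the codecs
exploit: sequential ids, cycling atom names, repetitive residue/chain
labels, fixed-decimal coordinates following a seeded random walk (step SD
1.5 Å — local, bond-length-scale moves, because spatial locality is what
makes delta chains effective on coordinates; i.i.d. positions would not
show this), mostly-constant occupancies, two-decimal B factors, and
sparse `?`/`.` cells (default rate 0.05 each in `pdbx_formal_charge` and
`label_alt_id`, giving the near-uniform masks typical of archive files).
Structure factors enumerate a compact cubic hkl grid (monotone, hence
delta-friendly) with exponential amplitudes. Density stand-ins are
Gaussian draws.

These fixtures are *not* physically realistic structures: no covalent
geometry, no symmetry, no real density maps, and their category roster is
a small subset of a real archive entry. Passing tests therefore
demonstrate correctness of the codecs, the classifier's minimality within
its candidate family, and the direction of the size comparisons — not the
absolute archive-scale compression figures, which depend on real data and
were measured elsewhere on the full PDB. Default problem sizes (8000-atom
structure, 20,000 reflections, 10⁵ density values, several hundred
randomized arrays) were chosen as the smallest scales at which every
compression effect is clearly expressed.

The generators seed a local RNG and restore the caller's state, so
identical spec + seed yields byte-identical CIF text on any platform using
R's default Mersenne-Twister.

## Schema layer

Schemas are declarative data (`schema_def()`, or YAML via
`schema_from_yaml()`): per category, per column, a type in
`{int, float, str}` and a required flag. This replaces dictionary-driven
code generation with the same typed-access contract and nothing to
regenerate. The bundled `mmcif_schema()` covers the common
coordinate/topology categories; anything undeclared stays reachable
schema-lessly. Typed access refuses to coerce silently: masked rows come
back as `NA` plus a kind flag, and a malformed payload under a numeric
declaration is an error citing its row. The `mmtf-like` pruning profile is
the schema's category list — a documented approximation of the reduced
coordinate representation, user-overridable via `prune_cif(file, keep)`.

## Known limitations

- 64-bit integer columns are preserved as strings, not packed numerically.
- No streaming or partial decode; files are materialized in memory.
- `getTable`-style mutation APIs are out of scope; the model is
  read/transform/write.
- Byte identity with other BinaryCIF implementations is not guaranteed
  (rounding of exact halves, candidate tie-breaks); semantic equality is.
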