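# Deterministic synthetic-data generators.
#
# These emulate the statistical structure the column codecs exploit in real
# macromolecular files: sequential identifiers (delta-friendly), highly
# repetitive annotation strings, fixed-decimal coordinates following a
# random walk (local, covalent-geometry-like steps rather than i.i.d.
# positions, which is what makes delta encoding pay off), near-uniform
# masks, compact reflection index grids, and Gaussian density-like floats.
# All generators are seeded and leave the caller's RNG state untouched.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

BACKBONE8 <- c("N", "CA", "C", "O", "CB", "CG", "CD", "CE")

#' Parameters of the synthetic structure generator
#'
#' @param n_chains Number of chains.
#' @param residues_per_chain Residues per chain.
#' @param atoms_per_residue Atoms per residue (default 8).
#' @param coord_step Random-walk step scale in Angstrom (default 1.5,
#'   roughly a covalent-bond-length move per atom).
#' @param coord_decimals Printed coordinate decimals (default 3, the mmCIF
#'   convention matching the lossless fixed-point factor 1000).
#' @param unknown_rate Fraction of `?` cells in `pdbx_formal_charge`.
#' @param not_present_rate Fraction of `.` cells in `label_alt_id`.
#' @param seed RNG seed; identical spec + seed gives byte-identical CIF
#'   text.
#' @return A `synthetic_structure_spec` list.
#' @export
synthetic_structure_spec <- function(n_chains = 2L, residues_per_chain = 50L,
                                     atoms_per_residue = 8L,
                                     coord_step = 1.5, coord_decimals = 3L,
                                     unknown_rate = 0.05,
                                     not_present_rate = 0.05, seed = 42L) {
  stopifnot(n_chains >= 1L, residues_per_chain >= 1L, atoms_per_residue >= 1L,
            coord_step > 0, coord_decimals >= 0L,
            unknown_rate >= 0, unknown_rate <= 1,
            not_present_rate >= 0, not_present_rate <= 1)
  structure(list(n_chains = as.integer(n_chains),
                 residues_per_chain = as.integer(residues_per_chain),
                 atoms_per_residue = as.integer(atoms_per_residue),
                 coord_step = coord_step,
                 coord_decimals = as.integer(coord_decimals),
                 unknown_rate = unknown_rate,
                 not_present_rate = not_present_rate,
                 seed = as.integer(seed)),
            class = "synthetic_structure_spec")
}

#' Generate a synthetic mmCIF-style structure
#'
#' Builds an `atom_site` category with sequential ids, cycling atom names,
#' amino-acid residue names, per-chain asym ids, repeating sequence ids,
#' random-walk coordinates at fixed decimals, mostly-1.00 occupancies,
#' two-decimal B factors and sparse `?`/`.` cells, plus small `cell`,
#' `symmetry`, `entity`, `struct_asym` and `chem_comp` categories.
#'
#' @param spec A [synthetic_structure_spec()].
#' @return A [cif_file] with one data block.
#' @export
generate_structure_cif <- function(spec = synthetic_structure_spec()) {
  stopifnot(inherits(spec, "synthetic_structure_spec"))
  with_seed(spec$seed, {
    n_res <- spec$n_chains * spec$residues_per_chain
    n <- n_res * spec$atoms_per_residue
    chain_ids <- make.unique(rep(LETTERS, length.out = spec$n_chains),
                             sep = "")
    if (spec$n_chains <= 26L) chain_ids <- LETTERS[seq_len(spec$n_chains)]

    comp <- sample(AA3, n_res, replace = TRUE)
    atom_names <- rep(BACKBONE8, length.out = spec$atoms_per_residue)
    elem <- substring(atom_names, 1L, 1L)

    fmt_coord <- function(x) {
      formatC(round(x, spec$coord_decimals), format = "f",
              digits = spec$coord_decimals)
    }
    walk <- function() cumsum(stats::rnorm(n, 0, spec$coord_step))

    occ <- ifelse(stats::runif(n) < 0.98, "1.00", "0.50")
    biso <- formatC(stats::runif(n, 5, 80), format = "f", digits = 2)
    charge_kinds <- ifelse(stats::runif(n) < spec$unknown_rate,
                           KIND_UNKNOWN, KIND_PRESENT)
    alt_kinds <- ifelse(stats::runif(n) < spec$not_present_rate,
                        KIND_NOT_PRESENT, KIND_PRESENT)

    atom_site <- cif_category("atom_site", list(
      cif_column("group_PDB", rep("ATOM", n)),
      cif_column("id", as.character(seq_len(n))),
      cif_column("type_symbol", rep(elem, n_res)),
      cif_column("label_atom_id", rep(atom_names, n_res)),
      cif_column("label_alt_id",
                 ifelse(alt_kinds == KIND_PRESENT, "A", ""), alt_kinds),
      cif_column("label_comp_id", rep(comp, each = spec$atoms_per_residue)),
      cif_column("label_asym_id",
                 rep(rep(chain_ids, each = spec$residues_per_chain *
                           spec$atoms_per_residue), length.out = n)),
      cif_column("label_entity_id", rep("1", n)),
      cif_column("label_seq_id",
                 as.character(rep(rep(seq_len(spec$residues_per_chain),
                                      each = spec$atoms_per_residue),
                                  spec$n_chains))),
      cif_column("Cartn_x", fmt_coord(walk())),
      cif_column("Cartn_y", fmt_coord(walk())),
      cif_column("Cartn_z", fmt_coord(walk())),
      cif_column("occupancy", occ),
      cif_column("B_iso_or_equiv", biso),
      cif_column("pdbx_formal_charge",
                 ifelse(charge_kinds == KIND_PRESENT, "0", ""), charge_kinds),
      cif_column("pdbx_PDB_model_num", rep("1", n))
    ))

    cell <- cif_category("cell", list(
      cif_column("length_a", "128.460"),
      cif_column("length_b", "128.460"),
      cif_column("length_c", "230.720"),
      cif_column("angle_alpha", "90.00"),
      cif_column("angle_beta", "90.00"),
      cif_column("angle_gamma", "120.00")
    ))
    symmetry <- cif_category("symmetry", list(
      cif_column("entry_id", "SYNTH"),
      cif_column("space_group_name_H-M", "P 1")
    ))
    entity <- cif_category("entity", list(
      cif_column("id", "1"),
      cif_column("type", "polymer"),
      cif_column("pdbx_description", "synthetic polypeptide")
    ))
    struct_asym <- cif_category("struct_asym", list(
      cif_column("id", chain_ids),
      cif_column("entity_id", rep("1", spec$n_chains))
    ))
    comp_unique <- sort(unique(comp))
    chem_comp <- cif_category("chem_comp", list(
      cif_column("id", comp_unique),
      cif_column("type", rep("L-peptide linking", length(comp_unique))),
      cif_column("formula_weight",
                 formatC(stats::runif(length(comp_unique), 75, 250),
                         format = "f", digits = 3))
    ))

    cif_file(list(cif_block("SYNTH", list(
      entity, cell, symmetry, struct_asym, chem_comp, atom_site
    ))))
  })
}

#' Generate a density-like float column
#'
#' Seeded Gaussian draws standing in for electron-density map values; used
#' to exercise interval quantization bounds and outlier clamping.
#'
#' @param n Number of values (>= 0).
#' @param mean,sd Gaussian parameters.
#' @param seed RNG seed.
#' @return A [cif_column] named `"values"` whose payloads are six-decimal
#'   float text; parse with `as.numeric(col$values)`.
#' @export
generate_density_block <- function(n, mean = 0, sd = 1, seed = 42L) {
  stopifnot(n >= 0)
  with_seed(seed, {
    v <- stats::rnorm(n, mean, sd)
    cif_column("values", formatC(v, format = "f", digits = 6))
  })
}

#' Generate a synthetic structure-factor category
#'
#' Miller indices h, k, l enumerate a compact cubic grid (monotone within
#' each outer index, so delta chains apply); amplitudes F are exponentially
#' distributed with two printed decimals and sigmas are proportional with
#' noise.
#'
#' @param n_reflections Number of reflections (>= 0).
#' @param seed RNG seed.
#' @return A [cif_category] named `"refln"`.
#' @export
generate_structure_factors <- function(n_reflections, seed = 42L) {
  stopifnot(n_reflections >= 0)
  with_seed(seed, {
    n <- as.integer(n_reflections)
    m <- max(1L, ceiling(n^(1 / 3)))
    grid <- expand.grid(l = seq_len(m) - 1L, k = seq_len(m) - 1L,
                        h = seq_len(m) - 1L)
    grid <- grid[seq_len(n), , drop = FALSE]
    f <- round(stats::rexp(n, rate = 1 / 50) + 0.01, 2)
    sig <- round(0.05 * f + abs(stats::rnorm(n, 0, 0.5)) + 0.01, 2)
    cif_category("refln", list(
      cif_column("index_h", as.character(grid$h)),
      cif_column("index_k", as.character(grid$k)),
      cif_column("index_l", as.character(grid$l)),
      cif_column("F_meas_au", formatC(f, format = "f", digits = 2)),
      cif_column("F_meas_sigma_au", formatC(sig, format = "f", digits = 2))
    ))
  })
}

#' Wrap a structure-factor category in a one-block CIF file
#'
#' @inheritParams generate_structure_factors
#' @return A [cif_file].
#' @export
generate_structure_factors_cif <- function(n_reflections, seed = 42L) {
  cif_file(list(cif_block("SYNTHSF",
                          list(generate_structure_factors(n_reflections,
                                                          seed)))))
}
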