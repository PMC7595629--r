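# Schema-typed access, validation and category pruning.
#
# A schema is declarative data (no code generation): per category, per
# column, a declared type ("int", "float" or "str") and a required flag.
# Typed access never silently coerces: a masked row comes back flagged, a
# malformed payload under a numeric declaration is an error citing its row.

#' Define a schema
#'
#' @param categories Named list: each element is a named list of column
#'   declarations, each `list(type = "int"|"float"|"str", required =
#'   TRUE/FALSE)`.  A bare type string is shorthand for an optional column.
#' @return A `cif_schema` object.
#' @export
schema_def <- function(categories) {
  stopifnot(is.list(categories), !is.null(names(categories)))
  categories <- lapply(categories, function(cols) {
    lapply(cols, function(d) {
      if (is.character(d)) d <- list(type = d)
      d$type <- match.arg(d$type, c("int", "float", "str"))
      d$required <- isTRUE(d$required)
      d
    })
  })
  names(categories) <- canonical_category_name(names(categories))
  structure(list(categories = categories), class = "cif_schema")
}

#' Load a schema from a YAML config file
#'
#' Layout: top-level keys are category names; each maps column names to
#' either a type string or a map with `type` and optional `required` keys.
#'
#' @param path Path to a YAML file.
#' @return A `cif_schema`.
#' @export
schema_from_yaml <- function(path) {
  schema_def(yaml::read_yaml(path))
}

#' Built-in mmCIF subset schema
#'
#' Declares the commonly used coordinate and topology categories
#' (atom_site, cell, symmetry, entity, entity_poly, entity_poly_seq,
#' struct_asym, chem_comp, chem_comp_bond, pdbx_struct_assembly,
#' pdbx_struct_assembly_gen, pdbx_struct_oper_list).  Categories outside
#' the schema remain reachable through the generic, schema-less interface.
#'
#' @return A `cif_schema`.
#' @export
mmcif_schema <- function() {
  f <- function(required = FALSE) list(type = "float", required = required)
  i <- function(required = FALSE) list(type = "int", required = required)
  s <- function(required = FALSE) list(type = "str", required = required)
  schema_def(list(
    atom_site = list(
      group_PDB = s(), id = i(TRUE), type_symbol = s(),
      label_atom_id = s(), label_alt_id = s(), label_comp_id = s(),
      label_asym_id = s(), label_entity_id = s(), label_seq_id = i(),
      pdbx_PDB_ins_code = s(), Cartn_x = f(TRUE), Cartn_y = f(TRUE),
      Cartn_z = f(TRUE), occupancy = f(), B_iso_or_equiv = f(),
      pdbx_formal_charge = i(), auth_seq_id = i(), auth_comp_id = s(),
      auth_asym_id = s(), auth_atom_id = s(), pdbx_PDB_model_num = i()),
    cell = list(
      length_a = f(), length_b = f(), length_c = f(),
      angle_alpha = f(), angle_beta = f(), angle_gamma = f(),
      Z_PDB = i(), entry_id = s()),
    symmetry = list(entry_id = s(), `space_group_name_H-M` = s(),
                    Int_Tables_number = i()),
    entity = list(id = s(TRUE), type = s(), src_method = s(),
                  pdbx_description = s(), formula_weight = f(),
                  pdbx_number_of_molecules = i()),
    entity_poly = list(entity_id = s(), type = s(), nstd_linkage = s(),
                       pdbx_seq_one_letter_code = s(),
                       pdbx_strand_id = s()),
    entity_poly_seq = list(entity_id = s(), num = i(), mon_id = s(),
                           hetero = s()),
    struct_asym = list(id = s(TRUE), entity_id = s(),
                       pdbx_blank_PDB_chainid_flag = s(),
                       pdbx_modified = s(), details = s()),
    chem_comp = list(id = s(TRUE), type = s(), mon_nstd_flag = s(),
                     name = s(), formula = s(), formula_weight = f()),
    chem_comp_bond = list(comp_id = s(), atom_id_1 = s(), atom_id_2 = s(),
                          value_order = s(), pdbx_aromatic_flag = s(),
                          pdbx_stereo_config = s()),
    pdbx_struct_assembly = list(id = s(), details = s(),
                                method_details = s(),
                                oligomeric_details = s(),
                                oligomeric_count = i()),
    pdbx_struct_assembly_gen = list(assembly_id = s(), oper_expression = s(),
                                    asym_id_list = s()),
    pdbx_struct_oper_list = list(
      id = s(), type = s(), name = s(),
      `matrix[1][1]` = f(), `matrix[1][2]` = f(), `matrix[1][3]` = f(),
      `matrix[2][1]` = f(), `matrix[2][2]` = f(), `matrix[2][3]` = f(),
      `matrix[3][1]` = f(), `matrix[3][2]` = f(), `matrix[3][3]` = f(),
      `vector[1]` = f(), `vector[2]` = f(), `vector[3]` = f())
  ))
}

#' Category allowlist of the MMTF-like pruned representation
#'
#' The coordinate+topology subset kept when pruning a file down to roughly
#' the information an MMTF file carries.  This is a configurable
#' approximation of that representation, not an exact archival list.
#'
#' @return Character vector of category names.
#' @export
mmtf_like_profile <- function() {
  names(mmcif_schema()$categories)
}

#' Bind a schema to a file for typed access
#'
#' Binding is lazy and non-mutating: nothing is parsed until a typed column
#' is requested, and undeclared categories remain reachable through the
#' generic interface.
#'
#' @param file A [cif_file].
#' @param schema A `cif_schema`.
#' @param block Block index the view addresses (default 1).
#' @return A `cif_typed_view`.
#' @export
bind_schema <- function(file, schema = mmcif_schema(), block = 1L) {
  stopifnot(inherits(file, "cif_file"), inherits(schema, "cif_schema"))
  structure(list(file = file, schema = schema, block = as.integer(block)),
            class = "cif_typed_view")
}

#' Typed values of a declared column
#'
#' @param view A `cif_typed_view` from [bind_schema()].
#' @param category,column Names addressing a column declared in the schema.
#' @return A list with `values` (integer, double or character vector; `NA`
#'   at masked rows) and `kind` (per-row `"present"`, `"unknown"`,
#'   `"not_present"` flags).  A present payload that cannot be coerced to
#'   the declared numeric type is an error citing the row.
#' @export
get_typed_values <- function(view, category, column) {
  stopifnot(inherits(view, "cif_typed_view"))
  category <- canonical_category_name(category)
  decl <- view$schema$categories[[category]][[column]]
  if (is.null(decl)) {
    cif_stop("cif_usage_error", "column ", category, ".", column,
             " is not declared in the schema")
  }
  blk <- get_block(view$file, view$block)
  cat <- get_category(blk, category)
  if (is.null(cat)) {
    cif_stop("cif_usage_error", "category ", category, " absent from file")
  }
  col <- get_column(cat, column)
  if (is.null(col)) {
    cif_stop("cif_usage_error", "column ", category, ".", column,
             " absent from file")
  }
  present <- col$kinds == KIND_PRESENT
  out <- switch(decl$type,
    str = {
      v <- col$values
      v[!present] <- NA_character_
      v
    },
    int = coerce_numeric(col, present, category, column, integer = TRUE),
    float = coerce_numeric(col, present, category, column, integer = FALSE)
  )
  list(values = out, kind = kind_label(col$kinds))
}

coerce_numeric <- function(col, present, category, column, integer) {
  txt <- col$values[present]
  legal <- if (integer) is_integer_literal(txt) else is_numeric_literal(txt)
  if (!all(legal)) {
    row <- which(present)[which(!legal)[1]]
    cif_stop("cif_format_error", "cannot coerce ", category, ".", column,
             " row ", row, " ('", col$values[row], "') to ",
             if (integer) "int" else "float")
  }
  out <- rep(NA_real_, length(col$values))
  out[present] <- as.numeric(txt)
  if (integer) {
    if (all(is.na(out) | abs(out) <= .Machine$integer.max)) {
      out <- as.integer(out)
    }
  }
  out
}

#' Validate a file against a schema
#'
#' Reports missing required columns and numeric coercion failures; it never
#' raises.  Categories absent from the file are reported only when they
#' contain required columns.
#'
#' @param file A [cif_file].
#' @param schema A `cif_schema`.
#' @param block Block index (default 1).
#' @return A data frame with columns `category`, `column`, `row` and
#'   `problem` (zero rows for a conforming file).
#' @export
validate_cif <- function(file, schema = mmcif_schema(), block = 1L) {
  findings <- list()
  add <- function(category, column, row, problem) {
    findings[[length(findings) + 1L]] <<-
      data.frame(category = category, column = column, row = row,
                 problem = problem, stringsAsFactors = FALSE)
  }
  blk <- get_block(file, block)
  for (cn in names(schema$categories)) {
    cat <- get_category(blk, cn)
    decls <- schema$categories[[cn]]
    req <- names(decls)[vapply(decls, function(d) d$required, logical(1))]
    if (is.null(cat)) {
      for (coln in req) add(cn, coln, NA_integer_,
                            "required column missing (category absent)")
      next
    }
    for (coln in setdiff(req, names(cat$columns))) {
      add(cn, coln, NA_integer_, "required column missing")
    }
    for (coln in intersect(names(decls), names(cat$columns))) {
      decl <- decls[[coln]]
      if (decl$type == "str") next
      col <- cat$columns[[coln]]
      present <- col$kinds == KIND_PRESENT
      txt <- col$values[present]
      legal <- if (decl$type == "int") is_integer_literal(txt) else
        is_numeric_literal(txt)
      for (i in which(!legal)) {
        add(cn, coln, which(present)[i],
            paste0("value '", txt[i], "' is not a legal ", decl$type))
      }
    }
  }
  if (!length(findings)) {
    return(data.frame(category = character(0), column = character(0),
                      row = integer(0), problem = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' Prune a file to a set of categories
#'
#' Returns a new file containing only the listed categories (order
#' preserved); blocks are kept even when emptied and the input is left
#' unchanged.  Unknown names are ignored with a warning.
#'
#' @param file A [cif_file].
#' @param keep Character vector of category names (with or without leading
#'   underscore), e.g. [mmtf_like_profile()].
#' @return A pruned [cif_file].
#' @export
prune_cif <- function(file, keep) {
  stopifnot(inherits(file, "cif_file"), is.character(keep), length(keep) > 0)
  keep <- canonical_category_name(keep)
  all_names <- unique(unlist(lapply(file$blocks,
                                    function(b) names(b$categories))))
  unknown <- setdiff(keep, all_names)
  if (length(unknown)) {
    warning("categories not present in file: ",
            paste(unknown, collapse = ", "))
  }
  blocks <- lapply(file$blocks, function(b) {
    cif_block(b$header, unname(b$categories[names(b$categories) %in% keep]))
  })
  cif_file(blocks)
}
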