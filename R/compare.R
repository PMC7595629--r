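# Semantic equality between two CIF files: the round-trip verification
# oracle used by tests and by the `check` command.

#' Compare two CIF files semantically
#'
#' Checks block headers and order, category names, row counts, per-cell
#' kinds, and payloads.  When both payloads are numeric literals they are
#' compared as numbers: exactly by default, or within a per-column absolute
#' tolerance (use `0.5/factor` for a column stored fixed-point at that
#' factor).  Other payloads must match as text.
#'
#' @param a,b [cif_file] objects.
#' @param tolerances Named numeric vector of absolute tolerances keyed by
#'   `"category.column"`.
#' @param default_tol Absolute tolerance for numeric columns not listed in
#'   `tolerances` (default 0 = exact).
#' @param max_report Maximum number of divergences to record.
#' @return A list with `equal` (logical) and `differences` (character
#'   vector citing the first divergences), of class `cif_comparison`.
#' @export
semantically_equal <- function(a, b, tolerances = NULL, default_tol = 0,
                               max_report = 10L) {
  stopifnot(inherits(a, "cif_file"), inherits(b, "cif_file"))
  diffs <- character(0)
  note <- function(...) {
    if (length(diffs) < max_report) diffs <<- c(diffs, paste0(...))
  }
  if (length(a$blocks) != length(b$blocks)) {
    note("block count differs: ", length(a$blocks), " vs ", length(b$blocks))
  }
  for (bi in seq_len(min(length(a$blocks), length(b$blocks)))) {
    ba <- a$blocks[[bi]]
    bb <- b$blocks[[bi]]
    if (!identical(ba$header, bb$header)) {
      note("block ", bi, " header differs: '", ba$header, "' vs '",
           bb$header, "'")
    }
    na <- names(ba$categories)
    nb <- names(bb$categories)
    if (!identical(na, nb)) {
      note("block ", bi, " category names differ: [",
           paste(setdiff(union(na, nb), intersect(na, nb)), collapse = ", "),
           "]")
    }
    for (cn in intersect(na, nb)) {
      compare_category(ba$categories[[cn]], bb$categories[[cn]],
                       tolerances, default_tol, note)
    }
  }
  structure(list(equal = length(diffs) == 0L, differences = diffs),
            class = "cif_comparison")
}

compare_category <- function(ca, cb, tolerances, default_tol, note) {
  if (ca$row_count != cb$row_count) {
    note("category ", ca$name, ": rowCount ", ca$row_count, " vs ",
         cb$row_count)
    return()
  }
  na <- names(ca$columns)
  nb <- names(cb$columns)
  if (!setequal(na, nb)) {
    note("category ", ca$name, ": column sets differ [",
         paste(setdiff(union(na, nb), intersect(na, nb)), collapse = ", "),
         "]")
  }
  for (coln in intersect(na, nb)) {
    xa <- ca$columns[[coln]]
    xb <- cb$columns[[coln]]
    sel <- paste0(ca$name, ".", coln)
    tol <- default_tol
    if (!is.null(tolerances) && sel %in% names(tolerances)) {
      tol <- tolerances[[sel]]
    }
    kd <- which(xa$kinds != xb$kinds)
    if (length(kd)) {
      note(sel, " row ", kd[1], ": kind ", kind_label(xa$kinds[kd[1]]),
           " vs ", kind_label(xb$kinds[kd[1]]))
      next
    }
    present <- xa$kinds == KIND_PRESENT
    va <- xa$values[present]
    vb <- xb$values[present]
    same <- va == vb
    if (all(same)) next
    num <- !same & is_numeric_literal(va) & is_numeric_literal(vb)
    ok <- same
    ok[num] <- abs(as.numeric(va[num]) - as.numeric(vb[num])) <= tol
    if (!all(ok)) {
      i <- which(!ok)[1]
      row <- which(present)[i]
      note(sel, " row ", row, ": '", va[i], "' vs '", vb[i], "'",
           if (num[i]) paste0(" (|diff| > ", tol, ")") else "")
    }
  }
}

#' @export
print.cif_comparison <- function(x, ...) {
  if (x$equal) {
    cat("files are semantically equal\n")
  } else {
    cat("files differ:\n")
    for (d in x$differences) cat("  - ", d, "\n", sep = "")
  }
  invisible(x)
}
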