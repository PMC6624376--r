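## AMBER-style van der Waals parameter assignment by SYBYL atom type.

#' Load the bundled van der Waals parameter table
#'
#' Parameters (r0 = Rmin/2 in Angstrom, well depth in kcal/mol) transcribed
#' from the published AMBER ff14SB parameter set, keyed by SYBYL atom type,
#' with element-level fallback rows. Users may supply their own table in the
#' same format to [assign_vdw_parameters()].
#'
#' @param path optional path to an alternative table (tab-separated, `#`
#'   comments, columns `sybyl_type`, `amber_type`, `r0`, `eps`).
#' @return data.frame with columns `sybyl_type`, `amber_type`, `r0`, `eps`.
#' @export
vdw_parameter_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vdw_ff14sb.tsv", package = "pbdock")
  }
  tab <- read.table(path, header = FALSE, comment.char = "#", sep = "\t",
                    col.names = c("sybyl_type", "amber_type", "r0", "eps"),
                    stringsAsFactors = FALSE)
  bad <- tab$r0 <= 0.5 | tab$r0 >= 3.0 | tab$eps < 0 | tab$eps > 1.0
  if (any(bad)) {
    stop("vdW table entries out of range: ",
         paste(tab$sybyl_type[bad], collapse = ", "))
  }
  tab
}

#' Assign van der Waals parameters to a molecule
#'
#' Each atom's SYBYL type is looked up in the table; a type with no direct
#' entry falls back to its element (the token before the dot). Coordinates
#' and charges are untouched. Assignment is deterministic and independent of
#' atom order.
#'
#' @param mol a `molecule`.
#' @param table parameter table as returned by [vdw_parameter_table()].
#' @return the molecule with `r0` (Angstrom) and `eps` (kcal/mol) columns
#'   populated.
#' @export
assign_vdw_parameters <- function(mol, table = vdw_parameter_table()) {
  stopifnot(inherits(mol, "molecule"))
  types <- mol$atoms$type
  idx <- match(types, table$sybyl_type)
  fb <- is.na(idx)
  if (any(fb)) {
    idx[fb] <- match(sub("\\..*$", "", types[fb]), table$sybyl_type)
  }
  if (anyNA(idx)) {
    stop("no vdW parameters for atom type(s): ",
         paste(sort(unique(types[is.na(idx)])), collapse = ", "))
  }
  mol$atoms$r0 <- table$r0[idx]
  mol$atoms$eps <- table$eps[idx]
  mol
}

is_parameterized <- function(mol) {
  all(c("r0", "eps") %in% names(mol$atoms)) &&
    !anyNA(mol$atoms$r0) && !anyNA(mol$atoms$eps)
}

require_parameters <- function(mol, what = "molecule") {
  if (!is_parameterized(mol)) {
    stop(what, " has no vdW parameters; call assign_vdw_parameters() first")
  }
  invisible(mol)
}
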