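## TRIPOS MOL2 input/output and the molecule container.
##
## A molecule is a light S3 object: a name, an atom table (name, SYBYL type,
## Cartesian coordinates in Angstrom, partial charge in e, and -- once
## parameters are assigned -- the vdW radius r0 and well depth eps in
## kcal/mol), and a two-column bond index matrix.  Hydrogens are first-class
## atoms; nothing in the pipeline drops them implicitly.

#' Construct a molecule
#'
#' @param name molecule label.
#' @param atoms data.frame with columns `name`, `type` (SYBYL atom type,
#'   e.g. `"C.3"`), `x`, `y`, `z` (Angstrom), `charge` (e). Optional columns
#'   `r0` (Angstrom) and `eps` (kcal/mol) hold van der Waals parameters.
#' @param bonds integer matrix with two columns of 1-based atom indices
#'   (may have zero rows).
#' @return an object of class `molecule`.
#' @export
molecule <- function(name, atoms, bonds = matrix(integer(0), ncol = 2)) {
  stopifnot(is.data.frame(atoms))
  req <- c("name", "type", "x", "y", "z", "charge")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  crd <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) > 0 && !all(is.finite(crd))) stop("non-finite atom coordinates")
  if (nrow(atoms) > 0 && !all(is.finite(atoms$charge))) stop("non-finite atom charges")
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0 && (min(bonds) < 1 || max(bonds) > nrow(atoms))) {
    stop("bond indices outside 1..", nrow(atoms))
  }
  structure(list(name = as.character(name), atoms = atoms, bonds = bonds),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule '%s': %d atoms, %d bonds, net charge %+.4f e>\n",
              x$name, nrow(x$atoms), nrow(x$bonds), net_charge(x)))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `molecule`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Net charge of a molecule
#' @param mol a `molecule`.
#' @return sum of atomic partial charges, in e.
#' @export
net_charge <- function(mol) sum(mol$atoms$charge)

#' Atom coordinates as a matrix
#' @param mol a `molecule`.
#' @return numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @export
coords <- function(mol) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Replace atom coordinates
#' @param mol a `molecule`.
#' @param xyz numeric matrix with one row per atom.
#' @return the molecule with updated coordinates.
#' @export
set_coords <- function(mol, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == n_atoms(mol), ncol(xyz) == 3)
  mol$atoms$x <- xyz[, 1]
  mol$atoms$y <- xyz[, 2]
  mol$atoms$z <- xyz[, 3]
  mol
}

#' Element symbol of each atom
#'
#' Derived from the SYBYL type (the token before the first dot), so `"C.ar"`
#' is carbon and `"N.4"` nitrogen.
#' @param mol a `molecule`.
#' @return character vector of element symbols.
#' @export
elements <- function(mol) sub("\\..*$", "", mol$atoms$type)

#' Read TRIPOS MOL2 molecules
#'
#' Parses one or more `@<TRIPOS>MOLECULE` records. Both minimal (id, name,
#' x, y, z, type) and full 9-column ATOM lines are accepted; when present the
#' charge column is authoritative, otherwise charges are zero.
#' `@<TRIPOS>SUBSTRUCTURE` and other record types are ignored.
#'
#' @param path_or_text path to a MOL2 file, or a character vector of MOL2
#'   lines (anything containing a newline or of length > 1 is treated as
#'   text).
#' @return a list of `molecule` objects, in file order.
#' @export
read_mol2 <- function(path_or_text) {
  lines <- if (length(path_or_text) > 1 || grepl("\n", path_or_text[1], fixed = TRUE)) {
    unlist(strsplit(paste(path_or_text, collapse = "\n"), "\n", fixed = TRUE))
  } else {
    readLines(path_or_text, warn = FALSE)
  }
  mol_starts <- grep("^\\s*@<TRIPOS>MOLECULE\\s*$", lines)
  if (length(mol_starts) == 0) {
    stop("no @<TRIPOS>MOLECULE record found in MOL2 input")
  }
  bounds <- c(mol_starts, length(lines) + 1L)
  lapply(seq_along(mol_starts), function(m) {
    parse_mol2_record(lines, bounds[m], bounds[m + 1] - 1L)
  })
}

parse_mol2_record <- function(lines, from, to) {
  block <- lines[from:to]
  offset <- from - 1L
  name_line <- block[2]
  mol_name <- if (is.na(name_line)) "" else trimws(name_line)
  atom_at <- grep("^\\s*@<TRIPOS>ATOM\\s*$", block)
  if (length(atom_at) == 0) {
    stop("MOL2 record '", mol_name, "' has no @<TRIPOS>ATOM block")
  }
  atom_at <- atom_at[1]
  section_ends <- grep("^\\s*@<TRIPOS>", block)

  section_lines <- function(start) {
    nxt <- section_ends[section_ends > start]
    stop_at <- if (length(nxt)) min(nxt) - 1L else length(block)
    if (stop_at < start + 1L) return(integer(0))
    idx <- (start + 1L):stop_at
    idx[nzchar(trimws(block[idx])) & !startsWith(trimws(block[idx]), "#")]
  }

  atom_idx <- section_lines(atom_at)
  if (length(atom_idx) == 0) {
    stop("MOL2 record '", mol_name, "' has an empty ATOM block")
  }
  toks <- strsplit(trimws(block[atom_idx]), "\\s+")
  parse_atom <- function(tk, lineno) {
    if (length(tk) < 6) {
      stop("malformed ATOM line ", lineno, ": expected at least 6 fields")
    }
    xyz <- suppressWarnings(as.numeric(tk[3:5]))
    if (any(is.na(xyz))) {
      stop("non-numeric coordinate on ATOM line ", lineno)
    }
    q <- if (length(tk) >= 9) suppressWarnings(as.numeric(tk[9])) else 0
    if (is.na(q)) stop("non-numeric charge on ATOM line ", lineno)
    list(name = tk[2], type = tk[6], x = xyz[1], y = xyz[2], z = xyz[3], charge = q)
  }
  parsed <- Map(parse_atom, toks, atom_idx + offset)
  atoms <- data.frame(
    name = vapply(parsed, `[[`, character(1), "name"),
    type = vapply(parsed, `[[`, character(1), "type"),
    x = vapply(parsed, `[[`, numeric(1), "x"),
    y = vapply(parsed, `[[`, numeric(1), "y"),
    z = vapply(parsed, `[[`, numeric(1), "z"),
    charge = vapply(parsed, `[[`, numeric(1), "charge"),
    stringsAsFactors = FALSE
  )

  bonds <- matrix(integer(0), ncol = 2)
  bond_at <- grep("^\\s*@<TRIPOS>BOND\\s*$", block)
  if (length(bond_at)) {
    bidx <- section_lines(bond_at[1])
    if (length(bidx)) {
      btoks <- strsplit(trimws(block[bidx]), "\\s+")
      bonds <- t(vapply(btoks, function(tk) {
        ij <- suppressWarnings(as.integer(tk[2:3]))
        if (any(is.na(ij))) stop("malformed BOND line")
        ij
      }, integer(2)))
    }
  }
  molecule(mol_name, atoms, bonds)
}

#' Write a molecule as TRIPOS MOL2
#'
#' @param mol a `molecule` with at least one atom.
#' @param path destination file, or `NULL` to return the text invisibly
#'   without writing.
#' @return the MOL2 text, invisibly.
#' @export
write_mol2 <- function(mol, path = NULL) {
  stopifnot(inherits(mol, "molecule"))
  if (n_atoms(mol) == 0) stop("cannot write an empty molecule")
  a <- mol$atoms
  header <- c(
    "@<TRIPOS>MOLECULE",
    mol$name,
    sprintf("%d %d 1 0 0", nrow(a), nrow(mol$bonds)),
    "SMALL",
    "USER_CHARGES"
  )
  atom_lines <- sprintf("%7d %-8s %10.4f %10.4f %10.4f %-8s %3d %-8s %10.4f",
                        seq_len(nrow(a)), a$name, a$x, a$y, a$z, a$type,
                        1L, "MOL", a$charge)
  out <- c(header, "@<TRIPOS>ATOM", atom_lines)
  if (nrow(mol$bonds) > 0) {
    bond_lines <- sprintf("%6d %5d %5d %s", seq_len(nrow(mol$bonds)),
                          mol$bonds[, 1], mol$bonds[, 2], "1")
    out <- c(out, "@<TRIPOS>BOND", bond_lines)
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(paste(out, collapse = "\n"))
}
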