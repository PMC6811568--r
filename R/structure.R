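#' Construct a macromolecular structure object
#'
#' A `struct3d` is the hierarchical atom model used throughout the package:
#' a flat atom table (one row per atom, ordered) plus optional
#' crystallographic metadata (unit cell and space group). Residues are
#' identified by author numbering `(chain, resno, insert)`, which is treated
#' as authoritative everywhere.
#'
#' @param atoms data.frame with columns `serial` (integer), `name` (atom
#'   name), `alt` (alternate-location id, `""` if none), `resname` (3-letter
#'   residue code), `chain`, `resno` (integer, author numbering), `insert`
#'   (insertion code, `""` if none), `x`, `y`, `z` (Cartesian, Angstrom),
#'   `occ` (occupancy in \[0,1\]), `b` (isotropic B, Angstrom^2), `element`
#'   (element symbol), `het` (logical, HETATM record).
#' @param cell optional [unit_cell()].
#' @param space_group optional [space_group()] object or Hermann-Mauguin
#'   symbol (resolved via [space_group()]). A space group requires a cell.
#' @param id free-text label (e.g. a PDB id).
#' @return object of class `struct3d`.
#' @export
struct3d <- function(atoms, cell = NULL, space_group = NULL, id = "") {
  required <- c("serial", "name", "alt", "resname", "chain", "resno",
                "insert", "x", "y", "z", "occ", "b", "element", "het")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms)[required]
  atoms$serial <- as.integer(atoms$serial)
  atoms$resno <- as.integer(atoms$resno)
  atoms$het <- as.logical(atoms$het)
  for (col in c("name", "alt", "resname", "chain", "insert", "element"))
    atoms[[col]] <- as.character(atoms[[col]])
  rownames(atoms) <- NULL
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) && !all(is.finite(xyz)))
    stop("non-finite coordinates in atom table")
  if (nrow(atoms) && (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE)))
    stop("occupancy outside [0, 1]")
  if (nrow(atoms) && any(atoms$b < 0, na.rm = TRUE))
    stop("negative isotropic B-factor")
  if (nrow(atoms) && any(!nzchar(atoms$element)))
    stop("empty element symbol")
  if (!is.null(space_group)) {
    if (is.character(space_group)) space_group <- space_group(space_group)
    if (is.null(cell))
      stop("a structure with a space group must also carry a unit cell")
  }
  if (!is.null(cell) && !inherits(cell, "unit_cell"))
    stop("cell must be a unit_cell object")
  structure(
    list(atoms = atoms, cell = cell, space_group = space_group,
         id = as.character(id)),
    class = "struct3d")
}

#' @export
print.struct3d <- function(x, ...) {
  cat(sprintf("struct3d %s: %d atoms, %d residues, %d chain(s)\n",
              if (nzchar(x$id)) sQuote(x$id) else "(unnamed)",
              nrow(x$atoms), n_residues(x), length(unique(x$atoms$chain))))
  if (!is.null(x$cell))
    cat(sprintf("  cell: %.2f %.2f %.2f  %.2f %.2f %.2f\n",
                x$cell$a, x$cell$b, x$cell$c,
                x$cell$alpha, x$cell$beta, x$cell$gamma))
  if (!is.null(x$space_group))
    cat(sprintf("  space group: %s (%d ops)\n",
                x$space_group$hm_symbol, length(x$space_group$ops)))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `struct3d`.
#' @return integer atom count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Number of residues in a structure
#' @param s a `struct3d`.
#' @return integer count of distinct `(chain, resno, insert)` triples.
#' @export
n_residues <- function(s) {
  if (!nrow(s$atoms)) return(0L)
  length(unique(residue_key(s$atoms)))
}

residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
}

#' Atom coordinates as a matrix
#' @param s a `struct3d` or atom data.frame.
#' @return n x 3 numeric matrix of Cartesian coordinates (Angstrom).
#' @export
coords <- function(s) {
  atoms <- if (inherits(s, "struct3d")) s$atoms else s
  m <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

is_hydrogen <- function(atoms) toupper(atoms$element) %in% c("H", "D")

#' Heavy (non-hydrogen) atom subset
#'
#' Hydrogens (and deuteriums) are parsed and retained in the atom table but
#' excluded from every geometric computation in the package; this helper
#' performs that exclusion.
#'
#' @param s a `struct3d`.
#' @return a `struct3d` restricted to non-hydrogen atoms.
#' @export
heavy_atoms <- function(s) {
  s$atoms <- s$atoms[!is_hydrogen(s$atoms), , drop = FALSE]
  rownames(s$atoms) <- NULL
  s
}

#' Subset a structure by chain and residue range
#'
#' @param s a `struct3d`.
#' @param chain chain id(s); `NULL` keeps all.
#' @param resno integer vector of residue numbers, or `NULL`.
#' @return a `struct3d` containing the selected atoms.
#' @export
select_atoms <- function(s, chain = NULL, resno = NULL) {
  keep <- rep(TRUE, nrow(s$atoms))
  if (!is.null(chain)) keep <- keep & s$atoms$chain %in% chain
  if (!is.null(resno)) keep <- keep & s$atoms$resno %in% resno
  s$atoms <- s$atoms[keep, , drop = FALSE]
  rownames(s$atoms) <- NULL
  s
}

# 20 standard amino acids + selenomethionine (counted as protein in censuses)
STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL", "MSE")

WATER_RES <- c("HOH", "WAT", "DOD")

#' Split atoms into residue records
#'
#' @param s a `struct3d` or atom data.frame.
#' @return list of data.frames, one per residue, in file order.
#' @export
split_residues <- function(s) {
  atoms <- if (inherits(s, "struct3d")) s$atoms else s
  key <- residue_key(atoms)
  unname(split(atoms, factor(key, levels = unique(key))))
}
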