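#' Pair atoms of two structures for superposition
#'
#' Atoms are matched by `(mapped chain, residue number, insertion code,
#' atom name)` using author numbering; hydrogens are excluded and the
#' single-conformer tables produced by [read_structure()] are assumed.
#' There is no outlier rejection.
#'
#' @param a,b [struct3d()] objects.
#' @param chain_map named character vector mapping chains of `a` to chains
#'   of `b` (e.g. `c(A = "C")`); `NULL` pairs identical chain ids.
#' @return list with paired coordinate matrices `p` (from `a`) and `q`
#'   (from `b`), the pair count `n`, and the matched keys.
#' @export
pair_atoms <- function(a, b, chain_map = NULL) {
  stopifnot(inherits(a, "struct3d"), inherits(b, "struct3d"))
  aa <- heavy_atoms(a)$atoms
  bb <- heavy_atoms(b)$atoms
  if (!nrow(aa) || !nrow(bb)) stop("empty structure in pairing")
  chain_a <- aa$chain
  if (!is.null(chain_map)) {
    mapped <- chain_map[chain_a]
    keep <- !is.na(mapped)
    aa <- aa[keep, , drop = FALSE]
    chain_a <- unname(mapped[keep])
  }
  key_a <- paste(chain_a, aa$resno, aa$insert, aa$name, sep = "\r")
  key_b <- paste(bb$chain, bb$resno, bb$insert, bb$name, sep = "\r")
  ia <- which(!duplicated(key_a))
  ib <- which(!duplicated(key_b))
  m <- match(key_a[ia], key_b[ib])
  ok <- !is.na(m)
  if (!any(ok))
    stop("no atoms could be paired (disjoint numbering or chains?)")
  pa <- ia[ok]
  pb <- ib[m[ok]]
  list(p = as.matrix(aa[pa, c("x", "y", "z")]),
       q = as.matrix(bb[pb, c("x", "y", "z")]),
       n = sum(ok), keys = key_a[pa])
}

#' Kabsch superposition
#'
#' Least-squares optimal proper rotation and translation mapping `p` onto
#' `q` (SVD construction with reflection correction, so `det(rot) = +1`
#' always), plus the residual RMSD.
#'
#' @param p,q n x 3 paired coordinate matrices.
#' @return object of class `superposition`: `rot` (3x3), `trans`
#'   (length 3), `rmsd` (Angstrom), `n_atoms`. The fitted mapping is
#'   `q ~ rot p + trans`.
#' @export
kabsch <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (nrow(p) != nrow(q)) stop("point sets differ in size")
  if (nrow(p) < 3) stop("need at least 3 point pairs")
  cp <- colMeans(p); cq <- colMeans(q)
  p0 <- sweep(p, 2, cp); q0 <- sweep(q, 2, cq)
  sv <- svd(crossprod(p0, q0))
  if (min(sv$d) < 1e-12 && sv$d[2] < 1e-12)
    stop("degenerate (collinear) point configuration")
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cq - as.numeric(rot %*% cp)
  diffs <- q - (p %*% t(rot) + matrix(trans, nrow(p), 3, byrow = TRUE))
  structure(list(rot = rot, trans = trans,
                 rmsd = sqrt(mean(rowSums(diffs^2))),
                 n_atoms = nrow(p)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: %d atoms, RMSD %.3f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Superpose one structure on another
#'
#' Convenience wrapper: [pair_atoms()] then [kabsch()].
#'
#' @inheritParams pair_atoms
#' @return a `superposition` (see [kabsch()]) with the pairing count.
#' @export
superpose <- function(a, b, chain_map = NULL) {
  pr <- pair_atoms(a, b, chain_map)
  kabsch(pr$p, pr$q)
}

#' Per-domain B-factor statistics
#'
#' Unweighted mean of the isotropic B-factor over the non-hydrogen atoms
#' of each residue range.
#'
#' @param s a [struct3d()].
#' @param domains data.frame with columns `label`, `chain`, `start`, `end`
#'   (several rows may share a label to form multi-range domains).
#' @return data.frame with `label`, `mean_b` (Angstrom^2), `n_atoms`.
#' @export
domain_bfactor <- function(s, domains) {
  stopifnot(inherits(s, "struct3d"))
  domains <- as.data.frame(domains)
  need <- c("label", "chain", "start", "end")
  if (!all(need %in% names(domains)))
    stop("domains needs columns label, chain, start, end")
  atoms <- heavy_atoms(s)$atoms
  out <- lapply(unique(domains$label), function(lab) {
    sel <- rep(FALSE, nrow(atoms))
    for (i in which(domains$label == lab))
      sel <- sel | (atoms$chain == domains$chain[i] &
                      atoms$resno >= domains$start[i] &
                      atoms$resno <= domains$end[i])
    if (!any(sel))
      stop("domain ", sQuote(lab), " selects no atoms")
    data.frame(label = lab, mean_b = mean(atoms$b[sel]),
               n_atoms = sum(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Atom census of a model
#'
#' Counts non-hydrogen atoms partitioned as protein (standard amino acids
#' plus selenomethionine), water (HOH/WAT/DOD) and ligand (everything
#' else). The partition sums to the non-hydrogen total by construction.
#'
#' @param s a [struct3d()].
#' @return object of class `model_census` with integer fields
#'   `non_h_atoms`, `protein_atoms`, `ligand_atoms`, `water_atoms`.
#' @export
model_census <- function(s) {
  stopifnot(inherits(s, "struct3d"))
  atoms <- heavy_atoms(s)$atoms
  protein <- sum(atoms$resname %in% STANDARD_AA)
  water <- sum(atoms$resname %in% WATER_RES)
  structure(list(non_h_atoms = nrow(atoms),
                 protein_atoms = protein,
                 ligand_atoms = nrow(atoms) - protein - water,
                 water_atoms = water),
            class = "model_census")
}

#' @export
print.model_census <- function(x, ...) {
  cat(sprintf("census: %d non-H atoms (protein %d, ligand %d, water %d)\n",
              x$non_h_atoms, x$protein_atoms, x$ligand_atoms, x$water_atoms))
  invisible(x)
}
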