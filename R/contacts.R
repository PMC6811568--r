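#' Van der Waals radius set
#'
#' Fixed radii used for surface-area and cavity computations: C 1.70,
#' N 1.55, O 1.52, S 1.80, P 1.80 Angstrom; other elements fall back to
#' `default` when `strict = FALSE` in [sasa()].
#'
#' @param ... named overrides, e.g. `FE = 1.9`.
#' @param default fallback radius, Angstrom.
#' @return named numeric vector with a `default` attribute.
#' @export
vdw_radii <- function(..., default = 1.70) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
  dots <- c(...)
  if (length(dots)) r[names(dots)] <- dots
  attr(r, "default") <- default
  r
}

atom_radii <- function(elements, radii = vdw_radii(), strict = FALSE) {
  el <- toupper(elements)
  r <- radii[el]
  if (anyNA(r)) {
    if (strict)
      stop("no van der Waals radius for element(s): ",
           paste(unique(el[is.na(r)]), collapse = ", "))
    r[is.na(r)] <- attr(radii, "default") %||% 1.70
  }
  unname(r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic golden-section spiral points on the unit sphere
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples each atom's solvent-accessible sphere (radius = vdW radius +
#' probe) with a deterministic golden-section spiral point set and counts
#' points not buried inside any neighbouring atom's accessible sphere.
#' There is no randomness: results are exactly reproducible for a given
#' `n_points`. Hydrogens are excluded.
#'
#' @param s a [struct3d()], atom data.frame, or n x 3 coordinate matrix
#'   (then `elements` is required).
#' @param probe probe radius, Angstrom (water = 1.4).
#' @param n_points sphere sample points per atom.
#' @param radii van der Waals radius set from [vdw_radii()].
#' @param elements element symbols when `s` is a coordinate matrix.
#' @param strict error on elements without an assigned radius.
#' @return object of class `sasa_result`: `per_atom` (Angstrom^2 vector),
#'   `total`, `probe`, `n_points`.
#' @export
sasa <- function(s, probe = 1.4, n_points = 960L, radii = vdw_radii(),
                 elements = NULL, strict = FALSE) {
  if (inherits(s, "struct3d")) {
    hs <- heavy_atoms(s)
    xyz <- coords(hs)
    elements <- hs$atoms$element
  } else if (is.data.frame(s)) {
    keep <- !is_hydrogen(s)
    xyz <- as.matrix(s[keep, c("x", "y", "z")])
    elements <- s$element[keep]
  } else {
    xyz <- as.matrix(s)
    if (is.null(elements)) stop("elements required with raw coordinates")
  }
  if (!nrow(xyz)) stop("no atoms for SASA computation")
  r <- atom_radii(elements, radii, strict = strict) + probe
  pts <- sphere_points(n_points)
  n <- nrow(xyz)
  per_atom <- numeric(n)
  # neighbour prefilter via cell-free pairwise distances (fine at this scale)
  for (i in seq_len(n)) {
    ri <- r[i]
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    nb <- which(d < ri + r & seq_len(n) != i)
    surf <- sweep(pts * ri, 2, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- rowSums(sweep(surf, 2, xyz[j, ])^2)
        free <- free & dj2 > r[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else {
      frac <- 1
    }
    per_atom[i] <- frac * 4 * pi * ri^2
  }
  structure(list(per_atom = per_atom, total = sum(per_atom),
                 probe = probe, n_points = as.integer(n_points)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("SASA: %.1f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, length(x$per_atom), x$probe, x$n_points))
  invisible(x)
}

#' Buried interface area between two selections
#'
#' Single-interface convention:
#' `area = (SASA(A) + SASA(B) - SASA(A union B)) / 2`.
#' Selection B may live on a symmetry mate (give `op` and `shift`), in
#' which case the structure must carry a cell. Hydrogens are excluded;
#' waters and non-polypeptide residues are excluded by default.
#'
#' @param s a [struct3d()].
#' @param sel_a,sel_b chain id(s) of the two selections.
#' @param op optional [symop()] applied to selection B.
#' @param shift lattice shift for selection B (with `op`).
#' @param probe,n_points,radii see [sasa()].
#' @param polymer_only drop waters/ligands from the selections.
#' @return object of class `interface_area`: `sel_a`, `sel_b`, `op`,
#'   `shift`, `area` (Angstrom^2).
#' @export
interface_area <- function(s, sel_a, sel_b, op = NULL, shift = c(0L, 0L, 0L),
                           probe = 1.4, n_points = 960L, radii = vdw_radii(),
                           polymer_only = TRUE) {
  stopifnot(inherits(s, "struct3d"))
  hs <- heavy_atoms(s)
  if (polymer_only)
    hs$atoms <- hs$atoms[hs$atoms$resname %in% STANDARD_AA, , drop = FALSE]
  a <- hs$atoms[hs$atoms$chain %in% sel_a, , drop = FALSE]
  b <- hs$atoms[hs$atoms$chain %in% sel_b, , drop = FALSE]
  if (!nrow(a) || !nrow(b)) stop("empty selection")
  if (is.null(op) && length(intersect(sel_a, sel_b)))
    stop("selections must be disjoint for an identity-context interface")
  axyz <- as.matrix(a[, c("x", "y", "z")])
  bxyz <- as.matrix(b[, c("x", "y", "z")])
  if (!is.null(op)) {
    if (is.null(s$cell)) stop("symmetry-mate selection needs a unit cell")
    bxyz <- apply_symop(op, shift, bxyz, cell = s$cell)
  }
  sa <- sasa(axyz, probe, n_points, radii, elements = a$element)$total
  sb <- sasa(bxyz, probe, n_points, radii, elements = b$element)$total
  sab <- sasa(rbind(axyz, bxyz), probe, n_points, radii,
              elements = c(a$element, b$element))$total
  area <- max((sa + sb - sab) / 2, 0)
  structure(list(sel_a = sel_a, sel_b = sel_b, op = op, shift = shift,
                 area = area), class = "interface_area")
}

#' @export
print.interface_area <- function(x, ...) {
  opstr <- if (is.null(x$op)) "identity" else format_symop(x$op)
  cat(sprintf("interface %s | %s @ %s: %.1f A^2\n",
              paste(x$sel_a, collapse = "+"),
              paste(x$sel_b, collapse = "+"), opstr, x$area))
  invisible(x)
}

#' Crystal-contact interface table
#'
#' Enumerates every contact of the reference copy's polypeptide chains:
#' chain-chain interfaces within the asymmetric unit (identity operator)
#' and interfaces with each symmetry neighbour found by
#' [expand_neighbors()]. Rows with zero buried area are omitted.
#'
#' @param s a [struct3d()] with cell and space group.
#' @param cutoff neighbour search cutoff, Angstrom.
#' @param probe,n_points,radii see [sasa()].
#' @param min_area smallest buried area reported, Angstrom^2.
#' @return data.frame with columns `chain_a`, `chain_b`, `op` (triplet
#'   string, `"x,y,z"` for identity), `shift`, `area`.
#' @export
crystal_contact_table <- function(s, cutoff = 5, probe = 1.4,
                                  n_points = 960L, radii = vdw_radii(),
                                  min_area = 0.1) {
  stopifnot(inherits(s, "struct3d"))
  hs <- heavy_atoms(s)
  hs$atoms <- hs$atoms[hs$atoms$resname %in% STANDARD_AA, , drop = FALSE]
  chains <- unique(hs$atoms$chain)
  rows <- list()
  add_row <- function(ca, cb, opstr, shift, area) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain_a = ca, chain_b = cb, op = opstr,
      shift = paste(shift, collapse = ","), area = area,
      stringsAsFactors = FALSE)
  }
  if (length(chains) > 1) {
    cmb <- utils::combn(sort(chains), 2)
    for (i in seq_len(ncol(cmb))) {
      ia <- interface_area(s, cmb[1, i], cmb[2, i], probe = probe,
                           n_points = n_points, radii = radii)
      if (ia$area >= min_area)
        add_row(cmb[1, i], cmb[2, i], "x,y,z", c(0L, 0L, 0L), ia$area)
    }
  }
  if (!is.null(s$cell) && !is.null(s$space_group)) {
    nb <- expand_neighbors(hs, cutoff = cutoff)
    for (entry in nb) {
      for (ca in chains) for (cb in chains) {
        ia <- tryCatch(
          interface_area(s, ca, cb, op = entry$op, shift = entry$shift,
                         probe = probe, n_points = n_points, radii = radii),
          error = function(e) NULL)
        if (!is.null(ia) && ia$area >= min_area)
          add_row(ca, cb, format_symop(entry$op), entry$shift, ia$area)
      }
    }
  }
  if (!length(rows))
    return(data.frame(chain_a = character(0), chain_b = character(0),
                      op = character(0), shift = character(0),
                      area = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
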