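crystal_system_check <- function(sg, cell) {
  key <- normalise_sg_symbol(sg$hm_symbol)
  eq <- function(x, y, tol = 1e-6) abs(x - y) < tol
  fail <- function(msg) stop("cell violates ", sg$hm_symbol,
                             " constraints: ", msg)
  if (grepl("^P[36]", key)) {
    if (!eq(cell$a, cell$b)) fail("a must equal b")
    if (!eq(cell$alpha, 90) || !eq(cell$beta, 90) || !eq(cell$gamma, 120))
      fail("alpha = beta = 90, gamma = 120 required")
  } else if (grepl("^P4", key)) {
    if (!eq(cell$a, cell$b)) fail("a must equal b")
    if (!eq(cell$alpha, 90) || !eq(cell$beta, 90) || !eq(cell$gamma, 90))
      fail("all angles must be 90")
  } else if (key == "P212121") {
    if (!eq(cell$alpha, 90) || !eq(cell$beta, 90) || !eq(cell$gamma, 90))
      fail("all angles must be 90")
  } else if (key %in% c("P21", "C2")) {
    if (!eq(cell$alpha, 90) || !eq(cell$gamma, 90))
      fail("alpha = gamma = 90 required")
  }
  invisible(TRUE)
}

# rotate coordinates about the z axis by phi degrees
rot_z <- function(xyz, phi) {
  a <- phi * pi / 180
  r <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  xyz %*% t(r)
}

#' Generate a small synthetic crystal
#'
#' Places one poly-alanine helix (an ideal alpha helix, which is
#' self-clash-free by construction) inside the given cell so that no
#' symmetry copy approaches any other within 2.0 Angstrom. Placement is a
#' seeded random search over positions and orientations, so the result is
#' deterministic for a fixed seed and the packing invariant is verified
#' before returning. Intended as a lattice fixture for symmetry-expansion,
#' contact, crosslink and clash computations.
#'
#' @param space_group Hermann-Mauguin symbol (see
#'   [supported_space_groups()]).
#' @param cell a [unit_cell()] consistent with the group's crystal system.
#' @param n_res residues in the chain.
#' @param seed integer seed controlling placement.
#' @param max_tries placement attempts before giving up.
#' @param min_sep minimum allowed inter-copy atom separation, Angstrom.
#' @return a [struct3d()] with cell and space group attached.
#' @export
make_toy_crystal <- function(space_group, cell, n_res, seed = 1L,
                             max_tries = 400L, min_sep = 2.0) {
  sg <- space_group(space_group)
  stopifnot(inherits(cell, "unit_cell"))
  crystal_system_check(sg, cell)
  helix <- build_ideal_helix(n_res, cb = TRUE)
  base <- coords(helix)
  base <- sweep(base, 2, colMeans(base))
  tr <- frac_cart_transform(cell)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  placed <- NULL
  for (try in seq_len(max_tries)) {
    frac <- stats::runif(3)
    phi <- stats::runif(1, 0, 360)
    xyz <- rot_z(base, phi)
    xyz <- sweep(xyz, 2, as.numeric(tr$frac2cart %*% frac), "+")
    if (toy_packing_ok(xyz, sg, cell, tr, min_sep)) {
      placed <- xyz
      break
    }
  }
  if (is.null(placed))
    stop("could not place a ", n_res, "-residue chain in this cell without ",
         "symmetry clashes; use a larger cell or fewer residues")
  out <- helix
  out$atoms$x <- placed[, 1]; out$atoms$y <- placed[, 2]
  out$atoms$z <- placed[, 3]
  out$cell <- cell
  out$space_group <- sg
  out$id <- sprintf("toy_%s_%dres_seed%d",
                    gsub(" ", "", sg$hm_symbol), n_res, seed)
  out
}

toy_packing_ok <- function(xyz, sg, cell, tr, min_sep) {
  rng <- -1:1
  for (k in seq_along(sg$ops)) {
    mate0 <- apply_symop(sg$ops[[k]], c(0, 0, 0), xyz, cell = cell)
    for (i in rng) for (j in rng) for (l in rng) {
      if (k == 1L && i == 0L && j == 0L && l == 0L) next
      mate <- sweep(mate0, 2, as.numeric(tr$frac2cart %*% c(i, j, l)), "+")
      if (min_cross_dist(xyz, mate) < min_sep) return(FALSE)
    }
  }
  TRUE
}
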