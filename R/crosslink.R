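# geometric primitives -------------------------------------------------------

#' Bond angle at vertex b (degrees)
#' @param a,b,c Cartesian points.
#' @return angle in degrees.
#' @export
bond_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(pmin(pmax(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1)) * 180 / pi
}

#' Torsion angle of four points (degrees, signed)
#' @param p1,p2,p3,p4 Cartesian points.
#' @return dihedral in (-180, 180].
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# internal-coordinate atom placement: D such that |CD| = bond,
# angle(BCD) = ang (deg) and torsion(ABCD) = tors (deg)
place_internal <- function(a, b, c, bond, ang, tors) {
  ang <- ang * pi / 180; tors <- tors * pi / 180
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tors),
          bond * sin(ang) * sin(tors))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Model a S-gamma position from a cysteine-like residue frame
#'
#' Places S-gamma 1.81 Angstrom from C-beta with a 114.6 degree
#' CA-CB-SG angle at the requested chi1 torsion (N-CA-CB-SG).
#'
#' @param n,ca,cb backbone/C-beta positions.
#' @param chi1 side-chain torsion, degrees.
#' @return length-3 S-gamma position.
#' @export
model_sgamma <- function(n, ca, cb, chi1) {
  place_internal(n, ca, cb, bond = 1.81, ang = 114.6, tors = chi1)
}

# scoring ---------------------------------------------------------------------

DISULFIDE_TARGETS <- list(d_cb = 3.85, angle = 114.6, chi3 = 87)

#' Geometric strain score of a disulfide candidate
#'
#' Unitless quadratic strain about textbook disulfide geometry:
#' `w1 (d_cb - d0)^2 + w2 sum(angdev^2) + w3 dihdev^2` with deviations in
#' Angstrom and radians; the C-alpha-C-beta-S-gamma target is 114.6
#' degrees (both residues) and the chi3 target is +/- 87 degrees (the
#' nearer of the two is used). Absolute values are a ranking device, not
#' energies.
#'
#' @param d_cb C-beta to C-beta distance, Angstrom.
#' @param ang_a,ang_b C-alpha-C-beta-S-gamma angles of the two residues,
#'   degrees.
#' @param chi3 S-gamma dihedral (CB-SG-SG-CB), degrees.
#' @param weights length-3 weights `(w1, w2, w3)`.
#' @param d0 target C-beta separation, Angstrom.
#' @return non-negative score.
#' @export
score_disulfide <- function(d_cb, ang_a = 114.6, ang_b = 114.6, chi3 = 87,
                            weights = c(1, 1, 1), d0 = DISULFIDE_TARGETS$d_cb) {
  deg2rad <- pi / 180
  angdev <- ((ang_a - DISULFIDE_TARGETS$angle) * deg2rad)^2 +
    ((ang_b - DISULFIDE_TARGETS$angle) * deg2rad)^2
  wrap <- function(x) atan2(sin(x * deg2rad), cos(x * deg2rad)) / deg2rad
  dihdev <- min(abs(wrap(chi3 - DISULFIDE_TARGETS$chi3)),
                abs(wrap(chi3 + DISULFIDE_TARGETS$chi3))) * deg2rad
  weights[1] * (d_cb - d0)^2 + weights[2] * angdev + weights[3] * dihdev^2
}

# residue frame extraction: one row per residue with N/CA/C/CB positions
residue_frames <- function(s) {
  hs <- heavy_atoms(s)
  hs$atoms <- hs$atoms[hs$atoms$resname %in% STANDARD_AA, , drop = FALSE]
  res <- split_residues(hs$atoms)
  skipped <- character(0)
  out <- list()
  for (r in res) {
    get1 <- function(nm) {
      i <- which(r$name == nm)[1]
      if (is.na(i)) return(NULL)
      c(r$x[i], r$y[i], r$z[i])
    }
    n <- get1("N"); ca <- get1("CA"); cc <- get1("C")
    if (is.null(n) || is.null(ca) || is.null(cc)) {
      skipped <- c(skipped, paste0(r$chain[1], ":", r$resno[1]))
      next
    }
    cb <- get1("CB")
    if (is.null(cb)) cb <- cbeta_from_backbone(n, ca, cc)
    out[[length(out) + 1L]] <- list(
      chain = r$chain[1], resno = r$resno[1], resname = r$resname[1],
      n = n, ca = ca, c = cc, cb = cb)
  }
  if (length(skipped))
    warning("skipped residue(s) with incomplete backbone: ",
            paste(skipped, collapse = ", "))
  out
}

transform_frames <- function(frames, op, shift, cell) {
  lapply(frames, function(f) {
    m <- rbind(f$n, f$ca, f$c, f$cb)
    m2 <- apply_symop(op, shift, m, cell = cell)
    f$n <- m2[1, ]; f$ca <- m2[2, ]; f$c <- m2[3, ]; f$cb <- m2[4, ]
    f
  })
}

CHI1_ROTAMERS <- c(-60, 60, 180)

best_disulfide_geometry <- function(fa, fb, weights = c(1, 1, 1)) {
  d_ca <- sqrt(sum((fa$ca - fb$ca)^2))
  d_cb <- sqrt(sum((fa$cb - fb$cb)^2))
  best <- NULL
  for (x1 in CHI1_ROTAMERS) for (x2 in CHI1_ROTAMERS) {
    sga <- model_sgamma(fa$n, fa$ca, fa$cb, x1)
    sgb <- model_sgamma(fb$n, fb$ca, fb$cb, x2)
    chi3 <- torsion_angle(fa$cb, sga, sgb, fb$cb)
    e <- score_disulfide(d_cb, 114.6, 114.6, chi3, weights = weights)
    if (is.null(best) || e < best$energy)
      best <- list(chi3 = chi3, energy = e, sg_a = sga, sg_b = sgb)
  }
  c(list(d_ca = d_ca, d_cb = d_cb), best)
}

#' Scan a packed lattice for engineerable disulfide bridges
#'
#' Enumerates residue pairs whose backbone geometry could support a
#' cysteine-cysteine bridge: within the reference copy (`mode = "intra"`),
#' between the reference copy and its symmetry mates (`"inter"`), or both.
#' Pre-filters: C-alpha separation <= `d_ca_max` and C-beta separation in
#' `d_cb_range`. For each surviving pair, S-gamma atoms are modelled on
#' ideal geometry over a 3 x 3 chi1 rotamer grid and the lowest
#' [score_disulfide()] value is kept. Existing cysteines are scanned like
#' any other residue (their deposited C-beta is used); glycines get an
#' ideal reconstructed C-beta.
#'
#' @param s a [struct3d()]; cell and space group are required for
#'   `mode != "intra"`.
#' @param mode `"both"`, `"intra"` or `"inter"`.
#' @param d_ca_max C-alpha pre-filter, Angstrom.
#' @param d_cb_range C-beta acceptance window, Angstrom.
#' @param weights scoring weights, see [score_disulfide()].
#' @param min_seq_sep minimum residue-number separation within a chain.
#' @return data.frame sorted by `energy`: `chain_a`, `resno_a`, `chain_b`,
#'   `resno_b`, `op` (triplet string; `"x,y,z"` for intra), `shift`,
#'   `d_ca`, `d_cb`, `chi3`, `energy`.
#' @export
scan_disulfides <- function(s, mode = c("both", "intra", "inter"),
                            d_ca_max = 7.5, d_cb_range = c(3.0, 5.0),
                            weights = c(1, 1, 1), min_seq_sep = 2L) {
  mode <- match.arg(mode)
  frames <- residue_frames(s)
  if (!length(frames)) stop("no scannable residues")
  rows <- list()
  consider <- function(fa, fb, opstr, shift) {
    d_ca <- sqrt(sum((fa$ca - fb$ca)^2))
    if (d_ca > d_ca_max) return()
    d_cb <- sqrt(sum((fa$cb - fb$cb)^2))
    if (d_cb < d_cb_range[1] || d_cb > d_cb_range[2]) return()
    g <- best_disulfide_geometry(fa, fb, weights)
    rows[[length(rows) + 1L]] <<- data.frame(
      chain_a = fa$chain, resno_a = fa$resno,
      chain_b = fb$chain, resno_b = fb$resno,
      op = opstr, shift = paste(shift, collapse = ","),
      d_ca = g$d_ca, d_cb = g$d_cb, chi3 = g$chi3, energy = g$energy,
      stringsAsFactors = FALSE)
  }
  if (mode %in% c("both", "intra")) {
    nf <- length(frames)
    ca_mat <- t(vapply(frames, function(f) f$ca, numeric(3)))
    for (i in seq_len(nf - 1)) {
      d <- sqrt(rowSums(sweep(ca_mat[(i + 1):nf, , drop = FALSE], 2,
                              ca_mat[i, ])^2))
      for (jj in which(d <= d_ca_max)) {
        j <- i + jj
        fa <- frames[[i]]; fb <- frames[[j]]
        if (fa$chain == fb$chain &&
            abs(fa$resno - fb$resno) < min_seq_sep) next
        consider(fa, fb, "x,y,z", c(0L, 0L, 0L))
      }
    }
  }
  if (mode %in% c("both", "inter")) {
    if (is.null(s$cell) || is.null(s$space_group))
      stop("inter-molecular scan needs cell and space group")
    nb <- expand_neighbors(s, cutoff = d_ca_max + 0.5)
    for (entry in nb) {
      mate <- transform_frames(frames, entry$op, entry$shift, s$cell)
      mate_ca <- t(vapply(mate, function(f) f$ca, numeric(3)))
      for (i in seq_along(frames)) {
        d <- sqrt(rowSums(sweep(mate_ca, 2, frames[[i]]$ca)^2))
        for (j in which(d <= d_ca_max))
          consider(frames[[i]], mate[[j]], format_symop(entry$op),
                   entry$shift)
      }
    }
  }
  if (!length(rows))
    return(data.frame(chain_a = character(0), resno_a = integer(0),
                      chain_b = character(0), resno_b = integer(0),
                      op = character(0), shift = character(0),
                      d_ca = numeric(0), d_cb = numeric(0),
                      chi3 = numeric(0), energy = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$energy, out$chain_a, out$resno_a, out$resno_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
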