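# Shared fixtures and independent oracles, built in code at test time.

# fixed-column PDB text for a tiny alanine + water fixture with the
# reference hexagonal host cell on its CRYST1 record
toy_pdb_lines <- function() {
  c("CRYST1  192.690  192.690  123.940  90.00  90.00 120.00 P 65          6",
    "ATOM      1  N   ALA A 340      11.104   6.134   1.234  1.00 20.00           N",
    "ATOM      2  CA  ALA A 340      12.560   6.071   1.500  1.00 21.50           C",
    "ATOM      3  CB AALA A 340      13.100   7.420   1.900  0.60 22.00           C",
    "ATOM      4  CB BALA A 340      13.150   7.400   1.950  0.40 23.00           C",
    "ATOM      5  C   ALA A 340      13.050   5.000   2.480  1.00 20.00           C",
    "ATOM      6  O   ALA A 340      12.300   4.500   3.320  1.00 20.00           O",
    "ATOM      7  H   ALA A 340      10.700   5.500   0.560  1.00 10.00           H",
    "HETATM    8  O   HOH A 401       5.000   5.000   5.000  1.00 30.00           O",
    "END")
}

write_toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(toy_pdb_lines(), path)
  path
}

# the eight reference host-lattice candidates (printed V_M and resolution)
host_table_path <- function() {
  system.file("extdata", "host_candidates.csv", package = "hostlattice")
}

# independent brute-force symmetry-mate enumeration: all ops x shifts in
# [-2, 2]^3, direct all-pairs distance check, no bounding-box shortcuts
brute_force_neighbors <- function(s, cutoff) {
  ref <- coords(heavy_atoms(s))
  tr <- frac_cart_transform(s$cell)
  ops <- s$space_group$ops
  out <- character(0)
  for (k in seq_along(ops)) {
    for (i in -2:2) for (j in -2:2) for (l in -2:2) {
      if (k == 1 && i == 0 && j == 0 && l == 0) next
      f <- ref %*% t(tr$cart2frac)
      f <- f %*% t(ops[[k]]$rot)
      f <- sweep(f, 2, ops[[k]]$trans + c(i, j, l), "+")
      mate <- f %*% t(tr$frac2cart)
      dmin <- Inf
      for (m in seq_len(nrow(ref)))
        dmin <- min(dmin, sqrt(min(rowSums(sweep(mate, 2, ref[m, ])^2))))
      if (dmin <= cutoff)
        out <- c(out, paste(k, i, j, l))
    }
  }
  sort(out)
}

# independent SASA oracle: latitude/longitude surface grid with
# sin(theta)-weighted patch areas (arc spacing ~0.1 A)
grid_sasa <- function(xyz, elements, probe = 1.4, spacing = 0.1) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  r <- unname(radii[toupper(elements)]) + probe
  total <- 0
  for (i in seq_len(nrow(xyz))) {
    ri <- r[i]
    n_th <- max(8L, ceiling(pi * ri / spacing))
    th <- (seq_len(n_th) - 0.5) * pi / n_th
    area_i <- 0
    for (t in th) {
      n_ph <- max(8L, ceiling(2 * pi * ri * sin(t) / spacing))
      ph <- (seq_len(n_ph) - 0.5) * 2 * pi / n_ph
      pts <- cbind(ri * sin(t) * cos(ph), ri * sin(t) * sin(ph),
                   rep(ri * cos(t), n_ph))
      pts <- sweep(pts, 2, xyz[i, ], "+")
      free <- rep(TRUE, n_ph)
      for (j in seq_len(nrow(xyz))) {
        if (j == i) next
        free <- free & rowSums(sweep(pts, 2, xyz[j, ])^2) > r[j]^2
      }
      patch <- ri^2 * sin(t) * (pi / n_th) * (2 * pi / n_ph)
      area_i <- area_i + sum(free) * patch
    }
    total <- total + area_i
  }
  total
}

# synthetic host + binder pair sharing an ideal anchor helix
make_fusion_fixture <- function() {
  host <- build_ideal_helix(20, chain = "A", start = 101)
  binder <- build_ideal_helix(15, chain = "B", start = 1)
  list(host = host, binder = binder,
       ha = fit_helix_axis(host, chain = "A", resno = 106:120),
       ba = fit_helix_axis(binder, chain = "B", resno = 1:15))
}

# two cysteine residues built outward from textbook disulfide geometry
# (S-S 2.05 A, chi3 -87 deg, chi1 -60 deg on both sides), so the scan's
# rotamer grid can recover a near-zero strain score for this pair
make_ideal_cys_pair <- function() {
  h <- build_ideal_helix(1, cb = TRUE)
  g1 <- function(nm) {
    i <- which(h$atoms$name == nm)
    c(h$atoms$x[i], h$atoms$y[i], h$atoms$z[i])
  }
  n_a <- g1("N"); ca_a <- g1("CA"); c_a <- g1("C"); cb_a <- g1("CB")
  sg_a <- model_sgamma(n_a, ca_a, cb_a, -60)
  sg_b <- hostlattice:::place_internal(ca_a, cb_a, sg_a, 2.05, 104, 180)
  cb_b <- hostlattice:::place_internal(cb_a, sg_a, sg_b, 1.81, 104, -87)
  ca_b <- hostlattice:::place_internal(sg_a, sg_b, cb_b, 1.53, 114.6, 180)
  n_b <- hostlattice:::place_internal(sg_b, cb_b, ca_b, 1.46, 110.5, -60)
  c_b <- hostlattice:::place_internal(cb_b, n_b, ca_b, 1.52, 111, 120)
  row <- function(serial, name, chain, resno, p, element)
    data.frame(serial = serial, name = name, alt = "", resname = "CYS",
               chain = chain, resno = resno, insert = "",
               x = p[1], y = p[2], z = p[3], occ = 1, b = 0,
               element = element, het = FALSE, stringsAsFactors = FALSE)
  atoms <- rbind(
    row(1L, "N", "A", 1L, n_a, "N"), row(2L, "CA", "A", 1L, ca_a, "C"),
    row(3L, "C", "A", 1L, c_a, "C"), row(4L, "CB", "A", 1L, cb_a, "C"),
    row(5L, "N", "B", 1L, n_b, "N"), row(6L, "CA", "B", 1L, ca_b, "C"),
    row(7L, "C", "B", 1L, c_b, "C"), row(8L, "CB", "B", 1L, cb_b, "C"))
  struct3d(atoms)
}

# random rigid motion (rotation + translation), seeded by caller
random_rigid <- function() {
  th <- stats::runif(3, 0, 2 * pi)
  rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                 0, sin(th[1]), cos(th[1])), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0,
                 -sin(th[2]), 0, cos(th[2])), 3, 3, byrow = TRUE)
  rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  list(rot = rz %*% ry %*% rx, trans = stats::runif(3, -20, 20))
}

apply_rigid <- function(xyz, rg) {
  sweep(xyz %*% t(rg$rot), 2, rg$trans, "+")
}

apply_rigid_struct <- function(s, rg) {
  xyz <- apply_rigid(coords(s), rg)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}
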