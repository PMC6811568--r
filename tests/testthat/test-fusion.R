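test_that("ideal helix geometry: cylinder radius, rise and periodicity", {
  h <- build_ideal_helix(19)
  ca <- coords(hostlattice:::select_name(h, "CA"))
  r <- sqrt(ca[, 1]^2 + ca[, 2]^2)
  expect_equal(r, rep(2.3, 19), tolerance = 1e-9)
  expect_equal(diff(ca[, 3]), rep(1.5, 18), tolerance = 1e-9)
  # 18 steps at 100 deg/res = 1800 deg = 5 full turns: CA 19 eclipses CA 1
  expect_equal(ca[1, 1:2], ca[19, 1:2], tolerance = 1e-9)
  # an 18-residue helix spans 17 rises = 25.5 A along the axis
  expect_equal(ca[18, 3] - ca[1, 3], 17 * 1.5, tolerance = 1e-9)
  one <- build_ideal_helix(1)
  ca1 <- coords(hostlattice:::select_name(one, "CA"))
  expect_equal(sqrt(sum(ca1[1, 1:2]^2)), 2.3, tolerance = 1e-9)
})

test_that("axis fitting recovers the generating helix parameters", {
  params <- helix_params(rise = 1.5, twist = 100, ca_radius = 2.3)
  h <- build_ideal_helix(12, params)
  ax <- fit_helix_axis(h, chain = "A", resno = 1:12)
  expect_false(ax$nonhelical)
  expect_equal(ax$rise, 1.5, tolerance = 0.01)
  expect_equal(ax$twist, 100, tolerance = 0.5)
  expect_equal(ax$radius, 2.3, tolerance = 0.01)
  expect_equal(ax$direction, c(0, 0, 1), tolerance = 1e-6)
  # non-default geometry is recovered too
  p2 <- helix_params(rise = 1.9, twist = 120, ca_radius = 1.9)
  ax2 <- fit_helix_axis(build_ideal_helix(10, p2))
  expect_equal(ax2$rise, 1.9, tolerance = 0.01)
  expect_equal(ax2$twist, 120, tolerance = 0.5)
})

test_that("axis fit is invariant under rigid motion and flags lines", {
  set.seed(13)
  h <- build_ideal_helix(10)
  ca <- coords(hostlattice:::select_name(h, "CA"))
  for (i in 1:3) {
    moved <- apply_rigid(ca, random_rigid())
    ax <- fit_helix_axis(moved)
    expect_equal(ax$rise, 1.5, tolerance = 0.01)
    expect_equal(ax$twist, 100, tolerance = 0.5)
  }
  line <- cbind(seq(0, 15, length.out = 8), 0, 0)
  expect_true(fit_helix_axis(line)$nonhelical)
  expect_error(fit_helix_axis(ca[1:4, ]), "at least 5")
})

test_that("k = 0 fusion continues the shared helix seamlessly", {
  fx <- make_fusion_fixture()
  m0 <- shared_helix_fuse(fx$host, fx$ha, fx$binder, fx$ba, k = 0)
  expect_equal(m0$rotation_deg, 0)
  # fused CA trace is one ideal helix again
  ax <- fit_helix_axis(coords(hostlattice:::select_name(m0$structure, "CA")))
  expect_false(ax$nonhelical)
  expect_equal(ax$rise, 1.5, tolerance = 0.01)
  expect_equal(ax$twist, 100, tolerance = 0.5)
})

test_that("binder internal geometry is rigid under fusion", {
  fx <- make_fusion_fixture()
  m <- shared_helix_fuse(fx$host, fx$ha, fx$binder, fx$ba, k = 5)
  placed <- select_atoms(m$structure, chain = m$junction$binder_chain)
  orig <- select_atoms(fx$binder, resno = unique(placed$atoms$resno))
  expect_equal(nrow(placed$atoms), nrow(orig$atoms))
  d_orig <- stats::dist(coords(orig))
  d_new <- stats::dist(coords(placed))
  expect_lt(max(abs(d_orig - d_new)), 1e-6)
})

test_that("rotation arithmetic: (k2 - k1) x twist mod 360 within a degree", {
  fx <- make_fusion_fixture()
  models <- lapply(c(0, 4, 9, 18), function(k)
    shared_helix_fuse(fx$host, fx$ha, fx$binder, fx$ba, k = k))
  names(models) <- c("k0", "k4", "k9", "k18")
  # k4 vs k9: 500 deg = 140 deg
  expect_equal(relative_rotation(models$k4, models$k9)$angle_deg, 140,
               tolerance = 1)
  # k0 vs k18: full turns - pure translation by 18 x 1.5 = 27 A
  rr <- relative_rotation(models$k0, models$k18)
  expect_lt(rr$angle_deg, 1)
  expect_equal(sqrt(sum(rr$translation^2)), 27, tolerance = 0.1)
  # invariant: reported rotation is k x twist mod 360
  for (m in models)
    expect_equal(m$rotation_deg, (m$k_inserted * 100) %% 360)
})

test_that("clash counts equal the brute-force all-pairs oracle", {
  fx <- make_fusion_fixture()
  cell <- unit_cell(34, 34, 42, 90, 90, 120)
  host <- fx$host
  host$cell <- cell
  host$space_group <- space_group("P65")
  m <- shared_helix_fuse(host, fx$ha, fx$binder, fx$ba, k = 3)
  m <- clash_score(m, cutoff = 3.0)
  # oracle: O(n^2) double loop over moving vs static + mates
  s <- heavy_atoms(m$structure)
  jc <- m$junction
  moving_sel <- s$atoms$chain == jc$binder_chain |
    (s$atoms$chain == jc$host_chain & s$atoms$resno %in% jc$ext_resno)
  mov <- s$atoms[moving_sel, ]
  oth <- s$atoms[!moving_sel, ]
  path <- function(at) ifelse(at$chain == jc$binder_chain,
                              jc$host_end + length(jc$ext_resno) +
                                at$resno - jc$binder_start + 1,
                              at$resno)
  count <- 0L
  for (i in seq_len(nrow(mov))) for (j in seq_len(nrow(oth))) {
    d <- sqrt(sum((c(mov$x[i], mov$y[i], mov$z[i]) -
                     c(oth$x[j], oth$y[j], oth$z[j]))^2))
    if (d < 3.0 && abs(path(mov[i, ]) - path(oth[j, ])) > 2)
      count <- count + 1L
  }
  for (nb in expand_neighbors(s, cutoff = 4)) {
    for (i in seq_len(nrow(mov))) {
      d <- sqrt(rowSums(sweep(nb$xyz, 2,
                              c(mov$x[i], mov$y[i], mov$z[i]))^2))
      count <- count + sum(d < 3.0)
    }
  }
  expect_equal(m$clash_count, count)
})

test_that("clash count is monotone in the cutoff and zero when isolated", {
  fx <- make_fusion_fixture()
  far_binder <- fx$binder
  far_binder$atoms$x <- far_binder$atoms$x  # geometry set by anchor fit
  m <- shared_helix_fuse(fx$host, fx$ha, fx$binder, fx$ba, k = 2)
  counts <- vapply(c(3.5, 3.0, 2.5, 2.0, 1.0), function(ct)
    clash_score(m, cutoff = ct)$clash_count, integer(1))
  expect_true(all(diff(counts) <= 0))
  # a binder displaced far from everything cannot clash
  iso <- shared_helix_fuse(fx$host, fx$ha, fx$binder, fx$ba, k = 0)
  bsel <- iso$structure$atoms$chain == iso$junction$binder_chain
  iso$structure$atoms$x[bsel] <- iso$structure$atoms$x[bsel] + 100
  expect_equal(clash_score(iso, cutoff = 3.0)$clash_count, 0L)
})

test_that("rotational enumeration ranks wall-blocked orientations last", {
  fx <- make_fusion_fixture()
  # wall of atoms on one side of the helix axis, beyond the binder radius
  wall <- expand.grid(x = seq(4, 16, by = 1.5), y = seq(-10, 10, by = 1.5),
                      z = seq(32, 58, by = 1.5))
  wall_atoms <- data.frame(
    serial = seq_len(nrow(wall)) + 5000L, name = "C", alt = "",
    resname = "UNK", chain = "W", resno = seq_len(nrow(wall)) + 5000L,
    insert = "", x = wall$x, y = wall$y, z = wall$z, occ = 1, b = 0,
    element = "C", het = TRUE, stringsAsFactors = FALSE)
  host <- fx$host
  host$atoms <- rbind(host$atoms, wall_atoms)
  models <- enumerate_rotations(host, fx$ha, fx$binder, fx$ba,
                                k_range = 0:8)
  expect_length(models, 9)
  counts <- vapply(models, function(m) m$clash_count, integer(1))
  expect_true(all(diff(counts) >= 0))  # ranked ascending
  ks <- vapply(models, function(m) m$k_inserted, integer(1))
  # orientations pointing into the wall (x > 0 sector around z ~ 40+) rank
  # behind the free sector
  worst <- ks[counts == max(counts)]
  best <- ks[counts == min(counts)]
  expect_true(max(counts) > min(counts))
  expect_false(any(best %in% worst))
  # single-k enumeration trivially returns one model
  expect_length(enumerate_rotations(fx$host, fx$ha, fx$binder, fx$ba,
                                    k_range = 3), 1)
})

test_that("cavity radius: closed form, unbounded and monotone cases", {
  est <- cavity_radius(c(0, 0, 0), matrix(c(10, 0, 0), 1, 3))
  expect_equal(est$r_max, 8.3)  # 10 - 1.7 vdW
  empty <- struct3d(build_ideal_helix(1)$atoms[0, ])
  expect_equal(cavity_radius(c(0, 0, 0), empty)$r_max, Inf)
  # adding atoms can only shrink the cavity
  set.seed(21)
  pts <- matrix(runif(60, -20, 20), 20, 3)
  r_seq <- vapply(5:20, function(n)
    cavity_radius(c(0, 0, 0), pts[1:n, , drop = FALSE])$r_max, numeric(1))
  expect_true(all(diff(r_seq) <= 1e-12))
  # centre inside an atom floors at zero
  expect_equal(cavity_radius(c(10, 0, 0),
                             matrix(c(10, 0, 0), 1, 3))$r_max, 0)
})

test_that("cavity radius matches a grid search in a toy channel", {
  # two walls at x = +/- 12 A (carbon): channel half-width 12 - 1.7
  wall <- as.matrix(expand.grid(x = c(-12, 12), y = seq(-15, 15, 1),
                                z = seq(-15, 15, 1)))
  est <- cavity_radius(c(0, 0, 0), wall)
  grid_best <- min(sqrt(rowSums(sweep(wall, 2, c(0, 0, 0))^2)) - 1.7)
  expect_equal(est$r_max, grid_best, tolerance = 0.1)
  expect_equal(est$r_max, 10.3, tolerance = 1e-9)
})

test_that("cavity sizing sees symmetry mates of a packed lattice", {
  s <- make_toy_crystal("P1", unit_cell(12, 12, 12), 4, seed = 6)
  centre <- colMeans(coords(s)) + c(8, 0, 0)
  with_mates <- cavity_radius(centre, s)$r_max
  no_cell <- s; no_cell$cell <- NULL; no_cell$space_group <- NULL
  without <- cavity_radius(centre, no_cell)$r_max
  expect_lte(with_mates, without)
})
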