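test_that("cell volume: cubic closed form and determinant oracle agree", {
  expect_equal(cell_volume(unit_cell(10, 10, 10)), 1000)
  set.seed(42)
  for (i in 1:10) {
    cell <- unit_cell(runif(1, 20, 80), runif(1, 20, 80), runif(1, 20, 80),
                      runif(1, 70, 110), runif(1, 70, 110), runif(1, 70, 110))
    v_det <- abs(det(frac_cart_transform(cell)$frac2cart))
    expect_equal(cell_volume(cell), v_det, tolerance = 1e-10)
  }
})

test_that("the hexagonal host cell volume matches the closed form", {
  cell <- unit_cell(192.69, 192.69, 123.94, 90, 90, 120)
  v <- cell_volume(cell)
  expect_equal(v, 192.69^2 * 123.94 * sin(120 * pi / 180), tolerance = 1e-12)
  expect_equal(v / 1e6, 3.985, tolerance = 1e-3)
})

test_that("fractional/Cartesian transforms are mutually inverse", {
  ortho <- frac_cart_transform(unit_cell(10, 20, 30))
  expect_equal(ortho$frac2cart, diag(c(10, 20, 30)), tolerance = 1e-12)
  hexa <- frac_cart_transform(unit_cell(40, 40, 30, 90, 90, 120))
  expect_equal(hexa$frac2cart[1, 2], -20, tolerance = 1e-9)  # b cos(120)
  set.seed(7)
  for (i in 1:5) {
    cell <- unit_cell(runif(1, 20, 60), runif(1, 20, 60), runif(1, 20, 60),
                      runif(1, 80, 100), runif(1, 80, 100), runif(1, 80, 120))
    tr <- frac_cart_transform(cell)
    expect_equal(tr$frac2cart %*% tr$cart2frac, diag(3), tolerance = 1e-10)
    pts <- matrix(runif(30, -50, 50), 10, 3)
    back <- pts %*% t(tr$cart2frac) %*% t(tr$frac2cart)
    expect_lt(max(abs(back - pts)), 1e-8)
  }
})

test_that("symmetry-operator triplets parse to exact rotation/translation", {
  id <- parse_symop("x, y, z")
  expect_equal(id$rot, diag(3))
  expect_equal(id$trans, c(0, 0, 0))
  s1 <- parse_symop("−y, x − y − 1, z-1/3")
  expect_equal(s1$rot, matrix(c(0, -1, 0, 1, -1, 0, 0, 0, 1), 3, 3,
                              byrow = TRUE))
  expect_equal(s1$trans, c(0, -1, -1/3))
  s3 <- parse_symop("-x + 1, -y, z - 1/2")
  expect_equal(s3$trans, c(1, 0, -1/2))
  expect_error(parse_symop("x, y+q, z"), "cannot parse")
  # formatting round-trip is an equivalent triplet
  expect_equal(parse_symop(format_symop(s1))$rot, s1$rot)
  expect_equal(parse_symop(format_symop(s1))$trans, s1$trans)
})

test_that("space-group generation yields the right coset lists", {
  expect_length(space_group("P1")$ops, 1)
  expect_length(space_group("P21")$ops, 2)
  expect_length(space_group("C2")$ops, 4)
  p65 <- space_group("P 65")
  expect_length(p65$ops, 6)
  # contains the screw operator with translation z+5/6
  keys <- vapply(p65$ops, format_symop, character(1))
  expect_true("x-y,x,z+5/6" %in% keys)
  expect_error(space_group("P7"), "unsupported")
})

test_that("the four reference-host lattice contacts' operators are one P65 coset each", {
  p65 <- space_group("P65")
  footnote <- c("-y, x - y - 1, z-1/3", "x - y, x, z - 1/6",
                "-x + 1, -y, z - 1/2", "x - y, x, z + 5/6")
  keys <- vapply(p65$ops, function(o) hostlattice:::symop_key(o), character(1))
  for (txt in footnote) {
    op <- parse_symop(txt)
    expect_true(hostlattice:::symop_key(op) %in% keys)
  }
  # the 2nd and 4th differ by a pure integer lattice translation
  sym2 <- parse_symop("x - y, x, z - 1/6")
  sym4 <- parse_symop("x - y, x, z + 5/6")
  expect_equal(sym2$rot, sym4$rot)
  diff_t <- sym4$trans - sym2$trans
  expect_equal(diff_t, round(diff_t))
})

test_that("every supported space group is closed under composition", {
  for (sym in supported_space_groups()) {
    sg <- space_group(sym)
    keys <- vapply(sg$ops, function(o) hostlattice:::symop_key(o),
                   character(1))
    for (a in sg$ops) for (b in sg$ops) {
      ab <- compose_symop(a, b)
      expect_true(hostlattice:::symop_key(ab) %in% keys,
                  label = paste("closure of", sym))
    }
  }
})

test_that("apply_symop is an isometry and identity is a fixed point", {
  s <- make_toy_crystal("P65", unit_cell(40, 40, 30, 90, 90, 120), 6,
                        seed = 5)
  xyz <- coords(s)
  id <- s$space_group$ops[[1]]
  expect_equal(apply_symop(id, c(0, 0, 0), s), xyz, tolerance = 1e-10)
  d0 <- stats::dist(xyz)
  set.seed(11)
  for (k in seq_along(s$space_group$ops)) {
    shift <- sample(-2:2, 3, replace = TRUE)
    mate <- apply_symop(s$space_group$ops[[k]], shift, s)
    expect_lt(max(abs(stats::dist(mate) - d0)), 1e-6)
  }
})

test_that("expand_neighbors equals the brute-force oracle on small cells", {
  for (fix in list(
    list(sg = "P65", cell = unit_cell(40, 40, 30, 90, 90, 120), n = 8,
         seed = 7, cutoff = 5),
    list(sg = "P1", cell = unit_cell(18, 18, 18), n = 3, seed = 2,
         cutoff = 4),
    list(sg = "P212121", cell = unit_cell(30, 34, 38), n = 6, seed = 4,
         cutoff = 6))) {
    s <- make_toy_crystal(fix$sg, fix$cell, fix$n, seed = fix$seed)
    got <- expand_neighbors(s, fix$cutoff)
    got_keys <- sort(vapply(got, function(e)
      paste(e$op_index, e$shift[1], e$shift[2], e$shift[3]), character(1)))
    expect_equal(got_keys, brute_force_neighbors(s, fix$cutoff))
  }
})

test_that("an isolated chain in a huge P1 cell has no neighbours", {
  s <- make_toy_crystal("P1", unit_cell(200, 200, 200), 5, seed = 1)
  expect_length(expand_neighbors(s, 5), 0)
})

test_that("runaway expansion cutoffs are refused unless forced", {
  s <- make_toy_crystal("P1", unit_cell(18, 18, 18), 3, seed = 2)
  expect_error(expand_neighbors(s, 1000), "force")
  expect_silent(expand_neighbors(s, 1000, force = TRUE))
})

test_that("Matthews coefficient reproduces the 72% solvent host lattice", {
  expect_equal(100 * solvent_fraction(4.38), 72, tolerance = 0.5)
  expect_equal(solvent_fraction(1.2284), 0)
  # construct a crystal form with V_M exactly 4.38 and recompute
  cell <- unit_cell(192.69, 192.69, 123.94, 90, 90, 120)
  mw <- cell_volume(cell) / (6 * 4.38)
  res <- matthews(cell, "P65", mw)
  expect_equal(res$v_m, 4.38, tolerance = 1e-12)
  expect_equal(res$z_total, 6L)
  expect_equal(res$solvent_frac, 0.72, tolerance = 0.005)
})

test_that("Matthews math is homogeneous and solvent is monotone in V_M", {
  cell <- unit_cell(60, 70, 80)
  a <- matthews(cell, "P212121", 20000)
  b <- matthews(cell, "P212121", 40000)
  expect_equal(a$v_m, 2 * b$v_m, tolerance = 1e-12)
  v <- seq(1.5, 6, by = 0.25)
  expect_true(all(diff(solvent_fraction(v)) > 0))
  expect_error(matthews(cell, "P1", -5), "positive")
})

test_that("host screening keeps and ranks the reference candidates", {
  tab <- read_host_table(host_table_path())
  ranked <- screen_hosts(tab)
  expect_equal(nrow(ranked), 8L)
  expect_equal(ranked$pdb_id[1], "2BO4")
  expect_equal(ranked$v_m[1], 5.50)
  expect_true(all(diff(ranked$v_m) <= 0))
  # raising the V_M floor to 4.5 keeps the >= 4.5 rows only
  strict <- screen_hosts(tab, min_vm = 4.5)
  expect_equal(nrow(strict), 6L)
  expect_false(any(c("3IA2", "2ZXQ") %in% strict$pdb_id))
  expect_true("1TG7" %in% strict$pdb_id)  # 4.50 survives at equality
  # empty input passes through
  expect_equal(nrow(screen_hosts(tab[0, ])), 0L)
})
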