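test_that("the strain score is the stated quadratic form", {
  # all targets met -> zero
  expect_equal(score_disulfide(3.85, 114.6, 114.6, 87), 0)
  expect_equal(score_disulfide(3.85, 114.6, 114.6, -87), 0)  # either chi3 sign
  # perturbing d_cb by +0.5 A raises the score by exactly w1 * 0.25
  expect_equal(score_disulfide(4.35, 114.6, 114.6, 87) -
                 score_disulfide(3.85, 114.6, 114.6, 87), 0.25)
  expect_equal(score_disulfide(4.35, 114.6, 114.6, 87,
                               weights = c(2, 1, 1)) -
                 score_disulfide(3.85, 114.6, 114.6, 87,
                                 weights = c(2, 1, 1)), 0.5)
})

test_that("the score matches an independent reimplementation on random geometry", {
  oracle <- function(d_cb, ang_a, ang_b, chi3, w = c(1, 1, 1)) {
    rad <- pi / 180
    dev_chi <- min(abs((chi3 - 87 + 180) %% 360 - 180),
                   abs((chi3 + 87 + 180) %% 360 - 180)) * rad
    w[1] * (d_cb - 3.85)^2 +
      w[2] * (((ang_a - 114.6) * rad)^2 + ((ang_b - 114.6) * rad)^2) +
      w[3] * dev_chi^2
  }
  set.seed(31)
  for (i in 1:50) {
    d <- runif(1, 2.5, 6); aa <- runif(1, 90, 140); ab <- runif(1, 90, 140)
    x3 <- runif(1, -180, 180); w <- runif(3, 0.5, 2)
    expect_equal(score_disulfide(d, aa, ab, x3, weights = w),
                 oracle(d, aa, ab, x3, w), tolerance = 1e-10)
  }
})

test_that("a textbook disulfide geometry scores near zero and ranks first", {
  pair <- make_ideal_cys_pair()
  # add decoy residues a bit farther out so the scan has competition
  decoy <- build_ideal_helix(6, chain = "D", cb = TRUE)
  decoy$atoms$x <- decoy$atoms$x + 6
  decoy$atoms$y <- decoy$atoms$y + 2
  decoy$atoms$serial <- decoy$atoms$serial + 2000L
  s <- struct3d(rbind(pair$atoms, decoy$atoms))
  hits <- scan_disulfides(s, mode = "intra")
  expect_gt(nrow(hits), 1)
  expect_equal(hits$chain_a[1], "A")
  expect_equal(hits$chain_b[1], "B")
  expect_lt(hits$energy[1], 0.05)
  expect_equal(abs(hits$chi3[1]), 87, tolerance = 2)
})

test_that("pre-filters are sound against brute-force pair enumeration", {
  s <- make_toy_crystal("P1", unit_cell(12, 12, 12), 4, seed = 6)
  hits <- scan_disulfides(s, mode = "both")
  key <- function(ca, ra, cb, rb, op, sh)
    paste(ca, ra, cb, rb, op, sh, sep = "|")
  got <- key(hits$chain_a, hits$resno_a, hits$chain_b, hits$resno_b,
             hits$op, hits$shift)
  # oracle: enumerate residue frames directly
  frames <- hostlattice:::residue_frames(s)
  want <- character(0)
  accept <- function(fa, fb) {
    d_ca <- sqrt(sum((fa$ca - fb$ca)^2))
    d_cb <- sqrt(sum((fa$cb - fb$cb)^2))
    d_ca <= 7.5 && d_cb >= 3.0 && d_cb <= 5.0
  }
  for (i in seq_along(frames)) for (j in seq_along(frames)) {
    if (j <= i) next
    if (abs(frames[[i]]$resno - frames[[j]]$resno) < 2) next
    if (accept(frames[[i]], frames[[j]]))
      want <- c(want, key(frames[[i]]$chain, frames[[i]]$resno,
                          frames[[j]]$chain, frames[[j]]$resno,
                          "x,y,z", "0,0,0"))
  }
  for (nb in expand_neighbors(s, cutoff = 8)) {
    mate <- hostlattice:::transform_frames(frames, nb$op, nb$shift, s$cell)
    for (i in seq_along(frames)) for (j in seq_along(mate)) {
      if (accept(frames[[i]], mate[[j]]))
        want <- c(want, key(frames[[i]]$chain, frames[[i]]$resno,
                            mate[[j]]$chain, mate[[j]]$resno,
                            format_symop(nb$op),
                            paste(nb$shift, collapse = ",")))
    }
  }
  expect_setequal(got, want)
})

test_that("symmetric candidates carry identical geometry metrics", {
  s <- make_toy_crystal("P65", unit_cell(22, 22, 16.5, 90, 90, 120), 6,
                        seed = 3)
  hits <- scan_disulfides(s, mode = "inter")
  expect_gt(nrow(hits), 0)
  for (i in seq_len(nrow(hits))) {
    # the mirrored candidate (b, a @ inverse op) must appear with the same
    # distances and score
    twin <- hits[hits$resno_a == hits$resno_b[i] &
                   hits$resno_b == hits$resno_a[i], ]
    expect_gt(nrow(twin), 0)
    j <- which.min(abs(twin$d_cb - hits$d_cb[i]))
    expect_equal(twin$d_ca[j], hits$d_ca[i], tolerance = 1e-6)
    expect_equal(twin$d_cb[j], hits$d_cb[i], tolerance = 1e-6)
    expect_equal(twin$energy[j], hits$energy[i], tolerance = 1e-6)
  }
})

test_that("glycines get a reconstructed C-beta instead of being skipped", {
  pair <- make_ideal_cys_pair()
  g <- pair
  # strip residue B's C-beta and call it glycine: the scan must rebuild an
  # ideal C-beta from the backbone (independent of the fixture's own
  # internal-coordinate construction) and still find the bridge
  g$atoms$resname[g$atoms$chain == "B"] <- "GLY"
  g$atoms <- g$atoms[!(g$atoms$chain == "B" & g$atoms$name == "CB"), ]
  hits_cys <- scan_disulfides(pair, mode = "intra")
  hits_gly <- scan_disulfides(g, mode = "intra")
  expect_equal(nrow(hits_gly), 1L)
  expect_equal(hits_gly$d_cb, hits_cys$d_cb, tolerance = 0.1)
})

test_that("residues with missing backbone are skipped with a warning", {
  s <- make_toy_crystal("P1", unit_cell(40, 40, 40), 4, seed = 2)
  s$atoms <- s$atoms[!(s$atoms$resno == 2 & s$atoms$name == "CA"), ]
  expect_warning(hostlattice:::residue_frames(s), "incomplete backbone")
})
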