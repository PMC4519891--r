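test_that("kappa is the bend angle at the central residue", {
  # only rows i-2, i, i+2 matter for kappa at i = 3
  coords <- rbind(c(0, 0, 0), c(5, 5, 5), c(1, 1, 0), c(6, 6, 6), c(1, 1, 2))
  expect_equal(kappa_angle(coords, 3), 90)
  colin <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 2, 0), c(3, 3, 0), c(4, 4, 0))
  expect_equal(kappa_angle(colin, 3), 180)
  expect_error(kappa_angle(colin, 2), "3 <= i")
})

test_that("kappa is invariant under rigid motion, alpha flips under mirror", {
  set.seed(21)
  for (k in 1:25) {
    cf <- random_saw(9)
    rt <- random_rigid()
    moved <- apply_rigid(cf$coords, rt)
    for (i in 3:7) {
      expect_equal(kappa_angle(moved, i), kappa_angle(cf$coords, i),
                   tolerance = 1e-9)
      a <- alpha_angle(cf$coords, i)
      mirrored <- cf$coords %*% diag(c(1, 1, -1))
      am <- alpha_angle(mirrored, i)
      if (!is.na(a) && abs(abs(a) - 180) > 1e-9)
        expect_equal(am, -a, tolerance = 1e-9)
    }
  }
})

test_that("alpha matches hand-computed dihedrals and flags degeneracy", {
  zigzag <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(3, 1, 0))
  expect_equal(alpha_angle(zigzag, 2), 180)
  colin <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 2, 0), c(2, 2, 2))
  expect_true(is.na(alpha_angle(colin, 2)))
  set.seed(4)
  for (k in 1:30) {
    cf <- random_saw(6)
    a_pkg <- alpha_angle(cf$coords, 3)
    a_ora <- oracle_alpha(cf$coords[2, ], cf$coords[3, ], cf$coords[4, ],
                          cf$coords[5, ])
    if (is.na(a_pkg)) expect_true(is.na(a_ora))
    else expect_equal(a_pkg, a_ora, tolerance = 1e-9)
  }
})

test_that("exhaustive fragment enumeration reproduces the lattice angle ranges", {
  pairs <- enumerate_angle_pairs()
  expect_gt(nrow(pairs), 0)
  expect_equal(min(pairs$kappa), 30, tolerance = 1e-9)
  expect_equal(max(pairs$kappa), 150, tolerance = 1e-9)
  sp <- angle_spaces(pairs)
  expect_length(sp$alpha, 6)
  # mirror symmetry of the lattice: every nonzero alpha appears with both
  # signs, and the magnitude classes are the six discrete spaces
  nonzero <- setdiff(round(unique(pairs$alpha), 6), c(0, 180))
  expect_setequal(nonzero, -nonzero)
  expect_equal(sp$alpha,
               c(0, 54.73561, 70.52878, 109.47122, 125.26439, 180),
               tolerance = 1e-5)
})

test_that("the realized kappa multiset is invariant under lattice rotation", {
  pairs <- enumerate_angle_pairs()
  rot <- crossover_rotations()[["trihex_ppp_120"]]
  rotated <- vapply(strsplit(pairs$moves, " "), function(mv) {
    cf <- decode_moves("AAAAA", as.integer(mv))
    kappa_angle(cf$coords %*% t(rot), 3)
  }, 0)
  expect_equal(sort(round(rotated, 6)), sort(round(pairs$kappa, 6)))
})

test_that("binning rounds kappa to decade centers and alpha to the nearest space", {
  b <- bin_angle_pair(71.3, 58)
  expect_equal(c(b$kappa_bin, b$alpha_bin), c(70, 60))
  expect_true(is.na(bin_angle_pair(25, 60)$kappa_bin))
  expect_true(is.na(bin_angle_pair(170, 60)$kappa_bin))
  b <- bin_angle_pair(150, -109.5)
  expect_equal(c(b$kappa_bin, b$alpha_bin), c(150, -110))
  # circular distance: -178 is closer to 180 than to -130
  expect_equal(bin_angle_pair(90, -178)$alpha_bin, 180)
})

test_that("the packaged preference matrix matches its transcription cell by cell", {
  m <- ka_preferences()
  exp <- expected_preferences()
  expect_identical(dim(m), dim(exp))
  expect_identical(unname(m), unname(exp))
  expect_equal(angle_preference(70, 60, m), 17.87)
  expect_equal(angle_preference(150, -110, m), 17.46)
  expect_true(all(m["30", ] == 0))
  expect_equal(angle_preference(NA, NA, m), 0)
})

test_that("K^KA equals an independent recomputation from raw coordinates", {
  m <- ka_preferences()
  frag <- decode_moves("AAAAA", "1 1 2 12")  # single pair in the (70, 60) cell
  expect_equal(ka_energy(frag, m), -17.87)
  expect_warning(e <- ka_energy(decode_moves("AAAA", "1 2 1"), m), "short")
  expect_equal(e, 0)
  set.seed(31)
  for (k in 1:200) {
    cf <- random_saw(sample(5:35, 1))
    e <- ka_energy(cf, m)
    expect_lte(e, 0)
    expect_equal(e, oracle_ka_energy(cf$coords, m), tolerance = 1e-12)
  }
})

test_that("the angle constraint rejects degenerate and zero-preference chains", {
  m <- ka_preferences()
  straight <- decode_moves(strrep("A", 6), rep(1, 5))
  expect_false(check_angle_constraint(straight, m))
  expect_true(check_angle_constraint(decode_moves("AAAAA", "1 1 2 12"), m))
  # too short for any pair: vacuously feasible
  expect_true(check_angle_constraint(decode_moves("AAAA", "1 2 1"), m))
})
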