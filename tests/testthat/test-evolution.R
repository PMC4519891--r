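test_that("binary tournaments pick the better individual", {
  expect_equal(tournament_select(fitness = 5), 1L)
  set.seed(1)
  for (k in 1:20)
    expect_equal(tournament_select(fitness = c(-5, -3)), 1L)
  # crowded comparison: equal rank, larger crowding wins
  for (k in 1:20)
    expect_equal(tournament_select(rank = c(1, 1), crowding = c(Inf, 0.2)),
                 1L)
  for (k in 1:20)
    expect_equal(tournament_select(rank = c(2, 1), crowding = c(Inf, 0)),
                 2L)
  expect_error(tournament_select(fitness = numeric(0)), "empty")
})

test_that("the 17 crossover rotations are exact lattice symmetries", {
  rots <- crossover_rotations()
  expect_length(rots, 17)
  fam <- vapply(rots, attr, "", "family")
  expect_equal(sum(fam == "square"), 9)
  expect_equal(sum(fam == "trihex"), 8)
  keys <- vapply(rots, function(m) paste(m, collapse = ","), "")
  expect_equal(anyDuplicated(keys), 0)
  for (m in rots) {
    expect_true(all(m == round(m)))
    expect_equal(unname(m %*% t(m)), diag(3))
    expect_equal(det(m), 1)
  }
})

test_that("rotation crossover yields at most 17 valid offspring sharing the head", {
  set.seed(33)
  for (k in 1:15) {
    n <- sample(8:25, 1)
    seqs <- random_aa(n)
    p1 <- random_saw(n, seqs)
    p2 <- random_saw(n, seqs)
    g <- sample(2:(n - 1), 1)
    kids <- rotation_crossover(p1, p2, point = g)
    expect_lte(length(kids), 17)
    for (kid in kids) {
      d <- diff(kid$coords)
      expect_true(all(rowSums(d * d) == 2))
      expect_equal(anyDuplicated(kid$coords), 0)
      expect_equal(kid$coords[1:g, ], p1$coords[1:g, ], ignore_attr = TRUE)
      expect_identical(kid$moves[seq_len(g - 1)], p1$moves[seq_len(g - 1)])
    }
  }
  expect_error(rotation_crossover(random_saw(6, "AAAAAA"),
                                  random_saw(6, "CCCCCC")),
               "same sequence")
})

test_that("pull moves always produce valid self-avoiding walks", {
  set.seed(44)
  cf <- random_saw(2)
  res <- generalized_pull_move(cf)
  expect_true(all(rowSums(diff(res$coords)^2) == 2))
  cf <- random_saw(18)
  changed <- 0
  for (k in 1:1000) {
    nxt <- generalized_pull_move(cf)
    d <- diff(nxt$coords)
    expect_true(all(rowSums(d * d) == 2))
    expect_equal(anyDuplicated(nxt$coords), 0)
    if (!identical(nxt$coords, cf$coords)) changed <- changed + 1
    cf <- nxt
  }
  expect_gt(changed, 0)
  # a rejecting validity predicate forces the no-op fallback
  frozen <- generalized_pull_move(cf, valid = function(x) FALSE)
  expect_identical(frozen, cf)
})

test_that("K-site mutation is local and preserves walk validity", {
  set.seed(55)
  for (k in 1:200) {
    n <- sample(6:25, 1)
    cf <- random_saw(n)
    mut <- k_site_mutation(cf, k = 3)
    d <- diff(mut$coords)
    expect_true(all(rowSums(d * d) == 2))
    expect_equal(anyDuplicated(mut$coords), 0)
    expect_lte(sum(mut$moves != cf$moves), 3)
  }
  # K = n - 1 resamples the whole move string
  cf <- random_saw(7)
  mut <- k_site_mutation(cf, k = 6)
  expect_true(all(rowSums(diff(mut$coords)^2) == 2))
})

test_that("non-dominated sorting agrees with an exhaustive dominance oracle", {
  ns <- nondominated_sort(rbind(c(1, 2), c(2, 1), c(2, 2)))
  expect_equal(ns$rank, c(1, 1, 2))
  expect_equal(ns$fronts, list(c(1L, 2L), 3L))
  expect_equal(nondominated_sort(rbind(c(1, 1), c(1, 1)))$rank, c(1, 1))
  expect_equal(nondominated_sort(rbind(c(3, 4)))$rank, 1)
  set.seed(66)
  for (k in 1:20) {
    n <- sample(2:50, 1)
    obj <- matrix(sample(0:6, 2 * n, replace = TRUE), n, 2)
    expect_equal(nondominated_sort(obj)$rank, oracle_ranks(obj))
  }
})

test_that("crowding distance follows the boundary and gap rules", {
  expect_equal(crowding_distance(rbind(c(1, 2))), Inf)
  expect_equal(crowding_distance(rbind(c(1, 2), c(2, 1))), c(Inf, Inf))
  evenly <- rbind(c(0, 0), c(1, 1), c(2, 2))
  expect_equal(crowding_distance(evenly), c(Inf, 2, Inf))
  set.seed(77)
  obj <- matrix(stats::rnorm(20), 10, 2)
  perm <- sample(10)
  expect_equal(crowding_distance(obj)[perm], crowding_distance(obj[perm, ]))
})

test_that("elitist GA trajectories never worsen and respect trivial bounds", {
  cfg <- fold_config(12, generations = 0)
  r0 <- fold("CFCFCFCFCFCF", mode = "ga-hp", config = cfg, seed = 3)
  expect_equal(r0$best_energy, min(r0$energies))
  expect_equal(nrow(r0$history), 1)
  set.seed(88)
  for (k in 1:5) {
    r <- fold("CFCFCFCFCFCF", mode = "ga-hp",
              config = fold_config(12, generations = 8), seed = k)
    expect_true(all(diff(r$history$best) <= 0))
  }
  allp <- fold(strrep("G", 10), mode = "ga-hp",
               config = fold_config(10, generations = 3), seed = 1)
  expect_equal(allp$best_energy, 0)
})

test_that("ga-cp uses the supplied potential and demands one", {
  expect_error(fold("ACDEACDEAC", mode = "ga-cp"), "contact_matrix")
  m <- matrix(1, 20, 20, dimnames = list(aa20, aa20))
  r <- fold("ACDEACDEAC", mode = "ga-cp",
            config = fold_config(10, generations = 4), seed = 2,
            contact_matrix = m)
  # uniform potential: energy is minus the number of contacts
  expect_equal(r$best_energy, -nrow(contact_pairs(r$best)))
})

test_that("runs are byte-for-byte reproducible given the seed", {
  cfg <- fold_config(12, generations = 6)
  a <- fold("CFCFCFCFCFCF", mode = "nsga2", config = cfg, seed = 9)
  b <- fold("CFCFCFCFCFCF", mode = "nsga2", config = cfg, seed = 9)
  expect_identical(a, b)
  c1 <- fold("CFCFCFCFCFCF", mode = "ga-hp", config = cfg, seed = 9)
  c2 <- fold("CFCFCFCFCFCF", mode = "ga-hp", config = cfg, seed = 9)
  expect_identical(c1, c2)
})

test_that("multi-objective fronts are feasible, legal and mutually non-dominated", {
  m <- ka_preferences()
  for (mode in c("nsga", "nsga2")) {
    r <- fold("CFCFCFCFCFCF", mode = mode,
              config = fold_config(12, generations = 8), seed = 5)
    expect_gt(length(r$front), 0)
    for (cf in r$front) {
      d <- diff(cf$coords)
      expect_true(all(rowSums(d * d) == 2))
      expect_equal(anyDuplicated(cf$coords), 0)
      expect_true(check_angle_constraint(cf, m))
    }
    obj <- r$front_objectives
    for (i in seq_len(nrow(obj))) for (j in seq_len(nrow(obj)))
      if (i != j)
        expect_false(all(obj[i, ] <= obj[j, ]) && any(obj[i, ] < obj[j, ]))
    # stored objectives match recomputation
    recomputed <- t(vapply(r$front, function(cf)
      c(hp_energy(cf), ka_energy(cf, m)), c(0, 0)))
    expect_equal(unname(obj), unname(recomputed))
  }
})

test_that("feasible walk initialization honours the angle constraint", {
  m <- ka_preferences()
  set.seed(101)
  for (k in 1:10) {
    cf <- random_feasible_saw(15, matrix = m)
    expect_true(attr(cf, "feasible"))
    expect_true(check_angle_constraint(cf, m))
  }
})
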