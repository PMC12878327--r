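test_that("kabsch_rmsd is zero on identical sets and rigid transforms", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    a <- matrix(rnorm(n * 3, sd = 2), n, 3)
    expect_equal(kabsch_rmsd(a, a), 0, tolerance = 1e-12)
    b <- a %*% random_rotation() +
      matrix(runif(3, -10, 10), n, 3, byrow = TRUE)
    expect_lt(kabsch_rmsd(a, b), 1e-8)
  }
})

test_that("kabsch_rmsd is symmetric and invariant under rigid motion of either argument", {
  set.seed(202)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    a <- matrix(rnorm(n * 3), n, 3)
    b <- matrix(rnorm(n * 3), n, 3)
    expect_equal(kabsch_rmsd(a, b), kabsch_rmsd(b, a), tolerance = 1e-10)
    b_moved <- b %*% random_rotation() + matrix(rnorm(3), n, 3, byrow = TRUE)
    expect_equal(kabsch_rmsd(a, b_moved), kabsch_rmsd(a, b), tolerance = 1e-8)
  }
})

test_that("kabsch_rmsd agrees with independent oracles", {
  set.seed(303)
  # 4-atom case with one atom displaced 1 Angstrom, vs numeric minimization
  a <- matrix(c(
    0, 0, 0,
    1.5, 0, 0,
    0, 1.5, 0,
    0, 0, 1.5
  ), 4, 3, byrow = TRUE)
  b <- a
  b[4, ] <- b[4, ] + c(0, 0, 1.0)
  expect_equal(kabsch_rmsd(a, b), numeric_rmsd(a, b), tolerance = 1e-6)
  # random pairs vs Horn quaternion closed form
  for (i in 1:20) {
    n <- sample(3:15, 1)
    x <- matrix(rnorm(n * 3, sd = 1.5), n, 3)
    y <- x + matrix(rnorm(n * 3, sd = 0.5), n, 3)
    expect_equal(kabsch_rmsd(x, y), horn_rmsd(x, y), tolerance = 1e-9)
  }
})

test_that("kabsch_rmsd enforces shape and minimum size", {
  expect_error(kabsch_rmsd(matrix(0, 2, 3), matrix(0, 2, 3)), "At least 3 atoms")
  expect_error(kabsch_rmsd(matrix(0, 4, 3), matrix(0, 5, 3)), "equal dimension")
  expect_error(kabsch_rmsd(matrix(0, 4, 2), matrix(0, 4, 2)), "N x 3")
})

test_that("mirror images are not superposed onto each other", {
  set.seed(404)
  a <- matrix(rnorm(15), 5, 3)
  mirrored <- a
  mirrored[, 1] <- -mirrored[, 1]
  # a chiral point set cannot reach zero against its mirror image
  expect_gt(kabsch_rmsd(a, mirrored), 0.1)
})

test_that("energy-window filtering is inclusive and keeps the minimum", {
  base <- matrix(rnorm(12), 4, 3)
  mk <- function(dg) {
    make_ensemble(replicate(length(dg), base + rnorm(12), simplify = FALSE), dg)
  }
  expect_equal(
    filter_energy_window(mk(c(0, 2, 5.9)), 6)$conformers$delta_G,
    c(0, 2, 5.9)
  )
  expect_equal(
    filter_energy_window(mk(c(0, 6.0, 6.1)), 6)$conformers$delta_G,
    c(0, 6.0)
  )
  expect_equal(filter_energy_window(mk(c(0, 7, 8)), 6)$conformers$delta_G, 0)
})

test_that("ensembles at or below the cap are returned unchanged", {
  set.seed(7)
  coords <- lapply(1:3, function(i) matrix(runif(12, -3, 3), 4, 3))
  ens <- make_ensemble(coords, delta_G = c(0, 1, 2))
  pruned <- prune_ensemble(ens, prune_config(max_conformers = 20))
  expect_identical(pruned$conformers, ens$conformers)
})

test_that("exact duplicates collapse to the lowest-energy conformer", {
  base <- matrix(runif(12, -3, 3), 4, 3)
  ens <- make_ensemble(
    replicate(30, base, simplify = FALSE),
    delta_G = seq(0, 5.8, length.out = 30)
  )
  pruned <- prune_ensemble(ens, prune_config())
  expect_identical(n_conformers(pruned), 1L)
  expect_equal(pruned$conformers$delta_G, 0)
})

test_that("greedy pruning matches the spec example: near-duplicates interleaved by energy", {
  set.seed(515)
  # 21 mutually distant conformers + 4 near-duplicates of earlier members
  centres <- lapply(1:21, function(i) matrix(runif(18, -6, 6), 6, 3))
  dups <- lapply(centres[1:4], function(m) m + matrix(rnorm(18, sd = 0.03), 6, 3))
  coords <- append(centres, dups, after = 10) # interleave by position
  ens <- make_ensemble(coords, delta_G = seq(0, 5, length.out = 25))
  pruned <- prune_ensemble(ens, prune_config())
  expect_identical(n_conformers(pruned), 20L)
  expect_identical(
    pruned$conformers$conf_id,
    prune_oracle_ids(ens, 0.5, 20L)
  )
  # no retained pair is a near-duplicate
  cds <- pruned$conformers$coords
  for (i in seq_along(cds)[-1]) {
    for (j in seq_len(i - 1)) {
      expect_gt(kabsch_rmsd(cds[[i]], cds[[j]]), 0.5)
    }
  }
})

test_that("pruning is deterministic and idempotent", {
  set.seed(616)
  ens <- random_clustered_ensemble(28, n_atoms = 5, n_centres = 24)
  p1 <- prune_ensemble(ens, prune_config())
  p2 <- prune_ensemble(ens, prune_config())
  expect_identical(p1$conformers, p2$conformers)
  expect_identical(
    prune_ensemble(p1, prune_config())$conformers,
    p1$conformers
  )
  expect_true(0 %in% p1$conformers$delta_G) # lowest-energy conformer retained
  expect_false(is.unsorted(p1$conformers$delta_G))
})
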