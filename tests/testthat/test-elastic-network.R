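three_bead_chain <- function(spacing = 3.8) {
  calpha_model(cbind(c(0, spacing, 2 * spacing), 0, 0), rep("A", 3), 1:3)
}

test_that("pair list matches an all-pairs distance scan", {
  m <- three_bead_chain()
  topo <- build_topology(m, enm_params(cutoff = 8))
  expect_equal(topo$pairs[, c("i", "j")],
               data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L)),
               ignore_attr = TRUE)
  expect_equal(topo$pairs$d0, c(3.8, 7.6, 3.8))

  # tight cutoff and no bonded span keeps only the short pairs
  topo2 <- build_topology(m, enm_params(cutoff = 5, sequence_span = 0))
  expect_equal(topo2$pairs[, c("i", "j")],
               data.frame(i = c(1L, 2L), j = c(2L, 3L)),
               ignore_attr = TRUE)

  # against a brute-force scan on a random system
  r <- random_model(30, seed = 7)
  topo3 <- build_topology(r, enm_params(cutoff = 12, sequence_span = 0))
  d <- as.matrix(dist(r$xyz))
  expected <- which(upper.tri(d) & d < 12, arr.ind = TRUE)
  expect_equal(nrow(topo3$pairs), nrow(expected))
})

test_that("a whole-chain rigid block connects every pair at unit stiffness", {
  m <- random_model(10, seed = 1)
  topo <- build_topology(m, enm_params(), rigid_blocks = list(1:10))
  expect_equal(nrow(topo$pairs), 45L)
  expect_true(all(topo$pairs$kind == "rigid"))
  expect_true(all(topo$pairs$k == 1))

  expect_error(build_topology(m, enm_params(),
                              rigid_blocks = list(1:5, 4:8)), "overlap")
  expect_error(build_topology(m, enm_params(), rigid_blocks = list(9:11)),
               "out of range")
})

test_that("spring stiffness follows the bonded and Cartesian power laws", {
  p <- enm_params()
  expect_equal(spring_constant(1, 3.8, p), p$sequence_constant)
  expect_equal(spring_constant(2, 7.0, p),
               p$sequence_constant / 2^p$sequence_exponent)
  expect_equal(spring_constant(NA, p$reference_length, p),
               p$cartesian_constant)
  expect_equal(spring_constant(NA, 2 * p$reference_length, p),
               p$cartesian_constant / 64)
  # beyond the bonded span the Cartesian rule applies
  expect_equal(spring_constant(5, p$reference_length, p),
               p$cartesian_constant)
  # monotonically non-increasing in distance
  d <- seq(3, 15, by = 0.5)
  expect_true(all(diff(spring_constant(NA, d, p)) <= 0))
  expect_error(spring_constant(1, 0, p), "d0")
})

test_that("forces vanish at the source conformation and obey Newton's third law", {
  m <- random_model(15, seed = 2)
  topo <- build_topology(m, enm_params(cutoff = 15))
  expect_equal(max(abs(compute_forces(topo, m$xyz))), 0)
  expect_equal(potential_energy(topo, m$xyz), 0)

  xyz <- m$xyz + matrix(rnorm(45, sd = 0.4), 15, 3)
  f <- compute_forces(topo, xyz)
  expect_lt(max(abs(colSums(f))), 1e-8 * max(abs(f)))
  # zero net torque about the centroid
  rel <- sweep(xyz, 2L, colMeans(xyz))
  torque <- colSums(cbind(rel[, 2] * f[, 3] - rel[, 3] * f[, 2],
                          rel[, 3] * f[, 1] - rel[, 1] * f[, 3],
                          rel[, 1] * f[, 2] - rel[, 2] * f[, 1]))
  expect_lt(max(abs(torque)), 1e-7 * max(abs(f)))
})

test_that("a single stretched spring pulls the beads together", {
  m <- calpha_model(cbind(c(0, 4.8), 0, 0), rep("A", 2), 1:2)
  topo <- build_topology(m, enm_params(sequence_constant = 1,
                                       sequence_span = 1))
  topo$pairs$d0 <- 3.8
  f <- compute_forces(topo, m$xyz)
  expect_equal(f[1L, ], c(1, 0, 0))
  expect_equal(f[2L, ], c(-1, 0, 0))

  coincident <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_error(compute_forces(topo, coincident), "coincident")
})

test_that("forces are the exact negative gradient of the potential", {
  m <- random_model(20, seed = 3)
  topo <- build_topology(m, enm_params(cutoff = 14))
  xyz <- m$xyz + matrix(rnorm(60, sd = 0.3), 20, 3)
  f <- compute_forces(topo, xyz)
  g <- numeric_gradient(topo, xyz)
  expect_lt(max(abs(f + g)) / max(abs(f)), 1e-5)

  # energy decreases along a small steepest-descent step
  e0 <- potential_energy(topo, xyz)
  expect_lt(potential_energy(topo, xyz + 1e-4 * f), e0)
  expect_gte(e0, 0)
})

test_that("cutoff pair-list forces equal the all-pairs force when the cutoff covers the system", {
  m <- random_model(40, seed = 4)
  diam <- max(dist(m$xyz))
  topo_all <- build_topology(m, enm_params(cutoff = diam + 1))
  xyz <- m$xyz + matrix(rnorm(120, sd = 0.3), 40, 3)
  expect_equal(nrow(topo_all$pairs), 40 * 39 / 2)
  f_list <- compute_forces(topo_all, xyz)
  f_brute <- brute_force_forces(topo_all, xyz)
  expect_equal(f_list, f_brute, tolerance = 1e-12)
})

test_that("pair-list rebuild drops, admits and re-anchors pairs correctly", {
  m <- calpha_model(rbind(c(0, 0, 0), c(7, 0, 0)), c("A", "B"), c(1L, 1L))
  topo <- build_topology(m, enm_params(cutoff = 8))
  expect_equal(nrow(topo$pairs), 1L)

  # unchanged positions: identical list
  same <- rebuild_pair_list(topo, m$xyz)
  expect_equal(same$pairs, topo$pairs, ignore_attr = TRUE)

  # moved beyond the cutoff: non-bonded pair dropped
  apart <- rbind(c(0, 0, 0), c(9, 0, 0))
  expect_equal(nrow(rebuild_pair_list(topo, apart)$pairs), 0L)

  # rigid pair at 30 A is retained with its original rest length
  topo_r <- build_topology(m, enm_params(cutoff = 8),
                           rigid_blocks = list(1:2))
  far <- rbind(c(0, 0, 0), c(30, 0, 0))
  reb <- rebuild_pair_list(topo_r, far)
  expect_equal(nrow(reb$pairs), 1L)
  expect_equal(reb$pairs$kind, "rigid")
  expect_equal(reb$pairs$d0, 7)

  # adaptive rest lengths: Cartesian pairs re-anchor at current distance,
  # nearest-neighbour bonded pairs keep their original rest length
  chain <- calpha_model(cbind(c(0, 3.8, 7.6, 11.4), 0, 0), rep("A", 4), 1:4)
  tc <- build_topology(chain, enm_params(cutoff = 8, sequence_span = 1))
  stretched <- cbind(c(0, 4.0, 7.8, 11.9), 0, 0)
  reb2 <- rebuild_pair_list(tc, stretched)
  bonded <- reb2$pairs[reb2$pairs$kind == "bonded", ]
  expect_equal(bonded$d0, rep(3.8, 3))
  cart <- reb2$pairs[reb2$pairs$kind == "cartesian", ]
  expect_equal(cart$d0, c(7.8, 7.9))  # (1,3) and (2,4) at current distance
})

test_that("pair count grows linearly with chain length at fixed density", {
  sizes <- c(100, 250, 500, 1000, 2000)
  counts <- vapply(sizes, function(n) {
    fx <- make_two_state(n, 1, "uniform_translation", 0)
    nrow(build_topology(fx$start, enm_params())$pairs)
  }, numeric(1))
  slope <- coef(lm(log(counts) ~ log(sizes)))[2L]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})
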