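p0 <- force_field_params()

test_that("bonded FENE+WCA energy matches the closed form", {
  # frozen high-precision evaluations of the closed form
  expect_equal(bonded_energy(10, p0), 1726.0924, tolerance = 1e-6)
  expect_equal(bonded_energy(1, p0), 16.018776, tolerance = 1e-6)
  # independent re-evaluation at scattered points
  r <- c(0.85, 0.95, 1.05, 1.5, 5, 15, 19.5)
  expect_equal(bonded_energy(r, p0), oracle_bonded(r), tolerance = 1e-12)
  # logarithmic divergence approaching R0
  expect_gt(bonded_energy(20 * (1 - 1e-9), p0), 1e4)
  expect_error(bonded_energy(20, p0), "FENE domain")
  expect_error(bonded_energy(0, p0), "FENE domain")
  expect_error(bonded_energy(c(1, 25), p0), "bond 2")
})

test_that("bonded force is minus the energy derivative and vanishes at equilibrium", {
  for (r in c(0.9, 1.05, 1.5, 10)) {
    expect_equal(bonded_force(r, p0),
                 -fd_derivative(function(x) oracle_bonded(x), r),
                 tolerance = 1e-5)
  }
  req <- equilibrium_bond_length(p0)
  expect_lt(abs(bonded_force(req, p0)), 1e-5)
  # FENE divergence near maximum extension
  expect_lt(bonded_force(19.99, p0), -1e4)
  expect_error(bonded_force(20.5, p0), "FENE domain")
})

test_that("nonbonded WCA is quarter-shifted, truncated and continuous at the cutoff", {
  expect_identical(nonbonded_energy(1, p0), 1)       # 4(1 - 1 + 1/4)
  rc <- 2^(1 / 6)
  expect_identical(nonbonded_energy(rc, p0), 0)
  expect_equal(nonbonded_energy(0.9, p0), 7.636119, tolerance = 1e-6)
  # continuity of both energy and force across the cutoff
  expect_lt(abs(nonbonded_energy(rc - 1e-8, p0)), 1e-10)
  expect_lt(abs(nonbonded_energy(rc + 1e-8, p0)), 1e-10)
  expect_lt(abs(nonbonded_force(rc - 1e-8, p0)), 1e-6)
  expect_identical(nonbonded_force(rc + 1e-8, p0), 0)
  expect_identical(nonbonded_energy(3, p0), 0)
  expect_error(nonbonded_energy(0, p0), "positive")
})

test_that("harmonic restraint is symmetric about its rest length", {
  expect_identical(restraint_energy(2.2, p0), 0)
  expect_equal(restraint_energy(3.2, p0), 1)
  expect_equal(restraint_energy(1.2, p0), 1)
  expect_equal(restraint_energy(c(0, 4.4), p0), c(4.84, 4.84))
  expect_error(restraint_energy(-1, p0), "nonnegative")
})

test_that("equilibrium bond length is 0.99 sigma and agrees with a dense grid", {
  req <- equilibrium_bond_length(p0)
  expect_equal(round(req, 2), 0.99)
  # dense-grid minimization oracle, step 1e-5
  grid <- seq(0.5, 2^(1 / 6), by = 1e-5)
  expect_equal(req, grid[which.min(oracle_bonded(grid))],
               tolerance = 1e-4)
  # short FENE: grid oracle again
  p2 <- force_field_params(R0 = 1.5)
  grid2 <- seq(0.5, 1.12, by = 1e-5)
  e2 <- -0.5 * 30 * 1.5^2 * log(1 - (grid2 / 1.5)^2) + oracle_wca(grid2)
  expect_equal(round(equilibrium_bond_length(p2), 2),
               round(grid2[which.min(e2)], 2))
  expect_equal(round(equilibrium_bond_length(p2), 2), 0.96)
  # pure FENE (negligible core) is monotone: no interior minimum
  expect_error(
    equilibrium_bond_length(force_field_params(epsilon_star = 1e-12)),
    "no sign change|no interior")
})

test_that("equilibrium bond length scales linearly under sigma-rescaling", {
  r1 <- equilibrium_bond_length(force_field_params(sigma = 1))
  # rescale every length by 2 and the spring constants by 1/4
  r2 <- equilibrium_bond_length(force_field_params(
    sigma = 2, R0 = 40, kappa = 30 / 4, K = 1 / 4, r0 = 4.4))
  expect_equal(r2, 2 * r1, tolerance = 1e-6)
})

test_that("bonded energy is strictly convex around its minimizer", {
  req <- equilibrium_bond_length(p0)
  h <- 0.01
  curv <- (bonded_energy(req + h, p0) - 2 * bonded_energy(req, p0) +
             bonded_energy(req - h, p0)) / h^2
  expect_gt(curv, 0)
  expect_gt(bonded_energy(req + h, p0), bonded_energy(req, p0))
  expect_gt(bonded_energy(req - h, p0), bonded_energy(req, p0))
})

test_that("parameter validation rejects degenerate force fields", {
  expect_error(force_field_params(kappa = -1), "strictly positive")
  expect_error(force_field_params(R0 = 1), "exceed the WCA cutoff")
})

test_that("system energy of a single bond matches the pair closed form", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0))
  sys <- system_energy_forces(pos, NULL, p0)
  expect_equal(sys$energy, 16.018776, tolerance = 1e-6)
  expect_equal(sys$forces[1, ], -sys$forces[2, ])
  expect_equal(sys$forces[1, 1], -bonded_force(1, p0))
  one <- system_energy_forces(matrix(0, 1, 3), NULL, p0)
  expect_identical(one$energy, 0)
  expect_true(all(one$forces == 0))
  expect_error(
    system_energy_forces(rbind(c(0, 0, 0), c(25, 0, 0)), NULL, p0),
    "bond 1")
})

test_that("analytic forces match finite differences on random configurations", {
  set.seed(42)
  worst <- 0
  for (trial in 1:100) {
    n <- sample(3:20, 1)
    pos <- random_config(n, seed = trial)
    restraints <- if (n >= 5 && trial %% 2 == 0)
      restraint_set(rbind(c(1L, n), c(2L, n - 2L))) else NULL
    an <- system_energy_forces(pos, restraints, p0)$forces
    fd <- fd_forces(pos, restraints, p0)
    scale <- max(abs(fd), 1)
    worst <- max(worst, max(abs(an - fd)) / scale)
    # Newton's third law in aggregate
    expect_lt(max(abs(colSums(an))), 1e-8 * scale)
  }
  expect_lt(worst, 1e-5)
})
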