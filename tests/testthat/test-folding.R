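p0 <- force_field_params()

toy_hic <- function(entries, n = 4) {
  m <- matrix(0, n, n)
  for (e in entries) {
    m[e[1], e[2]] <- e[3]
    m[e[2], e[1]] <- e[3]
  }
  hic_matrix(m, bin_size = 5000L)
}

test_that("restraint selection excludes the diagonal band and honors rules", {
  expect_equal(nrow(select_restraints(toy_hic(list(), 10))$pairs), 0L)
  # counts {(1,3): 5, (1,4): 1, (2,4): 3}; top half by count
  hic <- toy_hic(list(c(1, 3, 5), c(1, 4, 1), c(2, 4, 3)))
  top <- select_restraints(hic, "top_quantile", q = 0.5)
  expect_equal(unname(top$pairs), rbind(c(1L, 3L), c(2L, 4L)))
  all3 <- select_restraints(hic)
  expect_equal(nrow(all3$pairs), 3L)
  thr <- select_restraints(hic, "count_threshold", threshold = 3)
  expect_equal(unname(thr$pairs), rbind(c(1L, 3L), c(2L, 4L)))
  # adjacent-only contacts yield nothing
  adj <- toy_hic(list(c(1, 2, 9), c(3, 4, 9)))
  expect_equal(nrow(select_restraints(adj)$pairs), 0L)
})

test_that("restraint and matrix validation reject malformed input", {
  expect_error(hic_matrix(matrix(1:6, 2, 3)), "square")
  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(hic_matrix(asym), "asymmetric")
  expect_error(hic_matrix(matrix(-1, 1, 1)), "nonnegative")
  expect_error(restraint_set(rbind(c(1L, 2L))), "bonded")
  expect_error(restraint_set(rbind(c(1L, 5L), c(1L, 5L))), "duplicate")
})

test_that("mc_fold is a no-op without restraints and at-rest with satisfied ones", {
  ch <- sarw_chain(10, seed = 2)
  out <- mc_fold(ch, restraint_set(NULL), mc_config(seed = 1))
  expect_identical(out$positions, ch$positions)
  expect_identical(attr(out, "mc_report")$sweeps, 0L)
  # a pair already within the activation radius is satisfied at sweep 0:
  # straight chain, beads 1 and 3 sit at 1.98 sigma < 2.2 sigma
  pos <- cbind(seq(0, 9) * 0.99, 0, 0)
  ch2 <- bead_chain(pos, 0.99, 0.9)
  rs <- restraint_set(rbind(c(1L, 3L)))
  out2 <- mc_fold(ch2, rs, mc_config(seed = 1))
  expect_identical(attr(out2, "mc_report")$sweeps, 0L)
  expect_identical(out2$positions, pos)
})

test_that("mc_fold pulls a distant pair together without breaking bonds", {
  ch <- sarw_chain(10, seed = 2)
  rs <- restraint_set(rbind(c(1L, 10L)))
  out <- mc_fold(ch, rs, mc_config(seed = 5), p0)
  rep <- attr(out, "mc_report")
  expect_true(rep$converged)
  expect_lte(rep$final_distances[1], 2.2)
  expect_lt(rep$max_bond_seen, p0$R0)
  bonds <- sqrt(rowSums(diff(out$positions)^2))
  expect_true(all(bonds < p0$R0))
})

test_that("mc_fold reports unsatisfied pairs when the budget is too small", {
  ch <- sarw_chain(40, seed = 3)
  rs <- restraint_set(rbind(c(1L, 40L)))
  err <- tryCatch(
    mc_fold(ch, rs, mc_config(max_sweeps = 1L, seed = 1)),
    error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "1 of 1 restraints unsatisfied")
  expect_match(conditionMessage(err), "worst distance")
})

test_that("kinetic temperature follows equipartition", {
  expect_identical(kinetic_temperature(matrix(0, 5, 3)), 0)
  v <- with_seed(99, matrix(rnorm(3e4), ncol = 3))  # Maxwell-Boltzmann, T = 1
  t1 <- kinetic_temperature(v)
  expect_equal(t1, 1, tolerance = 0.03)
  expect_equal(kinetic_temperature(2 * v), 4 * t1, tolerance = 1e-12)
})

test_that("zero-step dynamics leaves positions untouched", {
  ch <- sarw_chain(20, seed = 4)
  tr <- langevin_equilibrate(ch, NULL, sim_config(0L, seed = 1))
  expect_identical(tr$positions, ch$positions)
})

test_that("without thermostat the integrator conserves energy", {
  ch <- sarw_chain(50, seed = 7)
  tr <- langevin_equilibrate(
    ch, NULL,
    sim_config(1000L, damping = 0, timestep = 0.001, seed = 4,
               snapshot_stride = 10L))
  n <- length(tr$snapshots)
  etot <- vapply(seq_len(n), function(k)
    system_energy_forces(tr$snapshots[[k]], NULL, p0)$energy +
      1.5 * 50 * tr$temps[k], numeric(1))
  expect_lt((max(etot) - min(etot)) / abs(mean(etot)), 1e-3)
})

test_that("the thermostat holds the kinetic temperature near the target", {
  ch <- sarw_chain(50, seed = 7)
  tr <- langevin_equilibrate(ch, NULL, sim_config(20000L, seed = 3))
  burn <- seq_len(20)
  expect_equal(mean(tr$temps[-burn]), 1, tolerance = 0.05)
})

test_that("a single free bead diffuses like a Langevin particle", {
  # MSD slope 6 T / gamma per unit tau in the diffusive regime
  ch <- bead_chain(matrix(0, 1, 3))
  cfg <- sim_config(40000L, seed = 11, snapshot_stride = 100L)
  tr <- langevin_equilibrate(ch, NULL, cfg)
  xs <- t(vapply(tr$snapshots, function(s) s[1, ], numeric(3)))
  lag <- 10                       # snapshots = 10 tau
  dt_snap <- cfg$snapshot_stride * cfg$timestep
  disp2 <- rowSums((xs[-seq_len(lag), ] -
                      xs[seq_len(nrow(xs) - lag), ])^2)
  slope <- mean(disp2) / (lag * dt_snap)
  expect_gt(slope, 0.6 * 6)
  expect_lt(slope, 1.5 * 6)
})

test_that("fold_chromosome is deterministic and reports full satisfaction", {
  spec <- synthetic_spec(n_beads = 60L, compartment_block_length = 30L,
                         seed = 5L)
  ref <- make_reference_structure(spec)
  hic <- contacts_from_structure(ref$positions, 2.2)
  run <- function()
    suppressWarnings(fold_chromosome(
      hic, mc = mc_config(max_sweeps = 10000L, seed = 1),
      sim = sim_config(5000L), seed = 42L))
  a <- run()
  b <- run()
  expect_identical(a$positions, b$positions)
  expect_identical(a$seeds, b$seeds)
  expect_equal(a$report$fraction_satisfied_mc, 1.0)
  expect_lte(a$report$median_restrained_distance, 2.2 + 2)
  # chain stays connected through MC + minimization + dynamics
  bonds <- sqrt(rowSums(diff(a$positions)^2))
  expect_true(all(bonds < p0$R0))
})

test_that("a restraint-free fold leaves no restraint report entries", {
  hic <- hic_matrix(matrix(0, 30, 30))
  fs <- fold_chromosome(hic, sim = sim_config(2000L), seed = 9L)
  expect_equal(fs$report$n_restraints, 0L)
  bonds <- sqrt(rowSums(diff(fs$positions)^2))
  expect_true(all(bonds < p0$R0))
})
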