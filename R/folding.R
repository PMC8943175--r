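#' Set of harmonic Hi-C restraints
#'
#' Bead pairs `(i, j)` (1-based, `i + 1 < j`: adjacent beads are already
#' bonded) that carry the harmonic restraint \eqn{K(r-r_0)^2}.  A pair
#' counts as "connected" once its distance is at most
#' `activation_radius`.
#'
#' @param pairs Two-column matrix of bead index pairs (1-based).
#' @param K Restraint constant in \eqn{\epsilon/\sigma^2}.
#' @param r0 Rest length in \eqn{\sigma}.
#' @param activation_radius Connection distance in \eqn{\sigma}
#'   (default `r0`).
#' @return An object of class `restraint_set`.
#' @export
restraint_set <- function(pairs, K = 1, r0 = 2.2,
                          activation_radius = r0) {
  if (is.null(pairs) || length(pairs) == 0)
    pairs <- matrix(integer(), 0, 2)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must have two columns")
  storage.mode(pairs) <- "integer"
  if (nrow(pairs)) {
    swap <- pairs[, 1] > pairs[, 2]
    pairs[swap, ] <- pairs[swap, c(2, 1), drop = FALSE]
    if (any(pairs[, 1] < 1)) stop("bead indices are 1-based")
    if (any(pairs[, 2] - pairs[, 1] <= 1))
      stop("restraints must not join a bead to itself or its bonded ",
           "neighbor (need i + 1 < j)")
    if (anyDuplicated(pairs)) stop("duplicate restraint pairs")
  }
  colnames(pairs) <- c("i", "j")
  structure(list(pairs = pairs, K = K, r0 = r0,
                 activation_radius = activation_radius),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf(
    "Restraint set: %d pairs, K = %g e/s^2, r0 = %g s, activation %g s\n",
    nrow(x$pairs), x$K, x$r0, x$activation_radius))
  invisible(x)
}

#' Langevin dynamics configuration
#'
#' Reduced-unit settings for the Brownian-dynamics equilibration:
#' target temperature `T = 1`, damping \eqn{\gamma = 1\,\tau^{-1}} and
#' timestep \eqn{0.01\,\tau} by default, matching the published set-up.
#'
#' @param n_steps Number of integration steps.
#' @param temperature Reduced temperature (default 1).
#' @param damping Friction \eqn{\gamma} in \eqn{\tau^{-1}} (default 1);
#'   0 gives plain (NVE) velocity Verlet.
#' @param timestep \eqn{\Delta t} in \eqn{\tau} (default 0.01).
#' @param mass Bead mass (default 1).
#' @param seed Integer seed for thermostat noise and initial velocities.
#' @param snapshot_stride Steps between stored snapshots (default
#'   `max(1, n_steps %/% 100)`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_steps, temperature = 1, damping = 1,
                       timestep = 0.01, mass = 1, seed = 1L,
                       snapshot_stride = max(1L, n_steps %/% 100L)) {
  stopifnot(n_steps >= 0, temperature > 0, damping >= 0, timestep > 0,
            mass > 0, snapshot_stride >= 1)
  structure(list(n_steps = as.integer(n_steps), temperature = temperature,
                 damping = damping, timestep = timestep, mass = mass,
                 seed = as.integer(seed),
                 snapshot_stride = as.integer(snapshot_stride)),
            class = "sim_config")
}

#' Monte Carlo configuration
#'
#' Settings for the Metropolis restraint-satisfaction stage:
#' single-bead Gaussian displacement moves of scale `move_sigma`,
#' accepted on the full-system energy at `temperature`.  Restraints are
#' switched on in `ramp_stages` batches ordered by genomic separation
#' (smallest first), which avoids topological frustration when distant
#' pairs must be brought together; `ramp_stages = 1` activates all at
#' once.
#'
#' A restraint that has not yet connected is temporarily a stiffer,
#' shorter spring (`pull_stiffness * K`, rest length
#' `pull_factor * r0`), which guarantees its energy minimum lies below
#' the activation radius; on its first dip below activation it reverts
#' permanently to the standard \eqn{K(r-r_0)^2} harmonic.  The
#' satisfied end state is therefore governed by the published
#' potential alone.
#'
#' @param max_sweeps Maximum number of sweeps (one attempted move per
#'   bead each).
#' @param move_sigma Displacement scale in \eqn{\sigma} (default 0.5).
#' @param temperature Metropolis temperature (default 1).
#' @param ramp_stages Number of activation batches (default 1: all
#'   restraints active from the start, which converges fastest on
#'   compartmentalized problems).
#' @param pull_stiffness Stiffness multiplier for unconnected pairs
#'   (default 4).
#' @param pull_factor Rest-length factor for unconnected pairs
#'   (default 0.8).
#' @param wca_cap Energy cap in \eqn{\epsilon} on the nonbonded
#'   repulsion during MC (default 2): beads may occasionally pass
#'   through one another, which lets the chain escape topological
#'   traps while restraints are being connected.  `Inf` restores the
#'   full repulsion.  Residual overlaps are removed by the energy
#'   minimization that [fold_chromosome()] runs before the dynamics.
#' @param seed Integer seed.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(max_sweeps = 5000L, move_sigma = 0.5,
                      temperature = 1, ramp_stages = 1L,
                      pull_stiffness = 4, pull_factor = 0.8,
                      wca_cap = 2, seed = 1L) {
  stopifnot(max_sweeps >= 1, move_sigma > 0, temperature > 0,
            ramp_stages >= 1, pull_stiffness > 0, pull_factor > 0,
            pull_factor <= 1, wca_cap > 0)
  structure(list(max_sweeps = as.integer(max_sweeps),
                 move_sigma = move_sigma, temperature = temperature,
                 ramp_stages = as.integer(ramp_stages),
                 pull_stiffness = pull_stiffness,
                 pull_factor = pull_factor, wca_cap = wca_cap,
                 seed = as.integer(seed)),
            class = "mc_config")
}

#' Turn a Hi-C contact matrix into a restraint set
#'
#' Selects which contacts become harmonic bonds.  The diagonal and
#' adjacent bins (`|i - j| <= 1`) are always excluded: adjacency is
#' handled by the chain bonds.  Rules:
#' \describe{
#'   \item{`all_nonzero`}{every remaining nonzero contact (the default;
#'     the contacts are used directly).}
#'   \item{`top_quantile`}{the top fraction `q` of remaining nonzero
#'     contacts by count; ties at the boundary broken by (count
#'     descending, i ascending, j ascending).}
#'   \item{`count_threshold`}{contacts with count `>= threshold`.}
#' }
#'
#' @param hic A [hic_matrix] object.
#' @param rule One of `"all_nonzero"`, `"top_quantile"`,
#'   `"count_threshold"`.
#' @param q Fraction kept under `top_quantile` (default 0.5).
#' @param threshold Minimum count under `count_threshold` (default 1).
#' @param K,r0,activation_radius Passed to [restraint_set()].
#' @return A [restraint_set()].
#' @export
select_restraints <- function(hic,
                              rule = c("all_nonzero", "top_quantile",
                                       "count_threshold"),
                              q = 0.5, threshold = 1, K = 1, r0 = 2.2,
                              activation_radius = r0) {
  rule <- match.arg(rule)
  stopifnot(inherits(hic, "hic_matrix"))
  m <- hic$counts
  n <- nrow(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  keep <- (idx[, 2] - idx[, 1]) > 1 & m[idx] != 0
  idx <- idx[keep, , drop = FALSE]
  cnt <- m[idx]
  if (rule == "top_quantile") {
    stopifnot(q > 0, q <= 1)
    ord <- order(-cnt, idx[, 1], idx[, 2])
    n_keep <- ceiling(q * length(cnt))
    idx <- idx[ord[seq_len(n_keep)], , drop = FALSE]
  } else if (rule == "count_threshold") {
    idx <- idx[cnt >= threshold, , drop = FALSE]
  }
  if (nrow(idx)) idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  restraint_set(unname(idx), K = K, r0 = r0,
                activation_radius = activation_radius)
}

sorted_restraint_matrix <- function(restraints, n_beads) {
  rmat <- as_restraint_matrix(restraints, n_beads)
  if (nrow(rmat)) {
    sep <- rmat[, 2] - rmat[, 1]
    rmat <- rmat[order(sep, rmat[, 1]), , drop = FALSE]
  }
  rmat
}

#' Satisfy Hi-C restraints by Metropolis Monte Carlo
#'
#' Drives every restrained bead pair to within the activation radius
#' using single-bead Gaussian displacement moves accepted on the
#' full-system energy (bonds, WCA repulsion, active restraints).  A
#' pair is satisfied - stickily - the first time its distance dips to
#' `activation_radius` or below; once all pairs have connected the
#' stage ends and the harmonic bonds are preserved for the dynamics.
#' Chain bonds can never break: moves that would stretch a bond to
#' \eqn{R_0} have infinite energy and are rejected.
#'
#' @param chain A [bead_chain].
#' @param restraints A [restraint_set()].
#' @param cfg An [mc_config()].
#' @param p A [force_field_params()] object; its `K`/`r0` are
#'   overridden by the restraint set's.
#' @return The folded [bead_chain], with attribute `"mc_report"`
#'   holding sweeps used, acceptance rate, per-pair satisfaction and
#'   final distances.
#' @export
mc_fold <- function(chain, restraints, cfg = mc_config(),
                    p = force_field_params()) {
  stopifnot(inherits(chain, "bead_chain"),
            inherits(restraints, "restraint_set"),
            inherits(cfg, "mc_config"))
  p$K <- restraints$K
  p$r0 <- restraints$r0
  rmat <- sorted_restraint_matrix(restraints, chain$n_beads)
  if (nrow(rmat) == 0) {
    attr(chain, "mc_report") <- list(sweeps = 0L, converged = TRUE,
                                     n_restraints = 0L,
                                     acceptance_rate = NA_real_)
    return(chain)
  }
  res <- with_seed(cfg$seed, cpp_mc_fold(
    chain$positions, rmat, unclass(p), cfg$move_sigma, cfg$temperature,
    cfg$max_sweeps, restraints$activation_radius, cfg$ramp_stages,
    cfg$pull_stiffness, cfg$pull_factor, cfg$wca_cap))
  if (!res$converged)
    stop(sprintf(
      "mc_fold: %d of %d restraints unsatisfied after %d sweeps (worst distance %.3g sigma)",
      res$n_unsatisfied, nrow(rmat), res$sweeps, res$worst_distance))
  out <- bead_chain(res$positions, chain$bond_length,
                    chain$excluded_radius)
  attr(out, "mc_report") <- list(
    sweeps = res$sweeps, converged = res$converged,
    n_restraints = nrow(rmat), satisfied = res$satisfied,
    final_distances = res$final_distances, pairs = rmat + 1L,
    acceptance_rate = res$acceptance_rate,
    max_bond_seen = res$max_bond_seen)
  out
}

#' Relax a configuration by capped-step energy minimization
#'
#' Steepest descent on the full system energy (bonds, uncapped WCA
#' repulsion, harmonic restraints) with per-step displacements bounded
#' by `max_disp`, so that hard overlaps - e.g. left over by an MC
#' stage run with a capped repulsion - are pushed apart gently instead
#' of launching the dynamics.
#'
#' @param chain A [bead_chain] or `N x 3` coordinate matrix.
#' @param restraints A [restraint_set()] or `NULL`.
#' @param p A [force_field_params()] object.
#' @param max_steps Step budget (default 500).
#' @param max_disp Per-step displacement cap in \eqn{\sigma}
#'   (default 0.05).
#' @param force_tol Stop when the largest force component falls below
#'   this (default 10 \eqn{\epsilon/\sigma}).
#' @return A [bead_chain] (or matrix, matching the input) with relaxed
#'   coordinates; attribute `"minimize_report"` holds steps used and
#'   final energy.
#' @export
minimize_energy <- function(chain, restraints = NULL,
                            p = force_field_params(), max_steps = 500L,
                            max_disp = 0.05, force_tol = 10) {
  pos <- as_positions(chain)
  if (!is.null(restraints) && nrow(restraints$pairs)) {
    p$K <- restraints$K
    p$r0 <- restraints$r0
  }
  rmat <- as_restraint_matrix(restraints, nrow(pos))
  res <- cpp_minimize(pos, rmat, unclass(p), as.integer(max_steps),
                      max_disp, force_tol)
  out <- if (inherits(chain, "bead_chain"))
    bead_chain(res$positions, chain$bond_length, chain$excluded_radius)
  else res$positions
  attr(out, "minimize_report") <- list(steps = res$steps,
                                       energy = res$energy)
  out
}

#' Kinetic temperature of a velocity set
#'
#' \eqn{T = m \sum_i |v_i|^2 / (3N)} in reduced units.
#'
#' @param velocities `N x 3` matrix in \eqn{\sigma/\tau}.
#' @param mass Bead mass (default 1).
#' @return Reduced temperature.
#' @export
kinetic_temperature <- function(velocities, mass = 1) {
  v <- as.matrix(velocities)
  mass * sum(v^2) / (3 * nrow(v))
}

#' Equilibrate a restrained chain by Langevin dynamics
#'
#' Brownian-dynamics equilibration with implicit solvent: velocity
#' Verlet integration with an exact Ornstein-Uhlenbeck velocity update
#' (BAOAB splitting) implementing the Langevin thermostat at
#' `cfg$temperature` with friction `cfg$damping`.  Initial velocities
#' are Maxwell-Boltzmann at the target temperature.  With
#' `damping = 0` the thermostat is off and the integrator is plain
#' velocity Verlet.
#'
#' @param chain A [bead_chain] (restraints should already be satisfied;
#'   a warning is issued otherwise).
#' @param restraints A [restraint_set()] or `NULL`.
#' @param cfg A [sim_config()].
#' @param p A [force_field_params()] object.
#' @return A list of class `trajectory`: `positions` (final),
#'   `velocities` (final), `snapshots` (list of `N x 3` matrices every
#'   `snapshot_stride` steps), `temps` (kinetic temperature at each
#'   snapshot) and the configuration used.
#' @export
langevin_equilibrate <- function(chain, restraints = NULL,
                                 cfg = sim_config(1000L),
                                 p = force_field_params()) {
  stopifnot(inherits(chain, "bead_chain"), inherits(cfg, "sim_config"))
  if (cfg$timestep > 0.01 + 1e-12)
    warning("timestep exceeds 0.01 tau; integration may be unstable")
  if (!is.null(restraints) && nrow(restraints$pairs)) {
    p$K <- restraints$K
    p$r0 <- restraints$r0
    d <- pair_distances(chain$positions, restraints$pairs)
    if (any(d > restraints$activation_radius * 1.5))
      warning(sprintf(
        "%d restrained pairs start far beyond the activation radius",
        sum(d > restraints$activation_radius * 1.5)))
  }
  rmat <- as_restraint_matrix(restraints, chain$n_beads)
  if (cfg$n_steps == 0L) {
    return(structure(list(
      positions = chain$positions,
      velocities = matrix(0, chain$n_beads, 3),
      snapshots = list(), temps = numeric(0), config = cfg),
      class = "trajectory"))
  }
  res <- with_seed(cfg$seed, {
    v0 <- matrix(
      rnorm(3 * chain$n_beads, sd = sqrt(cfg$temperature / cfg$mass)),
      ncol = 3)
    cpp_langevin(chain$positions, v0, rmat, unclass(p), cfg$n_steps,
                 cfg$timestep, cfg$damping, cfg$temperature, cfg$mass,
                 cfg$snapshot_stride)
  })
  structure(list(positions = res$positions, velocities = res$velocities,
                 snapshots = res$snapshots, temps = res$temps,
                 final_energy = res$final_energy,
                 final_kinetic = res$final_kinetic, config = cfg),
            class = "trajectory")
}

pair_distances <- function(pos, pairs) {
  if (nrow(pairs) == 0) return(numeric(0))
  d <- pos[pairs[, 1], , drop = FALSE] - pos[pairs[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Folded chromosome structure
#'
#' Final coordinates plus the genomic binning, the restraint set and a
#' satisfaction report.
#' @name folded_structure
NULL

#' Fold a chromosome from a Hi-C contact matrix
#'
#' The full modeling sequence: self-avoiding-random-walk initial chain
#' (one bead per Hi-C bin), restraint selection, Monte Carlo restraint
#' satisfaction, then Langevin (Brownian-dynamics) equilibration with
#' the harmonic bonds preserved.
#'
#' @param hic A [hic_matrix].
#' @param p A [force_field_params()] object.
#' @param mc An [mc_config()].
#' @param sim A [sim_config()].
#' @param seed Master seed; per-stage seeds (SARW, MC, dynamics) are
#'   derived from it deterministically and recorded in the result.
#' @param rule,q,threshold Restraint selection, see
#'   [select_restraints()].
#' @return An object of class `folded_structure` with elements
#'   `positions`, `chrom`, `bin_size`, `bins`, `restraints`, `report`
#'   (sticky satisfaction fraction after MC - 1.0 by construction,
#'   since [mc_fold()] errors otherwise - plus final and median
#'   restrained distances after dynamics) and `seeds`.
#' @export
fold_chromosome <- function(hic, p = force_field_params(),
                            mc = mc_config(), sim = sim_config(20000L),
                            seed = 1L, rule = "all_nonzero", q = 0.5,
                            threshold = 1) {
  stopifnot(inherits(hic, "hic_matrix"))
  n <- nrow(hic$counts)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 3L))
  names(seeds) <- c("sarw", "mc", "dynamics")
  restraints <- select_restraints(hic, rule = rule, q = q,
                                  threshold = threshold, K = p$K,
                                  r0 = p$r0)
  chain <- sarw_chain(n, seed = seeds[["sarw"]])
  mc$seed <- seeds[["mc"]]
  folded <- mc_fold(chain, restraints, mc, p)
  mc_report <- attr(folded, "mc_report")
  folded <- minimize_energy(folded, restraints, p)
  sim$seed <- seeds[["dynamics"]]
  traj <- langevin_equilibrate(folded, restraints, sim, p)
  final_d <- pair_distances(traj$positions, restraints$pairs)
  report <- list(
    n_restraints = nrow(restraints$pairs),
    fraction_satisfied_mc = if (nrow(restraints$pairs))
      mean(mc_report$satisfied) else NA_real_,
    mc_sweeps = mc_report$sweeps,
    median_restrained_distance = if (length(final_d)) median(final_d)
      else NA_real_,
    mean_kinetic_temperature = if (length(traj$temps)) mean(traj$temps)
      else NA_real_)
  structure(list(positions = traj$positions, chrom = hic$chrom,
                 bin_size = hic$bin_size, bins = hic$bins,
                 restraints = restraints, report = report,
                 trajectory = traj, seeds = seeds),
            class = "folded_structure")
}

#' @export
print.folded_structure <- function(x, ...) {
  cat(sprintf("Folded structure: %d beads on %s (%g bp bins)\n",
              nrow(x$positions), x$chrom, x$bin_size))
  cat(sprintf(
    "  %d restraints; MC satisfaction %.3f in %d sweeps; median restrained distance %.3g sigma\n",
    x$report$n_restraints, x$report$fraction_satisfied_mc,
    x$report$mc_sweeps, x$report$median_restrained_distance))
  invisible(x)
}
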