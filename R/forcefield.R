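#' Force-field parameters in reduced units
#'
#' Bundle of all potential constants for the bead-spring chromosome
#' model: the FENE bond (spring constant \eqn{\kappa}, maximum extension
#' \eqn{R_0}) combined with a repulsive-core (WCA) Lennard-Jones term of
#' strength \eqn{\epsilon^*} between bonded beads, a purely repulsive
#' WCA interaction of strength \eqn{\epsilon} between nonbonded beads,
#' and a harmonic restraint \eqn{K(r - r_0)^2} between Hi-C contact
#' pairs.  Defaults are the published parameter set
#' (\eqn{\kappa = 30\,\epsilon^*/\sigma^2}, \eqn{R_0 = 20\,\sigma},
#' \eqn{\epsilon = \epsilon^* = 1}, \eqn{K = 1\,\epsilon/\sigma^2},
#' \eqn{r_0 = 2.2\,\sigma}), which place the equilibrium bond length at
#' \eqn{0.99\,\sigma}.
#'
#' @param sigma Length unit \eqn{\sigma} (default 1).
#' @param epsilon Nonbonded WCA strength \eqn{\epsilon} (default 1).
#' @param epsilon_star Bonded WCA strength \eqn{\epsilon^*} (default 1).
#' @param kappa FENE spring constant in \eqn{\epsilon^*/\sigma^2}
#'   (default 30).
#' @param R0 Maximum bond extension in \eqn{\sigma} (default 20).
#' @param K Harmonic restraint constant in \eqn{\epsilon/\sigma^2}
#'   (default 1).
#' @param r0 Restraint rest length in \eqn{\sigma} (default 2.2).
#' @return An object of class `force_field_params`.  The WCA cutoff
#'   \eqn{2^{1/6}\sigma} is derived, not settable.
#' @examples
#' p <- force_field_params()
#' equilibrium_bond_length(p)
#' @export
force_field_params <- function(sigma = 1, epsilon = 1, epsilon_star = 1,
                               kappa = 30, R0 = 20, K = 1, r0 = 2.2) {
  vals <- c(sigma = sigma, epsilon = epsilon, epsilon_star = epsilon_star,
            kappa = kappa, R0 = R0, K = K, r0 = r0)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  if (any(vals <= 0))
    stop("all force-field parameters must be strictly positive: ",
         paste(names(vals)[vals <= 0], collapse = ", "))
  lj_cutoff <- 2^(1 / 6) * sigma
  if (R0 <= lj_cutoff)
    stop("R0 (", R0, ") must exceed the WCA cutoff 2^(1/6)*sigma (",
         signif(lj_cutoff, 6), ")")
  structure(
    list(sigma = sigma, epsilon = epsilon, epsilon_star = epsilon_star,
         kappa = kappa, R0 = R0, K = K, r0 = r0, lj_cutoff = lj_cutoff),
    class = "force_field_params"
  )
}

#' @export
print.force_field_params <- function(x, ...) {
  cat("Force field (reduced units):\n")
  cat(sprintf("  FENE: kappa = %g e*/s^2, R0 = %g s; bonded WCA e* = %g\n",
              x$kappa, x$R0, x$epsilon_star))
  cat(sprintf("  nonbonded WCA: epsilon = %g, cutoff = %.6g s\n",
              x$epsilon, x$lj_cutoff))
  cat(sprintf("  restraint: K = %g e/s^2, r0 = %g s\n", x$K, x$r0))
  invisible(x)
}

check_bond_domain <- function(r, p, what = "bond") {
  bad <- which(!(r > 0 & r < p$R0))
  if (length(bad))
    stop(sprintf(
      "%s separation out of the FENE domain (0, R0 = %g): %s at r = %s",
      what, p$R0, paste(what, bad[1]), signif(r[bad[1]], 6)))
  invisible(TRUE)
}

#' Bonded (FENE + WCA) pair energy
#'
#' Energy of a bonded bead pair at separation `r`:
#' \eqn{-\tfrac{1}{2}\kappa R_0^2 \ln[1-(r/R_0)^2]} plus the
#' quarter-shifted repulsive Lennard-Jones core
#' \eqn{4\epsilon^*[(\sigma/r)^{12}-(\sigma/r)^6+\tfrac14]} for
#' \eqn{r \le 2^{1/6}\sigma} (zero beyond).
#'
#' @param r Bead separation(s) in \eqn{\sigma}, inside \eqn{(0, R_0)}.
#' @param p A [force_field_params()] object.
#' @return Energy in \eqn{\epsilon}, same length as `r`.
#' @export
bonded_energy <- function(r, p = force_field_params()) {
  check_bond_domain(r, p)
  as.numeric(cpp_bonded_energy(as.numeric(r), unclass(p)))
}

#' Bonded radial force
#'
#' Signed radial force \eqn{F(r) = -dU_{bonded}/dr}; negative values
#' pull the pair together.  Zero at the equilibrium bond length.
#'
#' @inheritParams bonded_energy
#' @return Force in \eqn{\epsilon/\sigma}.
#' @export
bonded_force <- function(r, p = force_field_params()) {
  check_bond_domain(r, p)
  as.numeric(cpp_bonded_force(as.numeric(r), unclass(p)))
}

#' Nonbonded (WCA) pair energy and force
#'
#' Purely repulsive Lennard-Jones interaction
#' \eqn{4\epsilon[(\sigma/r)^{12}-(\sigma/r)^6+\tfrac14]} for
#' \eqn{r \le 2^{1/6}\sigma} and exactly zero beyond; both energy and
#' force are continuous at the cutoff.
#'
#' @param r Separation(s) in \eqn{\sigma}, positive.
#' @param p A [force_field_params()] object.
#' @return Energy in \eqn{\epsilon} (or force in \eqn{\epsilon/\sigma}).
#' @export
nonbonded_energy <- function(r, p = force_field_params()) {
  if (any(r <= 0)) stop("nonbonded separation must be positive")
  as.numeric(cpp_nonbonded_energy(as.numeric(r), unclass(p)))
}

#' @rdname nonbonded_energy
#' @export
nonbonded_force <- function(r, p = force_field_params()) {
  if (any(r <= 0)) stop("nonbonded separation must be positive")
  as.numeric(cpp_nonbonded_force(as.numeric(r), unclass(p)))
}

#' Harmonic Hi-C restraint energy
#'
#' \eqn{U(r) = K (r - r_0)^2}, symmetric about the rest length `r0`.
#'
#' @param r Separation(s) in \eqn{\sigma}, nonnegative.
#' @param p A [force_field_params()] object.
#' @return Energy in \eqn{\epsilon}.
#' @export
restraint_energy <- function(r, p = force_field_params()) {
  if (any(r < 0)) stop("restraint separation must be nonnegative")
  as.numeric(cpp_restraint_energy(as.numeric(r), unclass(p)))
}

#' Equilibrium bond length of the FENE + WCA bond
#'
#' Locates the unique minimizer of [bonded_energy()] on \eqn{(0, R_0)}
#' by bracketed root-finding on [bonded_force()] within
#' \eqn{(0.5\sigma, 2^{1/6}\sigma)}.  With the default parameters the
#' answer is \eqn{0.99\,\sigma} to two decimals.
#'
#' @param p A [force_field_params()] object.
#' @param tol Root tolerance in \eqn{\sigma} (default `1e-8`).
#' @return The equilibrium bond length in \eqn{\sigma}.
#' @export
equilibrium_bond_length <- function(p = force_field_params(), tol = 1e-8) {
  lo <- 0.5 * p$sigma
  hi <- min(p$lj_cutoff, p$R0 * (1 - 1e-9))
  f_lo <- bonded_force(lo, p)
  f_hi <- bonded_force(hi, p)
  if (!(f_lo > 0 && f_hi < 0))
    stop("bonded force has no sign change in (0.5 sigma, cutoff); ",
         "no interior energy minimum (is the WCA core disabled?)")
  uniroot(function(r) bonded_force(r, p), c(lo, hi), tol = tol)$root
}

as_restraint_matrix <- function(restraints, n_beads) {
  if (is.null(restraints)) return(matrix(integer(), 0, 2))
  pairs <- if (inherits(restraints, "restraint_set")) restraints$pairs
           else restraints
  if (length(pairs) == 0 || nrow(pairs) == 0) return(matrix(integer(), 0, 2))
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  if (any(pairs < 1L) || any(pairs > n_beads))
    stop("restraint indices outside 1..", n_beads)
  pairs - 1L
}

#' Total system energy and per-bead forces
#'
#' Sums the three potentials over (i) consecutive-bead FENE+WCA bonds,
#' (ii) nonbonded WCA pairs within the cutoff, excluding directly bonded
#' neighbors whose repulsion is already in the bonded term, and (iii)
#' harmonic restraint pairs (which also feel the nonbonded repulsion if
#' within the cutoff).  Forces are analytic gradients; they obey
#' Newton's third law pairwise and sum to the zero vector.
#'
#' @param positions An `N x 3` coordinate matrix in \eqn{\sigma}, or a
#'   [bead_chain].
#' @param restraints A [restraint_set()] or a two-column matrix of
#'   1-based bead index pairs; `NULL` for none.
#' @param p A [force_field_params()] object.
#' @return A list with `energy` (scalar, \eqn{\epsilon}) and `forces`
#'   (`N x 3`, \eqn{\epsilon/\sigma}).
#' @export
system_energy_forces <- function(positions, restraints = NULL,
                                 p = force_field_params()) {
  pos <- as_positions(positions)
  rmat <- as_restraint_matrix(restraints, nrow(pos))
  res <- cpp_system_energy_forces(pos, rmat, unclass(p))
  if (!is.finite(res$energy) && res$bad_bond > 0)
    stop(sprintf(
      "bond %d (beads %d-%d) is at or beyond the maximum extension R0 = %g",
      res$bad_bond, res$bad_bond, res$bad_bond + 1L, p$R0))
  list(energy = res$energy, forces = res$forces)
}

as_positions <- function(x) {
  if (inherits(x, "bead_chain")) x <- x$positions
  if (inherits(x, "folded_structure")) x <- x$positions
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("positions must be an N x 3 matrix")
  storage.mode(x) <- "double"
  x
}
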