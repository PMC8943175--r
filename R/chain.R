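#' Bead chain container
#'
#' A linear polymer of `N` beads: coordinates plus the step geometry
#' used to build it.  Consecutive beads are `bond_length` apart and no
#' two beads approach closer than `excluded_radius`.
#'
#' @param positions `N x 3` coordinate matrix in \eqn{\sigma}.
#' @param bond_length Step length in \eqn{\sigma}.
#' @param excluded_radius Minimum pairwise distance in \eqn{\sigma}.
#' @return An object of class `bead_chain`.
#' @export
bead_chain <- function(positions, bond_length = 0.99,
                       excluded_radius = 0.9) {
  pos <- as_positions(positions)
  if (nrow(pos) < 1) stop("a chain needs at least one bead")
  structure(
    list(positions = pos, n_beads = nrow(pos), bond_length = bond_length,
         excluded_radius = excluded_radius),
    class = "bead_chain"
  )
}

#' @export
print.bead_chain <- function(x, ...) {
  cat(sprintf(
    "Bead chain: %d beads, bond length %g sigma, excluded radius %g sigma\n",
    x$n_beads, x$bond_length, x$excluded_radius))
  invisible(x)
}

#' Self-avoiding random walk chain
#'
#' Generates the initial linear polymer conformation as a self-avoiding
#' random walk: the first bead sits at the origin and each subsequent
#' bead steps `bond_length` in a uniformly random direction, rejected
#' and retried if it lands within `excluded_radius` of any earlier bead.
#' When a bead cannot be placed after `tries_per_bead` attempts the walk
#' retracts one bead and regrows (bounded by `max_backtrack`).
#'
#' @param n_beads Number of beads, at least 1.
#' @param bond_length Step length in \eqn{\sigma} (default 0.99, the
#'   equilibrium FENE+WCA bond length).
#' @param excluded_radius Self-avoidance radius in \eqn{\sigma}
#'   (default 0.9); must not exceed `bond_length`.
#' @param seed Integer seed; identical seeds give identical chains.
#' @param max_backtrack Total backtrack budget (default `50 * n_beads`).
#' @param tries_per_bead Direction attempts per bead before backtracking
#'   (default 60).
#' @return A [bead_chain] satisfying the self-avoidance invariants.
#' @examples
#' ch <- sarw_chain(100, seed = 1)
#' min(dist(ch$positions)) >= 0.9
#' @export
sarw_chain <- function(n_beads, bond_length = 0.99, excluded_radius = 0.9,
                       seed = 1L, max_backtrack = 50L * n_beads,
                       tries_per_bead = 60L) {
  stopifnot(n_beads >= 1)
  if (excluded_radius > bond_length)
    stop("excluded_radius must not exceed bond_length")
  pos <- with_seed(seed, cpp_sarw(
    as.integer(n_beads), bond_length, excluded_radius,
    start = c(0, 0, 0), confined = FALSE, center = c(0, 0, 0), radius = 0,
    obstacles = matrix(numeric(), 0, 3),
    max_backtrack = as.integer(max_backtrack),
    tries_per_bead = as.integer(tries_per_bead)))
  bead_chain(pos, bond_length = bond_length,
             excluded_radius = excluded_radius)
}
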