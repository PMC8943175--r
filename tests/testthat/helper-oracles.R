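# Independent oracles used across the test files.

# closed-form potentials, written out independently of the package
oracle_fene <- function(r, kappa = 30, R0 = 20) {
  -0.5 * kappa * R0^2 * log(1 - (r / R0)^2)
}
oracle_wca <- function(r, eps = 1, sigma = 1) {
  ifelse(r <= 2^(1 / 6) * sigma,
         4 * eps * ((sigma / r)^12 - (sigma / r)^6 + 0.25), 0)
}
oracle_bonded <- function(r) oracle_fene(r) + oracle_wca(r)

# central finite difference of a scalar function
fd_derivative <- function(f, x, h = 1e-5) (f(x + h) - f(x - h)) / (2 * h)

# numeric gradient of the total system energy wrt every coordinate
fd_forces <- function(pos, restraints = NULL, p = force_field_params(),
                      h = 1e-5) {
  g <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) {
    for (d in 1:3) {
      up <- pos; up[i, d] <- up[i, d] + h
      dn <- pos; dn[i, d] <- dn[i, d] - h
      g[i, d] <- -(system_energy_forces(up, restraints, p)$energy -
                   system_energy_forces(dn, restraints, p)$energy) / (2 * h)
    }
  }
  g
}

# quadratic brute-force co-occupancy scan (0-based half-open intervals)
brute_cooccupancy_fraction <- function(a_df, b_df, max_gap = 0) {
  if (!nrow(a_df)) return(NA_real_)
  hit <- vapply(seq_len(nrow(a_df)), function(i) {
    any(b_df$chrom == a_df$chrom[i] &
          b_df$start < a_df$end[i] + max_gap &
          a_df$start[i] < b_df$end + max_gap)
  }, logical(1))
  mean(hit)
}

# small random bead configuration with valid bonds and no hard overlap
random_config <- function(n, seed) {
  ch <- sarw_chain(n, seed = seed)
  jitter <- with_seed(seed + 1000L,
                      matrix(rnorm(3 * n, sd = 0.05), ncol = 3))
  ch$positions + jitter
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

random_peaks <- function(n, chrom = "chrS", span = 1e5, max_w = 2000,
                         seed = 1) {
  with_seed(seed, {
    s <- sort(sample.int(span, n))
    w <- sample.int(max_w, n)
    peak_set(rep(chrom, n), s, s + w, source = "random")
  })
}
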