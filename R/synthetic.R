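#' Specification for synthetic test data
#'
#' Parameters of the generated reference chromosome: beads are assigned
#' to `n_compartments` in alternating blocks of
#' `compartment_block_length` beads, each compartment's beads are
#' packed into a compact self-avoiding globule, and peak tracks are
#' emitted per bin with probability `enrichment_in` inside a mark's
#' home compartment and `enrichment_out` elsewhere.  This emulates the
#' statistical structure of a chromosome with transcriptionally
#' distinct spatial compartments whose marks segregate in 3D; it makes
#' no attempt at realistic Hi-C noise (distance decay, coverage bias)
#' or diploid structure.
#'
#' @param n_beads Total bead count.
#' @param n_compartments Number of spatial compartments (default 2).
#' @param compartment_block_length Beads per contiguous block
#'   (default 50); a shorter final block is allowed.
#' @param contact_radius Distance in \eqn{\sigma} below which a bead
#'   pair counts as a Hi-C contact (default 2.2, the restraint rest
#'   length).
#' @param enrichment_in Per-bin peak probability in the home
#'   compartment (default 0.8).
#' @param enrichment_out Per-bin peak probability elsewhere
#'   (default 0.1).
#' @param bin_size Genomic bin width in bp (default 5000).
#' @param chrom Fictitious chromosome name (default `"chrS"`).
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_beads = 200L, n_compartments = 2L,
                           compartment_block_length = 50L,
                           contact_radius = 2.2, enrichment_in = 0.8,
                           enrichment_out = 0.1, bin_size = 5000L,
                           chrom = "chrS", seed = 1L) {
  stopifnot(n_beads >= 1, n_compartments >= 1,
            compartment_block_length >= 1, contact_radius > 0,
            enrichment_in >= 0, enrichment_in <= 1,
            enrichment_out >= 0, enrichment_out <= 1)
  structure(list(n_beads = as.integer(n_beads),
                 n_compartments = as.integer(n_compartments),
                 compartment_block_length =
                   as.integer(compartment_block_length),
                 contact_radius = contact_radius,
                 enrichment_in = enrichment_in,
                 enrichment_out = enrichment_out,
                 bin_size = as.integer(bin_size), chrom = chrom,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

compartment_labels <- function(spec) {
  blocks <- ceiling(spec$n_beads / spec$compartment_block_length)
  lab <- rep(rep_len(seq_len(spec$n_compartments), blocks),
             each = spec$compartment_block_length)
  lab[seq_len(spec$n_beads)]
}

#' Generate a reference compartmentalized structure
#'
#' Builds a known ground-truth 3D structure: beads are assigned to
#' compartments in alternating blocks, each compartment's beads grow as
#' a compact self-avoiding walk confined to a sphere (globule), and the
#' globule centers are placed on a line separated by four globule
#' radii.  Each block's first bead starts on its globule surface at the
#' point nearest the previous bead, so inter-block linkers stay well
#' below the maximum bond extension \eqn{R_0 = 20\,\sigma} (an error is
#' raised if the geometry cannot honor that bound).
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `positions` (`N x 3`), integer `compartment`
#'   per bead, `centers` and `globule_radius`.
#' @export
make_reference_structure <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  comp <- compartment_labels(spec)
  n_per <- tabulate(comp, nbins = spec$n_compartments)
  bond <- 0.99
  excl <- 0.9
  # globule radius ~ dilute packing: volume per bead ~ 4 sigma^3
  radius <- max((3 * max(n_per) * 4 / (4 * pi))^(1 / 3), 2 * bond)
  sep <- 4 * radius
  # block-start beads sit on the facing surface (0.98 radius from the
  # center), so the worst-case linker is the previous bead on the far
  # side of its own sphere minus that offset
  max_linker <- sep + radius - 0.98 * radius
  if (max_linker >= 20)
    stop("globule geometry infeasible: worst-case linker ",
         signif(max_linker, 4), " sigma would exceed R0 = 20 sigma; ",
         "reduce the compartment size")
  centers <- cbind((seq_len(spec$n_compartments) - 1) * sep, 0, 0)
  pos <- matrix(NA_real_, spec$n_beads, 3)
  with_seed(spec$seed, {
    b <- 1L
    while (b <= spec$n_beads) {
      blk_end <- min(b + spec$compartment_block_length - 1L, spec$n_beads)
      cc <- comp[b]
      ctr <- centers[cc, ]
      start <- if (b == 1L) {
        ctr
      } else {
        prev <- pos[b - 1L, ]
        dir <- prev - ctr
        nd <- sqrt(sum(dir^2))
        if (nd < 1e-9) dir <- c(1, 0, 0) else dir <- dir / nd
        ctr + dir * radius * 0.98
      }
      placed <- pos[!is.na(pos[, 1]) & comp == cc, , drop = FALSE]
      pos[b:blk_end, ] <- cpp_sarw(
        blk_end - b + 1L, bond, excl, start = start, confined = TRUE,
        center = ctr, radius = radius, obstacles = placed,
        max_backtrack = 200L * (blk_end - b + 1L), tries_per_bead = 120L)
      b <- blk_end + 1L
    }
  })
  list(positions = pos, compartment = comp, centers = centers,
       globule_radius = radius)
}

#' Contact matrix from a known structure
#'
#' The inverse of the folding problem, for recovery benchmarks:
#' `counts[i, j] = 1` when beads `i` and `j` lie within
#' `contact_radius` (zero diagonal, symmetric).  With
#' `kind = "power_law"` the count decays as the inverse distance,
#' `1/d`, instead of a hard threshold.
#'
#' @param positions `N x 3` coordinates (or a structure from
#'   [make_reference_structure()]).
#' @param contact_radius Threshold in \eqn{\sigma}.
#' @param kind `"binary"` (default) or `"power_law"`.
#' @param chrom,bin_size Metadata for the [hic_matrix].
#' @return A [hic_matrix].
#' @export
contacts_from_structure <- function(positions, contact_radius = 2.2,
                                    kind = c("binary", "power_law"),
                                    chrom = "chrS", bin_size = 5000L) {
  kind <- match.arg(kind)
  stopifnot(contact_radius > 0)
  if (is.list(positions) && !is.null(positions$positions))
    positions <- positions$positions
  pos <- as_positions(positions)
  d <- as.matrix(dist(pos))
  m <- if (kind == "binary") (d <= contact_radius) * 1
       else ifelse(d <= contact_radius & d > 0, 1 / d, 0)
  diag(m) <- 0
  hic_matrix(m, chrom = chrom, bin_size = bin_size)
}

#' Generate mark tracks tied to compartments
#'
#' Emits three synthetic ChIP-seq peak tracks at one peak per genomic
#' bin: a `factor` and an `active_mark` homed in compartment 1, and a
#' `repressive_mark` homed in compartment 2 (or in compartment 1's
#' complement when there is a single compartment).  Inside a mark's
#' home compartment a bin carries a peak with probability
#' `enrichment_in`, elsewhere with `enrichment_out`.
#'
#' @param compartment Integer compartment label per bead.
#' @param spec A [synthetic_spec()] (probabilities, bin size, seed).
#' @return Named list of three [peak_set()] objects: `factor`,
#'   `active_mark`, `repressive_mark`.
#' @export
make_marked_tracks <- function(compartment, spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- length(compartment)
  homes <- list(factor = 1L, active_mark = 1L,
                repressive_mark = if (spec$n_compartments >= 2) 2L else NA)
  with_seed(spec$seed, {
    out <- lapply(names(homes), function(nm) {
      home <- homes[[nm]]
      in_home <- if (is.na(home)) !(compartment == 1L)
                 else compartment == home
      pr <- ifelse(in_home, spec$enrichment_in, spec$enrichment_out)
      hit <- runif(n) < pr
      if (!any(hit)) {
        return(peak_set(character(0), numeric(0), numeric(0),
                        source = nm))
      }
      k <- which(hit) - 1L
      peak_set(rep(spec$chrom, length(k)), k * spec$bin_size,
               (k + 1) * spec$bin_size, source = nm)
    })
    names(out) <- names(homes)
    out
  })
}

#' Generate a two-channel synthetic image pair
#'
#' Gaussian spots on a dark background: channel A gets `n_spots`
#' random spot centers; a fraction `coloc_fraction` of channel B's
#' spots share A's centers and the rest are placed independently.
#' Optional additive Gaussian noise.
#'
#' @param size Image side length in pixels.
#' @param n_spots Spots per channel.
#' @param coloc_fraction Fraction of shared centers in `[0, 1]`.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param spot_sd Spot width in pixels (default 2).
#' @param seed Integer seed.
#' @return List with matrices `a` and `b` (`size x size`).
#' @export
make_image_pair <- function(size = 64L, n_spots = 12L,
                            coloc_fraction = 1, noise_sd = 0,
                            spot_sd = 2, seed = 1L) {
  stopifnot(size >= 8, n_spots >= 1, coloc_fraction >= 0,
            coloc_fraction <= 1, noise_sd >= 0)
  render <- function(cx, cy) {
    img <- matrix(0, size, size)
    xs <- row(img); ys <- col(img)
    for (s in seq_along(cx)) {
      img <- img + exp(-((xs - cx[s])^2 + (ys - cy[s])^2) /
                         (2 * spot_sd^2))
    }
    img
  }
  with_seed(seed, {
    margin <- ceiling(3 * spot_sd)
    ax <- runif(n_spots, margin, size - margin)
    ay <- runif(n_spots, margin, size - margin)
    n_shared <- round(coloc_fraction * n_spots)
    bx <- c(ax[seq_len(n_shared)],
            runif(n_spots - n_shared, margin, size - margin))
    by <- c(ay[seq_len(n_shared)],
            runif(n_spots - n_shared, margin, size - margin))
    a <- render(ax, ay)
    b <- render(bx, by)
    if (noise_sd > 0) {
      a <- a + matrix(rnorm(size^2, sd = noise_sd), size, size)
      b <- b + matrix(rnorm(size^2, sd = noise_sd), size, size)
    }
    list(a = a, b = b)
  })
}
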