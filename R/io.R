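#' Write coordinates as an XYZ trajectory
#'
#' One frame per snapshot in plain XYZ format (atom count, comment
#' line, then `C x y z` per bead, coordinates in \eqn{\sigma}).
#'
#' @param frames A single `N x 3` matrix, a list of them, or a
#'   `trajectory` from [langevin_equilibrate()] (its snapshots are
#'   written, or the final positions if none were stored).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path) {
  if (inherits(frames, "trajectory")) {
    frames <- if (length(frames$snapshots)) frames$snapshots
              else list(frames$positions)
  }
  if (is.matrix(frames)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    m <- frames[[k]]
    writeLines(c(as.character(nrow(m)), sprintf("frame %d", k)), con)
    writeLines(sprintf("C %.6f %.6f %.6f", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Write a folded structure as TSV
#'
#' Columns: `bead_index` (1-based), `chrom`, `start`, `end`, `x`, `y`,
#' `z`.
#'
#' @param folded A `folded_structure` from [fold_chromosome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_tsv <- function(folded, path) {
  stopifnot(inherits(folded, "folded_structure"))
  df <- data.frame(bead_index = seq_len(nrow(folded$positions)),
                   chrom = folded$chrom, start = folded$bins$start,
                   end = folded$bins$end, x = folded$positions[, 1],
                   y = folded$positions[, 2], z = folded$positions[, 3])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the restraint satisfaction report as TSV
#'
#' One row per restrained pair: bead indices, genomic separation in
#' bins, and the final 3D distance.
#'
#' @param folded A `folded_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_restraint_report <- function(folded, path) {
  stopifnot(inherits(folded, "folded_structure"))
  pairs <- folded$restraints$pairs
  d <- pair_distances(folded$positions, pairs)
  df <- data.frame(i = pairs[, 1], j = pairs[, 2],
                   separation_bins = pairs[, 2] - pairs[, 1],
                   distance_sigma = d)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an RDF result as TSV
#'
#' @param rdf An `rdf_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rdf_tsv <- function(rdf, path) {
  stopifnot(inherits(rdf, "rdf_result"))
  df <- data.frame(r_lo = rdf$r_edges[-length(rdf$r_edges)],
                   r_hi = rdf$r_edges[-1], r_mid = rdf$r_mid,
                   g = rdf$g, n_pairs = rdf$n_pairs,
                   expected = rdf$expected)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a CCF result as TSV
#'
#' @param ccf A `ccf_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ccf_tsv <- function(ccf, path) {
  stopifnot(inherits(ccf, "ccf_result"))
  df <- data.frame(shift = ccf$shifts, r_pearson = ccf$r_pearson,
                   degenerate = ccf$degenerate)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a grayscale image
#'
#' Accepts a TIFF (first channel of the first image) or a plain-text
#' whitespace-separated numeric matrix.
#'
#' @param path Image path; `.tif`/`.tiff` is read as TIFF, anything
#'   else as a text matrix.
#' @return A numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(img)
  }
  m <- as.matrix(read.table(path))
  dimnames(m) <- NULL
  m
}

#' Write a grayscale image as a text matrix
#'
#' @param img Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_text <- function(img, path) {
  write.table(as.matrix(img), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
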