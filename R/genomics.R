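#' Hi-C contact matrix at fixed bin size
#'
#' A symmetric nonnegative contact-count matrix over ordered,
#' non-overlapping genomic bins of one chromosome.  Bins default to
#' contiguous `[k*bin_size, (k+1)*bin_size)` intervals (0-based
#' half-open); an explicit bin table may be given instead, e.g. when
#' unmappable bins were dropped.
#'
#' @param counts Square numeric matrix, symmetric to `1e-9`.
#' @param chrom Chromosome name.
#' @param bin_size Bin width in bp (default 5000).
#' @param bins Optional data frame with `start`, `end` columns (bp).
#' @return An object of class `hic_matrix`.
#' @export
hic_matrix <- function(counts, chrom = "chrS", bin_size = 5000L,
                       bins = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("contact matrix must be square")
  if (any(counts < 0)) stop("contact counts must be nonnegative")
  if (max(abs(counts - t(counts))) > 1e-9)
    stop("contact matrix is asymmetric beyond tolerance 1e-9")
  n <- nrow(counts)
  if (is.null(bins)) {
    bins <- data.frame(start = (seq_len(n) - 1) * bin_size,
                       end = seq_len(n) * bin_size)
  } else {
    bins <- as.data.frame(bins)
    stopifnot(all(c("start", "end") %in% names(bins)))
    if (nrow(bins) != n)
      stop("bin table length must equal the matrix dimension")
    if (any(bins$start >= bins$end)) stop("bins must have start < end")
    if (is.unsorted(bins$start) ||
        any(bins$start[-1] < bins$end[-nrow(bins)]))
      stop("bins must be sorted and non-overlapping")
  }
  dimnames(counts) <- NULL
  structure(list(counts = counts, chrom = chrom,
                 bin_size = as.integer(bin_size), bins = bins),
            class = "hic_matrix")
}

#' @export
print.hic_matrix <- function(x, ...) {
  nz <- sum(x$counts[upper.tri(x$counts)] != 0)
  cat(sprintf(
    "Hi-C matrix: %s, %d bins of %d bp, %d nonzero off-diagonal contacts\n",
    x$chrom, nrow(x$counts), x$bin_size, nz))
  invisible(x)
}

#' Read a contact matrix from plain text
#'
#' Two layouts are supported.  `coo` is a three-column text file
#' `bin_i<TAB>bin_j<TAB>count` with 0-based bin indices; missing entries
#' are 0, the matrix is symmetrized by mirroring, and entries given on
#' both triangles must agree to `1e-6`.  `dense` is a square
#' whitespace-separated numeric grid.  Bin metadata (chromosome, bin
#' size, bin count) comes from the arguments, or from a sidecar header
#' line `# chrom=<name> bin_size=<bp> n_bins=<n>` which takes effect
#' for any argument left `NULL`.
#'
#' @param path File path.
#' @param fmt `"coo"` or `"dense"`.
#' @param chrom,bin_size,n_bins Bin metadata (see above); `n_bins` is
#'   required for `coo` unless the sidecar line provides it.
#' @return A [hic_matrix].
#' @export
read_contact_matrix <- function(path, fmt = c("coo", "dense"),
                                chrom = NULL, bin_size = NULL,
                                n_bins = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  meta <- list()
  is_comment <- grepl("^\\s*#", lines)
  for (cl in lines[is_comment]) {
    for (kv in regmatches(cl, gregexpr("[A-Za-z_]+=[^ \t]+", cl))[[1]]) {
      p <- strsplit(kv, "=", fixed = TRUE)[[1]]
      meta[[p[1]]] <- p[2]
    }
  }
  chrom <- chrom %||% meta$chrom %||% "chrS"
  bin_size <- as.integer(bin_size %||% meta$bin_size %||% 5000L)
  n_bins <- if (!is.null(n_bins)) as.integer(n_bins)
            else if (!is.null(meta$n_bins)) as.integer(meta$n_bins)
            else NULL
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (fmt == "coo") {
    if (is.null(n_bins))
      stop("n_bins is required for COO input (argument or sidecar line)")
    m <- matrix(0, n_bins, n_bins)
    seen <- matrix(FALSE, n_bins, n_bins)
    for (ln in body_idx) {
      parts <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
      if (length(parts) != 3)
        stop("line ", ln, ": expected 'bin_i bin_j count'")
      vals <- suppressWarnings(as.numeric(parts))
      if (any(is.na(vals))) stop("line ", ln, ": non-numeric field")
      i <- vals[1]; j <- vals[2]; cnt <- vals[3]
      if (i != round(i) || j != round(j))
        stop("line ", ln, ": bin indices must be integers")
      if (i < 0 || j < 0 || i >= n_bins || j >= n_bins)
        stop("line ", ln, ": bin index out of range 0..", n_bins - 1)
      if (cnt < 0) stop("line ", ln, ": negative count")
      ii <- i + 1; jj <- j + 1
      if (seen[ii, jj] && abs(m[ii, jj] - cnt) > 1e-6)
        stop("line ", ln, ": conflicting duplicate entry for (", i, ",",
             j, ")")
      if (seen[jj, ii] && abs(m[jj, ii] - cnt) > 1e-6)
        stop("line ", ln, ": mirrored entries for (", i, ",", j,
             ") disagree beyond 1e-6")
      m[ii, jj] <- cnt
      seen[ii, jj] <- TRUE
    }
    m <- pmax(m, t(m))
  } else {
    rows <- lapply(body_idx, function(ln) {
      vals <- suppressWarnings(
        as.numeric(strsplit(trimws(lines[ln]), "[ \t]+")[[1]]))
      if (any(is.na(vals))) stop("line ", ln, ": non-numeric field")
      vals
    })
    if (!length(rows)) stop("dense matrix file has no data rows")
    nc <- lengths(rows)
    if (length(unique(nc)) != 1)
      stop("line ", body_idx[which(nc != nc[1])[1]], ": ragged row")
    m <- do.call(rbind, rows)
    if (nrow(m) != ncol(m)) stop("dense matrix must be square")
    if (any(m < 0)) stop("negative counts in dense matrix")
    if (max(abs(m - t(m))) > 1e-6)
      stop("dense matrix asymmetric beyond 1e-6")
    m <- (m + t(m)) / 2
    if (!is.null(n_bins) && n_bins != nrow(m))
      stop("n_bins (", n_bins, ") disagrees with matrix dimension (",
           nrow(m), ")")
  }
  hic_matrix(m, chrom = chrom, bin_size = bin_size)
}

#' Write a contact matrix as COO text
#'
#' Upper-triangle nonzero entries as `bin_i<TAB>bin_j<TAB>count`
#' (0-based), preceded by the sidecar header line that
#' [read_contact_matrix()] understands.
#'
#' @param hic A [hic_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(hic, path) {
  stopifnot(inherits(hic, "hic_matrix"))
  n <- nrow(hic$counts)
  idx <- which(upper.tri(hic$counts, diag = TRUE) & hic$counts != 0,
               arr.ind = TRUE)
  hdr <- sprintf("# chrom=%s bin_size=%d n_bins=%d", hic$chrom,
                 hic$bin_size, n)
  body <- sprintf("%d\t%d\t%s", idx[, 1] - 1L, idx[, 2] - 1L,
                  format(hic$counts[idx], trim = TRUE, scientific = FALSE))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' ChIP-seq peak set
#'
#' Sorted genomic intervals in 0-based half-open coordinates.
#'
#' @param chrom,start,end Vectors of equal length (`start < end`).
#' @param source Provenance string.
#' @return An object of class `peak_set`; a data frame underneath.
#' @export
peak_set <- function(chrom, start, end, source = "in-memory") {
  if (any(start >= end)) stop("peaks must have start < end")
  if (any(start < 0)) stop("negative peak start")
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(intervals = df, source = source), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set (%s): %d intervals on %d chromosome(s)\n",
              x$source, nrow(x$intervals),
              length(unique(x$intervals$chrom))))
  invisible(x)
}

#' Read peaks from a BED file
#'
#' BED3 or broader (extra columns ignored); `track`, `browser` and `#`
#' comment lines are skipped.  Coordinates are 0-based half-open and
#' must be non-negative integers with `start < end`.
#'
#' @param path BED file path.
#' @return A [peak_set()], sorted by (chrom, start).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^\\s*(#|track\\b|browser\\b)", lines)
  chroms <- character(0); starts <- numeric(0); ends <- numeric(0)
  for (ln in which(keep)) {
    parts <- strsplit(lines[ln], "\t| +")[[1]]
    if (length(parts) < 3)
      stop("line ", ln, ": BED needs at least 3 columns")
    s <- suppressWarnings(as.numeric(parts[2]))
    e <- suppressWarnings(as.numeric(parts[3]))
    if (is.na(s) || is.na(e) || s != round(s) || e != round(e))
      stop("line ", ln, ": non-integer coordinates")
    if (s >= e) stop("line ", ln, ": start >= end (empty interval)")
    if (s < 0) stop("line ", ln, ": negative start")
    chroms <- c(chroms, parts[1]); starts <- c(starts, s)
    ends <- c(ends, e)
  }
  peak_set(chroms, starts, ends, source = path)
}

#' Write a peak set as BED3
#'
#' @param peaks A [peak_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  df <- peaks$intervals
  writeLines(sprintf("%s\t%d\t%d", df$chrom, as.integer(df$start),
                     as.integer(df$end)), path)
  invisible(path)
}

peaks_to_granges <- function(peaks) {
  df <- peaks$intervals
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Map peaks onto beads
#'
#' Labels each bead (genomic bin) by whether the mark's peaks cover it.
#' Under `any_overlap` a single base pair of overlap suffices; under
#' `min_fraction` the union of peaks must cover at least a fraction `f`
#' of the bin.  Peaks on other chromosomes are dropped (with a message)
#' and peaks extending past the binned region are clipped.
#'
#' @param peaks A [peak_set()].
#' @param hic A [hic_matrix] supplying the binning (or a data frame of
#'   `start`/`end` bins plus `chrom=`/`bin_size=` attributes via the
#'   `chrom` argument).
#' @param rule `"any_overlap"` (default) or `"min_fraction"`.
#' @param f Minimum covered fraction under `min_fraction`.
#' @param mark_name Label stored with the result.
#' @return An object of class `bead_labeling`: logical vector `labels`
#'   (one per bead) plus metadata.
#' @export
label_beads <- function(peaks, hic, rule = c("any_overlap",
                                             "min_fraction"),
                        f = 0.5, mark_name = peaks$source) {
  rule <- match.arg(rule)
  stopifnot(inherits(peaks, "peak_set"), inherits(hic, "hic_matrix"))
  df <- peaks$intervals
  on_chrom <- df$chrom == hic$chrom
  if (any(!on_chrom))
    message(sum(!on_chrom), " peak(s) on other chromosomes dropped")
  df <- df[on_chrom, , drop = FALSE]
  bins <- hic$bins
  n <- nrow(bins)
  labels <- logical(n)
  frac <- numeric(n)
  if (nrow(df)) {
    lim <- max(bins$end)
    clipped <- sum(df$end > lim | df$start < min(bins$start))
    if (clipped) message(clipped, " peak(s) clipped to the binned region")
    df$end <- pmin(df$end, lim)
    df <- df[df$start < df$end, , drop = FALSE]
  }
  if (nrow(df)) {
    pk <- IRanges::reduce(
      IRanges::IRanges(start = df$start + 1, end = df$end))
    bn <- IRanges::IRanges(start = bins$start + 1, end = bins$end)
    ov <- IRanges::findOverlaps(bn, pk)
    if (length(ov)) {
      w <- IRanges::width(IRanges::pintersect(
        bn[S4Vectors::queryHits(ov)], pk[S4Vectors::subjectHits(ov)]))
      cov_by_bin <- tapply(w, S4Vectors::queryHits(ov), sum)
      idx <- as.integer(names(cov_by_bin))
      frac[idx] <- as.numeric(cov_by_bin) /
        (bins$end[idx] - bins$start[idx])
      labels <- if (rule == "any_overlap") frac > 0 else frac >= f
    }
  }
  structure(list(labels = labels, covered_fraction = frac,
                 mark_name = mark_name, rule = rule,
                 f = if (rule == "min_fraction") f else NA_real_),
            class = "bead_labeling")
}

#' @export
print.bead_labeling <- function(x, ...) {
  cat(sprintf("Bead labeling '%s' (%s): %d of %d beads marked\n",
              x$mark_name, x$rule, sum(x$labels), length(x$labels)))
  invisible(x)
}

#' Peak co-occupancy between two sets
#'
#' A peak of `a` is co-occupied if any peak of `b` lies within
#' `max_gap` bp of it; with the default `max_gap = 0` that means at
#' least 1 bp of overlap.  Each peak is counted once.  The symmetric
#' counts for `b` against `a` are also reported.
#'
#' @param a,b [peak_set()] objects.
#' @param max_gap Maximum allowed gap in bp (default 0 = require
#'   overlap).
#' @return A list of class `cooccupancy_report`: `n_a`,
#'   `n_a_overlapping_b`, `fraction_a`, and the same for `b`.
#' @export
cooccupancy <- function(a, b, max_gap = 0L) {
  stopifnot(inherits(a, "peak_set"), inherits(b, "peak_set"),
            max_gap >= 0)
  ga <- peaks_to_granges(a)
  gb <- peaks_to_granges(b)
  # IRanges maxgap: -1 requires >=1 bp overlap; gap of g bp needs
  # maxgap >= g, and our "within max_gap" means gap < max_gap
  mg <- as.integer(max_gap) - 1L
  hits_a <- GenomicRanges::countOverlaps(ga, gb, maxgap = mg) > 0
  hits_b <- GenomicRanges::countOverlaps(gb, ga, maxgap = mg) > 0
  structure(list(
    n_a = length(ga), n_a_overlapping_b = sum(hits_a),
    fraction_a = if (length(ga)) mean(hits_a) else NA_real_,
    n_b = length(gb), n_b_overlapping_a = sum(hits_b),
    fraction_b = if (length(gb)) mean(hits_b) else NA_real_,
    max_gap = as.integer(max_gap)), class = "cooccupancy_report")
}

#' @export
print.cooccupancy_report <- function(x, ...) {
  cat(sprintf("Co-occupancy (max gap %d bp):\n", x$max_gap))
  cat(sprintf("  A: %d / %d peaks co-occupied (%.1f%%)\n",
              x$n_a_overlapping_b, x$n_a, 100 * x$fraction_a))
  cat(sprintf("  B: %d / %d peaks co-occupied (%.1f%%)\n",
              x$n_b_overlapping_a, x$n_b, 100 * x$fraction_b))
  invisible(x)
}

#' Three-set peak co-occupancy summary
#'
#' Venn-style counts for three peak sets: per set, how many peaks
#' overlap each other set and how many overlap both.
#'
#' @param a,b,c [peak_set()] objects.
#' @param max_gap As in [cooccupancy()].
#' @return A data frame with one row per set.
#' @export
cooccupancy_triple <- function(a, b, c, max_gap = 0L) {
  gs <- list(a = peaks_to_granges(a), b = peaks_to_granges(b),
             c = peaks_to_granges(c))
  mg <- as.integer(max_gap) - 1L
  out <- lapply(names(gs), function(nm) {
    others <- setdiff(names(gs), nm)
    h1 <- GenomicRanges::countOverlaps(gs[[nm]], gs[[others[1]]],
                                       maxgap = mg) > 0
    h2 <- GenomicRanges::countOverlaps(gs[[nm]], gs[[others[2]]],
                                       maxgap = mg) > 0
    data.frame(set = nm, n = length(gs[[nm]]),
               with_first_other = sum(h1), with_second_other = sum(h2),
               with_both = sum(h1 & h2))
  })
  do.call(rbind, out)
}
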