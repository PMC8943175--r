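write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("COO contact matrices are read, symmetrized and validated", {
  f <- write_tmp(c("0\t2\t5", "1\t3\t3"))
  hic <- read_contact_matrix(f, "coo", n_bins = 4)
  expect_equal(dim(hic$counts), c(4L, 4L))
  expect_equal(hic$counts[3, 1], 5)   # mirrored lower triangle
  expect_equal(hic$counts[1, 3], 5)
  expect_equal(hic$counts[2, 4], 3)
  expect_equal(sum(hic$counts), 16)   # 2 * (5 + 3)

  empty <- write_tmp(character(0))
  hic0 <- read_contact_matrix(empty, "coo", n_bins = 3)
  expect_equal(hic0$counts, matrix(0, 3, 3))

  bad <- write_tmp("0\t2\t-1")
  expect_error(read_contact_matrix(bad, "coo", n_bins = 4),
               "line 1.*negative")
  oob <- write_tmp("0\t9\t1")
  expect_error(read_contact_matrix(oob, "coo", n_bins = 4),
               "out of range")
  confl <- write_tmp(c("0\t2\t5", "2\t0\t4"))
  expect_error(read_contact_matrix(confl, "coo", n_bins = 4), "disagree")
})

test_that("sidecar metadata line supplies chrom, bin size and bin count", {
  f <- write_tmp(c("# chrom=chrT bin_size=2000 n_bins=5", "0\t3\t2"))
  hic <- read_contact_matrix(f, "coo")
  expect_equal(hic$chrom, "chrT")
  expect_equal(hic$bin_size, 2000L)
  expect_equal(nrow(hic$counts), 5L)
  expect_equal(hic$bins$end[5], 10000)
})

test_that("dense matrices require square symmetric nonnegative grids", {
  f <- write_tmp(c("0 1 0", "1 0 2", "0 2 0"))
  hic <- read_contact_matrix(f, "dense", bin_size = 1000)
  expect_equal(hic$counts[2, 3], 2)
  ragged <- write_tmp(c("0 1 0", "1 0", "0 2 0"))
  expect_error(read_contact_matrix(ragged, "dense"), "ragged")
})

test_that("contact matrices round-trip through COO text", {
  spec <- synthetic_spec(n_beads = 30L, compartment_block_length = 15L,
                         seed = 2L)
  hic <- contacts_from_structure(make_reference_structure(spec), 2.2)
  f <- tempfile()
  write_contact_matrix(hic, f)
  back <- read_contact_matrix(f, "coo")
  expect_equal(back$counts, hic$counts)
  expect_equal(back$chrom, hic$chrom)
  expect_equal(back$bin_size, hic$bin_size)
})

test_that("BED parsing is 0-based half-open with strict validation", {
  f <- write_tmp(c("track name=x", "# c", "chr20\t0\t5000"))
  ps <- read_bed(f)
  expect_equal(nrow(ps$intervals), 1L)
  expect_equal(ps$intervals$start, 0)
  expect_equal(ps$intervals$end, 5000)

  unsorted <- write_tmp(c("chr20\t7000\t8000\tpeakB\t5",
                          "chr20\t100\t200"))
  ps2 <- read_bed(unsorted)
  expect_equal(ps2$intervals$start, c(100, 7000))

  expect_error(read_bed(write_tmp("chr20\t100\t100")), "line 1")
  expect_error(read_bed(write_tmp("chr20\t1.5\t7")), "line 1")
  expect_error(read_bed(write_tmp("chr20\t50")), "3 columns")
})

test_that("peak sets round-trip exactly through BED", {
  ps <- random_peaks(40, seed = 8)
  f <- tempfile(fileext = ".bed")
  write_bed(ps, f)
  back <- read_bed(f)
  expect_equal(back$intervals, ps$intervals)
})

test_that("peak-to-bead mapping follows half-open bin arithmetic", {
  hic <- hic_matrix(matrix(0, 4, 4), chrom = "chrS", bin_size = 5000L)
  straddle <- peak_set("chrS", 4999, 5001)
  lab <- label_beads(straddle, hic)
  expect_equal(which(lab$labels), c(1L, 2L))
  exact <- peak_set("chrS", 5000, 10000)
  expect_equal(which(label_beads(exact, hic)$labels), 2L)
  # 2000 of 5000 bp covered: fails the 0.5 fraction rule
  partial <- peak_set("chrS", 1000, 3000)
  expect_equal(which(label_beads(partial, hic)$labels), 1L)
  expect_equal(sum(label_beads(partial, hic, "min_fraction",
                               f = 0.5)$labels), 0L)
  expect_equal(sum(label_beads(partial, hic, "min_fraction",
                               f = 0.4)$labels), 1L)
})

test_that("off-chromosome peaks are dropped and overhangs clipped", {
  hic <- hic_matrix(matrix(0, 3, 3), chrom = "chrS", bin_size = 5000L)
  ps <- peak_set(c("chrS", "chrX"), c(14000, 0), c(99999, 100))
  expect_message(lab <- label_beads(ps, hic), "dropped")
  expect_equal(which(lab$labels), 3L)
})

test_that("any_overlap labels a superset of any min_fraction labeling", {
  hic <- hic_matrix(matrix(0, 40, 40), chrom = "chrS")
  ps <- random_peaks(60, span = 40 * 5000, seed = 21)
  any_lab <- label_beads(ps, hic)$labels
  for (f in c(0.1, 0.5, 0.9)) {
    frac_lab <- label_beads(ps, hic, "min_fraction", f = f)$labels
    expect_true(all(any_lab | !frac_lab))
  }
})

test_that("co-occupancy counting matches the quadratic oracle", {
  a <- peak_set(rep("c", 3), c(0, 20, 50), c(10, 30, 60))
  b <- peak_set(rep("c", 2), c(8, 31), c(12, 40))
  rep <- cooccupancy(a, b)
  expect_equal(rep$n_a_overlapping_b, 1L)
  expect_equal(rep$fraction_a, 1 / 3)

  ident <- cooccupancy(a, a)
  expect_equal(ident$fraction_a, 1)
  far <- peak_set("c", 1000, 1100)
  expect_equal(cooccupancy(a, far)$fraction_a, 0)

  # adjacency: [20,30) and [30,40) overlap only once a gap is allowed
  touching <- peak_set("c", 30, 40)
  expect_equal(cooccupancy(peak_set("c", 20, 30), touching)$fraction_a, 0)
  expect_equal(
    cooccupancy(peak_set("c", 20, 30), touching, max_gap = 1)$fraction_a,
    1)

  for (s in 1:10) {
    x <- random_peaks(25, span = 5e4, seed = s)
    y <- random_peaks(25, span = 5e4, seed = s + 100)
    for (gap in c(0, 500)) {
      expect_equal(cooccupancy(x, y, gap)$fraction_a,
                   brute_cooccupancy_fraction(x$intervals, y$intervals,
                                              gap))
    }
  }
})

test_that("three-set co-occupancy counts peaks shared by all subunits", {
  a <- peak_set(rep("c", 3), c(0, 100, 200), c(10, 110, 210))
  b <- peak_set(rep("c", 2), c(5, 105), c(15, 115))
  c3 <- peak_set(rep("c", 1), 8, 12)
  venn <- cooccupancy_triple(a, b, c3)
  expect_equal(venn$with_both[venn$set == "a"], 1L)
  expect_equal(venn$n, c(3L, 2L, 1L))
})
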