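# Pipeline orchestration: each run_* function reads its inputs, runs
# the corresponding stages, writes artifacts plus a JSON parameter
# manifest into the output directory, and returns the result invisibly.
# Exit-code conventions for the command-line wrapper:
#   0 success, 2 configuration error, 3 I/O error, 4 convergence failure.

write_manifest <- function(out_dir, stage, params) {
  params$stage <- stage
  params$package_version <- as.character(utils::packageVersion("chromofold"))
  jsonlite::write_json(params,
                       file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

ensure_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Generate a complete synthetic input set on disk
#'
#' Writes a reference structure (TSV + XYZ), its contact matrix (COO
#' text), the three mark tracks (BED) and one synthetic image pair
#' (text matrices) into `out_dir`, all derived from one
#' [synthetic_spec()].
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A [synthetic_spec()].
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_data <- function(out_dir, spec = synthetic_spec()) {
  ensure_out_dir(out_dir)
  ref <- make_reference_structure(spec)
  hic <- contacts_from_structure(ref$positions, spec$contact_radius,
                                 chrom = spec$chrom,
                                 bin_size = spec$bin_size)
  tracks <- make_marked_tracks(ref$compartment, spec)
  imgs <- make_image_pair(seed = spec$seed)
  paths <- list(
    hic = file.path(out_dir, "synthetic_hic.coo.txt"),
    reference_tsv = file.path(out_dir, "reference_structure.tsv"),
    reference_xyz = file.path(out_dir, "reference_structure.xyz"),
    factor = file.path(out_dir, "factor.bed"),
    active_mark = file.path(out_dir, "active_mark.bed"),
    repressive_mark = file.path(out_dir, "repressive_mark.bed"),
    image_a = file.path(out_dir, "image_a.txt"),
    image_b = file.path(out_dir, "image_b.txt"))
  write_contact_matrix(hic, paths$hic)
  ref_df <- data.frame(bead_index = seq_len(spec$n_beads),
                       compartment = ref$compartment,
                       x = ref$positions[, 1], y = ref$positions[, 2],
                       z = ref$positions[, 3])
  write.table(ref_df, paths$reference_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_xyz(ref$positions, paths$reference_xyz)
  for (nm in names(tracks)) write_bed(tracks[[nm]], paths[[nm]])
  write_image_text(imgs$a, paths$image_a)
  write_image_text(imgs$b, paths$image_b)
  write_manifest(out_dir, "simulate_data", unclass(spec))
  invisible(paths)
}

#' Fold a chromosome from files
#'
#' Reads a contact matrix, runs [fold_chromosome()], and writes the
#' structure (XYZ + TSV), the restraint report and a parameter
#' manifest into `out_dir`.
#'
#' @param hic_path Contact matrix path (COO text or dense TSV).
#' @param out_dir Output directory.
#' @param fmt,chrom,bin_size,n_bins Passed to [read_contact_matrix()].
#' @param seed Master seed.
#' @param rule,q,threshold Restraint selection, see
#'   [select_restraints()].
#' @param p,mc,sim Force field and stage configurations.
#' @return The `folded_structure`, invisibly.
#' @export
run_fold <- function(hic_path, out_dir, fmt = "coo", chrom = NULL,
                     bin_size = NULL, n_bins = NULL, seed = 1L,
                     rule = "all_nonzero", q = 0.5, threshold = 1,
                     p = force_field_params(), mc = mc_config(),
                     sim = sim_config(20000L)) {
  if (!file.exists(hic_path))
    stop("contact matrix not found: ", hic_path)
  ensure_out_dir(out_dir)
  hic <- read_contact_matrix(hic_path, fmt = fmt, chrom = chrom,
                             bin_size = bin_size, n_bins = n_bins)
  folded <- fold_chromosome(hic, p = p, mc = mc, sim = sim, seed = seed,
                            rule = rule, q = q, threshold = threshold)
  write_structure_tsv(folded, file.path(out_dir, "structure.tsv"))
  write_xyz(folded$trajectory, file.path(out_dir, "trajectory.xyz"))
  write_xyz(folded$positions, file.path(out_dir, "structure.xyz"))
  write_restraint_report(folded, file.path(out_dir,
                                           "restraint_report.tsv"))
  write_manifest(out_dir, "fold", list(
    hic = hic_path, seed = seed, rule = rule, q = q,
    threshold = threshold, force_field = unclass(p),
    mc = unclass(mc), sim = unclass(sim),
    derived_seeds = as.list(folded$seeds), report = folded$report))
  invisible(folded)
}

#' RDF colocalization of mark pairs on a folded structure
#'
#' Reads a folded structure TSV and at least two BED tracks, maps each
#' track onto the beads, computes the RDF of the first track (the
#' "factor") against each remaining mark, and writes per-pair RDF TSVs
#' plus a proximity-score summary ordering the marks by short-range
#' closeness to the factor.
#'
#' @param structure_path A `structure.tsv` from [run_fold()] (or any
#'   TSV with `chrom`, `start`, `end`, `x`, `y`, `z` columns).
#' @param bed_paths Named character vector of BED paths, length >= 2;
#'   the first entry is the factor.
#' @param out_dir Output directory.
#' @param r_max,dr,n_permutations,seed,baseline RDF settings, see
#'   [radial_distribution()].
#' @param r_short Proximity-score range in \eqn{\sigma}.
#' @param rule Peak-to-bead rule, see [label_beads()].
#' @return Invisibly, a list with the RDFs and the summary data frame
#'   (marks sorted by decreasing proximity score).
#' @export
run_rdf <- function(structure_path, bed_paths, out_dir, r_max = 20,
                    dr = 0.5, n_permutations = 100L, seed = 1L,
                    baseline = "permutation", r_short = 2,
                    rule = "any_overlap") {
  if (length(bed_paths) < 2)
    stop("run_rdf needs a factor plus at least one mark (>= 2 BEDs)")
  if (n_permutations < 1 && baseline == "permutation")
    stop("permutation baseline needs n_permutations >= 1")
  if (!file.exists(structure_path))
    stop("structure file not found: ", structure_path)
  missing <- bed_paths[!file.exists(bed_paths)]
  if (length(missing)) stop("BED file(s) not found: ",
                            paste(missing, collapse = ", "))
  ensure_out_dir(out_dir)
  st <- read.table(structure_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  pos <- as.matrix(st[, c("x", "y", "z")])
  bins <- data.frame(start = st$start, end = st$end)
  hic <- hic_matrix(matrix(0, nrow(st), nrow(st)), chrom = st$chrom[1],
                    bin_size = st$end[1] - st$start[1], bins = bins)
  if (is.null(names(bed_paths)))
    names(bed_paths) <- basename(bed_paths)
  labelings <- lapply(seq_along(bed_paths), function(k)
    label_beads(read_bed(bed_paths[[k]]), hic, rule = rule,
                mark_name = names(bed_paths)[k]))
  names(labelings) <- names(bed_paths)
  factor_lab <- labelings[[1]]
  marks <- labelings[-1]
  rdfs <- list()
  scores <- numeric(0)
  for (nm in names(marks)) {
    rdf <- radial_distribution(pos, factor_lab, marks[[nm]],
                               r_max = r_max, dr = dr,
                               n_permutations = n_permutations,
                               seed = seed, baseline = baseline)
    write_rdf_tsv(rdf, file.path(out_dir, paste0(
      "rdf_", names(bed_paths)[1], "_vs_", nm, ".tsv")))
    rdfs[[nm]] <- rdf
    scores[nm] <- proximity_score(rdf, r_short)
  }
  summary <- data.frame(mark = names(scores),
                        proximity_score = as.numeric(scores))
  summary <- summary[order(-summary$proximity_score), , drop = FALSE]
  rownames(summary) <- NULL
  write.table(summary, file.path(out_dir, "rdf_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "rdf", list(
    structure = structure_path, beds = as.list(bed_paths),
    r_max = r_max, dr = dr, n_permutations = n_permutations,
    seed = seed, baseline = baseline, r_short = r_short, rule = rule))
  invisible(list(rdfs = rdfs, summary = summary))
}

#' Van Steensel CCF of two image files
#'
#' Reads two equal-sized grayscale images (TIFF or text matrix),
#' computes the shifted-Pearson cross-correlation, writes the curve as
#' TSV, and reports where the zero-shift value sits relative to the
#' curve's extrema.
#'
#' @param image_a_path,image_b_path Image paths.
#' @param out_dir Output directory.
#' @param max_shift,axis See [van_steensel_ccf()].
#' @return Invisibly, a list with the `ccf_result` and a one-row
#'   summary (`r_at_zero`, `argmax_shift`, `argmin_shift`,
#'   `zero_is_max`, `zero_is_min`).
#' @export
run_ccf <- function(image_a_path, image_b_path, out_dir,
                    max_shift = 20L, axis = "x") {
  for (f in c(image_a_path, image_b_path))
    if (!file.exists(f)) stop("image not found: ", f)
  ensure_out_dir(out_dir)
  a <- read_image(image_a_path)
  b <- read_image(image_b_path)
  ccf <- van_steensel_ccf(a, b, max_shift = max_shift, axis = axis)
  write_ccf_tsv(ccf, file.path(out_dir, "ccf.tsv"))
  i0 <- which(ccf$shifts == 0)
  summary <- data.frame(
    r_at_zero = ccf$r_pearson[i0],
    argmax_shift = ccf$shifts[which.max(ccf$r_pearson)],
    argmin_shift = ccf$shifts[which.min(ccf$r_pearson)],
    zero_is_max = ccf$shifts[which.max(ccf$r_pearson)] == 0L,
    zero_is_min = ccf$shifts[which.min(ccf$r_pearson)] == 0L)
  write.table(summary, file.path(out_dir, "ccf_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "ccf", list(
    image_a = image_a_path, image_b = image_b_path,
    max_shift = max_shift, axis = axis))
  invisible(list(ccf = ccf, summary = summary))
}

#' Peak co-occupancy of two BED files
#'
#' @param bed_a_path,bed_b_path BED paths.
#' @param out_dir Output directory.
#' @param max_gap See [cooccupancy()].
#' @return Invisibly, the `cooccupancy_report`; a TSV is written to
#'   `out_dir`.
#' @export
run_cooccupancy <- function(bed_a_path, bed_b_path, out_dir,
                            max_gap = 0L) {
  for (f in c(bed_a_path, bed_b_path))
    if (!file.exists(f)) stop("BED not found: ", f)
  ensure_out_dir(out_dir)
  rep <- cooccupancy(read_bed(bed_a_path), read_bed(bed_b_path),
                     max_gap = max_gap)
  df <- data.frame(set = c("a", "b"),
                   n = c(rep$n_a, rep$n_b),
                   n_cooccupied = c(rep$n_a_overlapping_b,
                                    rep$n_b_overlapping_a),
                   fraction = c(rep$fraction_a, rep$fraction_b))
  write.table(df, file.path(out_dir, "cooccupancy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "cooccupancy", list(
    bed_a = bed_a_path, bed_b = bed_b_path, max_gap = max_gap))
  invisible(rep)
}

#' Command-line dispatcher
#'
#' Thin wrapper tying the pipeline stages to a shell interface; the
#' installed script `inst/cli/chromofold.R` calls this and exits with
#' the returned status.  Subcommands: `simulate-data`, `fold`, `rdf`,
#' `ccf`, `cooccupancy`.  Flags use `--key value` (or `--key=value`)
#' form; `--bed` is repeatable as `name=path`.
#'
#' @param args Character vector, as from `commandArgs(TRUE)`.
#' @return Integer exit status, invisibly: 0 success, 2 configuration
#'   error, 3 I/O error, 4 convergence failure.
#' @export
chromofold_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop_config("usage: chromofold <simulate-data|fold|rdf|ccf|cooccupancy> [--flags]")
    cmd <- args[1]
    opts <- parse_cli_flags(args[-1])
    out <- opts$out %||% stop_config("--out is required")
    seed <- as.integer(opts$seed %||% "1")
    switch(cmd,
      "simulate-data" = {
        spec <- synthetic_spec(
          n_beads = as.integer(opts$`n-beads` %||% "200"),
          seed = seed)
        simulate_data(out, spec)
      },
      "fold" = {
        hic <- opts$hic %||% stop_config("--hic is required")
        if (!file.exists(hic)) stop_io("contact matrix not found: ", hic)
        run_fold(hic, out, seed = seed,
                 rule = opts$`restraint-rule` %||% "all_nonzero",
                 n_bins = if (!is.null(opts$`n-bins`))
                   as.integer(opts$`n-bins`),
                 sim = sim_config(as.integer(opts$steps %||% "20000")))
      },
      "rdf" = {
        beds <- opts$bed
        if (is.null(beds)) stop_config("--bed name=path (repeatable) is required")
        kv <- strsplit(beds, "=", fixed = TRUE)
        paths <- vapply(kv, `[`, "", 2)
        names(paths) <- vapply(kv, `[`, "", 1)
        run_rdf(opts$structure %||% stop_config("--structure is required"),
                paths, out, r_max = as.numeric(opts$`r-max` %||% "20"),
                dr = as.numeric(opts$dr %||% "0.5"),
                n_permutations = as.integer(opts$permutations %||% "100"),
                seed = seed)
      },
      "ccf" = {
        run_ccf(opts$a %||% stop_config("--a image is required"),
                opts$b %||% stop_config("--b image is required"), out,
                max_shift = as.integer(opts$`max-shift` %||% "20"))
      },
      "cooccupancy" = {
        run_cooccupancy(opts$a %||% stop_config("--a BED is required"),
                        opts$b %||% stop_config("--b BED is required"),
                        out,
                        max_gap = as.integer(opts$`max-gap` %||% "0"))
      },
      stop_config("unknown subcommand: ", cmd))
    0L
  },
  chromofold_config_error = function(e) { message(conditionMessage(e)); 2L },
  chromofold_io_error = function(e) { message(conditionMessage(e)); 3L },
  error = function(e) {
    msg <- conditionMessage(e)
    message(msg)
    if (grepl("unsatisfied|diverged|backtrack budget", msg)) 4L else 2L
  })
  invisible(status)
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!grepl("^--", a)) stop_config("unexpected argument: ", a)
    if (grepl("=", a)) {
      key <- sub("^--", "", sub("=.*", "", a))
      val <- sub("^[^=]*=", "", a)
      i <- i + 1
    } else {
      key <- sub("^--", "", a)
      if (i == length(args) || grepl("^--", args[i + 1]))
        stop_config("flag --", key, " needs a value")
      val <- args[i + 1]
      i <- i + 2
    }
    opts[[key]] <- c(opts[[key]], val)
  }
  opts
}

stop_config <- function(...) {
  stop(structure(class = c("chromofold_config_error", "error",
                           "condition"),
                 list(message = paste0(...), call = NULL)))
}

stop_io <- function(...) {
  stop(structure(class = c("chromofold_io_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
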