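#' Configuration for an insertion-verification run
#'
#' Collects every tunable of the verification pipeline with its default.
#' Either a built-in fixture (`fixture = "wt"`, `"allele542"`,
#' `"allele320"`) is simulated, or a reference `panel` and `reads` are
#' supplied directly (paths to FASTA/FASTQ, or in-memory `DNAStringSet`s)
#' together with the `construct_interval` on the expected-mutant panel
#' entry.
#'
#' @param fixture Fixture name, or `NULL` when supplying `panel`/`reads`.
#' @param seed Seed governing read simulation.
#' @param locus_seed Seed governing the toy locus sequence.
#' @param n_reads,mean_length,length_sd Long-read simulation parameters.
#' @param substitution_rate,insertion_rate,deletion_rate Per-base error
#'   rates for simulated reads.
#' @param cut_sites Optional Cas9 cut offsets for enrichment-style read
#'   starts.
#' @param panel,reads Paths or `DNAStringSet`s (non-fixture mode).
#' @param construct_interval [genomic_interval()] of the construct on the
#'   expected-mutant panel entry (non-fixture mode).
#' @param k,step Unique k-mer length and read sampling stride (verification
#'   defaults 20 and 5).
#' @param scope Uniqueness scope for [build_unique_index()].
#' @param max_diag_offset,max_gap,min_anchors Chaining parameters.
#' @param gap_tol,margin,adjacency_tol,min_copy_fraction,min_classify_fraction,n_max
#'   Structure-inference parameters (see [infer_configuration()]).
#' @param out_dir Optional output directory for intermediate files.
#' @param dotplots Number of per-read dot-plot PNGs to write when
#'   `out_dir` is set (default 0).
#' @return A list of class `run_config`.
#' @export
verify_config <- function(fixture = NULL, seed = 42L, locus_seed = 7L,
                          n_reads = 200L, mean_length = 8000,
                          length_sd = 1000, substitution_rate = 0.05,
                          insertion_rate = 0.03, deletion_rate = 0.04,
                          cut_sites = NULL, panel = NULL, reads = NULL,
                          construct_interval = NULL, k = 20L, step = 5L,
                          scope = "global", max_diag_offset = 50L,
                          max_gap = 500L, min_anchors = 3L, gap_tol = 200L,
                          margin = 200L, adjacency_tol = 1000L,
                          min_copy_fraction = 0.3,
                          min_classify_fraction = 0.5, n_max = 8L,
                          out_dir = NULL, dotplots = 0L) {
  cfg <- as.list(environment())
  if (is.null(fixture) && (is.null(panel) || is.null(reads) ||
                           is.null(construct_interval)))
    stop("supply either a fixture name or panel + reads + construct_interval")
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file of `verify_config()` fields; unknown keys are
#' rejected. A `construct_interval` may be given as a region string.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- names(formals(verify_config))
  bad <- setdiff(names(doc), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(doc$construct_interval) && is.character(doc$construct_interval))
    doc$construct_interval <- parse_region(doc$construct_interval)
  do.call(verify_config, doc)
}

resolve_verify_inputs <- function(config) {
  if (!is.null(config$fixture)) {
    locus <- make_toy_locus(seed = config$locus_seed)
    fx <- make_fixture_allele(config$fixture, locus)
    expected <- if (config$fixture == "allele542") fx
                else make_fixture_allele("allele542", locus)
    sim <- simulate_long_reads(
      fx$genome, n_reads = config$n_reads,
      mean_length = config$mean_length, length_sd = config$length_sd,
      substitution_rate = config$substitution_rate,
      insertion_rate = config$insertion_rate,
      deletion_rate = config$deletion_rate,
      cut_sites = config$cut_sites, seed = config$seed)
    list(panel = expected$genome, reads = sim$reads, truth = sim$truth,
         construct_interval = expected$construct_interval, fixture = fx)
  } else {
    panel <- if (is.character(config$panel) && length(config$panel) == 1L &&
                 file.exists(config$panel)) read_genome_fasta(config$panel)
             else as_dss(config$panel)
    reads <- if (is.character(config$reads) && length(config$reads) == 1L &&
                 file.exists(config$reads)) read_fastq(config$reads)
             else as_dss(config$reads)
    list(panel = panel, reads = reads, truth = NULL,
         construct_interval = config$construct_interval, fixture = NULL)
  }
}

#' Run the insertion-verification pipeline end to end
#'
#' Builds the unique k-mer index over the reference panel, anchors every
#' read, chains anchors into per-read architectures against the
#' expected-mutant reference, classifies reads, and infers the allele
#' configuration (class, minimum copy number, orientation pattern). When
#' `out_dir` is set, anchors, architectures, the JSON report and optional
#' dot plots are written there.
#'
#' @param config A `run_config` from [verify_config()] /
#'   [read_run_config()], or a plain list of `verify_config()` arguments.
#' @return An object of class `verification_report`.
#' @export
run_verify <- function(config) {
  if (!inherits(config, "run_config")) config <- do.call(verify_config, config)
  inp <- resolve_verify_inputs(config)
  index <- build_unique_index(inp$panel, k = config$k, scope = config$scope)
  anchors <- scan_reads(inp$reads, index, step = config$step)
  ci <- inp$construct_interval
  read_ids <- names(inp$reads)
  widths <- stats::setNames(Biostrings::width(inp$reads), read_ids)
  mut_anchors <- anchors[anchors$ref_name == ci$chrom, , drop = FALSE]
  by_read <- split(mut_anchors, factor(mut_anchors$read_id, levels = read_ids))
  archs <- lapply(read_ids, function(id) {
    a <- by_read[[id]]
    attr(a, "k") <- config$k
    read_architecture(a, read_length = widths[[id]],
                      max_diag_offset = config$max_diag_offset,
                      max_gap = config$max_gap,
                      min_anchors = config$min_anchors,
                      gap_tol = config$gap_tol, k = config$k, read_id = id)
  })
  conf <- if (length(archs)) {
    infer_configuration(
      archs, ci, n_max = config$n_max, margin = config$margin,
      gap_tol = config$gap_tol, adjacency_tol = config$adjacency_tol,
      min_copy_fraction = config$min_copy_fraction,
      min_classify_fraction = config$min_classify_fraction)
  } else {
    warning("no reads supplied; verification report is empty")
    list(class = NA_character_, copy_count_min = NA_integer_,
         orientation_pattern = "", patterns_all = character(0),
         read_labels = table(factor(character(0), levels = c(
           "WT", "expected_knockin", "multi_copy", "ambiguous",
           "unclassified"))),
         junction_support = table(factor(character(0), levels = c(
           "colinear-gap", "deletion", "insertion", "inversion",
           "copy-junction"))))
  }
  report <- structure(list(
    allele_class = conf$class,
    copy_count_min = conf$copy_count_min,
    orientation_pattern = conf$orientation_pattern,
    patterns_all = conf$patterns_all,
    read_labels = as.list(conf$read_labels),
    junction_support = as.list(conf$junction_support),
    n_reads = length(read_ids),
    parameters = config_echo(config),
    tool = paste0("kanchor ", as.character(utils::packageVersion("kanchor"))),
    input_checksums = NULL),
    class = "verification_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    panel_fa <- file.path(config$out_dir, "panel.fa")
    reads_fq <- file.path(config$out_dir, "reads.fastq")
    write_genome_fasta(inp$panel, panel_fa)
    write_fastq(inp$reads, reads_fq)
    report$input_checksums <- as.list(tools::md5sum(c(panel_fa, reads_fq)))
    export_dotplot(anchors, file.path(config$out_dir, "anchors.tsv"))
    write_architectures(archs, file.path(config$out_dir, "architectures.tsv"))
    if (config$dotplots > 0L) {
      for (id in utils::head(read_ids, config$dotplots)) {
        a <- anchors[anchors$read_id == id, , drop = FALSE]
        plot_dotplot(a, file = file.path(config$out_dir,
                                         paste0("dotplot_", id, ".png")))
      }
    }
    write_report(report, file.path(config$out_dir, "report.json"))
  }
  report$architectures <- archs
  report$anchors <- anchors
  report$truth <- inp$truth
  report
}

config_echo <- function(config) {
  keep <- setdiff(names(config), c("panel", "reads", "construct_interval",
                                   "out_dir"))
  vals <- config[keep]
  vals <- vals[!vapply(vals, is.null, logical(1))]
  vals
}

#' Write a verification report as JSON
#'
#' Serializes the machine-readable part of a `verification_report`
#' (class, copy number, patterns, tallies, parameters, checksums);
#' per-read architectures and anchors are exported separately as TSV.
#'
#' @param report A `verification_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  keep <- setdiff(names(report), c("architectures", "anchors", "truth"))
  jsonlite::write_json(report[keep], path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.verification_report <- function(x, ...) {
  cat("verification report\n")
  cat(sprintf("  allele class:    %s\n", x$allele_class))
  cat(sprintf("  copy_count_min:  %d\n", x$copy_count_min))
  cat(sprintf("  pattern:         %s\n",
              if (nzchar(x$orientation_pattern)) x$orientation_pattern else "-"))
  cat(sprintf("  reads:           %d\n", x$n_reads))
  cat("  read labels:     ",
      paste(sprintf("%s=%d", names(x$read_labels),
                    unlist(x$read_labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Run the duplicated-element disambiguation pipeline
#'
#' Simulates (or loads) short read pairs over a knock-in genome carrying a
#' duplicated element, assigns every pair to one element copy through
#' genome-wide unique k-mers, and emits per-base coverage from uniquely
#' assigned fragments. With the default fixture the element is the
#' enhancer duplicated between its native site and the integrated
#' construct.
#'
#' @param fixture Fixture allele carrying the duplication (default
#'   `"allele542"`).
#' @param locus_seed,seed Seeds for locus and pair simulation.
#' @param n_pairs Number of simulated pairs.
#' @param read_length,insert_mean,insert_sd Pair geometry.
#' @param substitution_rate,insertion_rate,deletion_rate Per-base error
#'   rates (default 0).
#' @param k_unique Uniqueness probe length (default 20).
#' @param min_unique_kmers,pad,pair_mode See [assign_read_pairs()].
#' @param coverage_region Optional [genomic_interval()] for the coverage
#'   track (default: the whole mutant genome).
#' @param out_dir Optional output directory (assignments TSV + bedGraph).
#' @return A list of class `disambiguation_result`: `assignments` (with
#'   truth columns `true_start`, `true_end`, `true_locus`), `coverage`,
#'   `element`, `summary` (status tally), `n_wrong_locus`.
#' @export
run_disambiguate <- function(fixture = "allele542", locus_seed = 7L,
                             seed = 42L, n_pairs = 2000L, read_length = 50L,
                             insert_mean = 200, insert_sd = 50,
                             substitution_rate = 0, insertion_rate = 0,
                             deletion_rate = 0, k_unique = 20L,
                             min_unique_kmers = 1L, pad = 2000L,
                             pair_mode = "either-mate",
                             coverage_region = NULL, out_dir = NULL) {
  locus <- make_toy_locus(seed = locus_seed)
  fx <- make_fixture_allele(fixture, locus)
  element <- duplicated_element(fx$genome, "element",
                                fx$element_copies[[1L]],
                                fx$element_copies[[2L]])
  index <- build_unique_index(fx$genome, k = k_unique)
  sim <- simulate_short_pairs(fx$genome, n_pairs = n_pairs,
                              read_length = read_length,
                              insert_mean = insert_mean,
                              insert_sd = insert_sd,
                              substitution_rate = substitution_rate,
                              insertion_rate = insertion_rate,
                              deletion_rate = deletion_rate, seed = seed)
  asg <- assign_read_pairs(sim$reads1, sim$reads2, index, element,
                           pair_mode = pair_mode,
                           min_unique_kmers = min_unique_kmers, pad = pad)
  truth_locus <- true_locus(sim$truth, element, pad)
  asg$true_start <- sim$truth$start
  asg$true_end <- sim$truth$end
  asg$true_locus <- truth_locus
  n_wrong <- sum(asg$status == "unique" & !is.na(asg$locus) &
                   !is.na(asg$true_locus) & asg$locus != asg$true_locus)
  region <- coverage_region %||%
    genomic_interval(names(fx$genome)[1L], 0,
                     Biostrings::width(fx$genome)[1L])
  uniq <- asg$status == "unique"
  cov <- coverage_track(
    data.frame(chrom = region$chrom, start = sim$truth$start[uniq],
               end = sim$truth$end[uniq]), region)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(asg, file.path(out_dir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_bedgraph(cov, file.path(out_dir, "coverage.bedGraph"))
  }
  structure(list(assignments = asg, coverage = cov, element = element,
                 summary = table(asg$status), n_wrong_locus = n_wrong),
            class = "disambiguation_result")
}

# Expected element copy for a truth fragment: the copy whose padded
# neighborhood contains the fragment; NA elsewhere.
true_locus <- function(truth, element, pad) {
  res <- rep(NA_integer_, nrow(truth))
  for (i in 1:2) {
    nb <- neighborhood(element$copies[[i]], pad)
    hit <- truth$start < nb$end & truth$end > nb$start
    res[hit & is.na(res)] <- i
  }
  res
}

#' Build a mutant genome from an allele specification
#'
#' Applies an [allele_spec()] (given directly or as a YAML file) to a
#' wild-type genome (given directly or as FASTA) and, when `out_dir` is
#' set, writes the mutant FASTA (60-column wrap), a UCSC chain file for
#' lift-over, and the edit targets as BED.
#'
#' @param genome Named `DNAStringSet` or FASTA path.
#' @param spec [allele_spec()] or YAML path.
#' @param out_dir Optional output directory.
#' @return A list with `genome` (mutant `DNAStringSet`) and `map`
#'   (`coordinate_map`).
#' @export
run_build_genome <- function(genome, spec, out_dir = NULL) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome_fasta(genome)
  if (is.character(spec) && length(spec) == 1L && file.exists(spec))
    spec <- read_allele_spec(spec)
  res <- apply_edits(genome, spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genome_fasta(res$genome,
                       file.path(out_dir, paste0(spec$name, ".fa")))
    write_chain(res$map, file.path(out_dir, paste0(spec$name, ".chain")))
    if (nrow(spec$edits))
      write_edits_bed(spec, file.path(out_dir, paste0(spec$name, ".bed")))
  }
  res
}
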