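#' Blueprint for a toy duplicated-enhancer locus
#'
#' Desk-scale stand-in for a multi-megabase regulatory locus: a random
#' 60-kb sequence carrying one 532-bp enhancer element (the length of the
#' cloned distal-limb enhancer) and, 30 kb away, a CRISPR integration site
#' flanked by homology arms. The targeting construct is
#' enhancer + promoter + reporter, 4,190 bp in total (the size of the
#' excised enhancer-reporter fragment), and its enhancer part is the exact
#' sequence of the native element, so that knock-in alleles built from the
#' blueprint carry a genuinely duplicated element.
#'
#' @param total_length Locus length in bp (default 60,000).
#' @param element_length Enhancer element length (default 532).
#' @param element_copy1_offset 0-based offset of the native element
#'   (default 15,000).
#' @param insertion_site_offset 0-based offset of the integration target
#'   (default 45,000).
#' @param target_site_length Length of the inter-arm host segment replaced
#'   upon integration (default 26, the distance between the printed
#'   homology-arm coordinates).
#' @param left_ha_length,right_ha_length Homology-arm lengths (defaults
#'   1035 and 1048, the printed arm sizes).
#' @param construct_parts Named lengths of the construct pieces; must start
#'   with `enhancer = element_length` and sum to the construct size
#'   (default enhancer 532, promoter 600, reporter 3058 = 4,190).
#' @param gc_content GC fraction of the random background (default 0.45).
#' @return A list of class `locus_blueprint`.
#' @export
locus_blueprint <- function(total_length = 60000L, element_length = 532L,
                            element_copy1_offset = 15000L,
                            insertion_site_offset = 45000L,
                            target_site_length = 26L,
                            left_ha_length = 1035L, right_ha_length = 1048L,
                            construct_parts = c(enhancer = 532L,
                                                promoter = 600L,
                                                reporter = 3058L),
                            gc_content = 0.45) {
  bp <- list(total_length = as.integer(total_length),
             element_length = as.integer(element_length),
             element_copy1_offset = as.integer(element_copy1_offset),
             insertion_site_offset = as.integer(insertion_site_offset),
             target_site_length = as.integer(target_site_length),
             left_ha_length = as.integer(left_ha_length),
             right_ha_length = as.integer(right_ha_length),
             construct_parts = construct_parts,
             gc_content = gc_content)
  if (bp$element_length != unname(construct_parts[1L]))
    stop("the first construct part must be the enhancer element itself")
  if (bp$element_copy1_offset + bp$element_length > bp$total_length ||
      bp$insertion_site_offset + bp$target_site_length > bp$total_length ||
      bp$insertion_site_offset - bp$left_ha_length < 0 ||
      bp$insertion_site_offset + bp$target_site_length +
        bp$right_ha_length > bp$total_length)
    stop("infeasible layout: features extend beyond the locus")
  gap <- abs(bp$insertion_site_offset - bp$element_copy1_offset)
  if (gap < 10000L)
    stop("element copy and insertion site must be separated by >= 10 kb")
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0,1)")
  class(bp) <- "locus_blueprint"
  bp
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate the toy locus and its targeting construct
#'
#' Draws a random background sequence at the blueprint's GC content; the
#' native enhancer element is simply the sequence found at its offset, and
#' the construct concatenates that element with random promoter and
#' reporter parts drawn from the same stream. Fully deterministic per
#' seed.
#'
#' @param blueprint A [locus_blueprint()].
#' @param seed Integer seed.
#' @param seqname Name of the toy chromosome (default `"chrT"`).
#' @return A list of class `toy_locus`: `genome` (named `DNAStringSet`),
#'   `construct` (character, 4,190 bp by default), `features` (data frame
#'   of named 0-based intervals: element_copy1, target_site, left_HA,
#'   right_HA), `blueprint`, `seqname`.
#' @export
make_toy_locus <- function(blueprint = locus_blueprint(), seed = 7L,
                           seqname = "chrT") {
  stopifnot(inherits(blueprint, "locus_blueprint"))
  bp <- blueprint
  withr::with_seed(as.integer(seed), {
    background <- random_dna(bp$total_length, bp$gc_content)
    extra <- sum(bp$construct_parts[-1L])
    tail_parts <- random_dna(extra, bp$gc_content)
  })
  element <- substr(background, bp$element_copy1_offset + 1L,
                    bp$element_copy1_offset + bp$element_length)
  construct <- paste0(element, tail_parts)
  features <- data.frame(
    name = c("element_copy1", "target_site", "left_HA", "right_HA"),
    start = c(bp$element_copy1_offset, bp$insertion_site_offset,
              bp$insertion_site_offset - bp$left_ha_length,
              bp$insertion_site_offset + bp$target_site_length),
    end = c(bp$element_copy1_offset + bp$element_length,
            bp$insertion_site_offset + bp$target_site_length,
            bp$insertion_site_offset,
            bp$insertion_site_offset + bp$target_site_length +
              bp$right_ha_length),
    stringsAsFactors = FALSE)
  genome <- Biostrings::DNAStringSet(stats::setNames(background, seqname))
  structure(list(genome = genome, construct = construct,
                 features = features, blueprint = bp, seqname = seqname),
            class = "toy_locus")
}

#' Build a fixture allele on the toy locus
#'
#' Three emulated genotypes: `"wt"` (no edit), `"allele542"` (single-copy
#' knock-in: the inter-arm target segment is replaced by one construct
#' copy) and `"allele320"` (multi-copy tandem array: the same target is
#' replaced by `copies` construct copies in the given orientation pattern,
#' reverse-complemented where the pattern says `-`). The default array is
#' four copies in pattern `+,+,-,+`: the copy count matches the minimum
#' reconstructed for the multi-copy founder line, while the orientation
#' pattern is a stand-in fixture truth (no pattern is published), recorded
#' in the returned object so tests compare against the fixture's own
#' truth.
#'
#' @param fixture `"wt"`, `"allele542"` or `"allele320"`.
#' @param locus A [make_toy_locus()] result.
#' @param copies Number of tandem copies for `allele320` (default 4).
#' @param orientation_pattern Character vector over `+`/`-` of length
#'   `copies` (default `c("+","+","-","+")`).
#' @return A list of class `fixture_allele`: `name`, `spec`
#'   ([allele_spec()]), `genome` (mutant `DNAStringSet`), `map`
#'   (`coordinate_map`), `construct_interval` (construct span on the
#'   *expected single-copy mutant*, the reference used for read
#'   verification), `element_copies` (the two duplicated-element intervals
#'   on the 542-type mutant), `copy_intervals` (construct copy spans on
#'   this fixture's own genome), `orientation_pattern`, `copies`.
#' @export
make_fixture_allele <- function(fixture = c("wt", "allele542", "allele320"),
                                locus, copies = 4L,
                                orientation_pattern = c("+", "+", "-", "+")) {
  fixture <- match.arg(fixture)
  stopifnot(inherits(locus, "toy_locus"))
  bp <- locus$blueprint
  feats <- locus$features
  site <- feats[feats$name == "target_site", ]
  left_ha <- genomic_interval(locus$seqname,
                              feats$start[feats$name == "left_HA"],
                              feats$end[feats$name == "left_HA"])
  right_ha <- genomic_interval(locus$seqname,
                               feats$start[feats$name == "right_HA"],
                               feats$end[feats$name == "right_HA"])
  clen <- nchar(locus$construct)
  cstart <- site$start
  if (fixture == "wt") {
    spec <- allele_spec("wt", locus$seqname)
    applied <- apply_edits(locus$genome, spec)
    copy_iv <- list()
    pattern <- character(0)
    copies <- 0L
  } else if (fixture == "allele542") {
    spec <- build_knockin_allele(locus$genome, locus$construct,
                                 left_ha, right_ha, "allele542")
    applied <- apply_edits(locus$genome, spec)
    copy_iv <- list(genomic_interval(locus$seqname, cstart, cstart + clen))
    pattern <- "+"
    copies <- 1L
  } else {
    if (length(orientation_pattern) != copies)
      stop("orientation_pattern must have length 'copies'")
    if (!all(orientation_pattern %in% c("+", "-")))
      stop("orientation_pattern entries must be '+' or '-'")
    parts <- vapply(orientation_pattern, function(o) {
      if (o == "+") locus$construct
      else as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(locus$construct)))
    }, character(1))
    payload <- paste(parts, collapse = "")
    spec <- build_knockin_allele(locus$genome, payload,
                                 left_ha, right_ha, "allele320")
    applied <- apply_edits(locus$genome, spec)
    copy_iv <- lapply(seq_len(copies), function(i)
      genomic_interval(locus$seqname, cstart + (i - 1L) * clen,
                       cstart + i * clen))
    pattern <- orientation_pattern
  }
  # duplicated-element copies live on the single-copy (542-type) mutant
  elem <- feats[feats$name == "element_copy1", ]
  element_copies <- list(
    genomic_interval(locus$seqname, elem$start, elem$end),
    genomic_interval(locus$seqname, cstart, cstart + bp$element_length))
  structure(list(name = fixture, spec = spec, genome = applied$genome,
                 map = applied$map,
                 construct_interval = genomic_interval(locus$seqname, cstart,
                                                       cstart + clen),
                 element_copies = element_copies,
                 copy_intervals = copy_iv,
                 orientation_pattern = pattern,
                 copies = as.integer(copies)),
            class = "fixture_allele")
}

inject_errors <- function(chars, sub_rate, ins_rate, del_rate) {
  bases <- c("A", "C", "G", "T")
  n <- length(chars)
  if (del_rate > 0) chars <- chars[stats::runif(n) >= del_rate]
  n <- length(chars)
  if (n == 0L) return(chars)
  if (sub_rate > 0) {
    hit <- which(stats::runif(n) < sub_rate)
    if (length(hit)) {
      repl <- bases[(match(chars[hit], bases) - 1L +
                       sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L]
      # N positions (match NA) get a uniform random base
      na <- is.na(repl)
      if (any(na)) repl[na] <- sample(bases, sum(na), replace = TRUE)
      chars[hit] <- repl
    }
  }
  if (ins_rate > 0) {
    ins <- stats::runif(n) < ins_rate
    if (any(ins)) {
      idx <- rep(seq_len(n), 1L + ins)
      out <- chars[idx]
      newpos <- which(c(FALSE, diff(idx) == 0L))
      out[newpos] <- sample(bases, length(newpos), replace = TRUE)
      chars <- out
    }
  }
  chars
}

#' Simulate nanopore-like long reads with ground truth
#'
#' Draws read lengths from a normal distribution truncated to
#' `[min_length, genome length]`, places starts uniformly (or within
#' +/- 500 bp of Cas9 `cut_sites`, emulating Cas9-targeted enrichment of
#' reads around an insertion site), samples the strand equiprobably and
#' injects substitution/insertion/deletion errors base-wise at the given
#' per-base rates. Default error rates (5%/3%/4%) approximate a
#' contemporary nanopore error profile. Fully reproducible per seed.
#'
#' @param genome Named [Biostrings::DNAStringSet] with a single entry, or
#'   entry selected by `seqname`.
#' @param n_reads Number of reads.
#' @param mean_length,length_sd Read length distribution in bp.
#' @param substitution_rate,insertion_rate,deletion_rate Per-base error
#'   rates, each in `[0, 0.2]`.
#' @param cut_sites Optional integer offsets; read starts are drawn
#'   uniformly within +/- 500 bp of a random cut site instead of uniformly
#'   over the genome.
#' @param seed Integer seed.
#' @param min_length Lower truncation of the length distribution (default
#'   200).
#' @param id_prefix Read id prefix.
#' @return A list of class `simulated_reads`: `reads` (named
#'   `DNAStringSet`) and `truth` (data frame `read_id`, `start`, `end`
#'   (0-based half-open origin on the source genome), `strand`, `length`).
#' @export
simulate_long_reads <- function(genome, n_reads, mean_length = 8000,
                                length_sd = 1000, substitution_rate = 0.05,
                                insertion_rate = 0.03, deletion_rate = 0.04,
                                cut_sites = NULL, seed = 1L,
                                min_length = 200L, id_prefix = "read") {
  genome <- as_dss(genome)
  if (length(genome) != 1L)
    stop("simulate_long_reads expects a single-sequence genome")
  check_rates(substitution_rate, insertion_rate, deletion_rate)
  if (n_reads < 1L) stop("n_reads must be >= 1")
  L <- Biostrings::width(genome)[1L]
  if (mean_length < min_length) stop("mean_length below minimum read length")
  gseq <- as.character(genome[[1L]])
  withr::with_seed(as.integer(seed), {
    lens <- pmin(pmax(round(stats::rnorm(n_reads, mean_length, length_sd)),
                      min_length), L)
    starts <- integer(n_reads)
    if (is.null(cut_sites)) {
      starts <- vapply(lens, function(l)
        as.integer(floor(stats::runif(1, 0, L - l + 1))), integer(1))
    } else {
      cs <- as.integer(cut_sites)[sample.int(length(cut_sites), n_reads,
                                             replace = TRUE)]
      jitter <- as.integer(round(stats::runif(n_reads, -500, 500)))
      starts <- pmin(pmax(cs + jitter, 0L), pmax(L - lens, 0L))
    }
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- character(n_reads)
    for (i in seq_len(n_reads)) {
      frag <- substr(gseq, starts[i] + 1L, starts[i] + lens[i])
      chars <- strsplit(frag, "", fixed = TRUE)[[1L]]
      chars <- inject_errors(chars, substitution_rate, insertion_rate,
                             deletion_rate)
      s <- paste(chars, collapse = "")
      if (strands[i] == "-")
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      seqs[i] <- s
    }
  })
  ids <- sprintf("%s_%04d", id_prefix, seq_len(n_reads))
  reads <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  truth <- data.frame(read_id = ids, start = starts,
                      end = starts + lens, strand = strands,
                      length = lens, stringsAsFactors = FALSE)
  structure(list(reads = reads, truth = truth), class = "simulated_reads")
}

check_rates <- function(...) {
  r <- c(...)
  if (any(r < 0 | r > 0.2))
    stop("error rates must lie in [0, 0.2]")
}

#' Simulate paired short reads with ground truth
#'
#' Draws fragments uniformly over a region (default: the whole genome),
#' with normally distributed insert sizes clipped to at least twice the
#' read length (with a warning), and reports the two inward-facing mates.
#' Error rates default to zero, emulating clean short-read data.
#'
#' @inheritParams simulate_long_reads
#' @param n_pairs Number of fragment pairs.
#' @param read_length Mate length in bp (default 50).
#' @param insert_mean,insert_sd Fragment size distribution (default
#'   200 +/- 50).
#' @param region Optional [genomic_interval()] restricting fragment
#'   placement.
#' @return A list of class `simulated_pairs`: `reads1`, `reads2` (named
#'   `DNAStringSet`s; mate 2 is the reverse complement of the fragment
#'   end) and `truth` (data frame `pair_id`, `start`, `end` (fragment,
#'   0-based half-open), `strand`).
#' @export
simulate_short_pairs <- function(genome, n_pairs, read_length = 50L,
                                 insert_mean = 200, insert_sd = 50,
                                 substitution_rate = 0, insertion_rate = 0,
                                 deletion_rate = 0, region = NULL,
                                 seed = 1L, id_prefix = "pair") {
  genome <- as_dss(genome)
  if (length(genome) != 1L)
    stop("simulate_short_pairs expects a single-sequence genome")
  check_rates(substitution_rate, insertion_rate, deletion_rate)
  L <- Biostrings::width(genome)[1L]
  lo <- if (is.null(region)) 0L else max(0L, region$start)
  hi <- if (is.null(region)) L else min(L, region$end)
  gseq <- as.character(genome[[1L]])
  min_insert <- 2L * read_length
  if (insert_mean < min_insert)
    warning("insert_mean below twice the read length; fragments clipped")
  withr::with_seed(as.integer(seed), {
    frag <- pmax(round(stats::rnorm(n_pairs, insert_mean, insert_sd)),
                 min_insert)
    frag <- pmin(frag, hi - lo)
    starts <- vapply(frag, function(f)
      as.integer(floor(stats::runif(1, lo, hi - f + 1))), integer(1))
    strands <- sample(c("+", "-"), n_pairs, replace = TRUE)
    s1 <- character(n_pairs); s2 <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      fs <- substr(gseq, starts[i] + 1L, starts[i] + frag[i])
      if (strands[i] == "-")
        fs <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fs)))
      m1 <- substr(fs, 1L, read_length)
      m2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        substr(fs, nchar(fs) - read_length + 1L, nchar(fs)))))
      err <- function(s) {
        if (substitution_rate == 0 && insertion_rate == 0 && deletion_rate == 0)
          return(s)
        paste(inject_errors(strsplit(s, "", fixed = TRUE)[[1L]],
                            substitution_rate, insertion_rate, deletion_rate),
              collapse = "")
      }
      s1[i] <- err(m1); s2[i] <- err(m2)
    }
  })
  ids <- sprintf("%s_%05d", id_prefix, seq_len(n_pairs))
  truth <- data.frame(pair_id = ids, start = starts, end = starts + frag,
                      strand = strands, stringsAsFactors = FALSE)
  structure(list(reads1 = Biostrings::DNAStringSet(stats::setNames(s1, ids)),
                 reads2 = Biostrings::DNAStringSet(stats::setNames(s2, ids)),
                 truth = truth),
            class = "simulated_pairs")
}

#' Read and write FASTQ with placeholder qualities
#'
#' The pipeline ignores base qualities; `write_fastq` emits a constant
#' Q20 quality string (`"5"` in Sanger encoding) and `read_fastq` loads
#' sequences only.
#'
#' @param reads Named [Biostrings::DNAStringSet].
#' @param path File path.
#' @param quality_char Single Sanger quality character (default `"5"`,
#'   Q20).
#' @return `write_fastq` returns `path` invisibly; `read_fastq` returns a
#'   named `DNAStringSet`.
#' @export
write_fastq <- function(reads, path, quality_char = "5") {
  reads <- as_dss(reads)
  quals <- Biostrings::BStringSet(vapply(Biostrings::width(reads), function(w)
    strrep(quality_char, w), character(1)))
  qreads <- Biostrings::QualityScaledDNAStringSet(
    reads, Biostrings::PhredQuality(quals))
  Biostrings::writeQualityScaledXStringSet(qreads, filepath = path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  names(x) <- sub("\\s.*$", "", names(x))
  x
}
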