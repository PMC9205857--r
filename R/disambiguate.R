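#' Describe a duplicated element: two identical copies in one genome
#'
#' Records the two locations of a sequence-identical element (for instance
#' a native enhancer and its transgenic copy integrated elsewhere). Reads
#' falling entirely inside either copy can never be attributed to one of
#' them; attribution requires flanking sequence, which this module probes
#' with genome-wide unique k-mers.
#'
#' @param genome Named [Biostrings::DNAStringSet] of the (mutant) genome.
#' @param name Element name.
#' @param copy1,copy2 [genomic_interval()]s of the two copies; their
#'   underlying sequences must be exactly equal and the intervals disjoint.
#' @return An object of class `duplicated_element`.
#' @export
duplicated_element <- function(genome, name, copy1, copy2) {
  genome <- as_dss(genome)
  stopifnot(inherits(copy1, "genomic_interval"),
            inherits(copy2, "genomic_interval"))
  s1 <- element_seq(genome, copy1)
  s2 <- element_seq(genome, copy2)
  if (!identical(s1, s2))
    stop("invalid element: the two copy intervals carry different sequences")
  if (identical(copy1$chrom, copy2$chrom) &&
      span_overlap(copy1$start, copy1$end, copy2$start, copy2$end) > 0)
    stop("invalid element: copy intervals overlap")
  structure(list(name = name, copies = list(copy1, copy2)),
            class = "duplicated_element")
}

element_seq <- function(genome, iv) {
  if (!iv$chrom %in% names(genome))
    stop("sequence '", iv$chrom, "' not found in genome")
  as.character(Biostrings::subseq(genome[[iv$chrom]], iv$start + 1L, iv$end))
}

#' Assign reads to one copy of a duplicated element
#'
#' Emulates a unique-mapping (high-MAPQ) filter without running an aligner:
#' a read is `unique` when at least `min_unique_kmers` of its k-mers hit the
#' genome-wide unique k-mer index and all such hits fall within a single
#' locus neighborhood (a copy interval padded by `pad` bp); it is
#' `ambiguous` when it matches the genome but carries too few unique
#' k-mers (every k-mer of a read lying fully inside the duplicated element
#' occurs twice, so such reads are always ambiguous); it is `unmapped` when
#' no k-mer of the read occurs in the genome at all. Sequencing errors can
#' only destroy unique k-mers, so errors degrade `unique` to `ambiguous`,
#' never to an assignment at the wrong copy.
#'
#' @param reads Named [Biostrings::DNAStringSet] of reads.
#' @param index Genome-wide [build_unique_index()] of the mutant genome
#'   (single-entry panel).
#' @param element A [duplicated_element()].
#' @param min_unique_kmers Minimum unique-k-mer hits for a `unique` call
#'   (default 1).
#' @param pad Neighborhood padding around each copy interval in bp
#'   (default 2000); unique hits outside both neighborhoods leave the read
#'   `unique` with locus `NA` (elsewhere in the genome).
#' @return Data frame with columns `read_id`, `status`
#'   (`unique`/`ambiguous`/`unmapped`), `locus` (1, 2 or `NA`) and
#'   `n_unique_kmers`.
#' @export
assign_reads <- function(reads, index, element, min_unique_kmers = 1L,
                         pad = 2000L) {
  stopifnot(inherits(index, "unique_kmer_index"),
            inherits(element, "duplicated_element"))
  if (min_unique_kmers < 1L) stop("min_unique_kmers must be >= 1")
  reads <- as_dss(reads)
  k <- index$k
  tab <- index$table
  n1 <- neighborhood(element$copies[[1L]], pad)
  n2 <- neighborhood(element$copies[[2L]], pad)
  nr <- length(reads)
  rs <- as.character(reads)
  rc <- as.character(Biostrings::reverseComplement(reads))
  nwin <- pmax(Biostrings::width(reads) - k + 1L, 0L)
  read_of <- rep(seq_len(nr), nwin)
  starts <- unlist(lapply(nwin, seq_len), use.names = FALSE)
  km_f <- substring(rs[read_of], starts, starts + k - 1L)
  km_r <- substring(rc[read_of], starts, starts + k - 1L)
  # one global lookup instead of per-read hashing
  hit_f <- match_windows(km_f, index)
  hit_r <- match_windows(km_r, index)
  hit_read <- c(read_of[hit_f$window], read_of[hit_r$window])
  hit_row <- c(hit_f$row, hit_r$row)
  n_unique <- tabulate(hit_read, nbins = nr)
  present_any <- km_f %in% index$all_kmers | km_r %in% index$all_kmers
  present <- tabulate(read_of[present_any], nbins = nr) > 0L | n_unique > 0L
  p <- tab$ref_offset[hit_row]
  rn <- tab$ref_name[hit_row]
  in1 <- rn == n1$chrom & p >= n1$start & p < n1$end
  in2 <- rn == n2$chrom & p >= n2$start & p < n2$end
  any1 <- tabulate(hit_read[in1], nbins = nr) > 0L
  any2 <- tabulate(hit_read[in2], nbins = nr) > 0L
  status <- ifelse(!present, "unmapped",
            ifelse(n_unique < min_unique_kmers | (any1 & any2),
                   "ambiguous", "unique"))
  locus <- ifelse(status == "unique" & any1, 1L,
           ifelse(status == "unique" & any2, 2L, NA_integer_))
  data.frame(read_id = names(reads), status = status,
             locus = as.integer(locus),
             n_unique_kmers = ifelse(status == "unmapped", 0L, n_unique),
             stringsAsFactors = FALSE)
}

neighborhood <- function(iv, pad) {
  list(chrom = iv$chrom, start = max(0, iv$start - pad), end = iv$end + pad)
}

#' Assign read pairs to one copy of a duplicated element
#'
#' Assigns each mate with [assign_reads()] and combines the calls. In
#' `"either-mate"` mode (the default, mirroring how a paired aligner
#' rescues an element-internal mate through its uniquely mapped partner) a
#' pair is `unique` as soon as one mate is; in `"both-mates"` mode both
#' mates must be unique and agree. Mates that are unique at conflicting
#' loci demote the pair to `ambiguous`.
#'
#' @param reads1,reads2 Named [Biostrings::DNAStringSet]s of the two mates,
#'   in pair order.
#' @inheritParams assign_reads
#' @param pair_mode `"either-mate"` or `"both-mates"`.
#' @return Data frame with `pair_id`, `status`, `locus`, `n_unique_kmers`
#'   (summed over mates).
#' @export
assign_read_pairs <- function(reads1, reads2, index, element,
                              pair_mode = c("either-mate", "both-mates"),
                              min_unique_kmers = 1L, pad = 2000L) {
  pair_mode <- match.arg(pair_mode)
  reads1 <- as_dss(reads1); reads2 <- as_dss(reads2)
  if (length(reads1) != length(reads2))
    stop("mate sets differ in length")
  a1 <- assign_reads(reads1, index, element, min_unique_kmers, pad)
  a2 <- assign_reads(reads2, index, element, min_unique_kmers, pad)
  combine <- function(s1, l1, s2, l2) {
    conflict <- !is.na(l1) && !is.na(l2) && l1 != l2
    if (pair_mode == "either-mate") {
      if ((s1 == "unique" || s2 == "unique") && !conflict) {
        locus <- if (s1 == "unique" && !is.na(l1)) l1
                 else if (s2 == "unique" && !is.na(l2)) l2
                 else NA_integer_
        return(list("unique", locus))
      }
      if (conflict) return(list("ambiguous", NA_integer_))
      if (s1 == "ambiguous" || s2 == "ambiguous")
        return(list("ambiguous", NA_integer_))
      list("unmapped", NA_integer_)
    } else {
      if (s1 == "unique" && s2 == "unique" && !conflict) {
        locus <- if (!is.na(l1)) l1 else l2
        return(list("unique", locus))
      }
      if (s1 == "unmapped" && s2 == "unmapped")
        return(list("unmapped", NA_integer_))
      list("ambiguous", NA_integer_)
    }
  }
  comb <- Map(combine, a1$status, a1$locus, a2$status, a2$locus)
  data.frame(pair_id = names(reads1),
             status = vapply(comb, `[[`, character(1), 1L),
             locus = vapply(comb, function(x) as.integer(x[[2L]]), integer(1)),
             n_unique_kmers = a1$n_unique_kmers + a2$n_unique_kmers,
             stringsAsFactors = FALSE)
}

#' Per-base coverage from uniquely assigned reads
#'
#' Piles up read (or fragment) placements over a region. Only placements
#' the caller has already filtered to unique assignments should be passed
#' in; the function itself is a plain pile-up.
#'
#' @param placements Data frame with 0-based half-open columns `start`,
#'   `end` (and optionally `chrom`).
#' @param region [genomic_interval()] to report over.
#' @return Integer vector of per-base coverage, one entry per base of
#'   `region`, with the region recorded in attributes `chrom` and `start`.
#' @export
coverage_track <- function(placements, region) {
  stopifnot(inherits(region, "genomic_interval"))
  if (nrow(placements) && "chrom" %in% names(placements))
    placements <- placements[placements$chrom == region$chrom, , drop = FALSE]
  width <- interval_length(region)
  if (!nrow(placements)) {
    cov <- integer(width)
  } else {
    clipped_start <- pmax(placements$start, region$start)
    clipped_end <- pmin(placements$end, region$end)
    keep <- clipped_end > clipped_start
    ir <- IRanges::IRanges(start = clipped_start[keep] - region$start + 1L,
                           end = clipped_end[keep] - region$start)
    cov <- as.integer(IRanges::coverage(ir, width = width))
  }
  attr(cov, "chrom") <- region$chrom
  attr(cov, "start") <- region$start
  cov
}

#' Write a coverage track as bedGraph
#'
#' @param track Integer coverage vector from [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  chrom <- attr(track, "chrom")
  start0 <- attr(track, "start")
  r <- rle(as.integer(track))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + starts + 1L,
                              end = start0 + ends),
    score = r$values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Filter fragment pairs overlapping a duplicated element
#'
#' Removes any fragment pair with an end lying fully inside one of the
#' element copies: such an end carries no flanking sequence and therefore
#' no unique k-mers, so the pair cannot be attributed to a copy. All other
#' pairs are retained unchanged.
#'
#' @param pairs Data frame with 0-based half-open columns `start1`, `end1`,
#'   `start2`, `end2` (fragment-end intervals on the mutant genome).
#' @param element A [duplicated_element()].
#' @return The retained rows of `pairs`, with the number removed in
#'   attribute `n_removed`.
#' @export
fragment_pair_filter <- function(pairs, element) {
  stopifnot(inherits(element, "duplicated_element"))
  inside_any <- function(s, e) {
    res <- rep(FALSE, length(s))
    for (cp in element$copies)
      res <- res | (s >= cp$start & e <= cp$end)
    res
  }
  drop <- inside_any(pairs$start1, pairs$end1) |
    inside_any(pairs$start2, pairs$end2)
  out <- pairs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  out
}
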