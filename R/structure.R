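#' Chain anchors of one read into collinear segments
#'
#' Mechanizes the visual reading of a dot plot: anchors are swept left to
#' right along the read and an anchor extends the current segment when it
#' shares the reference and strand of the previous anchor, lies within
#' `max_gap` bp on the read, and stays within `max_diag_offset` bp of the
#' previous anchor's diagonal (`ref_offset - read_offset` on the forward
#' strand, `ref_offset + read_offset` on the reverse strand, so that indel
#' drift is measured locally). Chaining is performed independently per
#' reference; segments supported by fewer than `min_anchors` anchors are
#' discarded.
#'
#' @param anchors Anchor data frame for a single read (see [scan_read()]).
#' @param max_diag_offset Maximum local diagonal drift in bp (default 50).
#' @param max_gap Maximum read-offset gap between consecutive anchors of a
#'   segment (default 500).
#' @param min_anchors Minimum anchors per reported segment (default 3).
#' @param k Anchor k-mer length, used to close segment ends over the final
#'   window; recovered from the `k` attribute of `anchors` when present.
#' @return A data frame of segments ordered by read start, with columns
#'   `read_id`, `ref_name`, `strand`, `read_start`, `read_end`,
#'   `ref_start`, `ref_end` (0-based half-open, `read_end`/`ref_end`
#'   include the final k-mer) and `n_anchors`. The `k` used is recovered
#'   from the attribute `k` if present on `anchors`, else 20.
#' @export
chain_anchors <- function(anchors, max_diag_offset = 50L, max_gap = 500L,
                          min_anchors = 3L, k = attr(anchors, "k") %||% 20L) {
  if (!nrow(anchors)) return(empty_segments())
  if (length(unique(anchors$read_id)) > 1L)
    stop("chain_anchors expects anchors from a single read")
  out <- lapply(split(anchors, anchors$ref_name), function(a) {
    a <- a[order(a$read_offset, a$ref_offset), , drop = FALSE]
    sign <- ifelse(a$strand == "+", 1, -1)
    diag <- a$ref_offset - sign * a$read_offset
    n <- nrow(a)
    brk <- if (n > 1L) {
      gap <- diff(a$read_offset)
      same <- a$strand[-1L] == a$strand[-n]
      drift <- abs(diff(diag))
      c(TRUE, !same | gap > max_gap | drift > max_diag_offset)
    } else TRUE
    grp <- cumsum(brk)
    do.call(rbind, lapply(split(seq_len(n), grp), function(i) {
      s <- a[i, , drop = FALSE]
      plus <- s$strand[1L] == "+"
      data.frame(
        read_id = s$read_id[1L], ref_name = s$ref_name[1L],
        strand = s$strand[1L],
        read_start = min(s$read_offset), read_end = max(s$read_offset) + k,
        ref_start = if (plus) s$ref_offset[1L] else min(s$ref_offset),
        ref_end = (if (plus) s$ref_offset[nrow(s)] else max(s$ref_offset)) + k,
        n_anchors = nrow(s), stringsAsFactors = FALSE)
    }))
  })
  seg <- do.call(rbind, out)
  seg <- seg[seg$n_anchors >= min_anchors, , drop = FALSE]
  seg <- seg[order(seg$read_start, seg$read_end), , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

empty_segments <- function() {
  data.frame(read_id = character(0), ref_name = character(0),
             strand = character(0), read_start = integer(0),
             read_end = integer(0), ref_start = integer(0),
             ref_end = integer(0), n_anchors = integer(0),
             stringsAsFactors = FALSE)
}

#' Per-read architecture: segments plus typed junctions
#'
#' Chains the anchors of one read (see [chain_anchors()]) and classifies
#' every junction between consecutive segments as `colinear-gap`,
#' `deletion`, `insertion`, `inversion` or `copy-junction`. A junction is an
#' inversion when the strands differ; on a shared strand, a backward jump
#' of the reference beyond `gap_tol` marks a copy junction (the read
#' re-enters the same reference interval, as in a tandem array), while an
#' excess of reference over read gap (or vice versa) beyond `gap_tol`
#' marks a deletion (or insertion) relative to the reference.
#'
#' @inheritParams chain_anchors
#' @param read_length Length of the read in bp (used for coverage
#'   fractions by [classify_read()]).
#' @param gap_tol Slack in bp before a gap difference is called a junction
#'   type other than `colinear-gap` (default 200, sized for nanopore indel
#'   noise).
#' @return An object of class `read_architecture`: list with `read_id`,
#'   `read_length`, `segments` (data frame) and `junctions` (data frame
#'   with `left`, `right` segment indexes, `type` and `orientation`).
#' @export
read_architecture <- function(anchors, read_length,
                              max_diag_offset = 50L, max_gap = 500L,
                              min_anchors = 3L, gap_tol = 200L,
                              k = attr(anchors, "k") %||% 20L,
                              read_id = NULL) {
  seg <- chain_anchors(anchors, max_diag_offset = max_diag_offset,
                       max_gap = max_gap, min_anchors = min_anchors, k = k)
  rid <- read_id %||% (if (nrow(anchors)) anchors$read_id[1L] else NA_character_)
  jn <- if (nrow(seg) > 1L) {
    do.call(rbind, lapply(seq_len(nrow(seg) - 1L), function(i) {
      a <- seg[i, ]; b <- seg[i + 1L, ]
      data.frame(left = i, right = i + 1L,
                 type = junction_type(a, b, gap_tol),
                 orientation = paste0(a$strand, b$strand),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(left = integer(0), right = integer(0), type = character(0),
               orientation = character(0), stringsAsFactors = FALSE)
  }
  structure(list(read_id = rid, read_length = read_length,
                 segments = seg, junctions = jn),
            class = "read_architecture")
}

junction_type <- function(a, b, gap_tol) {
  if (!identical(a$ref_name, b$ref_name)) return("copy-junction")
  if (a$strand != b$strand) return("inversion")
  read_gap <- b$read_start - a$read_end
  ref_delta <- if (a$strand == "+") b$ref_start - a$ref_end
               else a$ref_start - b$ref_end
  if (ref_delta < -gap_tol) return("copy-junction")
  if (ref_delta - read_gap > gap_tol) return("deletion")
  if (read_gap - ref_delta > gap_tol) return("insertion")
  "colinear-gap"
}

#' @export
print.read_architecture <- function(x, ...) {
  cat(sprintf("read_architecture %s (%d bp): %d segment(s), %d junction(s)\n",
              x$read_id, x$read_length, nrow(x$segments), nrow(x$junctions)))
  if (nrow(x$segments)) print(x$segments)
  invisible(x)
}

# Coalesce read-adjacent segments that continue the same collinear block
# (same reference, same strand, colinear-gap junction): an anchor dearth
# longer than max_gap splits one copy into several segments, which must
# not be counted as separate copies. Copy junctions, inversions and
# deletions/insertions are never merged.
merge_collinear_segments <- function(seg, gap_tol = 200L) {
  if (nrow(seg) < 2L) return(seg)
  seg <- seg[order(seg$read_start), , drop = FALSE]
  grp <- integer(nrow(seg))
  grp[1L] <- 1L
  for (i in 2:nrow(seg)) {
    a <- seg[i - 1L, ]; b <- seg[i, ]
    joinable <- identical(a$ref_name, b$ref_name) &&
      a$strand == b$strand &&
      junction_type(a, b, gap_tol) == "colinear-gap"
    grp[i] <- if (joinable) grp[i - 1L] else grp[i - 1L] + 1L
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(seg)), grp), function(i) {
    s <- seg[i, , drop = FALSE]
    data.frame(read_id = s$read_id[1L], ref_name = s$ref_name[1L],
               strand = s$strand[1L],
               read_start = min(s$read_start), read_end = max(s$read_end),
               ref_start = min(s$ref_start), ref_end = max(s$ref_end),
               n_anchors = sum(s$n_anchors), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Flag which segments of an architecture count as transgene-construct
# copies. A segment counts when its overlap with the construct interval
# reaches 50% of the shorter of (segment span, construct length) -- so a
# read tiling flank-construct-flank as one collinear segment still counts
# one copy -- and at least `min_copy_fraction` of the construct length, so
# that sub-30% truncated edge copies are flagged but not counted.
copy_flags <- function(segments, construct_interval, min_copy_fraction = 0.3) {
  ci <- construct_interval
  on_ref <- segments$ref_name == ci$chrom
  ov <- span_overlap(segments$ref_start, segments$ref_end, ci$start, ci$end)
  cw <- ci$end - ci$start
  sw <- segments$ref_end - segments$ref_start
  counted <- on_ref & ov >= 0.5 * pmin(sw, cw) & ov >= min_copy_fraction * cw
  truncated <- on_ref & ov > 0 & !counted
  list(counted = counted, truncated = truncated, overlap = ov)
}

#' Count construct copies observed in one read
#'
#' Returns the number of chained segments of a read that represent a copy
#' of the targeting construct: segments whose reference span overlaps the
#' construct interval by at least half of the shorter of the two spans.
#' Truncated terminal copies shorter than `min_copy_fraction` of the
#' construct are flagged but not counted, matching the conservative
#' "minimum copy number" framing of tandem-array reconstruction.
#'
#' @param arch A [read_architecture()].
#' @param construct_interval [genomic_interval()] of the construct on the
#'   expected-mutant (or vector) reference.
#' @param min_copy_fraction Minimum fraction of the construct a segment
#'   must cover to count as a copy (default 0.3).
#' @param gap_tol Junction slack used when coalescing split collinear
#'   segments before counting (default 200).
#' @return Integer copy count.
#' @export
count_copies_in_read <- function(arch, construct_interval,
                                 min_copy_fraction = 0.3, gap_tol = 200L) {
  stopifnot(inherits(arch, "read_architecture"),
            inherits(construct_interval, "genomic_interval"))
  seg <- merge_collinear_segments(arch$segments, gap_tol)
  if (!nrow(seg)) return(0L)
  sum(copy_flags(seg, construct_interval, min_copy_fraction)$counted)
}

#' Classify a read against the expected allele models
#'
#' Labels a read by the architecture it shows on the expected single-copy
#' mutant reference: `WT` for a purely collinear chain without construct
#' copies (a construct-sized deletion junction, i.e. a read spanning the
#' integration site without the insert, is still `WT`); `expected_knockin`
#' for exactly one construct copy without inversion or copy junctions;
#' `multi_copy` for two or more copies, or one copy plus an inversion or
#' copy junction (direct evidence of a second copy); `ambiguous` when the
#' chained segments cover less than `min_classify_fraction` of the read;
#' `unclassified` otherwise.
#'
#' @inheritParams count_copies_in_read
#' @param min_classify_fraction Minimum fraction of the read covered by
#'   segments for a confident call (default 0.5).
#' @return One of `"WT"`, `"expected_knockin"`, `"multi_copy"`,
#'   `"ambiguous"`, `"unclassified"`.
#' @export
classify_read <- function(arch, construct_interval,
                          min_classify_fraction = 0.5,
                          min_copy_fraction = 0.3, gap_tol = 200L) {
  stopifnot(inherits(arch, "read_architecture"))
  seg <- arch$segments
  covered <- sum(pmax(0, seg$read_end - seg$read_start))
  if (!nrow(seg) || covered < min_classify_fraction * arch$read_length)
    return("ambiguous")
  m <- count_copies_in_read(arch, construct_interval, min_copy_fraction,
                            gap_tol)
  jn <- arch$junctions
  structural <- sum(jn$type %in% c("inversion", "copy-junction"))
  if (m == 0L) {
    ok <- all(jn$type %in% c("colinear-gap", "deletion", "insertion")) &&
      length(unique(seg$strand)) == 1L
    return(if (ok) "WT" else "unclassified")
  }
  if (m >= 2L || (m >= 1L && structural >= 1L)) return("multi_copy")
  if (m == 1L) return("expected_knockin")
  "unclassified"
}

# Orientation evidence of one read: the strand string of its counted copy
# segments in read order, plus flank anchoring. `anchored_first`/
# `anchored_last` say whether the first/last copy observation is read-
# adjacent to reference flank beyond the construct boundary, and
# `first_boundary`/`last_boundary` record which side ("L" left of the
# construct, "R" right of it). A flank anchor only constrains pattern
# matching when the adjacent copy itself was counted.
copy_evidence <- function(arch, construct_interval, margin = 200L,
                          gap_tol = 200L, adjacency_tol = 1000L,
                          min_copy_fraction = 0.3) {
  ci <- construct_interval
  seg <- merge_collinear_segments(arch$segments, gap_tol)
  seg <- seg[seg$ref_name == ci$chrom, , drop = FALSE]
  ev <- list(ostr = character(0), anchored_first = FALSE,
             first_boundary = NA_character_, anchored_last = FALSE,
             last_boundary = NA_character_)
  if (!nrow(seg)) return(ev)
  seg <- seg[order(seg$read_start), , drop = FALSE]
  fl <- copy_flags(seg, ci, min_copy_fraction)
  idx <- which(fl$counted)
  ev$ostr <- seg$strand[idx]
  if (!length(idx)) return(ev)
  touches_left <- seg$ref_start <= ci$start - margin &
    seg$ref_end >= ci$start - gap_tol
  touches_right <- seg$ref_end >= ci$end + margin &
    seg$ref_start <= ci$end + gap_tol
  first <- idx[1L]; last <- idx[length(idx)]
  # a counted copy segment can itself extend into flank (merged segment);
  # which flank sits at its read-start vs read-end side depends on strand
  anchor_at <- function(copy_i, side_before) {
    plus <- seg$strand[copy_i] == "+"
    self_bound <- if (side_before) {
      if (plus && touches_left[copy_i]) "L"
      else if (!plus && touches_right[copy_i]) "R"
      else NA_character_
    } else {
      if (plus && touches_right[copy_i]) "R"
      else if (!plus && touches_left[copy_i]) "L"
      else NA_character_
    }
    if (!is.na(self_bound)) return(self_bound)
    cand <- if (side_before) rev(seq_len(copy_i - 1L)) else
      if (copy_i < nrow(seg)) seq.int(copy_i + 1L, nrow(seg)) else integer(0)
    for (j in cand) {
      gap <- if (side_before) seg$read_start[copy_i] - seg$read_end[j]
             else seg$read_start[j] - seg$read_end[copy_i]
      if (gap > adjacency_tol) next
      if (touches_left[j]) return("L")
      if (touches_right[j]) return("R")
    }
    NA_character_
  }
  b <- anchor_at(first, side_before = TRUE)
  if (!is.na(b)) { ev$anchored_first <- TRUE; ev$first_boundary <- b }
  b <- anchor_at(last, side_before = FALSE)
  if (!is.na(b)) { ev$anchored_last <- TRUE; ev$last_boundary <- b }
  ev
}

flip_strand <- function(x) chartr("+-", "-+", x)

# Does an orientation pattern (character vector over +/-) explain one
# read's evidence? The read may come from either genome strand, so the
# observed string must occur as a contiguous substring of the pattern
# (forward frame) or of its reverse-flip (reverse frame); flank anchors pin
# the match to the pattern ends and rule out the geometrically impossible
# frame.
pattern_consistent <- function(pattern, ev) {
  m <- length(ev$ostr)
  if (m == 0L) return(TRUE)
  try_frame <- function(pat, start_bound, end_bound) {
    # start_bound/end_bound: boundary letter that anchors the start/end of
    # the observation in this frame, or NA
    n <- length(pat)
    if (m > n) return(FALSE)
    starts <- seq_len(n - m + 1L)
    if (isTRUE(ev$anchored_first)) {
      if (!identical(ev$first_boundary, start_bound)) return(FALSE)
      starts <- starts[starts == 1L]
    }
    if (isTRUE(ev$anchored_last)) {
      if (!identical(ev$last_boundary, end_bound)) return(FALSE)
      starts <- starts[starts == n - m + 1L]
    }
    for (s in starts)
      if (all(pat[s:(s + m - 1L)] == ev$ostr)) return(TRUE)
    FALSE
  }
  fwd <- try_frame(pattern, "L", "R")
  rc <- try_frame(rev(flip_strand(pattern)), "R", "L")
  fwd || rc
}

#' Infer the allele configuration from a set of read architectures
#'
#' Aggregates per-read evidence into a copy-number/orientation call for the
#' allele. The copy-count floor is the maximum [count_copies_in_read()]
#' over all reads; it is then refined upward by junction stitching:
#' orientation patterns of increasing length `n` (up to `n_max`) are
#' enumerated exhaustively (2^n at this scale) and the smallest `n` for
#' which some pattern explains every read's ordered copy observations --
#' in either read frame, respecting flank anchoring -- is reported as the
#' minimum copy number, together with all co-optimal patterns in
#' lexicographic order (`+` before `-`). The call never exceeds the
#' evidence: reads spanning at most `m` consecutive copies can only
#' support a minimum, matching the "minimum of four copies" style of
#' conclusion this analysis is designed to reproduce.
#'
#' @param archs List of [read_architecture()] objects.
#' @param construct_interval [genomic_interval()] of the construct on the
#'   expected-mutant reference.
#' @param n_max Cap on the pattern enumeration (default 8).
#' @param margin,gap_tol,adjacency_tol,min_copy_fraction,min_classify_fraction
#'   See [copy_evidence()], [count_copies_in_read()] and [classify_read()].
#' @return An object of class `allele_configuration`: list with
#'   `copy_count_min`, `orientation_pattern` (string such as `"++-+"`,
#'   empty when no insertion), `patterns_all`, `class` (one of
#'   `no_insertion`, `single_copy_knockin`, `multi_copy_tandem`,
#'   `inconsistent`), `junction_support`, `read_labels` and `n_reads`.
#' @export
infer_configuration <- function(archs, construct_interval, n_max = 8L,
                                margin = 200L, gap_tol = 200L,
                                adjacency_tol = 1000L,
                                min_copy_fraction = 0.3,
                                min_classify_fraction = 0.5) {
  if (!length(archs)) stop("no read architectures supplied")
  stopifnot(all(vapply(archs, inherits, logical(1), "read_architecture")))
  counts <- vapply(archs, count_copies_in_read, integer(1),
                   construct_interval = construct_interval,
                   min_copy_fraction = min_copy_fraction, gap_tol = gap_tol)
  labels <- vapply(archs, classify_read, character(1),
                   construct_interval = construct_interval,
                   min_classify_fraction = min_classify_fraction,
                   min_copy_fraction = min_copy_fraction, gap_tol = gap_tol)
  jn <- unlist(lapply(archs, function(a) a$junctions$type), use.names = FALSE)
  junction_support <- table(factor(jn, levels = c("colinear-gap", "deletion",
                                                  "insertion", "inversion",
                                                  "copy-junction")))
  floor_n <- max(counts)
  result <- list(copy_count_min = as.integer(floor_n),
                 orientation_pattern = "",
                 patterns_all = character(0),
                 class = "no_insertion",
                 junction_support = junction_support,
                 read_labels = table(factor(labels, levels = c(
                   "WT", "expected_knockin", "multi_copy", "ambiguous",
                   "unclassified"))),
                 n_reads = length(archs))
  if (floor_n == 0L) {
    class(result) <- "allele_configuration"
    return(result)
  }
  evs <- lapply(archs, copy_evidence, construct_interval = construct_interval,
                margin = margin, gap_tol = gap_tol,
                adjacency_tol = adjacency_tol,
                min_copy_fraction = min_copy_fraction)
  evs <- Filter(function(e) length(e$ostr) > 0L, evs)
  found <- NULL
  for (n in seq.int(floor_n, n_max)) {
    pats <- orientation_patterns(n)
    ok <- vapply(pats, function(p) all(vapply(evs, function(e)
      pattern_consistent(p, e), logical(1))), logical(1))
    if (any(ok)) {
      found <- list(n = n, patterns = pats[ok])
      break
    }
  }
  if (is.null(found)) {
    result$class <- "inconsistent"
  } else {
    result$copy_count_min <- as.integer(found$n)
    result$patterns_all <- vapply(found$patterns, paste, character(1),
                                  collapse = "")
    result$orientation_pattern <- result$patterns_all[1L]
    result$class <- if (found$n >= 2L) "multi_copy_tandem"
                    else "single_copy_knockin"
  }
  class(result) <- "allele_configuration"
  result
}

# All +/- patterns of length n in lexicographic order with + < -.
orientation_patterns <- function(n) {
  grid <- do.call(expand.grid,
                  c(rev(rep(list(c("+", "-")), n)),
                    list(stringsAsFactors = FALSE)))
  grid <- grid[, rev(seq_len(n)), drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) as.character(unlist(grid[i, ])))
}

#' @export
print.allele_configuration <- function(x, ...) {
  cat(sprintf("allele_configuration: class=%s, copy_count_min=%d, pattern=%s (%d co-optimal)\n",
              x$class, x$copy_count_min,
              if (nzchar(x$orientation_pattern)) x$orientation_pattern else "-",
              length(x$patterns_all)))
  cat("read labels:\n")
  print(x$read_labels)
  invisible(x)
}

#' Write per-read architectures as TSV
#'
#' One row per segment, with junction types to the following segment in the
#' `junction_to_next` column.
#'
#' @param archs List of [read_architecture()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_architectures <- function(archs, path) {
  rows <- lapply(archs, function(a) {
    if (!nrow(a$segments)) return(NULL)
    df <- a$segments
    df$junction_to_next <- c(a$junctions$type, NA_character_)
    df
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- cbind(empty_segments(),
                                 junction_to_next = character(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
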