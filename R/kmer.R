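#' Build a unique k-mer index over a reference panel
#'
#' Enumerates every k-mer of every panel sequence and keeps only those that
#' occur exactly once across the whole panel counting both strands. Such
#' k-mers place a read window unambiguously, which is what makes them usable
#' as anchors when comparing noisy long reads against wild-type, expected
#' mutant and vector references at once. k-mers containing `N` are never
#' stored, and a k-mer equal to its own reverse complement is excluded
#' because its strand would be undecidable (with both strands counted such
#' a k-mer can in fact never reach a count of one).
#'
#' @param panel Named [Biostrings::DNAStringSet] (or named character vector)
#'   of reference sequences, e.g. wild-type locus, expected mutant locus and
#'   cloning vector.
#' @param k Window length in bp; the verification default is 20.
#' @param scope `"global"` (default) requires uniqueness across the whole
#'   panel; `"per_entry"` computes uniqueness within each panel entry
#'   separately, in which case one k-mer may anchor to several entries.
#' @return An object of class `unique_kmer_index` with fields `k`, `scope`,
#'   `table` (data frame `kmer`, `ref_name`, `ref_offset` with 0-based
#'   offsets), `ref_lengths`, and `all_kmers` (every distinct forward k-mer
#'   of the panel, used for presence queries).
#' @export
build_unique_index <- function(panel, k = 20L, scope = c("global", "per_entry")) {
  scope <- match.arg(scope)
  panel <- as_dss(panel)
  k <- as.integer(k)
  if (k < 8L)
    stop("k must be at least 8")
  lens <- Biostrings::width(panel)
  if (all(lens < k)) {
    warning("all panel sequences are shorter than k; index is empty")
    empty <- data.frame(kmer = character(0), ref_name = character(0),
                        ref_offset = integer(0), stringsAsFactors = FALSE)
    return(new_kmer_index(k, scope, empty, stats::setNames(lens, names(panel)),
                          character(0)))
  }
  per_entry <- lapply(seq_along(panel), function(i) {
    L <- lens[i]
    if (L < k) {
      return(data.frame(kmer = character(0), ref_name = character(0),
                        ref_offset = integer(0), stringsAsFactors = FALSE))
    }
    s <- as.character(panel[[i]])
    pos <- seq_len(L - k + 1L)
    km <- substring(s, pos, pos + k - 1L)
    ok <- !grepl("[^ACGT]", km)
    data.frame(kmer = km[ok], ref_name = names(panel)[i],
               ref_offset = pos[ok] - 1L, stringsAsFactors = FALSE)
  })
  filter_unique <- function(df) {
    if (!nrow(df)) return(df)
    u <- unique(df$kmer)
    cF <- tabulate(match(df$kmer, u), nbins = length(u))
    rc_u <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(u)))
    idx <- match(rc_u, u)
    cR <- ifelse(is.na(idx), 0L, cF[idx])
    keep <- u[cF + cR == 1L]
    df[df$kmer %in% keep, , drop = FALSE]
  }
  all_fwd <- unique(unlist(lapply(per_entry, `[[`, "kmer"), use.names = FALSE))
  tab <- if (scope == "global") {
    filter_unique(do.call(rbind, per_entry))
  } else {
    do.call(rbind, lapply(per_entry, filter_unique))
  }
  tab <- tab[order(tab$kmer), , drop = FALSE]
  rownames(tab) <- NULL
  if (!nrow(tab))
    warning("no unique k-mers found; index is empty")
  new_kmer_index(k, scope, tab, stats::setNames(lens, names(panel)), all_fwd)
}

new_kmer_index <- function(k, scope, tab, ref_lengths, all_kmers) {
  # run-length lookup so per-entry indexes can map one k-mer to several rows
  kmers <- unique(tab$kmer)
  row_start <- match(kmers, tab$kmer)
  row_count <- tabulate(match(tab$kmer, kmers), nbins = length(kmers))
  structure(list(k = k, scope = scope, table = tab, kmers = kmers,
                 row_start = row_start, row_count = row_count,
                 ref_lengths = ref_lengths, all_kmers = all_kmers),
            class = "unique_kmer_index")
}

#' @export
print.unique_kmer_index <- function(x, ...) {
  cat(sprintf("unique_kmer_index: k=%d, scope=%s, %d unique k-mers over %d reference(s)\n",
              x$k, x$scope, nrow(x$table), length(x$ref_lengths)))
  invisible(x)
}

# Match a character vector of windows against the index; returns a data
# frame of (window_idx, row) hits, covering multi-row k-mers.
match_windows <- function(windows, index) {
  m <- match(windows, index$kmers)
  hit <- which(!is.na(m))
  if (!length(hit))
    return(data.frame(window = integer(0), row = integer(0)))
  starts <- index$row_start[m[hit]]
  counts <- index$row_count[m[hit]]
  data.frame(window = rep(hit, counts),
             row = unlist(lapply(seq_along(hit), function(i)
               seq.int(starts[i], length.out = counts[i])), use.names = FALSE))
}

#' Anchor a read against a unique k-mer index
#'
#' Samples `k`-bp windows of the read every `step` bases (window phase fixed
#' at read offset 0) and reports an anchor wherever the window string, or
#' its reverse complement, hits the unique index. The verification protocol
#' tests 20-bp read windows on a 5-bp stride and keeps only windows exactly
#' identical to a unique reference 20-mer.
#'
#' @param read A `DNAString`, or single character string; reads shorter than
#'   `k` yield an empty anchor table (not an error).
#' @param index A [build_unique_index()] result.
#' @param step Sampling stride in bp (default 5).
#' @param read_id Identifier recorded with every anchor.
#' @return A data frame of anchors ordered by read offset, with columns
#'   `read_id`, `read_offset`, `ref_name`, `ref_offset` (both 0-based) and
#'   `strand` (`"+"`/`"-"`).
#' @export
scan_read <- function(read, index, step = 5L, read_id = "read") {
  stopifnot(inherits(index, "unique_kmer_index"))
  step <- as.integer(step)
  if (step < 1L) stop("step must be >= 1")
  s <- toupper(as.character(read))
  L <- nchar(s)
  k <- index$k
  if (L < k) return(empty_anchors())
  offsets <- seq.int(0L, L - k, by = step)
  windows <- substring(s, offsets + 1L, offsets + k)
  fwd <- match_windows(windows, index)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(windows)))
  rev <- match_windows(rc, index)
  tab <- index$table
  out <- rbind(
    if (nrow(fwd)) data.frame(read_id = read_id,
                              read_offset = offsets[fwd$window],
                              ref_name = tab$ref_name[fwd$row],
                              ref_offset = tab$ref_offset[fwd$row],
                              strand = "+", stringsAsFactors = FALSE),
    if (nrow(rev)) data.frame(read_id = read_id,
                              read_offset = offsets[rev$window],
                              ref_name = tab$ref_name[rev$row],
                              ref_offset = tab$ref_offset[rev$row],
                              strand = "-", stringsAsFactors = FALSE))
  if (is.null(out)) return(empty_anchors())
  out <- out[order(out$read_offset, out$ref_name, out$ref_offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_anchors <- function() {
  data.frame(read_id = character(0), read_offset = integer(0),
             ref_name = character(0), ref_offset = integer(0),
             strand = character(0), stringsAsFactors = FALSE)
}

#' Anchor a whole read set
#'
#' Applies [scan_read()] to every sequence of a read set and binds the
#' anchor tables.
#'
#' @param reads Named [Biostrings::DNAStringSet] (names become read ids).
#' @inheritParams scan_read
#' @return A single anchor data frame (see [scan_read()]).
#' @export
scan_reads <- function(reads, index, step = 5L) {
  reads <- as_dss(reads)
  out <- lapply(seq_along(reads), function(i)
    scan_read(reads[[i]], index, step = step, read_id = names(reads)[i]))
  out <- do.call(rbind, out)
  if (is.null(out)) empty_anchors() else out
}

#' Export and re-import anchor dot plots
#'
#' `export_dotplot` writes an anchor table as TSV with a fixed column order
#' and deterministic row order (ascending read offset); `read_dotplot`
#' parses such a file back into the anchor data frame, so that export
#' followed by import is the identity.
#'
#' @param anchors Anchor data frame from [scan_read()].
#' @param path File path.
#' @return `export_dotplot` returns `path` invisibly; `read_dotplot`
#'   returns an anchor data frame.
#' @export
export_dotplot <- function(anchors, path) {
  cols <- c("read_id", "read_offset", "ref_name", "ref_offset", "strand")
  stopifnot(all(cols %in% names(anchors)))
  anchors <- anchors[order(anchors$read_offset, anchors$ref_name,
                           anchors$ref_offset), cols, drop = FALSE]
  utils::write.table(anchors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname export_dotplot
#' @export
read_dotplot <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "character",
                                         "integer", "character"))
  rownames(df) <- NULL
  df
}

#' Draw a read-versus-reference dot plot
#'
#' Plots anchors of a single read as (read offset, reference offset) points,
#' one panel per reference, with forward anchors in blue and reverse
#' anchors in red. Diagonals indicate collinear blocks; anti-diagonals,
#' inversions.
#'
#' @param anchors Anchor data frame for one read.
#' @param file Optional PNG path; when given the plot is written there.
#' @param main Plot title.
#' @return Invisibly, the anchors.
#' @export
plot_dotplot <- function(anchors, file = NULL, main = unique(anchors$read_id)[1]) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  refs <- unique(anchors$ref_name)
  if (!length(refs)) {
    graphics::plot.new()
    graphics::title(main = paste(main, "(no anchors)"))
    return(invisible(anchors))
  }
  old <- graphics::par(mfrow = c(length(refs), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (r in refs) {
    a <- anchors[anchors$ref_name == r, , drop = FALSE]
    graphics::plot(a$read_offset, a$ref_offset,
                   col = ifelse(a$strand == "+", "#2166ac", "#b2182b"),
                   pch = 16, cex = 0.4, xlab = "read offset (bp)",
                   ylab = paste(r, "offset (bp)"),
                   main = if (r == refs[1]) main else "")
  }
  invisible(anchors)
}
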