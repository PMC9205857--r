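#' Genomic interval (0-based, half-open)
#'
#' Creates a genomic interval following the BED convention: `start` is
#' 0-based inclusive, `end` is exclusive, so the interval covers
#' `end - start` bases. Printed spans of the form `"chrN:a-b"` are ingested
#' with `start = a`, `end = b`; under this convention the enhancer span
#' chr2:74075311-74075843 has length `74075843 - 74075311 = 532` bp, matching
#' its printed size.
#'
#' @param chrom Sequence (chromosome) name.
#' @param start 0-based inclusive start offset.
#' @param end Exclusive end offset; must be greater than `start` (zero-length
#'   points are only legal as insertion targets, see [genome_edit()]).
#' @param allow_empty Internal switch permitting `start == end`; used by
#'   [genome_edit()] for insertion points.
#' @return An object of class `genomic_interval`.
#' @seealso [parse_region()], [interval_length()]
#' @examples
#' enh <- genomic_interval("chr2", 74075311, 74075843)
#' interval_length(enh) # 532
#' @export
genomic_interval <- function(chrom, start, end, allow_empty = FALSE) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("'start' and 'end' must be single non-missing numbers")
  if (start < 0)
    stop("invalid interval: start must be >= 0")
  if (end < start || (!allow_empty && end == start))
    stop(sprintf("invalid interval: %s:%s-%s is empty or reversed",
                 chrom, format(start, scientific = FALSE),
                 format(end, scientific = FALSE)))
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%d bp)\n", x$chrom,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              as.integer(x$end - x$start)))
  invisible(x)
}

#' Parse a printed region string into a genomic interval
#'
#' Accepts `"chr2:74075311-74075843"` as well as the comma-grouped form
#' `"chr2:74,075,311-74,075,843"` and en-dash separators as they appear in
#' print.
#'
#' @param region A single region string.
#' @inheritParams genomic_interval
#' @return A [genomic_interval()].
#' @export
parse_region <- function(region, allow_empty = FALSE) {
  stopifnot(is.character(region), length(region) == 1L)
  clean <- gsub(",", "", region, fixed = TRUE)
  clean <- gsub("–", "-", clean) # en dash
  m <- regmatches(clean, regexec("^([^:]+):([0-9]+)-([0-9]+)$", clean))[[1]]
  if (length(m) != 4L)
    stop("cannot parse region string: ", region)
  genomic_interval(m[2], as.numeric(m[3]), as.numeric(m[4]),
                   allow_empty = allow_empty)
}

#' Length of a genomic interval in base pairs
#'
#' @param interval A [genomic_interval()].
#' @return Integer number of bases, `end - start`.
#' @export
interval_length <- function(interval) {
  stopifnot(inherits(interval, "genomic_interval"))
  as.integer(interval$end - interval$start)
}

#' Distance between the start positions of two intervals
#'
#' Absolute difference between the start offsets of two intervals on the
#' same chromosome, e.g. the span between a native element and a distal
#' integration site.
#'
#' @param a,b [genomic_interval()] objects on the same chromosome.
#' @return Distance in base pairs (numeric).
#' @export
interval_start_distance <- function(a, b) {
  stopifnot(inherits(a, "genomic_interval"), inherits(b, "genomic_interval"))
  if (!identical(a$chrom, b$chrom))
    stop("intervals lie on different chromosomes: ", a$chrom, " vs ", b$chrom)
  abs(b$start - a$start)
}

# Overlap (bp) between two half-open numeric spans.
span_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}
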