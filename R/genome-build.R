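#' Describe a single genome edit
#'
#' A `genome_edit` records one breakpoint-exact modification of a host
#' sequence: a deletion, insertion, replacement or inversion. Targets use
#' the 0-based half-open convention of [genomic_interval()] and always refer
#' to original wild-type coordinates, never to coordinates shifted by other
#' edits of the same allele.
#'
#' @param kind One of `"deletion"`, `"insertion"`, `"replacement"`,
#'   `"inversion"`.
#' @param chrom Host sequence name.
#' @param start,end Target interval (0-based half-open). Insertions use a
#'   zero-length point with `start == end`; all other kinds require a
#'   non-empty target.
#' @param payload Nucleotide string over `A,C,G,T,N`; required for
#'   insertion and replacement, forbidden otherwise.
#' @param label Free-text label carried through to BED exports.
#' @return An object of class `genome_edit`.
#' @export
genome_edit <- function(kind, chrom, start, end, payload = NULL, label = "") {
  kind <- match.arg(kind, c("deletion", "insertion", "replacement", "inversion"))
  needs_payload <- kind %in% c("insertion", "replacement")
  if (needs_payload) {
    if (is.null(payload) || !nzchar(payload))
      stop(kind, " edits require a non-empty payload")
    payload <- toupper(as.character(payload))
    if (grepl("[^ACGTN]", payload))
      stop("payload contains characters outside A,C,G,T,N")
  } else if (!is.null(payload)) {
    stop(kind, " edits must not carry a payload")
  }
  target <- genomic_interval(chrom, start, end,
                             allow_empty = (kind == "insertion"))
  if (kind == "insertion" && target$end != target$start)
    stop("insertion targets must be zero-length points (start == end)")
  if (kind != "insertion" && target$end == target$start)
    stop(kind, " targets must be non-empty intervals")
  structure(list(kind = kind, target = target,
                 payload = if (needs_payload) payload else NA_character_,
                 label = as.character(label)),
            class = "genome_edit")
}

#' Allele specification: an ordered, non-overlapping set of edits
#'
#' Collects the exact breakpoints that turn a wild-type host sequence into
#' a mutant allele. Edits are sorted by target start and must not overlap;
#' all targets are interpreted against original wild-type coordinates.
#'
#' @param name Allele identifier, e.g. `"allele542"`.
#' @param host Host sequence name; every edit must target this sequence.
#' @param edits A list of [genome_edit()] objects (possibly empty).
#' @return An object of class `allele_spec` whose `$edits` element is a
#'   data frame with columns `kind`, `start`, `end`, `payload`, `label`.
#' @export
allele_spec <- function(name, host, edits = list()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(host), length(host) == 1L)
  if (inherits(edits, "genome_edit")) edits <- list(edits)
  if (!all(vapply(edits, inherits, logical(1), "genome_edit")))
    stop("'edits' must be a list of genome_edit objects")
  df <- if (length(edits)) {
    bad <- vapply(edits, function(e) !identical(e$target$chrom, host), logical(1))
    if (any(bad))
      stop("all edits must target the host sequence '", host, "'")
    data.frame(
      kind = vapply(edits, `[[`, character(1), "kind"),
      start = vapply(edits, function(e) e$target$start, numeric(1)),
      end = vapply(edits, function(e) e$target$end, numeric(1)),
      payload = vapply(edits, `[[`, character(1), "payload"),
      label = vapply(edits, `[[`, character(1), "label"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(kind = character(0), start = numeric(0), end = numeric(0),
               payload = character(0), label = character(0),
               stringsAsFactors = FALSE)
  }
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1L) {
    if (any(df$end[-nrow(df)] > df$start[-1L]))
      stop("edit targets overlap; targets must be pairwise disjoint")
  }
  structure(list(name = name, host = host, edits = df), class = "allele_spec")
}

#' @export
print.allele_spec <- function(x, ...) {
  cat(sprintf("allele_spec '%s' on %s: %d edit(s)\n",
              x$name, x$host, nrow(x$edits)))
  if (nrow(x$edits)) {
    show <- x$edits
    show$payload <- ifelse(is.na(show$payload), "",
                           paste0(substr(show$payload, 1, 12),
                                  ifelse(nchar(show$payload) > 12, "...", "")))
    print(show)
  }
  invisible(x)
}

#' Apply an allele specification to a wild-type genome
#'
#' Splices a mutant sequence out of the wild-type host by applying all edits
#' of an [allele_spec()] in coordinate order. Untouched bases are copied
#' verbatim (including `N`s), inversion targets are reverse-complemented in
#' place, and a [coordinate map][lift_position()] relating wild-type and
#' mutant offsets is returned alongside. The mutant length obeys
#' `|mutant| = |WT| - sum(deleted/replaced targets) + sum(payloads)`.
#'
#' @param genome A named [Biostrings::DNAStringSet] containing the host.
#' @param spec An [allele_spec()].
#' @return A list with elements `genome` (a `DNAStringSet` in which the host
#'   entry has been replaced by the mutant sequence) and `map` (a
#'   `coordinate_map`).
#' @export
apply_edits <- function(genome, spec) {
  stopifnot(inherits(spec, "allele_spec"))
  genome <- as_dss(genome)
  if (!spec$host %in% names(genome))
    stop("host sequence '", spec$host, "' not found in genome")
  wt <- genome[[spec$host]]
  L <- length(wt)
  ed <- spec$edits
  if (nrow(ed) && max(ed$end) > L)
    stop("edit target extends beyond host sequence bounds (length ", L, ")")

  pieces <- list()
  blocks <- list()   # aligned blocks: wt_start, wt_end, mut_start, mut_end, strand
  deleted <- list()  # wt-only
  inserted <- list() # mutant-only
  cursor <- 0
  mut_cursor <- 0
  push_block <- function(ws, we, ms, me, strand) {
    blocks[[length(blocks) + 1L]] <<- c(ws, we, ms, me, strand)
  }
  keep_segment <- function(from, to) {
    if (to > from) {
      pieces[[length(pieces) + 1L]] <<- Biostrings::subseq(wt, from + 1L, to)
      push_block(from, to, mut_cursor, mut_cursor + (to - from), "+")
      mut_cursor <<- mut_cursor + (to - from)
    }
  }
  for (i in seq_len(nrow(ed))) {
    keep_segment(cursor, ed$start[i])
    kind <- ed$kind[i]
    tlen <- ed$end[i] - ed$start[i]
    if (kind == "deletion") {
      deleted[[length(deleted) + 1L]] <- c(ed$start[i], ed$end[i], ed$label[i])
    } else if (kind == "insertion") {
      pl <- Biostrings::DNAString(ed$payload[i])
      pieces[[length(pieces) + 1L]] <- pl
      inserted[[length(inserted) + 1L]] <-
        c(mut_cursor, mut_cursor + length(pl), ed$label[i])
      mut_cursor <- mut_cursor + length(pl)
    } else if (kind == "replacement") {
      deleted[[length(deleted) + 1L]] <- c(ed$start[i], ed$end[i], ed$label[i])
      pl <- Biostrings::DNAString(ed$payload[i])
      pieces[[length(pieces) + 1L]] <- pl
      inserted[[length(inserted) + 1L]] <-
        c(mut_cursor, mut_cursor + length(pl), ed$label[i])
      mut_cursor <- mut_cursor + length(pl)
    } else if (kind == "inversion") {
      seg <- Biostrings::reverseComplement(
        Biostrings::subseq(wt, ed$start[i] + 1L, ed$end[i]))
      pieces[[length(pieces) + 1L]] <- seg
      push_block(ed$start[i], ed$end[i], mut_cursor, mut_cursor + tlen, "-")
      mut_cursor <- mut_cursor + tlen
    }
    cursor <- ed$end[i]
  }
  keep_segment(cursor, L)

  mut <- if (length(pieces)) do.call(Biostrings::xscat, pieces)
         else Biostrings::DNAString("")
  blk <- if (length(blocks)) {
    m <- do.call(rbind, blocks)
    data.frame(wt_start = as.numeric(m[, 1]), wt_end = as.numeric(m[, 2]),
               mut_start = as.numeric(m[, 3]), mut_end = as.numeric(m[, 4]),
               strand = m[, 5], stringsAsFactors = FALSE)
  } else {
    data.frame(wt_start = numeric(0), wt_end = numeric(0),
               mut_start = numeric(0), mut_end = numeric(0),
               strand = character(0), stringsAsFactors = FALSE)
  }
  del <- rows_to_df(deleted, c("wt_start", "wt_end", "label"))
  ins <- rows_to_df(inserted, c("mut_start", "mut_end", "label"))
  map <- structure(list(host = spec$host, allele = spec$name,
                        wt_length = L, mut_length = length(mut),
                        blocks = blk, deleted = del, inserted = ins),
                   class = "coordinate_map")
  out <- genome
  # replace host entry while preserving order and the other sequences
  out_list <- as.list(out)
  out_list[[spec$host]] <- mut
  out <- Biostrings::DNAStringSet(out_list)
  list(genome = out, map = map)
}

rows_to_df <- function(rows, cols) {
  if (!length(rows)) {
    df <- data.frame(a = numeric(0), b = numeric(0), label = character(0),
                     stringsAsFactors = FALSE)
    names(df) <- cols
    return(df)
  }
  m <- do.call(rbind, rows)
  df <- data.frame(as.numeric(m[, 1]), as.numeric(m[, 2]), m[, 3],
                   stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

#' @export
print.coordinate_map <- function(x, ...) {
  cat(sprintf("coordinate_map %s -> %s: WT %d bp, mutant %d bp, %d block(s), %d deleted, %d inserted\n",
              x$host, x$allele, x$wt_length, x$mut_length,
              nrow(x$blocks), nrow(x$deleted), nrow(x$inserted)))
  invisible(x)
}

#' Lift positions between wild-type and mutant coordinates
#'
#' Translates 0-based offsets across the edits recorded in a
#' `coordinate_map` (from [apply_edits()]). Positions inside deleted
#' wild-type segments, or inside mutant-only inserted sequence, cannot be
#' lifted and are returned as `NA` with a reason. Outside edited intervals
#' the mapping is bijective; positions inside inverted blocks map to the
#' mirrored offset on the other genome.
#'
#' @param map A `coordinate_map`.
#' @param position Vector of 0-based offsets on the source genome.
#' @param direction `"wt_to_mutant"` or `"mutant_to_wt"`.
#' @return A data frame with columns `position`, `lifted` (0-based offset or
#'   `NA`) and `reason` (`NA`, `"deleted"` or `"inserted-only"`).
#' @export
lift_position <- function(map, position,
                          direction = c("wt_to_mutant", "mutant_to_wt")) {
  stopifnot(inherits(map, "coordinate_map"))
  direction <- match.arg(direction)
  position <- as.numeric(position)
  src_len <- if (direction == "wt_to_mutant") map$wt_length else map$mut_length
  if (any(position < 0 | position >= src_len))
    stop("position out of bounds for source genome (length ", src_len, ")")
  blk <- map$blocks
  lifted <- rep(NA_real_, length(position))
  reason <- rep(NA_character_, length(position))
  if (direction == "wt_to_mutant") {
    s <- blk$wt_start; e <- blk$wt_end; os <- blk$mut_start; oe <- blk$mut_end
    hole <- map$deleted; hs <- hole$wt_start; he <- hole$wt_end
    hole_reason <- "deleted"
  } else {
    s <- blk$mut_start; e <- blk$mut_end; os <- blk$wt_start; oe <- blk$wt_end
    hole <- map$inserted; hs <- hole$mut_start; he <- hole$mut_end
    hole_reason <- "inserted-only"
  }
  for (i in seq_along(position)) {
    p <- position[i]
    j <- which(p >= s & p < e)
    if (length(j) == 1L) {
      if (blk$strand[j] == "+") {
        lifted[i] <- os[j] + (p - s[j])
      } else {
        lifted[i] <- os[j] + (e[j] - 1 - p)
      }
    } else if (any(p >= hs & p < he)) {
      reason[i] <- hole_reason
    } else {
      reason[i] <- hole_reason # unreachable for well-formed maps
    }
  }
  data.frame(position = position, lifted = lifted, reason = reason,
             stringsAsFactors = FALSE)
}

#' Build an allele specification for a homology-arm knock-in
#'
#' Expresses a targeted integration as a single edit: by default the host
#' segment lying between the two homology arms, `[left_ha$end,
#' right_ha$start)`, is replaced by the construct's inter-arm payload, which
#' is how homology-directed repair resolves a cut-site segment. Setting
#' `retain_target = TRUE` instead keeps the host segment and inserts the
#' payload at the point `left_ha$end`.
#'
#' @param genome Named [Biostrings::DNAStringSet] holding the host.
#' @param construct Nucleotide string (or `DNAString`): either the full
#'   targeting construct beginning with the left-arm sequence and ending
#'   with the right-arm sequence (`construct_contains_arms = TRUE`), or the
#'   inter-arm payload only.
#' @param left_ha,right_ha [genomic_interval()]s of the homology arms on the
#'   host; `left_ha$end` must not exceed `right_ha$start`.
#' @param name Allele name for the resulting [allele_spec()].
#' @param construct_contains_arms Whether `construct` includes the homology
#'   arms themselves.
#' @param retain_target Keep the inter-arm host segment and insert instead
#'   of replacing (see Details).
#' @param verify_arms When the construct contains its arms, check that they
#'   match the host sequence exactly (arms containing `N` never verify).
#' @return An [allele_spec()] with a single replacement (or insertion) edit.
#' @export
build_knockin_allele <- function(genome, construct, left_ha, right_ha, name,
                                 construct_contains_arms = FALSE,
                                 retain_target = FALSE,
                                 verify_arms = construct_contains_arms) {
  stopifnot(inherits(left_ha, "genomic_interval"),
            inherits(right_ha, "genomic_interval"))
  if (!identical(left_ha$chrom, right_ha$chrom))
    stop("homology arms must lie on the same host sequence")
  if (left_ha$end > right_ha$start)
    stop("homology arms overlap or are reversed: left_ha$end > right_ha$start")
  genome <- as_dss(genome)
  host <- left_ha$chrom
  if (!host %in% names(genome))
    stop("host sequence '", host, "' not found in genome")
  construct <- toupper(as.character(construct))
  if (construct_contains_arms) {
    ll <- interval_length(left_ha)
    rl <- interval_length(right_ha)
    if (nchar(construct) < ll + rl)
      stop("construct shorter than the two homology arms combined")
    if (verify_arms) {
      hseq <- genome[[host]]
      larm <- as.character(Biostrings::subseq(hseq, left_ha$start + 1L, left_ha$end))
      rarm <- as.character(Biostrings::subseq(hseq, right_ha$start + 1L, right_ha$end))
      if (grepl("N", larm, fixed = TRUE) || grepl("N", rarm, fixed = TRUE) ||
          !identical(substr(construct, 1L, ll), larm) ||
          !identical(substr(construct, nchar(construct) - rl + 1L,
                            nchar(construct)), rarm))
        stop("homology arm sequences do not match the host genome")
    }
    payload <- substr(construct, ll + 1L, nchar(construct) - rl)
  } else {
    payload <- construct
  }
  if (!nzchar(payload))
    stop("inter-arm payload is empty")
  edit <- if (retain_target || left_ha$end == right_ha$start) {
    genome_edit("insertion", host, left_ha$end, left_ha$end,
                payload = payload, label = name)
  } else {
    genome_edit("replacement", host, left_ha$end, right_ha$start,
                payload = payload, label = name)
  }
  allele_spec(name, host, list(edit))
}

# Coerce character / DNAString / DNAStringSet inputs to a named DNAStringSet.
as_dss <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    if (length(x) && is.null(names(x)))
      stop("genome DNAStringSet must be named")
    return(x)
  }
  if (inherits(x, "DNAString")) stop("supply a *named* DNAStringSet")
  if (is.character(x)) {
    if (length(x) && is.null(names(x)))
      stop("character genomes must be named")
    return(Biostrings::DNAStringSet(x))
  }
  stop("cannot interpret genome of class ", paste(class(x), collapse = "/"))
}
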