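#' Read and write genome FASTA files
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()] that fix the line width at 60 columns.
#'
#' @param path File path.
#' @param genome Named [Biostrings::DNAStringSet].
#' @return `read_genome_fasta` returns a `DNAStringSet`;
#'   `write_genome_fasta` returns `path` invisibly.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  # keep only the first whitespace-delimited token of each header
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname read_genome_fasta
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_dss(genome), filepath = path, width = 60L)
  invisible(path)
}

#' Serialize an allele specification
#'
#' `write_allele_spec` stores an [allele_spec()] as a YAML document carrying
#' the name, host and the full edit table (including payload sequences).
#' `write_edits_bed` additionally exports the edit targets as BED6, with the
#' edit label in the name column and strand `-` marking inversions.
#' `read_allele_spec` round-trips the YAML form.
#'
#' @param spec An [allele_spec()].
#' @param path Output (or input) file path.
#' @return `read_allele_spec` returns an [allele_spec()]; the writers return
#'   `path` invisibly.
#' @export
write_allele_spec <- function(spec, path) {
  stopifnot(inherits(spec, "allele_spec"))
  ed <- spec$edits
  doc <- list(
    name = spec$name,
    host = spec$host,
    edits = lapply(seq_len(nrow(ed)), function(i) {
      e <- list(kind = ed$kind[i], start = ed$start[i], end = ed$end[i],
                label = ed$label[i])
      if (!is.na(ed$payload[i])) e$payload <- ed$payload[i]
      e
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_allele_spec
#' @export
read_allele_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  edits <- lapply(doc$edits, function(e) {
    genome_edit(e$kind, doc$host, e$start, e$end,
                payload = e$payload, label = e$label %||% "")
  })
  allele_spec(doc$name, doc$host, edits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_allele_spec
#' @export
write_edits_bed <- function(spec, path) {
  stopifnot(inherits(spec, "allele_spec"))
  ed <- spec$edits
  gr <- GenomicRanges::GRanges(
    seqnames = spec$host,
    ranges = IRanges::IRanges(start = ed$start + 1, end = ed$end),
    strand = ifelse(ed$kind == "inversion", "-", "+"))
  gr$name <- ifelse(nzchar(ed$label), ed$label, ed$kind)
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export a coordinate map as a UCSC chain file
#'
#' Writes the collinear blocks of a `coordinate_map` (from [apply_edits()])
#' in UCSC chain format with the wild-type sequence as target and the mutant
#' as query. Runs of same-orientation blocks become one chain with `dt`/`dq`
#' gaps; each inverted block is emitted as its own minus-strand chain with
#' query coordinates expressed on the reverse strand, as the format
#' requires.
#'
#' @param map A `coordinate_map`.
#' @param path Output file path.
#' @param target_name,query_name Sequence names to print; default to the
#'   host name and `<host>_<allele>`.
#' @return `path`, invisibly.
#' @export
write_chain <- function(map, path, target_name = map$host,
                        query_name = paste0(map$host, "_", map$allele)) {
  stopifnot(inherits(map, "coordinate_map"))
  blk <- map$blocks
  con <- file(path, "w")
  on.exit(close(con))
  chain_id <- 0L
  emit_plus_run <- function(rows) {
    chain_id <<- chain_id + 1L
    first <- rows[1L, ]; last <- rows[nrow(rows), ]
    cat(sprintf("chain %d %s %d + %d %d %s %d + %d %d %d\n",
                1000L, target_name, map$wt_length,
                as.integer(first$wt_start), as.integer(last$wt_end),
                query_name, map$mut_length,
                as.integer(first$mut_start), as.integer(last$mut_end),
                chain_id), file = con)
    for (i in seq_len(nrow(rows))) {
      size <- rows$wt_end[i] - rows$wt_start[i]
      if (i < nrow(rows)) {
        dt <- rows$wt_start[i + 1L] - rows$wt_end[i]
        dq <- rows$mut_start[i + 1L] - rows$mut_end[i]
        cat(sprintf("%d %d %d\n", as.integer(size), as.integer(dt),
                    as.integer(dq)), file = con)
      } else {
        cat(sprintf("%d\n", as.integer(size)), file = con)
      }
    }
    cat("\n", file = con)
  }
  emit_minus_block <- function(row) {
    chain_id <<- chain_id + 1L
    qs <- map$mut_length - row$mut_end
    qe <- map$mut_length - row$mut_start
    cat(sprintf("chain %d %s %d + %d %d %s %d - %d %d %d\n",
                1000L, target_name, map$wt_length,
                as.integer(row$wt_start), as.integer(row$wt_end),
                query_name, map$mut_length,
                as.integer(qs), as.integer(qe), chain_id), file = con)
    cat(sprintf("%d\n\n", as.integer(row$wt_end - row$wt_start)), file = con)
  }
  if (nrow(blk)) {
    run <- blk$strand == "+"
    grp <- cumsum(c(TRUE, diff(run) != 0))
    for (g in split(seq_len(nrow(blk)), grp)) {
      if (blk$strand[g[1L]] == "+") emit_plus_run(blk[g, , drop = FALSE])
      else for (i in g) emit_minus_block(blk[i, , drop = FALSE])
    }
  }
  invisible(path)
}
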