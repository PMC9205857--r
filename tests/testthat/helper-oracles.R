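# Independent oracles and small fixture builders shared across the suite.
# Oracles deliberately avoid the package's hashed-index / splice code paths:
# the scan oracle string-searches every window with Biostrings::matchPattern,
# and the splice oracle edits plain character strings with substr().

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Brute-force window scan: compare every sampled read window against every
# position of every panel sequence on both strands; keep single-location
# hits. Mirrors the anchor contract without any k-mer table.
brute_scan <- function(read, panel, k, step, read_id = "read") {
  read <- toupper(as.character(read))
  L <- nchar(read)
  if (L < k) return(NULL)
  offsets <- seq.int(0L, L - k, by = step)
  rows <- list()
  for (o in offsets) {
    w <- substr(read, o + 1L, o + k)
    if (grepl("[^ACGT]", w)) next
    hits <- list()
    for (nm in names(panel)) {
      subj <- Biostrings::DNAString(panel[[nm]])
      fw <- Biostrings::start(Biostrings::matchPattern(w, subj))
      rv <- Biostrings::start(Biostrings::matchPattern(revcomp_chr(w), subj))
      for (p in fw) hits[[length(hits) + 1L]] <- list(nm, p - 1L, "+")
      for (p in rv) hits[[length(hits) + 1L]] <- list(nm, p - 1L, "-")
    }
    if (length(hits) == 1L) {
      h <- hits[[1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = read_id, read_offset = as.integer(o), ref_name = h[[1L]],
        ref_offset = h[[2L]], strand = h[[3L]], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# Brute-force string-splice of an edit table onto a host string, applied in
# decreasing coordinate order so earlier surgery cannot shift later targets.
splice_oracle <- function(host, edits) {
  for (i in rev(seq_len(nrow(edits)))) {
    s <- edits$start[i]; e <- edits$end[i]
    before <- substr(host, 1L, s)
    after <- substr(host, e + 1L, nchar(host))
    mid <- switch(edits$kind[i],
                  deletion = "",
                  insertion = edits$payload[i],
                  replacement = edits$payload[i],
                  inversion = revcomp_chr(substr(host, s + 1L, e)))
    host <- paste0(before, mid, after)
  }
  host
}

# Random non-overlapping edit set on a host of length L; returns an
# allele_spec. Inversions/deletions/replacements get targets of 10-120 bp,
# payloads 10-200 bp.
random_spec <- function(L, max_edits = 5L, host = "chrH",
                        name = "rand_allele") {
  n <- sample.int(max_edits + 1L, 1L) - 1L
  if (n == 0L) return(allele_spec(name, host))
  bp <- sort(sample(0:L, 2L * n))        # distinct sorted breakpoints
  starts <- bp[seq(1L, 2L * n, by = 2L)]
  ends <- bp[seq(2L, 2L * n, by = 2L)]
  kinds <- sample(c("deletion", "insertion", "replacement", "inversion"),
                  n, replace = TRUE)
  edits <- lapply(seq_len(n), function(i) {
    if (kinds[i] == "insertion") {
      genome_edit("insertion", host, starts[i], starts[i],
                  payload = rand_dna(sample(10:200, 1L)),
                  label = paste0("e", i))
    } else if (kinds[i] == "replacement") {
      genome_edit("replacement", host, starts[i], ends[i],
                  payload = rand_dna(sample(10:200, 1L)),
                  label = paste0("e", i))
    } else {
      genome_edit(kinds[i], host, starts[i], ends[i], label = paste0("e", i))
    }
  })
  allele_spec(name, host, edits)
}

# One shared toy locus and its fixtures, computed once per test run.
shared_locus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_locus(seed = 7)
    cache
  }
})

shared_fixture <- local({
  cache <- list()
  function(which) {
    if (is.null(cache[[which]]))
      cache[[which]] <<- make_fixture_allele(which, shared_locus())
    cache[[which]]
  }
})
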