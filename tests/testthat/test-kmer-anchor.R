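panel_of <- function(...) Biostrings::DNAStringSet(c(...))

test_that("index keeps exactly the globally unique k-mers", {
  # seed-fixed 103-bp sequence whose 96 8-mers (and reverse complements)
  # are all distinct, verified here by brute-force enumeration
  withr::with_seed(21, s <- rand_dna(103))
  km <- substring(s, 1:96, 8:103)
  rc <- vapply(km, revcomp_chr, character(1))
  stopifnot(!anyDuplicated(c(km, rc)))
  idx <- build_unique_index(panel_of(ref = s), k = 8)
  expect_identical(nrow(idx$table), 96L)
  expect_identical(idx$table$ref_name, rep("ref", 96))
  expect_setequal(idx$table$ref_offset, 0:95)
})

test_that("k-mers inside an exact tandem duplication are dropped", {
  withr::with_seed(22, {
    unit <- rand_dna(20)
    s <- paste0(rand_dna(200), unit, unit, rand_dna(200))
  })
  idx <- build_unique_index(panel_of(ref = s), k = 20)
  # every 20-mer fully inside either repeat copy occurs twice
  dup_offsets <- c(200:(200 + 20 - 20), 220:(220 + 20 - 20))
  expect_false(any(dup_offsets %in% idx$table$ref_offset))
  # but flanking 20-mers survive
  expect_true(0 %in% idx$table$ref_offset)
})

test_that("uniqueness counts both strands and across panel entries", {
  withr::with_seed(23, a <- rand_dna(300))
  # same sequence present as its own reverse complement elsewhere: nothing
  # inside the shared region is unique
  expect_warning(
    idx <- build_unique_index(panel_of(x = a, y = revcomp_chr(a)), k = 20),
    "no unique k-mers")
  expect_identical(nrow(idx$table), 0L)
  # per-entry scoping restores within-entry uniqueness
  idx2 <- build_unique_index(panel_of(x = a, y = revcomp_chr(a)), k = 20,
                             scope = "per_entry")
  expect_identical(nrow(idx2$table), 2L * (300L - 20L + 1L))
})

test_that("degenerate panels raise the documented conditions", {
  expect_error(build_unique_index(panel_of(a = "ACGTACGTACGT"), k = 7),
               "at least 8")
  expect_warning(build_unique_index(panel_of(a = "ACGTACGTAC"), k = 20),
                 "shorter than k")
  withr::with_seed(24, s <- rand_dna(100))
  withN <- paste0(substr(s, 1, 50), "N", substr(s, 52, 100))
  idx <- build_unique_index(panel_of(ref = withN), k = 20)
  # no stored k-mer contains N
  expect_false(any(grepl("N", idx$table$kmer)))
})

test_that("a perfect read over an all-unique region anchors on the diagonal", {
  withr::with_seed(25, s <- rand_dna(1000))
  idx <- build_unique_index(panel_of(ref = s), k = 20)
  read <- substr(s, 301, 420) # 120 bp
  a <- scan_read(read, idx, step = 5, read_id = "r1")
  expect_identical(nrow(a), 21L) # floor((120-20)/5)+1
  expect_true(all(a$strand == "+"))
  expect_identical(a$read_offset, seq(0L, 100L, by = 5L))
  expect_identical(a$ref_offset, seq(300L, 400L, by = 5L))
  # reverse-complement read: same loci, flipped strand, reversed order
  b <- scan_read(revcomp_chr(read), idx, step = 5, read_id = "r1rc")
  expect_identical(nrow(b), 21L)
  expect_true(all(b$strand == "-"))
  expect_identical(b$ref_offset, seq(400L, 300L, by = -5L))
  # self-scan of the full panel sequence: main diagonal only
  d <- scan_read(s, idx, step = 5)
  expect_true(all(d$strand == "+"))
  expect_identical(d$ref_offset, d$read_offset)
})

test_that("substituted windows lose their anchors exactly", {
  withr::with_seed(26, s <- rand_dna(2000))
  idx <- build_unique_index(panel_of(ref = s), k = 20)
  read <- substr(s, 501, 900)
  # plant substitutions at read offsets 60 and 250 (0-based)
  mutate <- function(r, off) {
    b <- substr(r, off + 1, off + 1)
    sub <- setdiff(c("A", "C", "G", "T"), b)[1]
    paste0(substr(r, 1, off), sub, substr(r, off + 2, nchar(r)))
  }
  mread <- mutate(mutate(read, 60), 250)
  a <- scan_read(mread, idx, step = 5, read_id = "m")
  oracle <- brute_scan(mread, c(ref = s), k = 20, step = 5, read_id = "m")
  expect_identical(a$read_offset, oracle$read_offset)
  expect_identical(a$ref_offset, oracle$ref_offset)
  # windows covering a substitution never anchor
  covering <- function(off) a$read_offset[a$read_offset > off - 20 &
                                            a$read_offset <= off]
  expect_length(covering(60), 0)
  expect_length(covering(250), 0)
})

test_that("reads shorter than k and N-containing windows yield no anchors", {
  withr::with_seed(27, s <- rand_dna(500))
  idx <- build_unique_index(panel_of(ref = s), k = 20)
  expect_identical(nrow(scan_read("ACGTACGT", idx)), 0L)
  read <- paste0(substr(s, 101, 130), "N", substr(s, 132, 200))
  a <- scan_read(read, idx, step = 1, read_id = "n")
  # offsets 11..30 cover the N at read offset 30
  expect_false(any(a$read_offset %in% 11:30))
})

test_that("anchor tables round-trip through the dot-plot TSV", {
  withr::with_seed(28, s <- rand_dna(400))
  idx <- build_unique_index(panel_of(ref = s), k = 20)
  a <- scan_read(substr(s, 51, 250), idx, step = 5, read_id = "rt")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_dotplot(a, tsv)
  back <- read_dotplot(tsv)
  expect_equal(back, a, ignore_attr = TRUE)
  expect_identical(readLines(tsv)[1],
                   "read_id\tread_offset\tref_name\tref_offset\tstrand")
  # empty anchor set: header-only file
  export_dotplot(a[0, ], tsv)
  expect_identical(length(readLines(tsv)), 1L)
  expect_identical(nrow(read_dotplot(tsv)), 0L)
})

test_that("scan_read equals the brute-force matcher on random panels and reads", {
  withr::with_seed(29, {
    for (i in 1:20) {
      panel <- c(wt = rand_dna(sample(800:1500, 1)),
                 mut = rand_dna(sample(800:1500, 1)))
      # plant a shared segment so some windows are non-unique
      shared <- rand_dna(60)
      panel["mut"] <- paste0(substr(panel["mut"], 1, 400), shared,
                             substr(panel["mut"], 461, nchar(panel["mut"])))
      panel["wt"] <- paste0(substr(panel["wt"], 1, 300), shared,
                            substr(panel["wt"], 361, nchar(panel["wt"])))
      src <- sample(names(panel), 1)
      start <- sample(1:(nchar(panel[[src]]) - 300), 1)
      read <- substr(panel[[src]], start, start + 299)
      if (stats::runif(1) < 0.5) read <- revcomp_chr(read)
      step <- sample(c(3, 5, 7), 1)
      idx <- build_unique_index(Biostrings::DNAStringSet(panel), k = 20)
      mine <- scan_read(read, idx, step = step, read_id = "r")
      oracle <- brute_scan(read, panel, k = 20, step = step, read_id = "r")
      if (is.null(oracle)) {
        expect_identical(nrow(mine), 0L)
      } else {
        expect_equal(mine, oracle, ignore_attr = TRUE)
      }
    }
  })
})
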