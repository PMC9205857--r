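host_genome <- function(seq) Biostrings::DNAStringSet(c(chrH = seq))

test_that("genome_edit validates kinds, payloads and targets", {
  expect_error(genome_edit("deletion", "chrH", 10, 10), "empty")
  expect_error(genome_edit("insertion", "chrH", 10, 20, payload = "ACGT"),
               "zero-length")
  expect_error(genome_edit("insertion", "chrH", 10, 10), "payload")
  expect_error(genome_edit("replacement", "chrH", 10, 20, payload = "ACXT"),
               "outside")
  expect_error(genome_edit("deletion", "chrH", 10, 20, payload = "ACGT"),
               "must not carry")
  e <- genome_edit("insertion", "chrH", 10, 10, payload = "acgtn")
  expect_identical(e$payload, "ACGTN")
})

test_that("allele_spec sorts edits and rejects overlaps", {
  e1 <- genome_edit("deletion", "chrH", 100, 200)
  e2 <- genome_edit("inversion", "chrH", 10, 50)
  sp <- allele_spec("a", "chrH", list(e1, e2))
  expect_identical(sp$edits$start, c(10, 100))
  e3 <- genome_edit("deletion", "chrH", 40, 120)
  expect_error(allele_spec("a", "chrH", list(e2, e3)), "overlap")
  # abutting half-open targets are legal
  e4 <- genome_edit("deletion", "chrH", 50, 60)
  expect_silent(allele_spec("a", "chrH", list(e2, e4)))
})

test_that("apply_edits conserves length and leaves untouched bases intact", {
  withr::with_seed(11, {
    g <- host_genome(rand_dna(10000))
  })
  del <- allele_spec("del", "chrH",
                     list(genome_edit("deletion", "chrH", 1000, 1532)))
  res <- apply_edits(g, del)
  expect_identical(Biostrings::width(res$genome)[1], 10000L - 532L)
  # bases outside the edit unchanged
  expect_identical(as.character(Biostrings::subseq(res$genome[[1]], 1, 1000)),
                   as.character(Biostrings::subseq(g[[1]], 1, 1000)))
  expect_identical(as.character(Biostrings::subseq(res$genome[[1]], 1001)),
                   as.character(Biostrings::subseq(g[[1]], 1533)))
  # empty edit list: identity
  id <- apply_edits(g, allele_spec("wt", "chrH"))
  expect_identical(as.character(id$genome[[1]]), as.character(g[[1]]))
  expect_identical(id$map$blocks$wt_start, 0)
  # 4190-bp payload insertion grows the genome by exactly the payload
  withr::with_seed(12, pl <- rand_dna(4190))
  ins <- allele_spec("ins", "chrH",
                     list(genome_edit("insertion", "chrH", 5000, 5000,
                                      payload = pl)))
  res2 <- apply_edits(g, ins)
  expect_identical(Biostrings::width(res2$genome)[1], 10000L + 4190L)
  expect_error(apply_edits(g, allele_spec("bad", "chrH", list(
    genome_edit("deletion", "chrH", 9990, 10010)))), "bounds")
})

test_that("apply_edits agrees with the string-splice oracle on random edit sets", {
  withr::with_seed(202, {
    for (rep in 1:40) {
      host <- rand_dna(sample(500:3000, 1))
      spec <- random_spec(nchar(host))
      res <- apply_edits(host_genome(host), spec)
      expect_identical(as.character(res$genome[[1]]),
                       splice_oracle(host, spec$edits))
      # length bookkeeping
      ed <- spec$edits
      removed <- sum((ed$end - ed$start)[ed$kind %in% c("deletion", "replacement")])
      added <- sum(nchar(ed$payload[ed$kind %in% c("insertion", "replacement")]))
      expect_equal(res$map$mut_length,
                   nchar(host) - removed + added)
    }
  })
})

test_that("applying the same inversion twice restores the wild type", {
  withr::with_seed(13, g <- host_genome(rand_dna(2000)))
  inv <- allele_spec("inv", "chrH",
                     list(genome_edit("inversion", "chrH", 300, 900)))
  once <- apply_edits(g, inv)
  twice <- apply_edits(once$genome, inv)
  expect_identical(as.character(twice$genome[[1]]), as.character(g[[1]]))
  expect_false(identical(as.character(once$genome[[1]]),
                         as.character(g[[1]])))
})

test_that("lift_position is bijective outside edits and explains holes", {
  withr::with_seed(14, g <- host_genome(rand_dna(5000)))
  spec <- allele_spec("mix", "chrH", list(
    genome_edit("deletion", "chrH", 1000, 1532),
    genome_edit("insertion", "chrH", 2000, 2000, payload = strrep("ACGT", 25)),
    genome_edit("inversion", "chrH", 3000, 3400)))
  map <- apply_edits(g, spec)$map
  expect_identical(lift_position(map, 0)$lifted, 0)
  # after a single 532-bp deletion, downstream offsets shift by -532
  expect_identical(lift_position(map, 1600)$lifted, 1600 - 532)
  inside <- lift_position(map, 1200)
  expect_true(is.na(inside$lifted))
  expect_identical(inside$reason, "deleted")
  # mutant-only inserted bases have no wild-type image
  ins_pos <- lift_position(map, 2000 - 532 + 10, "mutant_to_wt")
  expect_identical(ins_pos$reason, "inserted-only")
  # inverted block maps to the mirrored offset
  p <- 3100
  lp <- lift_position(map, p)$lifted
  back <- lift_position(map, lp, "mutant_to_wt")$lifted
  expect_identical(back, p)
  expect_error(lift_position(map, 5000), "out of bounds")
})

test_that("lift round-trip holds for random edits and positions", {
  withr::with_seed(303, {
    for (rep in 1:25) {
      host <- rand_dna(2000)
      spec <- random_spec(2000)
      map <- apply_edits(host_genome(host), spec)$map
      pos <- sample(0:1999, 40)
      fwd <- lift_position(map, pos)
      ok <- !is.na(fwd$lifted)
      if (any(ok)) {
        back <- lift_position(map, fwd$lifted[ok], "mutant_to_wt")
        expect_equal(back$lifted, pos[ok])
      }
      # positions inside deletions/replacements must report the hole
      expect_true(all(fwd$reason[!ok] == "deleted"))
    }
  })
})

test_that("knock-in allele replaces the inter-arm segment", {
  withr::with_seed(15, g <- host_genome(rand_dna(8000)))
  left <- genomic_interval("chrH", 2000, 3035)
  right <- genomic_interval("chrH", 3061, 4109)
  withr::with_seed(16, payload <- rand_dna(4190))
  sp <- build_knockin_allele(g, payload, left, right, "ki")
  expect_identical(sp$edits$kind, "replacement")
  expect_identical(sp$edits$start, 3035)
  expect_identical(sp$edits$end, 3061)   # 26 bp of host removed
  res <- apply_edits(g, sp)
  expect_identical(Biostrings::width(res$genome)[1], 8000L - 26L + 4190L)
  # brute-force assembly: flank + payload + flank
  expect_identical(as.character(res$genome[[1]]),
                   paste0(substr(as.character(g[[1]]), 1, 3035), payload,
                          substr(as.character(g[[1]]), 3062, 8000)))
  # full-construct mode verifies and strips the arms
  arms <- paste0(substr(as.character(g[[1]]), 2001, 3035), payload,
                 substr(as.character(g[[1]]), 3062, 4109))
  sp2 <- build_knockin_allele(g, arms, left, right, "ki2",
                              construct_contains_arms = TRUE)
  expect_identical(sp2$edits$payload, payload)
  bad <- paste0(rand_dna(1035), payload, rand_dna(1048))
  expect_error(build_knockin_allele(g, bad, left, right, "ki3",
                                    construct_contains_arms = TRUE),
               "do not match")
  # abutting arms give a pure insertion
  left0 <- genomic_interval("chrH", 2000, 3000)
  right0 <- genomic_interval("chrH", 3000, 4000)
  sp3 <- build_knockin_allele(g, payload, left0, right0, "ki4")
  expect_identical(sp3$edits$kind, "insertion")
  expect_error(build_knockin_allele(g, payload, right0, left0, "ki5"),
               "overlap|reversed")
  # retain mode keeps the host segment
  sp4 <- build_knockin_allele(g, payload, left, right, "ki6",
                              retain_target = TRUE)
  res4 <- apply_edits(g, sp4)
  expect_identical(Biostrings::width(res4$genome)[1], 8000L + 4190L)
})

test_that("allele specs and coordinate maps round-trip through disk formats", {
  withr::with_seed(17, g <- host_genome(rand_dna(3000)))
  spec <- allele_spec("io", "chrH", list(
    genome_edit("replacement", "chrH", 100, 200, payload = "ACGTACGTAC",
                label = "swap"),
    genome_edit("inversion", "chrH", 500, 800, label = "flip")))
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_allele_spec(spec, yml)
  back <- read_allele_spec(yml)
  expect_identical(back$edits, spec$edits)
  expect_identical(back$name, spec$name)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_edits_bed(spec, bed)
  reimport <- rtracklayer::import(bed)
  expect_identical(length(reimport), 2L)
  expect_identical(as.character(GenomicRanges::strand(reimport)),
                   c("+", "-"))
  expect_identical(GenomicRanges::start(reimport) - 1L, c(100L, 500L))
  chain <- withr::local_tempfile(fileext = ".chain")
  map <- apply_edits(g, spec)$map
  write_chain(map, chain)
  lines <- readLines(chain)
  expect_true(any(grepl("^chain", lines)))
  # chain blocks cover every aligned base exactly once
  sizes <- sum(vapply(strsplit(grep("^[0-9]", lines, value = TRUE), " "),
                      function(x) as.integer(x[1]), integer(1)))
  expect_identical(sizes, as.integer(sum(map$blocks$wt_end - map$blocks$wt_start)))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, fa)
  expect_identical(as.character(read_genome_fasta(fa)[[1]]),
                   as.character(g[[1]]))
  expect_true(all(nchar(readLines(fa)[-1]) <= 60))
})
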