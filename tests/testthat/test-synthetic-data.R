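test_that("toy locus generation is deterministic and feature-complete", {
  l1 <- make_toy_locus(seed = 7)
  l2 <- make_toy_locus(seed = 7)
  expect_identical(as.character(l1$genome[[1]]), as.character(l2$genome[[1]]))
  expect_identical(Biostrings::width(l1$genome)[1], 60000L)
  expect_identical(nchar(l1$construct), 4190L)
  # the construct begins with the exact native element sequence
  elem <- l1$features[l1$features$name == "element_copy1", ]
  expect_identical(substr(l1$construct, 1, 532),
                   substr(as.character(l1$genome[[1]]), elem$start + 1,
                          elem$end))
  l3 <- make_toy_locus(seed = 8)
  expect_false(identical(as.character(l1$genome[[1]]),
                         as.character(l3$genome[[1]])))
  # fasta written twice from the same seed is byte-identical
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(make_toy_locus(seed = 3)$genome, f1)
  write_genome_fasta(make_toy_locus(seed = 3)$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(make_toy_locus(locus_blueprint(element_copy1_offset = 70000)),
               "beyond|separated")
  expect_error(locus_blueprint(insertion_site_offset = 20000), "10 kb")
})

test_that("fixture alleles encode the intended architectures", {
  wt <- shared_fixture("wt")
  fx542 <- shared_fixture("allele542")
  fx320 <- shared_fixture("allele320")
  locus <- shared_locus()
  expect_identical(as.character(wt$genome[[1]]),
                   as.character(locus$genome[[1]]))
  # exact string search: one construct occurrence in 542
  cnt <- function(g, pat) {
    Biostrings::countPattern(pat, g[[1]]) +
      Biostrings::countPattern(revcomp_chr(pat), g[[1]])
  }
  expect_identical(cnt(fx542$genome, locus$construct), 1L)
  # four occurrences (forward + reverse complement) in the 320 array
  expect_identical(cnt(fx320$genome, locus$construct), 4L)
  expect_identical(Biostrings::countPattern(locus$construct,
                                            fx320$genome[[1]]), 3L)
  # length conservation for both knock-ins
  expect_identical(Biostrings::width(fx542$genome)[1],
                   60000L - 26L + 4190L)
  expect_identical(Biostrings::width(fx320$genome)[1],
                   60000L - 26L + 4L * 4190L)
  # the duplicated element really is duplicated on the 542 genome
  g <- as.character(fx542$genome[[1]])
  e1 <- fx542$element_copies[[1]]; e2 <- fx542$element_copies[[2]]
  expect_identical(substr(g, e1$start + 1, e1$end),
                   substr(g, e2$start + 1, e2$end))
  expect_error(make_fixture_allele("allele320", locus, copies = 3),
               "length")
})

test_that("long-read simulation honors truth records and error settings", {
  fx <- shared_fixture("allele542")
  sim0 <- simulate_long_reads(fx$genome, n_reads = 40, mean_length = 3000,
                              length_sd = 500, substitution_rate = 0,
                              insertion_rate = 0, deletion_rate = 0,
                              seed = 13)
  g <- as.character(fx$genome[[1]])
  for (i in seq_len(40)) {
    tr <- sim0$truth[i, ]
    origin <- substr(g, tr$start + 1, tr$end)
    readseq <- as.character(sim0$reads[[i]])
    expect_identical(readseq,
                     if (tr$strand == "+") origin else revcomp_chr(origin))
  }
  # same seed -> identical FASTQ bytes
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(simulate_long_reads(fx$genome, 10, seed = 3)$reads, f1)
  write_fastq(simulate_long_reads(fx$genome, 10, seed = 3)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(as.character(read_fastq(f1)),
                   as.character(simulate_long_reads(fx$genome, 10,
                                                    seed = 3)$reads))
  # noisy reads differ from the reference but only modestly in length
  sim1 <- simulate_long_reads(fx$genome, n_reads = 10, mean_length = 3000,
                              seed = 13)
  expect_true(all(abs(Biostrings::width(sim1$reads) /
                        sim1$truth$length - 1) < 0.1))
  expect_error(simulate_long_reads(fx$genome, 10, substitution_rate = 0.5),
               "rates")
  # cut-site anchoring keeps read starts near the cut
  sim2 <- simulate_long_reads(fx$genome, n_reads = 30, mean_length = 5000,
                              cut_sites = c(40000), seed = 14)
  expect_true(all(abs(sim2$truth$start - 40000) <= 500))
})

test_that("mean read length is recovered at sampling precision", {
  fx <- shared_fixture("allele542")
  sim <- simulate_long_reads(fx$genome, n_reads = 1000, mean_length = 8000,
                             length_sd = 1000, substitution_rate = 0,
                             insertion_rate = 0, deletion_rate = 0,
                             seed = 15)
  expect_lt(abs(mean(sim$truth$length) - 8000) / 8000, 0.05)
})

test_that("short-pair simulation produces inward-facing exact mates", {
  fx <- shared_fixture("allele542")
  sim <- simulate_short_pairs(fx$genome, n_pairs = 50, seed = 16)
  g <- as.character(fx$genome[[1]])
  for (i in seq_len(50)) {
    tr <- sim$truth[i, ]
    frag <- substr(g, tr$start + 1, tr$end)
    if (tr$strand == "-") frag <- revcomp_chr(frag)
    expect_identical(as.character(sim$reads1[[i]]), substr(frag, 1, 50))
    expect_identical(as.character(sim$reads2[[i]]),
                     revcomp_chr(substr(frag, nchar(frag) - 49, nchar(frag))))
  }
  # determinism
  sim2 <- simulate_short_pairs(fx$genome, n_pairs = 50, seed = 16)
  expect_identical(as.character(sim$reads1), as.character(sim2$reads1))
  expect_identical(sim$truth, sim2$truth)
  expect_warning(simulate_short_pairs(fx$genome, 5, insert_mean = 60,
                                      seed = 1),
                 "clipped")
})

test_that("uniformly placed fragments cover a region evenly", {
  fx <- shared_fixture("allele542")
  region <- genomic_interval("chrT", 10000, 20000)
  sim <- simulate_short_pairs(fx$genome, n_pairs = 5000, region = region,
                              seed = 17)
  cov <- coverage_track(data.frame(start = sim$truth$start,
                                   end = sim$truth$end), region)
  interior <- cov[1000:9000]
  expect_lt(stats::sd(interior) / mean(interior), 0.25)
  expect_lt(abs(mean(interior) - 5000 * 200 / 10000) / (5000 * 200 / 10000),
            0.1)
})
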