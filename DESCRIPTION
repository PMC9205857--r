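Package: kanchor
Title: Verification of Targeted Transgene Insertions by Unique k-mer
    Anchoring of Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to verify CRISPR knock-in alleles from Cas9-targeted
    nanopore sequencing. Builds mutant genome sequences from exact
    breakpoints and lifts coordinates between wild-type and mutant
    assemblies; anchors long reads to a reference panel through globally
    unique k-mers sampled on a sliding window, producing dot plots;
    chains anchors into orientation-aware segments to classify reads and
    reconstruct the minimum copy number and orientation pattern of
    tandem transgene arrays; and assigns short reads to one of two
    identical duplicated elements using unique flanking k-mers. A
    seeded simulator generates toy loci, knock-in fixtures and noisy
    long or paired short reads with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
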