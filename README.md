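# kanchor

Verification of CRISPR knock-in alleles from Cas9-targeted nanopore
sequencing, by unique k-mer anchoring of long reads.

## The problem

Targeted transgenesis often does not deliver the allele that was designed.
Instead of a single construct copy integrated between its homology arms,
founder animals can carry tandem arrays of several copies in mixed
orientations — a difference that changes the biology of the allele and is
invisible to standard genotyping PCR. Long nanopore reads enriched around
the integration site (Cas9-targeted sequencing) can resolve the true
structure, but their error rate defeats naive exact alignment, and when
the construct duplicates a genomic element (e.g. an enhancer cloned from
the same locus), short-read assays can no longer tell the two copies
apart.

`kanchor` provides the verification computations for this setting, for
mouse-genetics and genome-engineering labs:

- **Mutant genome construction** — splice a mutant assembly from a
  wild-type sequence plus breakpoint-exact edits (deletion, insertion,
  replacement, inversion), with a coordinate map, lift-over, and UCSC
  chain export. A homology-arm knock-in is a single replacement of the
  inter-arm host segment by the construct payload.
- **Unique k-mer dot plots** — index the k-mers (default k = 20) that
  occur exactly once across a reference panel (wild-type, expected
  mutant, vector) counting both strands; test k-bp read windows every
  `step` bases (default 5) and keep exact hits as anchors. A window
  anchors at reference offset `r` with strand `+` when the window equals
  the unique k-mer at `r`, and strand `-` when its reverse complement
  does.
- **Copy number and orientation** — chain anchors into collinear
  segments, type the junctions (collinear gap, deletion, insertion,
  inversion, copy junction), and search orientation patterns of
  increasing length n for the smallest n whose adjacent-copy pattern
  explains every read. The result is a *minimum* copy number
  `n_min = min { n : some s in {+,-}^n is consistent with every read }`
  together with all co-optimal patterns.
- **Duplicated-element read assignment** — emulate a MAPQ >= 30
  unique-mapping filter with genome-wide unique k-mers: a read is
  assigned to one element copy only if it carries unique sequence, and is
  structurally ambiguous when it lies fully inside the duplicated
  element. Errors can only demote reads to ambiguous, never flip the
  locus.
- **Synthetic data** — a seeded generator for a 60-kb toy locus with a
  532-bp duplicated enhancer element, a 4190-bp
  enhancer-promoter-reporter construct, single-copy and 4-copy
  mixed-orientation fixture alleles, and nanopore-like long reads / clean
  short pairs with ground truth.

## Worked example

Verify the multi-copy fixture end to end (simulate 200 nanopore-like
reads from the 4-copy tandem-array allele, anchor them against the
expected single-copy mutant, and reconstruct the array):

```r
library(kanchor)

report <- run_verify(list(fixture = "allele320", seed = 42, n_reads = 200))
report
#> verification report
#>   allele class:    multi_copy_tandem
#>   copy_count_min:  4
#>   pattern:         ++-+
#>   reads:           200
#>   read labels:      WT=150, expected_knockin=15, multi_copy=35, ambiguous=0, unclassified=0
```

The report says the reads are only explainable by at least four construct
copies, in orientations `+ + - +` (the fixture's ground truth): 150 reads
lie in unedited flank, 15 span a single correctly placed copy, and 35
carry multi-copy evidence (copy junctions or inversions). The same call
on the single-copy fixture returns `single_copy_knockin` with
`copy_count_min = 1`, and on the wild-type fixture `no_insertion`.

Assigning 10,000 clean read pairs over the genome with the duplicated
enhancer:

```r
dis <- run_disambiguate(n_pairs = 10000, seed = 42)
dis$summary
#> ambiguous    unique
#>       103      9897
dis$n_wrong_locus
#> [1] 0
```

Pairs touching only the duplicated element stay ambiguous (103 here);
every assigned pair is at its true copy.

A thin command-line wrapper with `simulate`, `build-genome`, `verify` and
`disambiguate` subcommands ships in `inst/cli/kanchor.R`.

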