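---
title: "Verifying targeted transgene insertions with unique k-mer anchors"
author: "kanchor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying targeted transgene insertions with unique k-mer anchors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kanchor)
```

## The problem

CRISPR knock-in experiments routinely produce alleles that differ from the
intended design: instead of one construct copy integrated by
homology-directed repair, founders may carry tandem arrays of several
copies in mixed orientations. Because the copies are sequence-identical,
short reads cannot resolve the array, and even long nanopore reads are too
error-prone for naive exact matching. The situation is compounded when the
construct itself duplicates a genomic element — for example an enhancer
cloned from the same locus it is re-inserted into — so that short-read
assays (ATAC, CUT&RUN, capture Hi-C) can no longer tell the two copies
apart.

`kanchor` implements the verification computations for this setting as a
reusable pipeline:

1. **genome building** — splice a mutant genome from a wild-type sequence
   and breakpoint-exact edits, with coordinate lift-over between the two
   assemblies;
2. **unique k-mer anchoring** — match k-bp read windows, sampled every
   `step` bases, against the k-mers that occur exactly once in a reference
   panel, yielding dot-plot anchors that are immune to the repetitive
   parts of the locus;
3. **structure inference** — chain anchors into orientation-aware
   segments, classify each read, and reconstruct the minimum copy number
   and an orientation pattern consistent with every read;
4. **duplicated-element disambiguation** — assign short reads to one of
   two identical element copies only when they contain genome-wide unique
   sequence, emulating a high-MAPQ filter without running an aligner;
5. **synthetic data** — a seeded generator for a desk-scale locus,
   knock-in fixtures, and noisy reads with ground truth.

## Coordinates and genome construction

All intervals are 0-based half-open (the BED convention). A printed span
`chr2:74075311-74075843` is ingested as `start = 74075311`,
`end = 74075843` and measures `532` bp, which reproduces the printed
length of the relocated enhancer element and anchors the whole package to
one consistent arithmetic.

Edits (`deletion`, `insertion`, `replacement`, `inversion`) are expressed
against *original* wild-type coordinates and must not overlap; this
matches how breakpoints are recorded at the bench and makes the result
independent of edit order. `apply_edits()` returns the mutant sequence
together with a block-structured coordinate map; `lift_position()` is
bijective outside edited intervals and reports `deleted` /
`inserted-only` for positions with no image. Maps export to UCSC chain
format; inversions become their own minus-strand chains because the format
cannot mix orientations within one chain.

A homology-arm knock-in is a single replacement: the host segment between
the arms — 26 bp in the emulated design, the distance between the printed
arm coordinates — is replaced by the construct payload. Whether those
guide-site bases are retained or replaced by repair is not stated for the
original alleles; we default to *replaced*, the usual HDR outcome, and
expose `retain_target = TRUE` for the alternative (a pure insertion at the
left arm's end).

## Unique k-mer anchoring

The verification core follows the published recipe: 20-bp read windows
are tested every 5 bp and kept only when exactly identical to a k-mer
that is *unique in the reference*. We interpret uniqueness globally —
across every panel entry and both strands — because global uniqueness is
what makes an anchor unambiguous when reads are compared simultaneously
against wild-type, expected-mutant and vector references; per-entry
scoping is available (`scope = "per_entry"`) since the original scripts
do not state which was used. A k-mer equal to its own reverse complement
can never reach a both-strand count of one and is therefore naturally
excluded, as are k-mers containing `N`. Window phase starts at read
offset 0; the stride's phase is not stated in the protocol, and offset 0
is the deterministic, convention-free choice.

At default nanopore-like error rates (see below) roughly 8% of 20-bp
windows are error-free, so an 8-kb read yields on the order of a hundred
anchors — sparse, but far more than the chaining step needs.

## From anchors to allele calls

Chaining mechanizes what one would do by eye on a dot plot. Sweeping
anchors left to right along the read, an anchor extends the current
segment when it keeps the reference and strand, lies within `max_gap =
500` bp on the read, and drifts at most `max_diag_offset = 50` bp from
the *previous* anchor's diagonal. Measuring drift locally rather than
against the segment start matters: nanopore indel bias makes the diagonal
wander by roughly 1% of the distance travelled, which would breach any
fixed global band over a multi-kilobase segment while staying well inside
the local one. Segments need `min_anchors = 3` support. Because an anchor
dearth longer than `max_gap` occasionally splits one true segment in two,
read-adjacent segments joined by a `colinear-gap` junction are coalesced
again before any copy is counted; without this, a split copy would be
counted twice and the copy-number call could exceed the truth.

Junctions between consecutive segments are typed by geometry: differing
strands mean an `inversion`; on a shared strand a backward reference jump
beyond `gap_tol = 200` bp is a `copy-junction` (the read re-enters the
construct interval, the signature of a tandem array); an excess of
reference over read gap is a `deletion`, the reverse an `insertion`.

A segment counts as a construct copy when its overlap with the construct
interval reaches 50% of the shorter of segment span and construct length,
and at least 30% of the construct. The `min()` in the first rule is
deliberate: a read tiling flank–construct–flank over the expected mutant
chains into a *single* collinear segment much longer than the construct,
and the copy inside it must still count as one. The 30% floor keeps
sub-threshold truncated edge copies from inflating the count; they are
flagged instead.

`infer_configuration()` aggregates reads. The copy-count floor is the
largest per-read count; junction stitching then searches orientation
patterns of increasing length `n` (all `2^n` patterns up to `n_max = 8`,
enumerated lexicographically with `+` before `-`) for the smallest `n`
such that one pattern explains every read: each read's ordered copy
orientations must occur as a contiguous substring of the pattern in the
read's frame — either as given, or reversed with flipped signs for reads
from the other genome strand — and reads that run into genomic flank pin
their match to the corresponding end of the pattern. The reported value is
therefore a *minimum* copy number, exactly the style of conclusion the
underlying experiment supports ("a minimum of four copies ... with
multiple orientations"), and all co-optimal patterns are reported. If no
pattern up to `n_max` works, the allele is `inconsistent`.

## Duplicated-element disambiguation

The short-read stages of the original study kept only alignments with
MAPQ ≥ 30, i.e. uniquely mapping reads, to separate the native element
from its transgenic copy. We emulate the *intent* of that filter without
an aligner: a read (or pair) is assigned to a copy only if at least
`min_unique_kmers` of its k-mers hit the genome-wide unique k-mer index
and all such hits fall inside a single padded copy neighborhood. Every
k-mer of a read lying fully inside the duplicated element occurs twice in
the mutant genome, so such reads are structurally `ambiguous`; sequencing
errors can only destroy unique k-mers, so errors degrade `unique` to
`ambiguous`, never to the wrong copy. In paired mode (`either-mate`, the
default) a pair is rescued by one uniquely placed mate, mirroring paired
aligner behavior. Whether this k-mer rule and a particular aligner's
MAPQ model agree on real data is only asserted on synthetic reads here.

## The synthetic locus and what it does (not) show

The generator scales the multi-megabase regulatory locus down to a 60-kb
toy: one 532-bp enhancer element (the printed element size) at offset
15 kb, and an integration site at offset 45 kb flanked by 1035/1048-bp
homology arms around a 26-bp guide segment — the printed arm geometry.
The targeting construct is element + promoter + reporter, 4190 bp in
total (the printed fragment size), and its enhancer part is the *exact*
native element sequence, so knock-in fixtures genuinely carry a
duplicated element. Three fixtures emulate the study genotypes: `wt`,
`allele542` (one correctly placed copy) and `allele320` (a tandem array;
copy count 4, the reconstructed minimum). The array's orientation pattern
`+,+,-,+` is a fixture stand-in — no pattern is published — so recovery
is always tested against the fixture's own truth.

Long reads default to 8000 ± 1000 bp with per-base substitution /
insertion / deletion rates of 5% / 3% / 4%, approximating a contemporary
nanopore profile; short pairs default to 2 × 50 bp with 200 ± 50 bp
inserts and no errors. Read starts are uniform, or anchored within
±500 bp of Cas9 cut sites to emulate Cas9-targeted enrichment. Every
simulation is a pure function of its seed.

What passing tests show: the method recovers copy number, orientation and
placement from reads whose error process is memoryless and whose coverage
is even. What they do not show: robustness to structured nanopore error
(homopolymer compression, strand-specific bias), chimeric library
artifacts, basecaller drift, or reference errors — none of which the
generator emulates.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely at desk scale,
chosen so the full suite completes in a few minutes on one core: 200
reads per end-to-end verification, 30 array-spanning reads per
copy-number recovery run (5 seeds × 5 copy numbers), 10,000 read pairs
for the disambiguation safety check, 100 randomized panels for the
scan-versus-brute-force oracle, and 1,000 randomized edit sets for the
genome-builder properties. Ties between co-optimal orientation patterns
break lexicographically (`+` before `-`) and all co-optimal patterns are
reported. Degenerate inputs (empty read sets, reads shorter than `k`,
all-short panels) return empty results or warnings, never crashes.

## Worked example

```{r example, eval = FALSE}
library(kanchor)

# multi-copy tandem-array fixture, end to end
report <- run_verify(list(fixture = "allele320", seed = 42, n_reads = 200))
report
#> verification report
#>   allele class:    multi_copy_tandem
#>   copy_count_min:  4
#>   pattern:         ++-+
#>   reads:           200
#>   read labels:      WT=150, expected_knockin=15, multi_copy=35,
#>                     ambiguous=0, unclassified=0

# duplicated-element safety on clean pairs
dis <- run_disambiguate(n_pairs = 10000, seed = 42)
dis$n_wrong_locus
#> [1] 0
```

## Known limitations

- Uniqueness is exact-match: a single error in a window suppresses its
  anchor, so very high error rates starve the chainer; the defaults leave
  ample margin at contemporary nanopore accuracy.
- Pattern stitching enumerates `2^n` patterns and is capped at
  `n_max = 8` copies; larger arrays report `inconsistent` rather than an
  unsupported guess.
- The read classifier models the junction types of the insertion design
  (insertion, deletion, inversion, copy junction); unrelated structural
  variants in the same reads are not modeled.
- Lift-over is single-sequence; multi-chromosome rearrangements are out
  of scope.
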