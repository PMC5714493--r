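---
title: "Discovering noncanonical GA/GG donor splice sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering noncanonical GA/GG donor splice sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasplice)
```

## The problem

Eukaryotic introns almost always begin with GT (rarely GC) and end with AG.
Spliced aligners and gene-model pipelines hard-code this: a junction whose
intron starts with GA or GG is simply never called, however deep the RNA
coverage. In the copepod *Eurytemora affinis*, 10–12% of introns in large,
intron-rich genes carry exactly such GA/GG donors, so automated gene models
for those genes are systematically truncated and the supporting spliced
reads are invisible in standard browsers. These noncanonical introns have a
characteristic context: an obligate AG at the end of the preceding exon, a
strong preference for A at intron position 3, and ordinary AG acceptors
with pyrimidine-rich tracts.

`gasplice` implements the full analysis as a testable pipeline: junction
discovery by anchored spliced alignment under a configurable donor
constraint, donor/acceptor classification and tabulation, splice-site
logos as information-content matrices, and intron position/phase
conservation across a protein alignment. Because the curated copepod
sequences are not available in machine-readable form, the package includes
a synthetic genome and read simulator that reproduces the statistical
structure of the curated gene set, so every downstream stage can be
validated against a known ground truth.

## Coordinate and strand conventions

All internal coordinates are 0-based half-open on the plus genomic axis;
GFF3 I/O converts to and from the 1-based inclusive convention at the
boundary, and junction tables are written BED-like (0-based half-open).
A single internal convention is the cheapest defense against the
off-by-one errors that junction arithmetic invites. On the minus strand,
transcript order is the reverse of genomic order and all splice-site
dinucleotides are read on the transcribed strand (reverse-complemented
slices). `N` bases are allowed in genomes; any dinucleotide or window
containing `N` is classified `other`, never silently matched.

## The simulator defines the study conditions

`sim_config()` fixes the synthetic genome's structure. Defaults mirror the
curated 10-gene set: 10 genes of 19–47 mostly short exons (40–250 nt),
introns of 60–2000 nt, one scaffold per gene with 200–500 nt intergenic
flanks, and uniform i.i.d. background composition (no copepod base
composition is published; the uniform null keeps every anchor statistic
analyzable). Donors follow the `AG|GTAAGT` consensus: intron positions
3–6 match the consensus with probability 0.9 per position, and the exon
preceding a *canonical* intron ends in AG with probability 0.55 — a
preference, not an obligation, which is the documented behaviour of
canonical sites. Noncanonical GA/GG introns get the obligate exon-terminal
AG (flag on by default) and A at intron position 3 with probability 0.9.
Acceptors are always AG behind a 10 nt tract with per-base pyrimidine
probability 0.8; no noncanonical acceptors are simulated because none were
observed. Donor classes are planted either by probability (default
GT 0.85, GC 0.03, GA 0.105, GG 0.015) or in **quota mode**, which deals an
exact multiset — `c(GT = 261, GC = 0, GA = 31, GG = 5)` reproduces the
curated 297-intron set whose 36 noncanonical donors are the 12% headline.

Reads emulate junction-spanning RNA evidence directly rather than whole
transcript shotgun: each intron receives `coverage` (default 10) reads of
length `read_length` (default 100) drawn from the spliced transcript with
the junction offset uniform over admissible positions and at least
`min_anchor` (8) nt on each side. Each read is exactly the concatenation
of two exon-side slices, confined to the two flanking exons; when those
exons are together shorter than the configured read length, the read is
clamped to what they can hold. This keeps every read a single-junction
read — multi-junction reads are out of scope for the single-split caller —
while preserving the anchor guarantees. Reads are error-free by default
(`error_rate` is a substitution-rate knob, not a claim about the data).

A uniqueness guard runs at genome emission: the spliced junction core
(`min_anchor` bases each side of every junction) must occur nowhere in the
genome as a contiguous sequence. Since every admissible spanning window
contains that core, no junction-spanning read window can be explained by
an unspliced placement. Offending genes are resampled a bounded number of
times, then the generator errors with advice to lengthen reads.

What the simulator does *not* emulate: real base composition and repeat
structure, sequencing error profiles, expression variation, paired ends,
indels, alternative splicing, and assembly gaps. Passing tests therefore
demonstrate the correctness of the algorithms under clean single-copy
genomes, not robustness to the pathologies of a draft assembly.

## Junction discovery

Discovery is an exact-match anchored spliced aligner. Both terminal
k-mers of each read (default `k = 16`) are matched exactly against both
genome strands through a batched dictionary lookup. For each colinear
anchor pair with a genomic gap of at least 4 nt, `call_junction()`
enumerates every split position `p` with `min_anchor ≤ p ≤ L −
min_anchor` such that the read equals the left genomic slice plus the
right genomic slice (computed with cumulative mismatch arrays, so an
optional mismatch budget of up to 2 substitutions is supported, with
mismatches banned within `min_anchor` of the junction; the default budget
is 0 because the evidence standard is exact spanning reads). A placement
is admissible when its intron ends with AG and starts with a donor
allowed by the mode: `gt` (GT only), `gy` (GT/GC — the constraint built
into standard aligners), `g` (any G-start: GT, GC, GA, GG), or `any`.

When identical bases flank a junction, several placements explain the
same read (junction slide). All admissible placements are reported in the
ambiguity set; the chosen placement maximizes donor priority
GT > GC > GA > GG, then takes the leftmost genomic interval. The priority
order is deliberately conservative: a GA junction is only ever reported
when no canonical placement explains the same read, which protects the
noncanonical percentage from inflation. With an obligate AG acceptor the
geometry already forbids most slides (a shift of ±1 or ±2 cannot produce
two AG acceptors around the same read), so ambiguity sets larger than one
are rare in practice and always resolved deterministically.

Per-read calls merge on identical (sequence, interval, strand); support
is the read count. Junctions below `min_support` (default 2) are retained
but flagged `pass_filter = FALSE` and excluded from summaries — the
automated analog of treating single-read junctions with caution during
curation. The support threshold is a design choice, not a published
value.

## Classification, tabulation, uncertainty

`classify_intron()` reads donor, acceptor, intron position 3 and
exon-terminal dinucleotide on the transcribed strand and computes phase
as coding-nucleotides-upstream mod 3 (phase 0 = between codons — the
standard convention; introns upstream of the coding start get phase `NA`
and are excluded from phase tables while still counting in donor
tallies). GC donors are kept as their own class rather than folded into
GT. `tabulate_donors()` produces the per-gene table, totals, the exact
noncanonical fraction, the half-up-rounded integer percent (presentation
only; machine outputs always carry the exact fraction — 36/297 = 12.12%
is displayed as 12%), and a 95% Wilson score interval. The Wilson
interval is computed closed-form and cross-checked in the tests against
`prop.test(correct = FALSE)`, which inverts the same score statistic.

## Splice-site logos

Donor windows are 10 exon + 13 intron bases; acceptor windows 16 intron +
7 exon bases, with `N` padding at sequence edges. Frequencies use an
additive pseudocount over per-position effective sample sizes (cells with
`N` drop out of their position only, not the whole row). Information
content is the classical logo measure `R = 2 − H − e(n)` with the
small-sample correction `e(n) = 3/(2·ln 2·n)` applied by default and
corrected values clamped at 0; both the correction and the equiprobable
background are configurable because the rendering service originally used
for such figures does not record its options. Acceptance is always on the
numeric matrix (TSV export), never on a rendered image; `plot_logo()` is
a convenience.

## Intron conservation

Conservation consumes a protein multiple alignment as input rather than
computing one — this decouples the shared/idiosyncratic logic from any
aligner choice, and the package's fixtures are synthetic alignments built
in code. Each intron maps to `residue_index = floor(cds_before/3)` (the
residue whose codon it interrupts, for phases 1–2) and then to the
alignment column holding that residue. Introns cluster into one homology
record when phases are equal and columns differ by at most `column_slack`
(single-linkage; default 0, the strict reading of "same position and
phase", with slack exposed because curation practice often tolerates ±1
column). Records spanning ≥ 2 species are `shared`; the rest
`idiosyncratic`; the partition is exhaustive, so per-species counts such
as 33 = 9 shared + 24 idiosyncratic fall out of `shared_counts()`. The
clustering is verified in the tests against connected components of the
exhaustive pairwise-compatibility graph.

## Numerical and scale choices

The default validation runs 10 genes / 297 introns / 2,970 reads
(~350 kb of genome); simulation takes a few seconds and discovery about
ten, so the whole suite and the acceptance script run comfortably on one
CPU. Tie-breaks, sort orders and merge keys are all deterministic, and a
fixed seed makes FASTA/GFF3/truth outputs byte-identical across runs.
Degenerate inputs are defined rather than accidental: empty read sets
yield empty call tables, an empty classified set yields an all-zero
summary with an `NA` fraction, single-exon genes yield no intron rows,
and coverage 0 yields zero reads with intact bookkeeping.

## Known limitations

The discovery module calls one junction per read (no multi-intron reads,
soft-clipping or indels) and requires exact AG acceptors in every mode.
Quota mode reproduces published *counts*; the underlying curated
sequences are not redistributable, so sequence-level reproduction of the
published logos is out of reach by construction, and the logo tests
assert structural properties (forced 2-bit positions, normalization, the
correction formula) instead of stack heights. The 297-intron total is
taken as printed even though the published per-gene exon counts imply a
slightly smaller exons−1 sum; the discrepancy traces to an
alternative-splicing arrangement in one gene that the simulator does not
attempt to model.
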