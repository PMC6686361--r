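---
title: "Characterizing circular mitogenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing circular mitogenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

This vignette explains the statistics and procedures mitochar implements,
the conventions and tunable parameters behind them, what the synthetic
generator does and does not emulate, and the design choices made where the
problem admitted more than one defensible answer.

## The coordinate model

A mitogenome is a circle. All coordinates are 1-based inclusive on the
heavy (H) strand, matching the convention of GenBank feature tables and of
published mitogenome gene tables. A feature with `end < start` wraps
across the arbitrary origin; its length is
`genome_length - start + 1 + end`. Light-strand (L) features keep H-strand
coordinates and are reverse-complemented only when their sense sequence is
extracted.

The signed gap between consecutive features is
`start(next) - end(this) - 1`, computed modulo the circle and centred into
`(-L/2, L/2]`, so that small overlaps stay negative rather than appearing
as near-full-circle spacers. The gap is attributed to the upstream feature
of each pair, and the final feature pairs with the first: summed lengths
plus summed signed gaps must equal the genome length exactly. This
closure identity is a theorem of the representation, and the test suite
asserts it on the published *G. himalayensis* annotation and on hundreds
of randomized synthetic annotations — it is the invariant that catches
coordinate-arithmetic regressions. Positional arithmetic is authoritative
throughout: where a published intergenic column disagrees with its own
coordinates, the coordinates win.

Stop codons are classified from the sense length modulo 3: a complete
terminal triplet must be one of the vertebrate mitochondrial stops
(TAA, TAG, AGA, AGG); remainder 1 with a terminal `T` is the incomplete
stop `T--`, remainder 2 with `TA` is `TA-`, both completed to UAA by
polyadenylation of the transcript. Anything else — including codons
containing `N` — is reported as `NA` with a warning rather than silently
coerced. Features shorter than 6 nt cannot carry both a start and any
stop and are rejected as malformed.

## Composition and skew

Strand asymmetry is summarized by `AT-skew = (A − T)/(A + T)` and
`GC-skew = (G − C)/(G + C)`. Ambiguity codes (including `N`) are excluded
from every denominator; when more than 1% of a sequence is ambiguous a
warning reports the excluded fraction. A skew whose denominator is empty
is `NA`, not 0 — a sequence with no G or C has no defined GC-skew.

`skew_table()` defaults to `h_strand` mode: every gene is measured on the
physical heavy strand regardless of coding strand. This is a deliberate
choice, because the diagnostic signature of vertebrate mitogenomes — the
light-strand genes (ND6 and eight tRNAs) showing skew signs opposite to
the heavy-strand genes — only appears when all genes are read on the same
physical strand. `sense` mode is available and, for an L-strand gene,
equals the composition of the reverse complement; both skews exactly
negate under reverse complement, a property the suite verifies on random
sequences.

Reported tables round percentages to 2 decimals and skews to 3, matching
the precision conventions of the mitogenome literature; unrounded values
stay in the returned objects.

## Codon usage

The genetic code is fixed to the vertebrate mitochondrial code
(translation table 2): AUA encodes Met, UGA encodes Trp, and AGA/AGG are
stops, so the stop family has four members and serine six. The four stops
are treated as one RSCU family — this is required to reproduce published
mitogenome codon tables, where e.g. a UAA count of 3 among stop counts
{3, 1, 1, 2} gives RSCU 3/(7/4) = 1.71.

For codon *c* in synonymous family *F*,

> RSCU(*c*) = count(*c*) / (Σ count over *F* / |*F*|)

A family with zero total yields RSCU 0 for all members. Codon extraction
reads each protein-coding gene on its sense strand from the start codon in
consecutive triplets and drops the 1–2 nt incomplete terminal codon. All
complete triplets are counted: on the emulated *G. himalayensis*
architecture this gives 3,797 codons, whereas the published codon table
sums to 3,765 under an unstated exclusion rule; mitochar always uses the
counted total as the percentage denominator, so percentages and RSCU are
internally consistent with the counts they accompany.

Amino-acid usage ranks families by summed codon count with alphabetical
tie-breaks. On the published counts, leucine (587 codons across six
synonyms) outranks isoleucine (352), even though the single most frequent
codon is isoleucine's AUU — the two claims are often conflated in
descriptive papers, so `aa_usage()` reports both separately.

## Control-region structure

The CR is modelled as three domains: hypervariable DI at the 5′ end
(poly-C run, TACAT/ATGTA palindromic motifs), conserved central DII (the
F, E, D, C boxes), and DIII (conserved sequence blocks). `partition_cr()`
anchors DII on the first and last central-box hit — F preferred naturally,
since it is the most 5′ — and requires at least one central box and one
CSB-class hit, erroring with the missing anchors listed otherwise.

Motif scanning uses IUPAC patterns with a per-entry mismatch budget, under
subset semantics (a text base matches a pattern symbol if every base the
text symbol could denote is allowed by the pattern symbol, so a text `N`
matches only a pattern `N`). All overlapping hits are reported. Because
no single canonical avian box/CSB sequence exists, the shipped motif
library (`inst/extdata/motif_library.tsv`) contains provisional synthetic
placeholder consensi, is marked with a version string, and is meant to be
replaced for the taxon under study; every report echoes the library
version used.

## Tandem-repeat decomposition

`find_tandem_repeats()` implements a perfect-match repeat model: maximal
non-extendable arrays in which every position equals the position one unit
earlier, reported once with the smallest primitive unit (a unit that is
not itself a tandem of a shorter unit) and suppressing arrays wholly
contained in longer ones. The copy number is span/unit-length rounded to
one decimal, so a trailing partial unit contributes fractionally: 12 full
copies of an 11-mer plus its first 8 nt span 140 bp and report as
12.7 × (11). This reproduces the published notation (which prints 12.8
for the same array; the prose-derived 12 + 8/11 = 12.7 is what the
arithmetic gives, and mitochar reports the arithmetic). No
mismatch-tolerant (alignment-scored) mode is provided: the published
repeat reports are reproducible without one, and a scored model would
bring in gap/mismatch parameters with no ground truth to calibrate them.

Defaults `min_unit = 5`, `max_unit = 250`, `min_copies = 2`: published
CCR repeat units in Falconiformes range 9–219 bp, so 250 leaves headroom;
units below 5 bp in AT-rich noncoding sequence are dominated by chance
microsatellite-like runs; fewer than two copies is not a tandem. The 5′/3′
anchor of each array is assigned by which half of the region holds the
array midpoint, mirroring how published CCR tables prefix their repeat
entries. `decompose_ccr()` labels the gaps around arrays as nr-CCR so the
segments tile the region exactly — an invariant asserted on arbitrary
inputs.

The finder is validated two ways: equivalence with an exhaustive
tile-and-compare search over all (start, unit-length) pairs on hundreds of
small regions, and exact recovery (unit length exact, copy number within
±0.1) of planted cassettes across 500 seeded trials.

## Alignment site classification

Columns are classified over unambiguous A/C/G/T cells only; gaps and
ambiguity codes are ignored, and a column with fewer than two usable cells
is excluded from all counts (and reported). One observed state is
constant; two or more is variable; a variable column with at least two
states each in at least two taxa is parsimony-informative, otherwise a
singleton. The identities constant + variable = classified columns and
informative + singleton = variable hold by construction and are asserted.
The exclusion convention for gapped columns is a genuine free choice —
published site counts rarely state theirs, and indeed the published
counts this package's checks are modelled on do not reconcile exactly
(5,472 + 5,889 ≠ 11,364) — so real-data site counts are validated only
against the package's own stated convention, and synthetic truth.

## What the generator emulates — and what it does not

`generate_genome()` plants, by default, the study conditions of the
*G. himalayensis* mitogenome: the 39-feature remnant-CCR raptor layout
with its exact lengths, strands, overlaps and spacers (including the 22 bp
tRNA-Pro→ND6 spacer); H-strand background at the published overall base
frequencies (A 24.55, C 31.59, G 14.37, T 29.49 %); PCG content drawn
from the published codon distribution (stops excluded internally) framed
by the annotated start/stop codons, incomplete stops included; a CR with
poly-C, palindromes, boxes and CSBs planted at fixed offsets on
CR-specific background (T 33.1, C 25.9, A 23.5, G 17.5 %); and a 619 bp
CCR of nr-CCR segments plus the two published repeat units (11 bp × 12.7
and a 44 bp unit) sized to the annotated CCR length. Where published
sources disagree on the CCR length (689 vs 619 bp), the annotation's
619 bp wins and the cassette copy numbers are sized to fit.

Overlapping genes make naive per-feature synthesis inconsistent, so
assembly is ordered — structural RNAs, then CR/CCR, then PCGs — followed
by an edge fix-up pass that rewrites each PCG's start and stop on the
final sequence. In the default layout every overlap is compatible (e.g.
the ATP6 stop TAA and the COXIII start ATG legitimately share their
A at the single overlapping base); incompatible user layouts are detected
by re-classifying every PCG after assembly and raising a config error.
The emitted truth's codon stream is re-extracted from the final sequence,
so truth and sequence cannot drift apart.

Noncoding backgrounds are cleaned by targeted resampling (capped at 1,000
rounds) so that motif scans and repeat searches recover *exactly* the
planted layout — no accidental poly-C runs, motif copies, or tandem
arrays. This is what makes 100% recovery a meaningful test rather than a
statistical accident.

What the generator does **not** emulate: tRNA/rRNA sequences are
random-composition placeholders with no secondary structure; there is no
evolutionary model (alignments are built column-wise by planted class,
not along a tree, and contain no indel process); PCGs have no
reading-frame constraint beyond start/stop (internal stops may occur on
the H-strand reading of overlapped spans); and codon streams are i.i.d.
draws, so per-gene skew heterogeneity (e.g. the near-zero AT-skew of real
ND1 vs the strongly positive ND5) is not reproduced — only the pooled
composition and the strand-inversion signature are. Passing tests on
synthetic data therefore demonstrate coordinate bookkeeping, counting,
scanning and decomposition correctness, not biological realism of the
sequence itself.

Determinism: all randomness flows from one explicitly passed seed
(`with_seed` restores the caller's RNG state), and identical
(config, seed) pairs yield byte-identical genomes, reports included.

## Numerical and degenerate-input conventions

- Percentages to 2 decimals, skews to 3, copy numbers to 1 — in reports;
  returned objects keep full precision.
- Empty sequences, zero codon totals, annotation-less genomes, ragged
  alignments, non-IUPAC symbols, and GenBank records without ORIGIN or
  with multi-interval features are named errors, never silent coercions.
- Ties in amino-acid ranking break alphabetically; ties between
  equal-span repeat arrays keep the shorter unit.
- Rejection sampling is capped at 1,000 rounds per region; exceeding the
  cap is a config error rather than a hang.

## Problem sizes used by the test suite

The suite validates oracle equivalence on regions of 30–300 bp (500
seeded trials for the repeat finder, with max unit length 15 to keep the
exhaustive oracle honest but tractable), planted-unit recovery on 500
cassettes with units of 5–50 bp and 2–30 copies, site classification on
1,000 alignments of 4–8 taxa × 5–30 columns, closure on 200 randomized
annotations plus full 17.4 kb genomes, and composition fidelity at 20 kb
(3σ binomial bounds). These sizes were chosen so each property is
exercised across its parameter range while the whole suite stays
interactive (~1 minute).

## Known limitations

- The GenBank reader is minimal by design: single-interval features of
  the five mitogenome types, `/gene` or `/product` names. It is not a
  general flat-file parser.
- The repeat model is exact-match only; diverged repeat copies (as a
  TRF-style scored search would find) are reported as separate arrays or
  missed.
- The default motif library's box/CSB consensi are placeholders; motif
  hits on real data are only as good as the library supplied.
- Whole-genome composition of the real KY594709 sequence can only be
  checked when the user supplies the sequence (see
  `tests/testthat/test-acceptance.R`); the package ships coordinates and
  counts, not third-party sequence data.
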