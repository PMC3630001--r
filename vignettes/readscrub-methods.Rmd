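---
title: "Cleaning protocol-contaminated cDNA reads: models and design"
author: "readscrub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning protocol-contaminated cDNA reads: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readscrub)
```

## The problem

Single-end cDNA shotgun reads (454-style ESTs) carry pieces of the library
protocol besides the transcript insert: a 5' sample barcode (MID), sequencing
adapters at both ends, amplification primers — sometimes concatenated or in
the wrong orientation when the protocol misbehaves — a poly-A tail or poly-T
head from the mRNA, occasionally vector fragments, and low-quality ends.
Any of these left in the reads propagates into mis-assemblies and wrong
expression estimates, so cleaning is the first analysis step, and a cleaner
should also *report* what it found: a protocol that produces many
concatenated primers is a protocol that needs fixing.

`readscrub` identifies each contaminant class with an explicit model,
narrows a per-read **clean interval** (0-based, half-open) rather than
cutting bases — so every stage's action is inspectable afterwards through
the per-read trim log — and tallies what it saw into a QC report. A
separate evaluation module classifies a cleaner's output as over- or
under-trimmed against genome alignments.

## Barcode demultiplexing

Barcodes sit at the very 5' end, so the search is a semi-global alignment
anchored at position 0: the barcode must be consumed entirely, the read's
suffix is free, and costs are unit (mismatch 1, indel 1). A read is assigned
to the barcode with the fewest errors if that minimum is at most
`max_errors` (default 2); the clean start advances to the end of the barcode
alignment, taking the shortest prefix when several attain the minimum.
Two *different* barcodes tying at the minimum make the read
`ambiguous_barcode` rather than a guess — the QC report counts these
separately. When barcodes keep a pairwise edit distance greater than
`2 * max_errors`, a misassignment would require more errors than the
acceptance budget allows, so every assignment the tool makes is correct by
construction; the tests verify this property empirically.

An optional `max_offset` allows leading stray bases before the barcode; it
defaults to 0 (strictly anchored), which is the common library layout.

## Locating adapters, primers and vectors

Contaminant search is seed-and-extend. Exact shared words of length
`word_size` (default 11) between the subject — in both orientations — and
the read's clean interval are clustered by diagonal (within the band
half-width) into anchors. Reverse-orientation matches are found by
reverse-complementing the *subject*, never the read, so read coordinates
stay stable. Because sequencing errors near a read end can destroy every
exact word exactly where partial matches are expected, the search
additionally probes each subject flush at both interval ends in both
orientations; probe alignments of unrelated sequence fail the identity
criteria and cost little.

Each anchor is extended with a banded Needleman–Wunsch alignment
(match +1, mismatch −1, linear gap −2, band half-width 5 around the anchor
diagonal, widened only as far as needed to connect the matrix corners) over
the read window the band can reach. Subject bases that run past a read end
by more than the band cannot align to anything; they are recorded as
overhang up front instead of entering the DP as forced terminal gaps.

Two numerical choices in the extension deserve a note, because both were
forced by concrete failure modes:

* **Hit geometry is traced on a read-end-free ("fitting") variant of the
  banded DP, while the reported score is the global one** (both matrices
  share the band, so the global score still equals unbanded
  Needleman–Wunsch whenever the band covers the matrix). A purely global
  path must spend terminal-gap penalties on the arbitrary window flanks;
  when a flank resembles the subject — the neighbouring copy in a tandem
  primer concatenation is the extreme case — absorbing flank bases into the
  aligned core becomes score-optimal and dilutes the core's percent
  identity below threshold. The fitting objective makes the flanks free and
  the canonical placement optimal.
* **Equal-scoring traceback paths are resolved with a two-phase tie
  preference**: gap moves win until the first diagonal of the (backward)
  traceback, diagonals win afterwards. Score-neutral gap placements thus
  surface as terminal runs — trimmed into overhangs — rather than as core
  columns.

### Middle versus end acceptance

A hit in the middle of a read must be near-perfect: aligned length at least
`middle_min_len` (15) and identity at least `middle_min_pid` (94%). A hit
at a read end may be partial, so it is judged by three quantities instead:
identity at least `end_min_pid` (90%), at most `end_max_unaligned_subj`
subject bases hanging past the read end (default `len(subject) − 8`, i.e.
at least 8 subject bases must be present), and at most
`end_max_unaligned_read` (2) read bases left between the hit and the read
end. A hit counts as terminal when it starts or ends within `end_zone`
(default `end_max_unaligned_read + 3`) of an interval end.

The full-match criterion applies to *every* hit and the end criterion
additionally rescues terminal partial hits. Making the two rules exclusive
would open a dead band: a full-length perfect match whose read overhang
falls between `end_max_unaligned_read` and `end_zone` would fail the end
rule and never be offered the middle rule. These thresholds are this
package's documented defaults, chosen so middle matches are near-exact
while genuinely terminal partial matches get through; they are
configurable and make no claim of parity with any other tool's defaults.
Matches shorter than `word_size` carry no seed and are undetectable unless
flush at an end — that is the search's resolution limit.

## The erroneous-read taxonomy

Amplification-primer hits classify each read. An error-free (`OK`) read has
at most one forward primer flush at the 5' end and/or one reverse primer
flush at the 3' end. The error classes are `RF` (reverse match at the 5'
end with a forward match at the 3' end — a misoriented or chimeric
construct), `fr` (forward and reverse matches of the same primer),
`NF`/`NR` (two or more forward/reverse matches — concatenation), `SF`
(forward match preceded by unaligned clean bases) and `RE` (reverse match
followed by unaligned clean bases). When several apply, the biologically
fatal ones win: `RF > fr > NF > NR > SF > RE`. Layouts matching no error
pattern (for example a lone flush reverse hit at the 5' end, which only
means its partner went undetected) fall back to `OK`.

Two classification choices are deliberate. First, "unaligned bases
before/after" is judged with the tolerance `end_max_unaligned_read` — the
same number of terminal bases the end criterion already treats as
negligible — because a single noise-induced base of boundary jitter should
not relabel a clean read as `SF`/`RE`. Second, `SF`/`RE` require the
offending hit not to sit flush at the *opposite* read end, where the layout
is the `RF`-type misorientation signature instead.

Trimming follows classification: `OK` reads advance past the flush 5'
forward hit and stop before the flush 3' reverse hit; `RF` and `fr` reads
are discarded by default (the whole insert is suspect); `SF`, `RE`, `NF`,
`NR` are salvaged by keeping the longest hit-free sub-interval (leftmost on
ties). The policy is configurable per type because detection and
consequence are genuinely separable decisions. Adapter and vector hits are
treated as contamination wherever they fall: the longest hit-free stretch
survives.

## Poly-A tails and poly-T heads

The tail model has three parameters: the minimum tail length
(`min_len`, default 8), the minimum A-fraction of the tail
(`min_fraction`, default 0.75, strict inequality), and the maximum distance
of the tail's outer edge from the interval end (`max_end_offset`, default
3). Among all windows whose outer edge lies within the offset of the 3'
end, whose length reaches `min_len` and whose A-fraction strictly exceeds
the cutoff, the *longest* is trimmed (the outermost on ties). The 5' side
is handled symmetrically with T (`both_sides`, on by default), after the 3'
side, and the stage runs after primer trimming because tails sit just
inside the 3' primer.

One consequence of the longest-window definition is worth stating plainly:
a pure tail of length $L$ may absorb up to about $L/3$ adjacent non-A bases
at the default cutoff, because a window of $L$ A's plus $j$ other bases
keeps a fraction above 0.75 while $j < L/3$. That is not a bug but the
model: a transcript base adjacent to the tail that happens to extend a
qualifying window has no observable boundary separating it from the tail.
The implementation is verified against an exhaustive window-enumeration
oracle, and both it and the simulator's ground-truth annotation use the
same definition (see below). The strict `>` on the fraction and the
inclusive `>=` on the length are intentional.

## Quality trimming

Per-base Phred scores are scanned with a sliding window (`window`, default
10) from each end of the interval: the boundary advances while the window
mean is below `min_mean_q` (default 20), then settles on the first base in
the accepted window scoring at least the threshold, so poor bases rescued
only by a high window mean are still removed; the two scans repeat until
stable. Reads retaining fewer than `min_len` (40) bases are discarded as
`low_quality`. This is a deliberately simple end-trimming contract — no
error-probability integration, no internal masking, no read splitting — and
it is idempotent and monotone in the threshold, which the tests check.

## Over-/under-trimming evaluation

Given genome alignments (PSL) of the same reads cleaned by two tools A and
B, the evaluator drops reads mapped to multiple locations by either tool
and pairs whose alignments sit on different targets or strands or overlap
by fewer than `overlap_min` (40) genome bases. For each remaining read and
each read end: a cleaner that left unaligned query bases on that side
(beyond `end_tolerance`, default 0, strict) is **under**-trimmed there;
otherwise it is **over**-trimmed when its aligned genome boundary is not
the outermost of the pair (minimum start / maximum end in genome
coordinates), and **correct** otherwise. Minus-strand hits have query
coordinates flipped to read orientation first, and the genome start/end
sides map to read 5'/3' through the strand. Signed deltas accompany the
classes (positive = excess genome bases trimmed).

Over-trimming by this rule is relative, not absolute: if the genome
continues with the same bases the contaminant starts with, perfect cleaning
is still scored as over-trimming. The k-mer audit quantifies this: for
every over-trimmed end it extracts the `k` (default 6) original-read bases
anchored at the outer edge of the over-trimmed region and tallies them —
tails of A's and adapter prefixes dominating that table indicate the
"over-trimming" was correct removal of contaminant sequence.

## The synthetic-read generator

`simulate_reads()` is the package's test bed and demo data source. Reads
are assembled as `[barcode][adapter5][primer layout per planted
class][insert][poly-A tail][revcomp(3' primer)][adapter3]`, with the error
classes planting their defining artifact (misoriented primers for `RF`, a
self-ligated pair for `fr`, 5–10 junk bases for `SF`/`RE`, tandem copies
for `NF`/`NR`) and a configurable fraction of `OK` reads built head-to-tail
with a 5' poly-T head. Substitutions and indels are applied per base at
configurable rates, qualities follow a 454-like profile (plateau 38,
linear decay to a floor of 25 over the last 15% of the read, Gaussian
noise), and everything is reproducible bit-for-bit from the seed.

Ground truth must be *well defined* for recovery claims to mean anything,
so the generator enforces identifiability by construction:

* protocol sequences are homopolymer-free and share no 11-mer with each
  other in either orientation; inserts are rejection-sampled to share no
  11-mer with any protocol sequence;
* planted tails are at least the tail model's `min_len`;
* the annotated true interval applies the tail model itself (both sides) to
  the noise-free read, because transcript bases indistinguishable from the
  tail have no observable boundary — for the tail component, "truth" can
  only be defined by the model;
* for noisy reads, the noise-free truth boundaries are mapped through the
  corruption's coordinate map.

Under these conditions the pipeline recovers the planted clean interval
exactly for every noise-free `OK` read and the planted class for every
noise-free artifact read, and stays above 95% class recovery at 1%
substitutions + 0.5% indels — the validation suite measures all of this on
5000-read batches.

What the generator does **not** emulate, and what passing tests therefore
do not show about real data: flowgram-level 454 chemistry (homopolymer
over/under-calls are not specially boosted by default), realistic
transcript sequence composition (inserts are uniform random, so the
11-mer-sharing guard excludes a class of real-world ambiguity where
transcripts genuinely resemble primers), chimeric inserts beyond the
primer-layout taxonomy, correlated error bursts, and barcode sets less
separated than the configured minimum distance. On real data the same
thresholds will trade sensitivity against precision in ways only a
genome-based evaluation (the `compare_trimming()` module) can quantify.

## Validation scales and numerical conventions

The test suite validates the alignment kernel against a prefix
edit-distance oracle (10,000 random pairs at four error budgets), the
banded aligner against unbanded Needleman–Wunsch at full band width (1,000
pairs), the tail trimmer against the exhaustive window oracle (10,000
planted-tail reads), the full pipeline against planted ground truth (5,000
reads, noise-free and noisy), demultiplexing (5,000 reads, 8 barcodes at
distance ≥ 5), and the evaluator against a hand-computed grid of boundary
offsets. These sizes are the package's own validation choices: large enough
for the stochastic bounds to be stable, small enough to run routinely.

Conventions collected in one place: coordinates are 0-based half-open
everywhere, PSL included (it already is); `N` matches nothing, not even
another `N` (conservative trimming); alignment costs are unit for the
barcode DP and +1/−1/−2 for extension, with no affine gaps anywhere;
tie-breaks prefer leftmost-then-shortest alignments, the first maximum in
salvage-interval selection, and the smallest prefix in the barcode DP;
stages may only narrow the clean interval, never widen it, and an interval
that empties discards its read with a stage-specific reason.

## Known limitations

* Contaminant matches shorter than the seed word and away from the read
  ends are invisible; lowering `word_size` trades speed for sensitivity.
* Middle matches of short primers tolerate only one error at the default
  94% identity — a 23-mer primer copy carrying two substitutions in the
  middle of a read is rejected by design; it is still found when terminal.
* The quality module trims ends only; internal low-quality stretches pass
  through.
* The evaluator assumes colinear alignments at read ends when converting
  genome-boundary deltas to read coordinates for the k-mer audit; spliced
  alignments with terminal introns would need block-level handling.
* Vector screening uses the same seed-and-extend engine and criteria as
  adapter search; it does not reproduce any external screening tool's
  match categories.
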