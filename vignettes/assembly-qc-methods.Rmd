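---
title: "Methods: clone-based assembly QC, read-depth copy number, and tandem-duplication inference"
author: "asmqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clone-based assembly QC, read-depth copy number, and tandem-duplication inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmqc)
```

This vignette documents the statistical models and procedures implemented
in `asmqc`, the assumptions behind them, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the numerical
and design choices that were genuinely open.

## Coordinates

Everything internal is 0-based, half-open (`[start, end)`, the BED
convention), including window tracks, calls and simulator truth. Printed
genome-browser-style spans are 1-based inclusive; conversion happens only
at rendering. Chromosome names are compared by exact string match — no
`chr` prefix normalisation — because silent renaming hides input errors.

## Clone-pair concordance screening

A clone of insert length $L$ with end reads of length $r$ aligned at
leftmost positions $p_A, p_B$ implies a fragment
$[\min(p_A,p_B),\ \max(p_A,p_B)+r)$. Classification is a total function
over six mutually exclusive classes, applied in order: interchromosomal;
same-strand; everted (opposite strands, leftmost read on the minus
strand — orientation alone, sizes ignored, because eversion is the tandem-
duplication signature regardless of span); then inward pairs split by the
insert-size bounds into concordant / too short / too long. Bounds are
inclusive on both ends — the library range is stated as "between" its
extremes — and configurable, so bound sensitivity can be explored. Pairs
with both ends at the same position are treated as inward.

Physical coverage counts concordant *fragments* (not reads) overlapping
each fixed window by at least 1 bp; windows tile each chromosome from 0,
final partial window included. Unsupported segments are maximal runs of
zero-count windows, discarding any run containing a chromosome's first or
last window: terminal scaffold ends legitimately lack spanning clones, and
window granularity is the natural resolution of the screen.

### What the zero-coverage screen can and cannot see

A point worth stating precisely, because it shapes the recovery tests. The
screen detects assembly sequence that no concordant clone supports. For
*spurious sequence* (assembly containing material absent from the sample)
the signal is clean: no fragment can map inside the segment, flanking
concordant fragments stop at its edges, and every fully interior window has
exactly zero coverage — the simulator tests recover such events exactly.

An *inversion*, by contrast, is length-preserving. A pair straddling the
entire inverted segment keeps its implied size and orientation and remains
concordant; a pair wholly inside it has both ends strand-flipped and
position-mirrored, which restores an inward geometry — also concordant.
For any inversion length, interior windows are therefore overlapped by
concordant fragments and never reach zero physical coverage under ideal
end mapping. What an inversion *does* produce is a breakpoint-local
signature: pairs with exactly one end inside the segment become same-strand
discordant. The tests assert exactly this pair of behaviours: insertion-kind
misassemblies are recovered by the zero-coverage screen; inversions are
detected by their same-strand breakpoint signal localising within one
insert length of the engineered breakpoints.

## Interval-enrichment permutation test

The statistic is the number of query intervals hit (each counted once),
not overlapping base pairs, matching how interval-screen results are
normally reported. The null re-places each interval independently,
preserving its length, uniformly over all genome-wide positions where it
fits on a single chromosome — chromosome choice weighted by eligible start
count, shuffled intervals free to overlap each other, nothing excluded.
This is the default behaviour of the standard interval-shuffling tools; a
`per_chrom` switch restricts placement to the source chromosome for
sensitivity analysis, without asserting which convention any particular
published screen used. The p-value uses the add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$ so it can never be
0 — the appropriate convention for permutation nulls. Calibration is
tested: with the query itself drawn from the null, the fraction of
p-values $\le 0.05$ over 200 replicates must fall within the binomial band
$[0.01, 0.12]$.

## Finished-clone accuracy

Clones are aligned to their placement interval by global dynamic
programming with affine gaps; a gap run of length $\ell$ costs
$g_{open} + g_{ext}\,\ell$, with DNA defaults 5 / −4 / 16 / 4. IUPAC
ambiguity codes are tolerated but always score as mismatches — the
conservative stance that every non-identity is a potential error.
Traceback tie-breaks are fixed (diagonal, then gap in the second sequence,
then gap in the first), so output is deterministic. The implementation is
a compiled banded DP: with `band = b` only cells within $b$ of the main
diagonal are evaluated (auto-widened to at least the length difference),
which is exact whenever the optimal path stays inside the band — the case
for finished clones against their own locus, where divergence is a few
parts in $10^4$. The full quadratic DP (`band = 0`) is the default and is
cross-checked in the tests against an independent aligner
(`Biostrings::pairwiseAlignment`) on random sequence pairs.

Accuracy accounting discards gap columns: with $m$ mismatches among $n$
aligned-nucleotide columns, $Q = -10\log_{10}(m/n)$, rounded **half-up**
(nearest integer, ties away from zero) — the worked pooled example
$m = 14{,}255$, $n = 26{,}778{,}153$ gives 32.74, i.e. Q33, whereas
flooring would give Q32. At $m = 0$ a continuity floor of $0.5$ observed
mismatches keeps the estimate finite. Aligned-nucleotide counts are taken
exactly as the both-base columns of the provided alignment; no end
trimming is second-guessed.

## Read-depth copy number

Windows accumulate unmasked sequence left to right and close at exactly
3,000 unmasked bp (configurable), stretching over masked spans; the
terminal remainder keeps its actual count, and the tests verify per-window
unmasked content and whole-chromosome conservation against a per-bp
recount. Copy number is
$\mathrm{CN}(w) = 2\,\frac{\text{rate}(w)}{\text{rate}(\text{control})}$
with rate = depth per unmasked bp. The control statistic is the **mean**
per-window rate over windows overlapping the control regions (the choice
the normalisation identity is tested against; a median option exists, and
GC correction is left to the upstream depth pipeline — the simulator emits
GC-neutral depth, and a correction hook would be a no-op here). Control
regions are a direct BED input.

Duplications are maximal runs of $\ge 4$ consecutive windows with
$\mathrm{CN} \ge 2.5$, both thresholds inclusive; a single sub-threshold
window breaks a run, runs never bridge chromosomes, and terminal windows
with under 50 % of the target unmasked content are excluded as unstable
denominators (configurable). Self-alignment duplication records are kept
at identity $\ge 90$ % and length $\ge 1$ kb, inclusive, and the merged
footprint of both record intervals is reported.

## Indel size spectra

Sizes strictly greater than 10 bp survive ("longer than 10 bp"); calls
overlapping any exclude set by $\ge 1$ bp are removed; filtering is
idempotent and its output provably disjoint from the excludes. Histograms
use bins of equal width on a log scale,
$[\,s_0 10^{k/d},\ s_0 10^{(k+1)/d})$ with $d$ bins per decade — the bin
width is a free display parameter, defaulting to 10 per decade. The
dimorphic mobile-element windows default to 150–250 bp (SINE) and 5–7 kb
(LINE), chosen around the characteristic ~200 bp and ~6 kb peaks; both are
configurable since no canonical window exists.

## Tandem duplications

Everted pairs on one chromosome are clustered by single linkage with a
fragment-gap threshold (default 10 kb, support $\ge 3$). The junction
estimate is the median midpoint between the everted end positions. Two
geometric facts matter:

* Eversion requires both ends inside duplicated copies. With inserts of
  ~40 kb, a two-copy duplication produces everted pairs only when its unit
  is at least insert-sized; short units in few copies instead yield
  size-discordant pairs, and multi-copy arrays (amylase-like) yield everted
  pairs at any unit length. The simulator reproduces this, and the tests
  exploit it.
* The everted end positions spread over roughly one insert length around
  the unit boundaries, so the median junction estimate concentrates at rate
  $\sim \mu_{insert}/\sqrt{n}$ — a few kb at typical support — regardless
  of the insert-size sd. Cluster spans are reported, but unit *lengths* are
  never inferred from clone spans: with units both far larger and far
  smaller than the insert, span-based length inference is
  geometry-dependent. Lengths come from split reads.

Split reads spanning a copy-to-copy junction align as two reference
segments, one ending at the unit end $e$, one starting at the unit start
$s$; the unit is $[\text{median}(s_i), \text{median}(e_i))$ — medians for
robustness to chimeric records, exact on noiseless input, within the
jitter radius under uniform breakpoint noise. Records with inferred
$s \ge e$ are rejected.

Allele decomposition enumerates all unordered tuples of positive integers
summing to the total diploid copy number, filtered by a multiset of fixed
per-allele counts; enumeration is exhaustive (totals here are small), and
infeasible constraints return an empty set with a diagnostic.

## The synthetic-data generator

The generator is the package's test instrument, and its defaults are the
study conditions the analyses assume: ~40 kb inserts
(mean 39 kb, sd 1 kb, truncated below at $2r$ to avoid overlapping-end
geometry), 500 bp end reads, 30× mean diploid depth, 3 kbp unmasked
windows, and clone error rates of order $10^{-3}$–$10^{-4}$ per bp.
Heterozygous events are realised as two explicit haplotypes mixed 50/50 in
clone placement and averaged in expected depth. Fragment ends are mapped
back to reference space through the engineered events, so orientation
signatures arise from geometry rather than labels; ends falling in novel
sequence or straddling a mapping segment boundary are dropped as
unmappable, as a real aligner would split or discard them. Depth is
simulated per window — $\text{Poisson}(\mu \cdot u_w \cdot
\mathrm{CN}_w/2)$, with $\mathrm{CN}_w$ the truth copy number averaged
over the window — not per read.

What it deliberately does not emulate: GC bias and mappability structure
in depth; sequencing-error models for long reads; chimeric clones and
mapping ambiguity; repeat-driven mis-mapping. Passing recovery tests
therefore demonstrate the estimators' correctness under their stated
statistical models, not robustness to every artefact of real data — the
filters those artefacts require (GC correction, repeat masks, control-region
curation) enter as inputs, not as modelled noise.

## Problem sizes and determinism

The test and acceptance workloads use chromosomes of 2–10 Mb, 2,000–12,000
clones, 20 depth-simulation replicates for duplication recovery, 200
replicate permutation tests of 99 permutations for null calibration, and
1 Mb of pooled clone alignment (25 × 40 kb, banded) for rate recovery —
sizes chosen so every property is measured at comfortable statistical
resolution while the whole suite runs in minutes on one core. Every
simulator is a pure function of (arguments, seed) on top of R's RNG, the
CLI stages write byte-identical outputs under a fixed `--seed`, and
writers emit fixed column orders with locale-independent sorting.

## Known limitations

* The concordance screen counts each clone record once; duplicate clone
  ids are not collapsed (whether published screens deduplicated is not
  generally stated).
* The banded aligner is exact only while the optimal path stays in-band;
  for highly divergent pairs use `band = 0` (quadratic).
* `estimate_copy_number` treats any window overlapping a control region as
  a control window; control regions should be chosen clear of suspected
  events.
* The permutation null re-places intervals independently; clumped query
  sets are represented only through their lengths.
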