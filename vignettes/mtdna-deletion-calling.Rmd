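---
title: "Calling mitochondrial DNA deletions from Cas9-targeted long reads"
author: "mtdelscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling mitochondrial DNA deletions from Cas9-targeted long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtdelscan)
```

## The problem

Somatic deletions of the 16,569 bp circular human mitochondrial genome
accumulate with age in postmitotic tissues. Nanopore Cas9-targeted
sequencing (nCATS) cuts the mitochondrial circle at a single guide site and
ligates sequencing adaptors to the cut ends, so each read is a single
unamplified mtDNA molecule linearized at the cut. Because every molecule is
sequenced whole, a deletion shows up *within* one read, and the deletion
frequency per molecule can be estimated directly as
(deletions above a size floor) / (mtDNA reads).

Calling those deletions from long-read alignments is not a solved
preprocessing step. Aligners represent small deletions as `D` runs inside
the primary alignment's CIGAR, but increasingly often report large
deletions as *chimeric* alignments: a primary plus a flag-2048
supplementary segment that are adjacent on the read but far apart on the
reference. A caller that only parses primary CIGARs therefore loses
sensitivity precisely for the large deletions that carry most of the aging
signal. `mtdelscan` implements three callers and their combination:

1. **Primary-CIGAR** — every `D` run strictly longer than 100 bp is a
   candidate; candidates on the same read within 300 bp are merged into a
   single event (the merged event spans from the first candidate's start to
   the last candidate's end — a single junction is what downstream per-read
   counts represent).
2. **Chimeric** — segments of one read are ordered along the query; an
   adjacent pair yields a deletion spanning the reference interval between
   them if each segment exceeds 200 bp, the pair is query-contiguous within
   300 bp, overlaps by less than 50 bp on both query and reference, lies on
   one strand, and is separated on the reference by more than the 100 bp
   size floor.
3. **Realignment** — reads whose length disagrees with their aligned
   reference span by more than 500 bp are realigned from scratch with an
   affine-gap local aligner (match 2, mismatch −3, gap open 5, extend 2,
   minimum score 100, both orientations tried); the aligned query interval
   is masked and the best remaining flank realigned; the two resulting
   segments must pass the same pairing rules as the chimeric caller.

Per read, calls from different callers whose intervals fall within 300 bp
are collapsed to their union, attributed to the highest-sensitivity source,
so a deletion found twice is counted once.

## The rotated reference

nCATS reads start at the cut site, which for the human guide falls after
standard position 1547 inside the minor arc. Aligning against the standard
circle would split every read across the origin; instead the reference is
*rotated*: bases 1..1547 are moved to the end, so rotated position 1 is
standard position 1548 and no read- or deletion-interval ever wraps.
All calling happens in the rotated frame; reported tables carry both
frames (`start_rot`/`end_rot` half-open, `start_std`/`end_std` the first
and last deleted base, with `start_std > end_std` for the rare event
spanning the standard origin).

One consequence worth spelling out: a deletion junction at rotated
position 4000 sits at standard position 4000 + 1547 = 5547. Descriptions
of the same simulated deletion set can therefore legitimately quote either
number depending on the frame; the generator below uses the rotated-frame
default 4000 and both are configurable.

Internally the package uses the 1-based closed/half-open conventions of
the Bioconductor stack (IRanges, GenomicAlignments, Rsamtools) end to end.
A 0-based layer mirroring BAM internals was considered and rejected: every
library boundary would need a conversion, and the conversions are where
off-by-one bugs live.

The minor arc (standard 408–5746) and major arc (5747 wrapping to 407) are
modeled as rotated-frame intervals; with the default cut the rotated minor
arc splits into `[1, 4199]` and `[15430, 16569]`. A deletion whose deleted
bases fit inside a single arc interval is classed `minor` or `major`,
anything else `both`. An exhaustive per-base oracle over random intervals
backs this in the tests.

## The read simulator

There is no public truth set for single-molecule mtDNA deletions, so the
package ships its own generator, and the generator — not any external
sequencing run — defines the benchmark conditions:

* ten template genomes, each the rotated reference with one deletion
  starting at rotated 4000 bp and extending 1–10 kbp (`sim_config()`);
* 500 reads per template by default; reads start at template position 1
  plus a uniform jitter of up to 50 bp (nCATS reads begin at the cut),
  85% on the forward strand, matching the strand bias downstream of the
  Cas9 PAM;
* lognormal read lengths (median 7 kbp, sdlog 0.55), truncated at the
  template length — a molecule cannot yield a read longer than itself;
* independent per-base errors: 4% mismatch, 2% insertion, 2% deletion
  (~8% aggregate, the right order for nanopore R9 chemistry).

Two design choices deserve justification:

**Paired geometry.** Read lengths, starts and strands are drawn once per
read ordinal and reused across all ten templates. Detection differences
between deletion sizes are then driven by the deletion size alone rather
than by resampled read populations — the common-random-numbers device from
simulation methodology. The same pairing is applied to the `mixed`-style
split decision below, which makes the primary-caller sensitivity curve
exactly non-increasing in deletion size instead of non-increasing in
expectation only.

**Idealized SAM fixtures.** `write_sam_fixture()` emits alignments
computed from the truth geometry, not from running an aligner: `cigar_D`
style encodes every junction as `<a>M<size>D<b>M`; `chimeric` style splits
each junction into a primary (the longer piece, soft-clipped) plus a
hard-clipped supplementary, query-contiguous and reference-distant;
`mixed` style chooses per read with probability
`plogis((size - 3000)/1200)` of a chimeric representation. The logistic
midpoint and scale emulate the empirical behaviour of long-read aligners,
which keep ~kb deletions in the CIGAR but split most deletions beyond a
few kb; they are simulator parameters, not claims about any specific
aligner version. What the fixtures deliberately do **not** model:
alignment-endpoint wobble around the junction, reference bias at direct
repeats, error-induced clipping, and mapping-quality degradation. Passing
the benchmark therefore demonstrates the callers' *logic* (thresholds,
pairing, merging, coordinate arithmetic) under controlled representation
shifts — it does not certify sensitivity on any particular aligner's
output, which is why the alignment step itself is kept external and
swappable.

The FASTQ output (with errors applied; reverse-strand reads
reverse-complemented) feeds the realignment caller, which is exercised on
the raw sequences and recovers simulated junctions exactly at zero error
and within the 300 bp pairing window at 10% aggregate error.

## Read-level filters

Only reads strictly longer than 400 bp (below which mtDNA cannot be
distinguished from nuclear copies of mitochondrial segments, NUMTs) and
strictly shorter than 17,000 bp (above which a read cannot be a single
mtDNA molecule) enter calling, with an optional mean base-quality floor of
Phred 5 applied when qualities are present. The filters are applied
uniformly before *all* callers so that every frequency shares one
denominator: the number of distinct filtered reads with a primary mtDNA
alignment.

## Statistics

`deletion_frequency()` is (calls with size > minimum) / (mtDNA reads); it
is non-increasing in the minimum by construction. `regress_log_freq()`
fits ordinary least squares of log10 frequency on donor age or on log10
ddPCR frequency. Samples with zero qualifying deletions have no defined
log frequency and are excluded from that threshold's regression — no
pseudocounts, because a pseudocount would manufacture a depth-dependent
floor exactly where the data are least informative.
`threshold_sweep()` repeats the regression over a grid of minimum sizes
and reports the threshold with the highest R², resolving ties toward the
smallest threshold; thresholds where fewer than three samples retain
events are reported missing, not zero.

`density_compare()` tests equality of two breakpoint distributions: both
samples are smoothed with a Gaussian kernel of standard deviation
`h = 50` bp on a 512-point grid spanning the genome, the statistic is the
integrated squared difference of the two density estimates, and the null
is built by permuting group labels over the pooled sample (p-value
`(1 + #{T_perm >= T_obs}) / (1 + n_permutations)`, so its floor is
`1/(n+1)`). The density is treated linearly, not circularly: with the
genome cut at the Cas9 site, breakpoints cannot wrap, and a linear kernel
matches how such breakpoint densities are conventionally estimated. The
permutation scheme always draws the smaller group's size from the sorted
pool, which makes the test exactly invariant under swapping the two
inputs at a fixed seed. Both endpoints of every deletion are pooled by
default (`starts` and `ends` are available separately via
`breakpoints_from_calls()`), and the default permutation count is 1,000.
Under the null the test is exact: a 500-replicate calibration in the test
suite keeps the rejection rate at nominal level.

`welch_t()` compares per-sample frequencies between groups with Welch's
unequal-variance t-test, on the log10 scale by default since frequencies
span orders of magnitude; a raw-scale option exists.
`subsample_reads()` provides the seeded uniform read subsamples used to
normalize depth across samples before plotting.

## The synthetic validation cohort

`simulate_cohort()` generates 15 samples aged 20–81 with two deletion
populations: an age-dependent signal in the major arc whose expected
per-read frequency follows `log10 f = intercept + slope * age` with
lognormal scatter (defaults: 4.3e-5 at age 25 rising 59-fold by age 75,
scatter 0.15 log10 units), and an age-independent minor-arc noise
population at 3e-3 per read with sizes ≤ 2 kbp. The signal size is fixed
at 9 kbp: every sweep threshold from 2 kbp to just below 9 kbp then
retains the identical signal set, their regressions tie exactly, and the
sweep's tie-break must report 2 kbp — a deterministic target. Thresholds
below 2 kbp admit the flat noise and score visibly lower. The default
read depth (2e5 per sample) keeps Poisson counting noise in the youngest,
lowest-count samples subdominant to the biological scatter; at lower
depth the OLS standard error understates the slope uncertainty and a
nominal 2-SE recovery check is no longer calibrated.

This cohort validates the statistics layer only. It does not model
read-level effects (those are the read simulator's job), breakpoint
hotspots, or shared reads between deletions.

## Numerical and degenerate-input choices

* All thresholds are strict inequalities (`> 100 bp`, `> 400 bp`,
  `< 17,000 bp`, `< 50 bp` overlap), and the unit tests pin every
  boundary from both sides.
* Chimeric pairs must share a strand; opposite-strand splits are
  inversion-like rearrangements and out of scope.
* Reads with several supplementary segments are chained pairwise along
  the query, one call per compatible adjacent junction; this reduces to
  the plain pair rule for the two-segment case.
* A constant regression response returns slope 0 and R² 0 rather than an
  unstable 0/0.
* Zero-read samples make `deletion_frequency()` error rather than return
  a silent `NaN`.
* `combine_calls()` treats overlapping-or-near intervals (gap ≤ 300 bp)
  on one read as one event and keeps their union; whether the true merged
  size should instead be the sum of the constituent `D` runs is not
  decidable from first principles — the union was chosen because a single
  junction-spanning molecule is the unit that per-read frequencies count.

## Problem sizes used in the test suite

The shipped benchmark runs 10 templates × 50 reads (~8% error) for the
sensitivity experiment, 100 randomized single-supplementary fixtures for
the caller-vs-oracle equivalence check, 500 replicates × 199 permutations
for the density-test calibration, and the 15-sample cohort above for
parameter recovery; these sizes give stable statistics while keeping the
whole suite comfortably reproducible on a laptop. The full-scale defaults
(500 reads per template, 1,000 permutations) are one flag away in
`sim_config()` and `density_compare()`.

## Known limitations

* The fixtures' representation model (logistic split by size) is a
  caricature of aligner behaviour; sensitivity numbers on real alignments
  will differ, and the alignment step is deliberately external.
* The realignment caller's two-pass scheme emits at most one junction per
  read; a read carrying two widely separated deletions is fully handled
  only by the CIGAR and chimeric callers.
* Insertions, duplications, inversions and SNV heteroplasmy are out of
  scope, as is NUMT detection.
* The density test assumes exchangeability under the null; strong
  per-sample clustering of breakpoints would call for a hierarchical
  permutation that is not implemented.
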