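# mtdelscan

Detection and quantitation of mitochondrial DNA (mtDNA) deletion mutations
from Cas9-targeted nanopore long reads.

## What problem this solves, and for whom

Somatic deletions of the 16,569 bp circular mitochondrial genome accumulate
with age and disease. Nanopore Cas9-targeted sequencing (nCATS) linearizes
each mtDNA molecule at a single guide cut and sequences it whole, so a
deletion is visible *inside* a single read and the deletion frequency per
molecule is simply

```
f(s) = #{deletions with size > s} / #{mtDNA reads}
```

The catch is the calling step: long-read aligners keep small deletions as
`D` runs in the primary alignment's CIGAR but report large ones as
*chimeric* alignments (a primary plus a flag-2048 supplementary segment,
adjacent on the read, distant on the reference). A CIGAR-only caller
therefore goes blind exactly where the aging signal lives. `mtdelscan` is
for anyone analyzing targeted long-read mtDNA data who needs
single-molecule deletion calls and the downstream statistics:

* **Rotated reference** — the circle is re-origined at the Cas9 cut
  (offset 1547 for the human guide) so reads and deletions never wrap;
  bidirectional coordinate maps and minor/major-arc classification
  (minor arc = standard 408–5746) are provided.
* **Three callers** — primary-CIGAR (`D` runs > 100 bp, merged within
  300 bp), chimeric pairing (segments > 200 bp, query-contiguous within
  300 bp, overlap < 50 bp on query and reference, same strand), and
  two-pass local realignment (triggered when read length and aligned span
  disagree by > 500 bp; affine-gap Smith–Waterman, match 2 / mismatch −3 /
  open 5 / extend 2). Per-read de-duplication combines the call sets.
* **An nCATS-style simulator** — deletion-bearing templates, seeded reads
  with a configurable error model, ground-truth tables, and SAM fixtures
  (`cigar_D`, `chimeric`, or a size-dependent `mixed` representation), so
  the whole pipeline is benchmarkable without any sequencing data.
* **Statistics** — per-sample deletion frequency, minimum-size threshold
  sweeps against donor age or ddPCR frequency (log10 OLS), arc-stratified
  trends, Welch's t between groups, seeded read subsampling, and a
  kernel-density permutation test (Gaussian kernel, h = 50 bp) comparing
  breakpoint distributions between tissues or against database catalogs.

## Worked example

Simulate the benchmark (10 templates carrying 1–10 kbp deletions starting
at rotated position 4000, 100 reads each, ~8% aggregate error), call
deletions from the mixed-representation alignments, and measure sensitivity
against truth:

```r
library(mtdelscan)

set.seed(1)
genome <- paste(sample(c("A","C","G","T"), 16569, TRUE,
                       prob = c(.31, .31, .13, .25)), collapse = "")
ref <- rotate_reference(genome, 1547)

cfg <- sim_config(reads_per_template = 100, seed = 1)
run <- cmd_simulate(ref, cfg, "sim_out", styles = "mixed")

calls_p <- cmd_call("sim_out/fixture_mixed.sam", ref, callers = "primary_cigar")
calls_c <- cmd_call("sim_out/fixture_mixed.sam", ref)   # primary + chimeric

sens <- cbind(
  sensitivity_by_size(run$sim$truth, calls_p)[c("del_size", "n_spanning", "fraction")],
  combined = sensitivity_by_size(run$sim$truth, calls_c)$fraction)
names(sens)[3] <- "primary_only"
print(sens, digits = 3)
```

```
   del_size n_spanning primary_only combined
1      1000         89       0.8876    1.000
2      2000         89       0.7528    1.000
3      3000         89       0.5056    0.989
4      4000         89       0.3371    0.989
5      5000         89       0.1461    0.989
6      6000         89       0.0449    0.989
7      7000         89       0.0112    0.989
8      8000         89       0.0112    0.989
9      9000         89       0.0000    0.989
10    10000         89       0.0000    0.989
```

Primary-CIGAR-only sensitivity collapses as deletions grow (they are
increasingly represented as chimeric alignments), while the combined
caller stays near 1 at every size. Calls carry both coordinate frames and
the arc class:

```r
head(calls_c[calls_c$size > 2000, ], 3)
```

```
                read_id start_rot end_rot  size   source start_std end_std  arc
90 del4000_s10000_r0001      4000   14000 10000 chimeric      5547   15546 both
```

(Note the frames: the junction at rotated 4000 is standard 5547.)

Cohort-level statistics on a synthetic 15-sample aging cohort:

```r
cohort <- simulate_cohort(ref, seed = 1)
sw  <- threshold_sweep(cohort, seq(500, 8000, 500), "age")
fit <- regress_log_freq(cohort, "age", min_size = 2000)
```

```
best threshold: 2000 bp
slope: 0.0345 log10/yr (generating 0.0354), R^2 = 0.95
```

The sweep recovers 2 kbp as the smallest minimum size isolating the
age-dependent deletion population, and the regression recovers the
generating slope within its standard error.

A command-line front end wrapping the same functions ships at
`system.file("cli", "mtdel.R", package = "mtdelscan")` with subcommands
`simulate`, `call`, `stats` and `sensitivity`.

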