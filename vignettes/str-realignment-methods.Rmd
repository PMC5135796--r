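---
title: "Repeat-aware realignment over STR regions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat-aware realignment over STR regions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strrealign)
```

## The problem

Short tandem repeats (STRs) — tracts of a 1–6 bp unit repeated in tandem —
vary in unit copy number between individuals.  A read sampled from a
non-reference allele differs from the reference by an insertion or deletion
of whole repeat units.  Seed-and-extend mappers place such reads by their
unique flank sequence and frequently soft-clip the other end instead of
introducing the repeat-length gap, or place the gap inconsistently between
tools.  Downstream repeat-size estimation from spanning reads then fails or
is biased.  This package realigns mapped reads around catalogued STR
regions with a dynamic program that knows the repeat structure, and writes
the result back as standard reference CIGARs.

## The genome model

The alignment target for a locus is not the raw reference but an ordered
series of subsequences $G_1,\dots,G_m$.  Flanking reference sequence enters
literally and is used once ($B_j = 0$); each catalogued STR region is
represented by a *single copy of its repeat unit* flagged reusable
($B_j = 1$).  A reusable subsequence may be traversed cyclically any number
of times — zero included — so one model expresses every repeat length.
Adjacent regions with no intervening reference yield consecutive reusable
subsequences, which the algorithm handles without special casing.

Catalogued intervals often contain irregular bases that do not follow the
annotated unit.  Before model construction each region is trimmed to the
longest interval whose in-frame mismatch fraction against tandem unit
copies is at most `error_rate` (default 0.1, leftmost interval on ties,
all unit frames tried).  Regions left with less than one unit length are
dropped.  Homopolymer regions of at least `homopolymer_skip` bp (default
15) are excluded from realignment by default: bases following long
homopolymer runs are error-enriched on Illumina instruments and realignment
there is counterproductive.

## The dynamic program

For read $R$ and model position $(j,k)$ (position $k$ of subsequence
$G_j$), six state families are kept: match/mismatch $s_M(i,j,k)$, insertion
$s_I(i,j,k)$, single deletion $s_D(i,j,k)$, bounded multi-deletion
$s_D(i,j,k,l)$ inside reusable subsequences, and left/right clips
$s_L(i)$, $s_R(i)$.  The total penalty is minimized; defaults equal the
BWA-MEM scoring defaults: match $-1$ (a reward), mismatch $4$, gap open
$6$, gap extension $1$, clip $5$.  Real-valued penalties are accepted.

Key transitions:

* **Cyclic reuse.** Inside a reusable unit the predecessor of position $k$
  is position $k-1$ modulo the unit length, so matches may wrap tail to
  head indefinitely — this is what models arbitrary copy numbers.
* **Boundary scan.** A match at the first position of $G_j$ may descend
  from the tails of preceding subsequences, scanning back until the first
  $B = 0$ subsequence (inclusive); reusable subsequences passed over are
  skipped free of charge, which is how a zero-copy allele (full tract
  deletion) is expressed.  The scan is computed incrementally so the cost
  per query row stays $O(\sum_j |G_j|)$.
* **Rotating multi-deletions.** Unbounded deletions inside a reusable unit
  would be degenerate (the unit can be reused forever), so deletion runs
  there are limited to $l < |G_j|$ and may rotate from the unit tail to its
  head: a deletion of $l$ consecutive unit positions ending at phase $k$ is
  opened from the match state at phase $(k-l) \bmod |G_j|$ and costs
  $p_{do} + (l-1)\,p_{de}$.  Net losses of whole copies are expressed by
  the free cyclic/boundary transitions instead, so the bound loses nothing.
* **Clips.** A clip costs a flat $p_c$ per event regardless of length.  A
  left clip may resume matching at any model position; a right clip may
  follow any match state; a fully clipped read is rejected.
* **Fitting semantics.** Unaligned model prefix and suffix are free: the
  window is longer than the read by construction, and penalizing the
  uncovered model would punish reads near window edges.

Multi-deletion states are not materialized: their penalty is the closed
form above and their traceback is the chained single deletion, so the
tables stay $O(|R|\sum_j|G_j|)$ while per-row update cost is
$O(\sum_j |G_j| + \sum_{B_j=1} |G_j|^2)$.  An explicitly materialized mode
exists solely for the equivalence check in the test suite; both modes
produce identical penalties and paths.

Ties are broken deterministically: candidate predecessors are evaluated in
a fixed order (match states first, then deletions, insertions, clips;
smaller positions first) with strict improvement required, so identical
inputs always give identical tracebacks.

## Projection back to the reference

Flank-aligned path segments translate positionally.  Each repeat-aligned
read fragment is realigned — same affine machinery, no reusable
subsequences — against the reference STR region sequence plus *one
trailing repeat-unit copy*, with the region's deletion-open penalty
lowered to `str_del_open` (default 4).  The trailing unit absorbs overflow
from irregular tracts; fragment bases aligned to it consume no reference
and project as insertions.  Anchoring follows the path context: a fragment
bounded by flank segments must cover the region end to end, while the side
on which the read itself begins or ends inside the tract is free.  In the
second pass, tie-breaking right-aligns insertions so repeat overflow
merges with the trailing-unit projection into a single insertion run.
Regions traversed with zero copies, and reusable subsequences skipped at
boundaries, project as deletions.  Clips become soft clips.  The stitched
CIGAR is validated (query-length consistency, monotone reference
coordinates); on any inconsistency the original record is kept.

A read is rewritten only when its projected alignment, rescored against
the reference with the standard penalties, is *strictly* better than the
original alignment rescored identically.  This makes the pipeline
fail-safe (no record ever gets worse) and idempotent (a second pass finds
no improvement and changes nothing).  Rewritten records keep their mapping
quality and mate fields, and record the original position and CIGAR in the
SAM-standard `OP`/`OC` tags; mate positions are refreshed only when both
ends were rewritten in the same run.  Reads clipped on both ends with
fewer than `min_aligned` (default 20) aligned bases keep their original
alignment as a guard against spurious fits.

## The synthetic benchmark

The simulator generates desk-scale versions of the study conditions used
throughout the package's tests:

* a random reference (default 100 kb) with ~50 implanted pure tracts,
  periods cycling over 1–6, reference tract sizes uniform in 16–72 bp,
  with the bases adjacent to each tract forced to break the repeat so the
  catalogued interval is exactly the maximal tract;
* a diploid genome in which each haplotype's repeat number is drawn
  uniformly over the range keeping the tract within 100 bp (reads of
  100 bp cannot span longer tracts, and the uniform prior is the simplest
  choice consistent with "randomly sampled repeat numbers");
* paired-end 100 bp reads at 40× (10× by downsampling pairs), fragment
  starts uniform, insert sizes Normal(500, 50) truncated at the read
  length, i.i.d. substitution errors at 0.1%, all qualities Q30.  The
  error model is substitution-only; no sequencer indels or PCR stutter.

The pre-realignment BAM is produced by an *emulated* seed-and-extend
mapper: each read is placed at its known simulated origin lifted to
reference coordinates (anchored by either flank, whichever scores better)
and extended without gaps, soft-clipping whatever does not fit — the
dominant mapper failure mode at STR loci, and exactly the artifact the
realigner is designed to repair.  This keeps the benchmark offline and
deterministic; it does not reproduce every behavior of a real mapper
(real mappers do place some repeat-length gaps, and mapping error away
from the simulated origin is absent), so absolute benchmark numbers are
not comparable to published mapper studies — only the before/after
contrast is meaningful.

Repeat sizes are then called by a deliberately naive spanning-read
estimator: reads spanning a region plus 5 bp of each flank imply a size
(`ref_size + insertions − deletions` inside the region); the two most
frequent sizes are called, one homozygous size if it holds ≥ 70% of the
spanning reads, and NA below 3 spanning reads.  The 70%/3 thresholds are
package choices — the estimator exists to measure alignment quality end to
end, not to compete with dedicated STR genotypers.  Alleles longer than a
read minus the flank margins are inherently uncallable from spanning
reads, which bounds the attainable call rate and RMSE in the benchmark.

Evaluation statistics: call rate (fraction of regions with a non-NA call,
per period and total); RMSE in bp between estimated and true diploid
sizes, NA calls replaced by the reference size, the two estimated alleles
paired with the two true alleles at minimum total squared error and pooled
per allele (a summed-diploid alternative is available); and Mendelian trio
consistency, where a child call (a, b) is consistent when one allele
occurs among one parent's called sizes and the other among the other
parent's, an NA parent being unconstrained.

## Numerical and scale choices

Penalties are held in doubles; with the integer defaults all comparisons
are exact.  The test suite verifies the engine against an independent
enumeration oracle on 1000 random tiny instances (reads ≤ 8 bp, models
≤ 12 bp), against a textbook affine fitting alignment in the no-repeat
no-clip limit, and runs the full pipeline on the 100 kb / ~50-region / 40×
benchmark above; the acceptance script repeats the benchmark plus a
simulated trio (60 kb, 30 regions) from a user seed.  These sizes keep the
whole suite in a few minutes on one core while exercising every code path
at realistic per-locus depth.

## Limitations

* Quality scores do not modulate penalties; the scheme is quality-free.
* No banding or vectorized acceleration; runtime grows with the full
  model × read product per candidate read.
* Deletion runs never cross subsequence boundaries, and a repeat unit can
  only be entered at its first phase from a preceding subsequence
  (mid-phase entry arises only at read starts and after clips).
* The emulated mapper and naive estimator bracket the realigner for
  benchmarking; real-data workflows would use a production mapper upstream
  and a dedicated STR caller downstream of the realigned BAM.
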