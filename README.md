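# strrealign

Repeat-aware realignment of mapped short reads over short tandem repeat
(STR) regions, for anyone estimating repeat sizes from high-throughput
sequencing: STR tracts (1–6 bp units) vary in copy number between
individuals, and reads carrying a non-reference allele are routinely
soft-clipped or given misplaced indels by seed-and-extend mappers, which
degrades every spanning-read repeat-size estimate downstream.

## The method

Each catalogued locus is turned into a genome model: a series of
subsequences `G_1..G_m` in which flanking reference sequence appears
literally (`B_j = 0`, used once) and each STR region is a single copy of
its repeat unit flagged reusable (`B_j = 1`).  A read `R` is aligned to the
model by a dynamic program over six state families — match `s_M(i,j,k)`,
insertion `s_I(i,j,k)`, deletion `s_D(i,j,k)`, rotating multi-deletion
`s_D(i,j,k,l)` with `l < |G_j|`, and left/right clips `s_L(i)`, `s_R(i)` —
minimizing total penalty with affine gaps (open + extension), a flat
per-event clip penalty, and free model prefix/suffix (fitting alignment).
Reusable units may be traversed cyclically any number of times, zero
included, so one model scores every repeat length; multi-deletions may
rotate across the unit's copy boundary and cost
`p_do + (l-1) * p_de`.  Defaults equal BWA-MEM scoring: match −1,
mismatch 4, gap open 6, extension 1, clip 5.

The optimal model path is projected back to reference coordinates: repeat
fragments are realigned against the reference tract plus one trailing unit
copy (deletion-open lowered to 4 on the tract), clips become soft clips,
and a read is rewritten only when the projected alignment strictly beats
its original alignment rescored with the same penalties.  The package also
ships a synthetic STR benchmark (diploid repeat-number genomes, paired-end
reads with substitution errors, an emulated gap-free mapper), a naive
spanning-read size estimator, and the evaluation statistics: call rate,
RMSE with NA-to-reference substitution, and Mendelian trio consistency.

## Worked example

```r
library(strrealign)
syn    <- make_synthetic_reference(length = 20000, n_regions = 8, seed = 42)
genome <- simulate_diploid_genome(syn$reference, syn$regions, seed = 43)
reads  <- simulate_reads(genome, coverage = 40, seed = 44)
rec    <- map_simulated_reads(reads, genome, syn$reference, near = syn$regions)
out    <- realign_records(rec, syn$reference,
                          trim_regions(syn$regions, syn$reference))
out$n_realigned
#> [1] 798

calls_orig <- naive_spanning_estimator(rec, syn$regions)
calls_re   <- naive_spanning_estimator(out$records, syn$regions)
call_rate(calls_orig)[7, ]; call_rate(calls_re)[7, ]
#>   period n called call_rate
#> 7  total 8      0         0
#>   period n called call_rate
#> 7  total 8      6      0.75
size_rmse(calls_orig, genome$truth)[7, ]; size_rmse(calls_re, genome$truth)[7, ]
#>   period n     rmse
#> 7  total 8 45.38171
#>   period n    rmse
#> 7  total 8 34.6888
calls_re[1:3, ]
#>   chrom start  end period ref_size a1 a2 n_span
#> 1  chrS  2220 2259      1       39 40 44     23
#> 2  chrS  4469 4521      2       52  8 42     29
#> 3  chrS  6683 6749      3       66  6 15     40
```

Before realignment every read over a variant tract is soft-clipped by the
emulated mapper and no region is callable; after realignment 798 records
carry proper repeat-length indels, 6 of 8 regions are called, and the
called diploid sizes above equal the simulated truth exactly (the true
alleles for the first three regions are 44/40, 8/42 and 6/15 bp).  The
RMSE is reported in bp over both alleles with NA calls replaced by the
reference size; the two uncalled regions (alleles too long for 100 bp
reads to span) keep it well above zero.

A BAM-in/BAM-out pipeline is available as `realign_bam()` or from the
shell via the bundled CLI:

```sh
strrealign run --bam in.bam --ref ref.fa --regions catalog.bed --out out.bam
```

with `make-ref`, `simulate`, `eval` and `trio` subcommands for the
benchmark workflow (`exec/strrealign`).

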