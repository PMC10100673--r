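# telomotif

De novo discovery of telomeric repeat motifs from assembled genomes or
unmapped sequencing reads, and quantitative analysis of single-base
variation inside assembled telomeres. Written for genome scientists who have
an assembly (or a pile of unmapped reads) and need to know what the
telomeric unit of their organism is — `TTAGGG`? `TTTAGGG`? a 24-nt yeast
motif? — and how faithfully the assembled arrays repeat it.

## The method

**Motif discovery.** The terminal `n` nucleotides of each chromosome end
(default 1000; terminal `N` runs excluded) are scanned for every kmer with
`k` in `[5, 30]`, the length range of all known telomeric units. Each kmer
is scored

    S = k × repeat times

with repeat times counted as maximal non-overlapping occurrences. All kmers
on one end are compared in pairs: the value of kmer1 against kmer2 is
`S₁ − S₂`, minus a substring penalty `(occurrences of kmer1 inside counted
occurrences of kmer2) × k₁` when kmer1 is a substring of kmer2. The kmer
with the most pairwise wins is the end's recommendation; recommendations
are reduced to their primitive units, pooled across rotation phases and
across the C-rich/G-rich strand orientation of the two chromosome ends, and
ranked by `suppChr` — the number of chromosome ends supporting the class —
with the maximum summed pairwise value as tie-break.

**Variation analysis.** Given a motif, the assembled array at each end is
located by exact occurrence matching (any rotation phase, fixed by the
outermost match, gaps capped at motif length + 1). Each gap between exact
copies is aligned globally to the motif (match +1, mismatch −2, gap −2 per
base, leftmost indel placement) and classified as a single-base change
(SC), deletion (SD) or insertion (SI); undecomposable gaps are COMPLEX and
excluded. Per end:

    SV frequency = SV count / total motif count      (typical + with-SV copies)
    SC% = SC/SV,  SD% = SD/SV,  SI% = SI/SV

plus a per-site positional profile in the shared G-rich coordinate frame.

A seedable simulator (`simulate_genome()`, `simulate_reads()`) generates
genomes and read sets with known telomeric structure and a full truth table
of injected events, so both halves of the package are scored against ground
truth in the tests.

## Worked example

```r
library(telomotif)
library(dplyr)

sim <- simulate_genome("TTAGGG", n_chromosomes = 4, copies_per_end = 100,
                       sc = 0.012, sd = 0.004, si = 0.004, seed = 7)
report <- detect_motif(sim$genome)
glance(report)
#> # A tibble: 1 × 8
#>   status   mode   top_motif motif_length suppchr_ends suppchr_chromosomes max_value n_windows
#>   DETECTED genome AGGGTT               6            7                   4     99729         8
```

`AGGGTT` is the rotation-canonical key of the injected `TTAGGG` class
(`canonical_rotation("TTAGGG")`): the unit was recovered, supported by 7 of
8 chromosome ends. Feeding it back into the variation analysis:

```r
va <- analyze_variation(sim$genome, tidy(report)$canonical_motif[1])
tidy(va) |> select(chrom_id, end, typical_count, sv_count, sv_frequency,
                   sc_pct, sd_pct, si_pct)
#> # A tibble: 8 × 8
#>   chrom_id end   typical_count sv_count sv_frequency sc_pct sd_pct si_pct
#> 1 chr01    left             97        3      0.03     0.667  0.333    0
#> 2 chr01    right           100        1      0.00990  0      0        1
#> 3 chr02    left             99        1      0.01     1      0        0
#> 4 chr02    right            99        1      0.01     1      0        0
#> 5 chr03    left             98        2      0.02     0.5    0.5      0
#> 6 chr03    right            95        5      0.05     0.8    0.2      0
#> 7 chr04    left             95        4      0.0404   0.5    0        0.5
#> 8 chr04    right            99        1      0.01     1      0        0
```

Each row is one chromosome end: how many exact motif copies the assembled
array contains, how many copies carry a single-base variant, the resulting
SV frequency, and the SC/SD/SI split. `autoplot(va, "frequency")` and
`autoplot(va, "profile")` draw the per-end frequencies and the per-site
d/i/c bar profile.

A command-line wrapper covering `detect`, `variants`, `simulate` and
`end2end` lives at `system.file("cli", "telomotif.R", package = "telomotif")`:

```sh
Rscript telomotif.R detect --fasta genome.fa --window 1000 --kmin 5 --kmax 30 --out run1
Rscript telomotif.R variants --fasta genome.fa --motif TTAGGG --extend 8000 --out run1
```

Exit status is 0 on success, 2 on usage errors, 3 when no telomere is
detectable.

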