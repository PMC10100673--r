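---
title: "Telomeric motif discovery and variation analysis with telomotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Telomeric motif discovery and variation analysis with telomotif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telomotif)
library(dplyr)
```

## The problem

Telomeres are tandem arrays of a short repeat unit (5-30 nt in all known
species) at the ends of linear chromosomes: `TTAGGG` in vertebrates,
`TTTAGGG` in *Arabidopsis*, and far more diverse, longer units in many
fungi. Knowing the unit is a prerequisite for telomere-length estimation,
probe design and comparative work, yet for most assembled genomes it has
never been determined experimentally. `telomotif` infers the unit de novo
from the sequence itself, and then quantifies how faithful the assembled
arrays are to it, copy by copy.

The package has two halves:

1. **Motif discovery** — a kmer-scoring tournament over chromosome-terminal
   windows, aggregated across chromosome ends.
2. **Variation analysis** — given a motif, locate each end's assembled
   array, align every imperfect copy ("gap") back to the motif, and
   classify single-base changes (SC), deletions (SD) and insertions (SI).

A third component, the simulator (`simulate_genome()`, `simulate_reads()`),
generates genomes with known telomeric structure so that every claim the
package makes can be scored against ground truth without downloading
assemblies.

## The detection model

For each chromosome end, the terminal `window_n` nucleotides are extracted
(default 1000 nt; terminal runs of `N` are skipped before counting, and an
end that is all `N` is skipped entirely). Within a window, every distinct
`k`-substring for `k` in `[kmin, kmax]` (default 5-30) is a candidate unit.
Its evidence is

\[ S = k \times \text{repeat times}, \]

where repeat times counts maximal non-overlapping left-to-right occurrences.
Candidates on one window then play an all-pairs tournament: the pairwise
value of kmer 1 against kmer 2 is \(S_1 - S_2\), and when kmer 1 is a
substring of kmer 2 it is further penalised by (number of its counted
occurrences lying inside counted occurrences of kmer 2) × (its length) —
those occurrences are already explained by the longer unit. A kmer wins a
pairing when its value is positive; the window's recommendation is the kmer
with the most wins (ties: higher `S`, then shorter minimal unit, then
alphabetical).

Two post-processing steps turn per-window winners into a motif call:

* **Minimal-period reduction.** Under the literal penalty the typical window
  winner is a long concatemer of the true unit (for example five copies of
  `TTAGGG` as one 30-mer): the concatemer inherits nearly the full score of
  its unit while the penalty demotes the unit itself. Reduction maps every
  winner to its primitive unit. This also means a near-`kmax` *primitive*
  concatemer (e.g. a 29-mer that is 4.83 copies of a 6-mer) occasionally
  wins a window; such windows contribute a spurious candidate class, but the
  class never accumulates cross-chromosome support, so the ranking is
  unaffected.
* **Rotation canonicalisation.** The phase in which a circularly repeated
  unit is reported is arbitrary (`TTAGTCAGGG` ≡ `CAGGGTTAGT`), and the left
  end of a chromosome shows the reverse complement (C-rich) of the unit seen
  at the right end. Left-end winners are reverse-complemented into the
  G-rich orientation and every unit is keyed by its lexicographically
  smallest rotation.

Classes are ranked by `suppchr_ends`, the number of chromosome ends whose
window winner reduces to the class, with the maximum summed pairwise value
(`max_value`) and then the class string as tie-breaks. We rank by *ends*
rather than chromosomes because each end is an independent piece of
evidence; the per-chromosome tally is reported alongside. The report is
`DETECTED` when the top class has at least `min_repeats` (default 3) repeats
on its best window and at least `min_suppchr` (default 2) supporting ends;
both thresholds are configurable and deliberately conservative, since a
single end can recommend a spurious unit on a telomere-free genome.

One computational choice matters: `detect_motif()` admits only kmers that
occur at least twice in the window (`min_count = 2`). A repeat unit recurs
by definition, and the ~25 000 singleton kmers of a 1000-nt window add
quadratic cost without repeat evidence. `enumerate_kmers()` and
`run_tournament()` themselves default to `min_count = 1`, so the tournament
can be (and in the tests is) checked against a literal brute-force oracle on
the full kmer set. On a window with no repeated kmer at all the window is
candidate-free either way. The only behavioural difference appears on
repeat-free windows that do contain incidental repeated 5-mers: the literal
full-set winner would be a long singleton that fails `min_repeats`, while
the filtered winner is a weak short kmer that fails it too — the verdict is
the same.

Read mode treats every read (FASTQ, or the FLAG-0x4 records of a SAM/BAM)
as one window, scores both the read and its reverse complement, keeps the
better orientation, and flags C-rich winners so that aggregation pools all
reads into the G-rich frame; support is then counted in reads.

## The variation model

Given a motif (G-rich orientation), each end's window — enlarged to
`window_n = 8000` by default, since assembled telomeres can reach several
kilobases and the variation search must span the whole array — is analysed
in the G-rich frame: right-end windows as stored, left-end windows
reverse-complemented. This single convention makes the left/right symmetry
exact: reverse-complementing a chromosome swaps its two ends' results
verbatim, and positional profiles from both ends share one coordinate
system.

The array is located by exact occurrence matching: the outermost (most
terminus-proximal) exact match of any rotation of the motif fixes the
phase, and the array is extended inward occurrence by occurrence as long as
the gap between consecutive occurrences does not exceed motif length + 1 nt.
The cap bounds every counted gap to lengths a single-base event can explain
and doubles as the array boundary — the first junction whose gap demands
two or more events (for instance two adjacent variant copies) terminates
the region. Ends with fewer than two exact occurrences are reported as
missing (`NAN` in the files): the telomere is too short to analyse.

Each gap is aligned globally to the phase motif with match +1, mismatch -2
and gap -2 per base. The mismatch penalty is the custom value used for this
classification task; the gap cost is our choice (the source procedure
specifies no gap penalty) and is set so a 1-nt indel and a mismatch are
directly comparable, which keeps a single mismatch preferred over an
insertion-deletion pair. Where score-optimal alignments differ only in
indel placement — inside a homopolymer run the true position is
undeterminable — the leftmost placement is the stated convention,
implemented by backward traceback preferring match, then insertion, then
deletion. A gap of length 1 is classified directly as an insertion between
copies (recorded after the final motif site) rather than aligned, since
aligning a single base against a full motif would manufacture spurious
deletions.

A gap classifies as one SV when its length is within one of the motif
length and its alignment carries exactly one edit: mismatch → SC, missing
motif base → SD, extra base → SI. Everything else is COMPLEX and excluded
from both the numerator and the denominator of the frequency — the total
motif count is defined as typical (exact) copies plus copies carrying one
SV, so undecomposable gaps belong to neither class. Per end,

\[ \text{SV frequency} = \frac{\text{SV count}}{\text{total motif count}},
   \qquad
   \text{SC\%} = \frac{\text{SC count}}{\text{SV count}}, \;
   \text{SD\%} = \frac{\text{SD count}}{\text{SV count}}, \;
   \text{SI\%} = \frac{\text{SI count}}{\text{SV count}}. \]

Sites are converted from the matched phase to the supplied motif's
coordinates so that profiles are comparable across ends and chromosomes;
insertions that fall between copies are reported after the final site
(`L + 1`).

## What the simulator emulates — and what it does not

`simulate_genome()` builds each chromosome as terminal `N` padding + C-rich
left array + random subtelomere + random core + random subtelomere + G-rich
right array + padding. Arrays carry at most one injected SV per copy, drawn
per copy from the `sc`/`sd`/`si` rates; every event is recorded with its
end, copy, site and bases, and coordinates in the truth table map exactly
onto the emitted sequence. Sub-seeds are derived deterministically per
chromosome and end, so one seed reproduces the FASTA byte for byte, and a
left array equals the reverse complement of the right array generated from
the same sub-seed.

Defaults follow the study conditions used throughout the tests: 8
chromosomes and 100 copies per end with a total per-copy SV rate of 0.02
(split 0.012/0.004/0.004) for detection; 1000 copies per end at rate 0.10
(split 60/20/20) for recovery checks. Where no condition was prescribed we
chose once what a small fungal-like assembly looks like — 500-nt
subtelomeres, a 2000-nt core, uniform ACGT background, no `N` padding —
and did not revisit the choices. The simulator does **not** model
sequencing error, base-quality, GC bias, diploidy, interstitial telomeric
repeats, or variable-unit telomeres such as the *Saccharomyces*
T(G)~2-3~(TG)~1-6~ family (which defeat exact-unit detection by design).
Passing tests therefore demonstrate correctness of the algorithms under
clean array structure with point variation, not robustness to assembly
artefacts.

Two estimator biases are worth knowing about, both measured against
simulator truth in the test suite. First, the boundary rule truncates the
analysed region at the first multi-variant junction, so at an injected rate
of 0.10 per copy the analysed depth averages roughly 120-150 copies per
end and the recovered frequency underestimates the injected rate by about
0.015. Second, adjacent SC/SD variant copies merge into region-terminating
or COMPLEX gaps while insertion copies often still contain an exact motif
occurrence (an inserted base leaves, e.g., `TTTAGGG` containing `TTAGGG`),
so SI survives pooling slightly better (&approx; +1.5 percentage points)
than SD. Both biases are small relative to the recovery tolerances and are
inherent to defining the denominator through exact-copy counting.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere on file; tibbles carry both
  frame and genomic coordinates.
* Non-ACGTN FASTA characters are coerced to `N` with a warning; kmers
  overlapping `N` are never counted; interior `N`s inside a window are kept.
* All tie-breaks (tournament winner, candidate ranking, rotation keys) are
  total orders, so every result is deterministic; the only randomness in
  the package lives in the simulator and is seed-controlled.
* Chromosomes shorter than the window return their full N-stripped length;
  all-`N` ends error individually and are skipped with a warning at genome
  level.
* `run_tournament()` on a window whose kmers all occur once returns a
  candidate-free result rather than electing a singleton.

## Worked example

```{r example}
sim <- simulate_genome("TTAGGG", n_chromosomes = 4, copies_per_end = 100,
                       sc = 0.012, sd = 0.004, si = 0.004, seed = 7)
report <- detect_motif(sim$genome)
glance(report)
tidy(report)

va <- analyze_variation(sim$genome, tidy(report)$canonical_motif[1])
tidy(va) |> select(chrom_id, end, typical_count, sv_count, sv_frequency,
                   sc_pct, sd_pct, si_pct)
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(va, "profile")
```

## Problem sizes in the tests

The test suite and the acceptance script work at deliberately moderate
sizes chosen as representative desk-scale experiments: 8-chromosome genomes
with 100 copies per end across six published motif lengths (5-24 nt, ten
seeded replicates each) for detection accuracy; 200 random windows of up to
60 nt with `k` in `[2, 8]` for exact agreement with the literal brute-force
tournament oracle; and twenty 1000-copy-per-end replicates for variation
recovery, pooled before comparing against the injected rates.

## Known limitations

* Variable-unit telomeres and units outside `[kmin, kmax]` are undetectable
  by construction.
* The per-kmer `Value` used for cross-chromosome ranking is the winner's
  summed pairwise values on its window — a stated convention; only the
  within-window win count is defined by the scoring model itself.
* Array boundaries are operational (gap cap), not biological; assembled
  telomere lengths and SV frequencies inherit that definition.
* Read-mode variation reports a single genome-wide average; per-chromosome
  resolution requires an assembly.
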