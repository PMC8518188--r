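---
title: "Iterative haplotype-resolved hybrid assembly: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative haplotype-resolved hybrid assembly: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Complex metagenomes (activated sludge, soil, gut) defeat monolithic
assembly: error-prone long reads give contiguity but poor base accuracy,
accurate short reads give accuracy but fragmentary assemblies, and both
suffer when hundreds of related genomes are assembled together. The approach
implemented here splits the metagenome *before* assembling it: a long-read
draft assembly is clustered into candidate haplotype bins by sequence
composition and coverage, all long and short reads are phased into those
bins, and each bin — now approximately a single-organism data set — is
hybrid-assembled and polished on its own. Reads assigned to genomes that
pass a quality gate are subtracted, and the whole procedure repeats on the
remaining reads so that progressively rarer genomes surface once dominant
ones are removed. The loop stops when the genomes reconstructed in an
iteration account for less than 2% of the data, or after a capped number of
iterations (default 11).

`hcbha` implements this loop end to end at desk scale, together with the
simulator and the reference-based evaluation suite used to test every stage.

## Pipeline stages and their models

### Draft assembly and per-bin assembly (mini OLC)

The built-in long-read assembler is a deliberately small
overlap-layout-consensus engine intended for genomes up to ~100 kb at up to
~50x depth; at real scale an external assembler (Flye-class, meta mode) is
plugged in through the `AssemblyBackend` contract of `assemble_bin()`, and
real-scale tool choices live in configuration, not code.

* **Overlaps** are candidate diagonals of shared canonical minimizers
  (`k = 11`, `w = 5`): hits between two reads are clustered by diagonal,
  chained colinearly, and kept when the chain has at least
  `min_chain_score = 10` seeds over at least `min_overlap = 500` bp.
  Because chains can arise between reads of *related* genomes, overlaps are
  additionally gated by chain density (`score >= 0.009 x overlap length`).
  On simulated data this sits between the same-genome density
  (~0.014/bp at 86.7% read accuracy) and the cross-genome density at ANI
  0.8-0.85 (~0.002/bp).
* **Layout** removes contained reads, then greedily links best overlaps into
  non-branching paths of oriented reads. Every junction is verified by a
  banded alignment of the next read's head against the current path tail:
  the junction is accepted only if the edit fraction is at most 0.28 (two
  86.7%-accuracy reads of one template align at ~0.23; reads of genomes at
  ANI 0.85 align at ~0.33) and the alignment lands where the chain predicted
  (+-350 bp). A rejected junction splits the path instead of forcing a
  chimeric contig.
* **Circularity** is called three ways: a cycle-closing overlap between a
  path's tail and head; a layout that walks a circular replicon past its
  origin (detected by re-locating the contig head downstream and trimming to
  one turn); and, after contig merging, a contig whose start is duplicated
  near its end.
* **Consensus** re-anchors all bin reads to the layout with unique 13-mers
  and applies per-column plurality votes (insertions and deletions
  included), two rounds by default.

Greedy best-overlap layout without transitive reduction can produce two
parallel paths over one replicon; near-duplicate contigs are removed by a
density-gated containment check before consensus (for circular pairs a
lower overlap fraction suffices because rotation splits the chain into one
arc).

### Short-read polishing

`polish_with_short_reads()` anchors reads by unique 21-mers on their
majority strand, aligns the inter-anchor gaps (and read ends) in a +-20 bp
band, and applies a column call when at least 3 reads cover it with at
least 70% agreement; columns without anchored coverage keep the draft base.
The 3-read/70% rule balances error correction against smashing true
haplotype differences; both values are configurable. Polishing runs twice
before contig merging and twice after (the merge fills junctions with raw
long-read sequence, which the re-polish corrects). On fixtures, two rounds
at 50x lift a 95%-identity draft above 99.9% (Q30+); the pipeline's mock
runs reach Q32-Q40 per genome.

### Binning

Draft contigs are profiled by canonical tetranucleotide frequency (136
dimensions; a 4-mer and its reverse complement count as one key; windows
containing N are skipped) plus `log(coverage + 1)`. TNF columns are z-scored
across contigs; coverage is z-scored and multiplied by `cov_weight = 3`.
Average-linkage hierarchical clustering on Euclidean distances is cut at
the largest merge-height gap by default (a fixed height or cluster count can
be forced), clusters below `min_bin_bases` are pooled into a reserved
leftover bin that skips assembly but re-enters later iterations, and an
amendment pass reassigns each contig to the nearest bin centroid when that
distance beats its current centroid by a 10% margin (to a fixpoint, at most
10 rounds). `cut_to_bins()` defaults to the 50 kb minimum bin size a real
run would use; the pipeline configuration uses 10 kb because the bundled
study conditions work with 20-50 kb genomes, which a 50 kb floor would
discard outright.

### Phasing and subtraction

Reads are assigned to bins by counting distinct shared canonical
minimizers (`k = 15`, `w = 10`) against an index of the bins' contigs. A
read (short-read mates jointly, summing the pair) is assigned to the
top-scoring bin only if the score reaches `min_score = 3`, the runner-up is
at most `tie_ratio = 0.8` of it (exact ties always stay unassigned), and the
score reaches a fraction of the read's own minimizer count
(`min_frac_long = 0.006`, `min_frac_short = 0.08`). The last gate is an
identity proxy: without it, reads of genomes that do not yet have a bin are
absorbed by a *related* bin — measured on a 3-genome ANI-0.8 fixture, a
single qualified genome wrongly consumed 71% of all bases during
subtraction. Subtraction re-assigns the full remaining read set against the
final qualified MAG sequences (not the draft bins) with stricter fractions
(0.04 long / 0.4 short), reflecting that polished MAGs anchor same-genome
reads far more densely. Unassigned reads carry forward as the remaining
data set.

### Under-split bins and the split rescue

The merge-height-gap cut can under-split a draft (two genomes in one bin),
especially when each genome contributes a single contig. The per-bin
assembler still reconstructs the genomes as separate contigs because the
junction gate refuses cross-genome joins, but the combined MAG fails
retention on contamination. A bin that assembles successfully yet fails
retention with contamination >= 10% and 2-8 contigs is therefore re-gated
per contig: each contig is assessed as its own candidate MAG and passes or
fails the usual gates. A genuine multi-contig genome caught in such a bin
would be split into partial MAGs (retained at the MQ tier at best) — the
cost of this rescue — but the alternative is discarding the bin outright
and stalling the iteration.

### Quality gating and tiers

In synthetic mode quality is assessed against the truth genomes:
completeness is the aligned genome fraction (AGF) of the best-matching
genome, contamination the percentage of aligned MAG bases hitting other
genomes, and the rRNA-operon requirement is represented by a planted 1.5 kb
marker locus that must be recovered at >= 99% identity over >= 95% of its
length. A CheckM-class estimator plugs in through the same QualityRecord
interface for real data. The gates use the thresholds exactly as stated:
qualified (subtraction trigger) means completeness > 90, contamination < 10
and fewer than 30 contigs; retention means completeness > 50 and
contamination < 10; tiers are complete (all contigs circular, regardless of
completeness), HQ (>= 90 / <= 5 with the full-length marker), MQ
(>= 50 / <= 10), else failed.

### Dereplication

MAGs collected across iterations are dereplicated with single-linkage
primary clusters at ANI >= 0.90 with alignment coverage >= 0.65, secondary
clusters at ANI >= 0.97, keeping per secondary cluster the MAG maximizing
`completeness - 5 x contamination + 0.5 log10(N50)` (an approximation of
the usual dereplication score; the exact scoring of the reference tool is
out of scope). ANI is estimated from bottom-sketch Jaccard similarity of
canonical 21-mers via `ani = 1 + ln(2J/(1+J))/k`, and coverage as the
fraction of one genome's sketch k-mers found in the other's full k-mer set.
On 20 kb genomes the sketch estimate tracks the construction identity of
mutated pairs within +-0.01 across 0.90-0.99.

### Evaluation

`align_to_reference()` seeds unique 21-mer anchors, chains them colinearly
(chains break at gaps over 1 kb or diagonal jumps), aligns inter-anchor
gaps with banded Needleman-Wunsch, extends block ends, and reports blocks
at >= 90% identity and >= 500 bp. From the blocks: AGF (percent of the
reference covered, interval union, coordinates folded on the circle for
circular references), purity (1 - unaligned MAG length / reference length,
floored at 0), misassembly breakpoints (reference/strand switches or
gap-versus-gap discrepancies beyond 1 kb between consecutive blocks of a
contig, with circular-aware gap arithmetic so a rotated closed genome is
not a false breakpoint), indel rates per 100 kb (the rate unit is stated
explicitly since conventions differ), and the assembly Q-score
`-10 log10((mismatches + insertions + deletions)/aligned)`, capped at Q90
for zero-error assemblies. Internal consistency: an error fraction of 0.133
maps to Q8.76, matching the pairing of 86.7% read accuracy with Q8.76.

## The simulator: what it does and does not emulate

`generate_community()` + `simulate_long_reads()` + `simulate_short_reads()`
provide full ground truth (genome of origin and exact pre-error coordinates
per read).

* Unrelated genomes are first-order Markov DNA with a genome-specific GC
  content (drawn from 0.35-0.65) and a random dinucleotide bias. This gives
  each genome a distinct oligonucleotide signature — the actual premise of
  composition-based binning. Uniform i.i.d. DNA would make all genomes
  compositionally identical and TNF binning untestable by construction.
* Strain-like fixtures derive all genomes from one ancestor by point
  substitution at rate (1 - ANI)/2, hitting a target pairwise identity.
* Long reads: lognormal lengths (median 8 kb, sd factor 2, floor 1 kb;
  only the 1 kb floor is externally fixed, the rest is a modeling choice),
  uniform positions with wrap-around on circular replicons, uniform strand,
  and i.i.d. per-base errors mixed 40:30:30
  substitution:insertion:deletion (ONT-like; configurable). `mean_accuracy`
  is defined on the *realigned* scale: alignment compresses interacting
  adjacent events (an insertion next to a deletion realigns as one
  substitution; per-type error streams realign at their planted rate, the
  mixed stream ~5% low at 13.3%), so events are planted at the first-order-
  corrected rate `(1 - acc)(1 + 0.39 (1 - acc))`. At the default 86.7%
  accuracy the realigned identity of simulated reads is then within half a
  point of target.
* Short reads: proper FR pairs, insert ~ Normal(350, 50) truncated at the
  read length, substitution-only errors whose per-base probability follows
  a two-level (Q40/Q10) quality string, so emitted qualities are consistent
  with realized errors and survive the mean-Q30 preprocessing filter at the
  default 0.3% error rate.
* Not modeled: chimeric reads, adapters, quality drift along reads, GC
  coverage bias, inter-sample differential coverage. Passing tests
  therefore demonstrate algorithmic correctness under clean sampling
  models, not robustness to every real-data artifact. The mixed
  mock-plus-background design of real benchmark datasets is approximated
  only by adding low-abundance genomes, not replicated.

## Study conditions wired into tests and the acceptance script

* Mock analogue: 8 unrelated genomes of 20-50 kb, even abundance, 30x long
  reads at 86.7% accuracy, 100x 2x150 short reads at 0.3% error. The
  recovery requirement is at least 7 of 8 genomes as 1-2 contig MAGs at
  AGF >= 95%, purity >= 0.99, Q >= 30, with at least 2 circular.
* Iterative recovery: 5 genomes of 15 kb at abundances 50:20:8:4:1 (a 50x
  span), deep full pools subsampled to 3 Mb working sets per iteration —
  the subsample-assemble-subtract cycle in miniature. The per-bin
  minimum of 25 long reads is sized to the 15 kb genomes (~13x).
* Phasing: 20 seeds of 3-genome ANI-0.85 communities; median precision
  >= 0.99 and recall >= 0.90 for long reads against the true genomes.
* Problem sizes (genome lengths, depths, seed counts) are chosen so each
  stage is exercised at realistic coverage while a full run remains a
  desk-scale computation.

## Numerical choices, ties, and degenerate inputs

* Alignment uses unit edit costs; on ties the traceback prefers the
  diagonal, so equal-cost gap placements do not scatter indel votes.
* Minimizers take the leftmost position on within-window hash ties;
  canonical k-mers use the lexicographically smaller of the packed forward
  and reverse-complement encodings (exact in doubles up to k = 26).
* Anchor deserts longer than 2 kb inside a read-to-draft alignment are
  skipped rather than force-aligned; uncovered draft columns keep their
  base.
* Zero-variance feature columns stay at zero instead of dividing by zero;
  a single-contig feature matrix is the zero row.
* Exact assignment ties (score == runner-up) are never phased; bins that
  lose every contig during amendment are dropped; a bin whose promotion
  would drop every contig raises a bin-collapse error which the pipeline
  converts into a failed bin without stopping.
* Mean base quality is the arithmetic mean of Phred scores (not the
  error-probability mean), matching common QC-tool behavior; short-read
  mates are filtered independently.
* The promotion step measures TNF distance to a per-dimension median
  centroid — robust to the very contaminant contigs it is meant to remove.

## Known limitations

* The built-in assembler targets small replicons; repeat structures longer
  than a read are not resolved (no repeat graph), and assembling genomes
  beyond ~100 kb or depths beyond ~50x is out of its design envelope.
* Contamination estimation is reference-based; in real mode it inherits
  whatever the plugged-in estimator measures.
* Phasing thresholds were calibrated on ANI <= 0.85 divergence; at
  strain-level divergence above ~0.9 ANI the minimizer identity proxy
  loses separation, which is also where binning itself stops working.
* Single-sample design: no differential-coverage binning across samples.
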