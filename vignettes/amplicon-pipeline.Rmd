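---
title: "From microfluidic amplicon reads to alleles, ploidy and targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From microfluidic amplicon reads to alleles, ploidy and targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplikit)
```

## The problem

Microfluidic PCR arrays amplify dozens of target regions across dozens of
samples in one run: a 48 × 48 array yields 2,304 isolated amplicons, and
dual combinatorial barcoding lets many arrays share one sequencing run
(24 P5-side × 36 P7-side 8 bp indexes give 864 unique sample tags from only
60 oligos). Each amplicon is built by a four-primer reaction: a
target-specific primer pair carrying universal CS1/CS2 tails, and a barcoded
adapter pair that anneals to those tails. A sequenced read pair therefore
looks like

```
read 1:  [TS-F primer][insert ......................
read 2:  [TS-R primer][insert, reverse complement ...
index 1: [P5 barcode]          index 2: [P7 barcode]
```

amplikit turns the raw paired FASTQ of such a run into per-sample,
per-target consensus sequences or allele sets, aggregates allele counts
into minimum-ploidy calls, and — on the design side — picks amplifiable
target regions from whole-plastome or per-locus alignments. A built-in
simulator generates complete runs with ground truth so every stage is
testable without external data.

## Demultiplexing model

A read pair is assigned to a **sample** by its two index sequences. Each
index is compared to its end's barcode table separately; a barcode matches
when its distance is at most `max_bc_dist` (default 1). On equal-length
sequences the distance is Hamming — a single edit on a fixed-length 8-mer
is a substitution — with Levenshtein as the fallback for unequal lengths.
Whether the two index distances should be thresholded jointly or per end is
underdetermined; amplikit thresholds **per end**, the usual dual-index
convention. When two barcodes tie at the minimal distance the read stays
unassigned: in a phylogenetic context a false sample assignment is worse
than a lost read.

The **target** comes from anchored fuzzy primer matching. The forward
primer is aligned against the start of read 1 (reverse primer against read
2) allowing up to `max_primer_dist` Levenshtein edits (default 4) anywhere
*except* the primer's 3'-terminal `firm_end_len` bases (default 4), which
must match the read exactly and contiguously — "firm ends". The rationale
is biological: mismatches at the primer's 3' terminus prevent polymerase
extension, so a real amplicon cannot disagree with its primer there, while
synthesis errors and SNPs elsewhere in the primer are tolerated. Because
indels are allowed in the fuzzy head, the number of read bases consumed
(and stripped before pooling) can differ from the primer length; the
matcher reports it. Both mates must match primers of the *same* target.
Every read ends up in exactly one (sample, target) pool or in the
unassigned tally with a reason (`barcode`, `primer`, `both`) — the run
report's conservation invariant.

The hot kernels (barcode lookup, firm-end matching, overlap merging) are
small C++ functions; the test suite checks them against exhaustive base-R
enumerations built on `utils::adist()`.

## Pool reduction

Each pool is reduced in four steps:

1. **Trim** (`trim1`/`trim2`, defaults 0): remove bases from each mate's 3'
   end. MiSeq substitution error concentrates at read ends, worst on read
   2; for 300 bp reads values around 75/150 are typical and improve allele
   retention. Trimming is exact; a read shorter than its trim becomes empty
   with a warning.
2. **Join** (`min_overlap` 10, `max_mismatch` 0.25): read 2 is
   reverse-complemented and every overlap of at least `min_overlap` bases
   is scored; the overlap with the lowest mismatch fraction (ties →
   longest) is accepted when that fraction is at most `max_mismatch`.
   Disagreements resolve toward the higher-quality base (tie → read 1),
   keeping the higher quality. Pairs without an acceptable overlap are
   concatenated `r1 + revcomp(r2)` with the junction index recorded, so a
   400 bp amplicon read as 225 + 150 trimmed mates still yields one
   alignable sequence.
3. **Modal length**: only reads whose joined length equals the pool's most
   frequent length survive; a tie goes to the longer variant
   (deterministic). This removes indel artifacts and off-target lengths
   before column-wise work.
4. **Reduce**, in one of three modes:
   - `consensus`: per column, the plurality base (tie → alphabetical).
   - `ambiguity`: per column, the IUPAC code over the bases supported by at
     least `min_reads` reads (s, default 5) *and* `min_freq` of the pool
     (f, default 0.05); if no base passes, the plurality base.
   - `occurrence` (allele recovery): reads are grouped by exact sequence
     identity; groups with at least s reads and at least f of the pool are
     kept as alleles. If nothing passes, the (sample, target) is
     **discarded**. The model: after PCR the true alleles dominate the
     pool, while error-bearing reads scatter across many rare variants, so
     an absolute floor plus a relative floor separates them. Allele
     identity is exact match — no clustering — which is why indels are the
     one error mode the thresholds cannot absorb.

The thresholds use the **post-modal-reduction** read total as denominator,
and modal-length reduction is applied in all three modes; both choices are
deliberate (the denominators should describe the reads actually eligible
to support an allele).

Haploid organellar targets are normally reduced with `consensus`, nuclear
targets with `ambiguity` (one record per sample) or `occurrence` (one
record per allele); the primer sheet's `genome` column is how a run
distinguishes them.

## Minimum ploidy

With alleles recovered per locus, the number of distinct alleles bounds
ploidy from below: 1–2 alleles are consistent with a diploid, 3–4 imply at
least tetraploid, more than 4 is reported as `higher` (artifacts can
inflate counts; users should inspect). `call_min_ploidy()` takes the
per-sample maximum over loci and the per-species maximum over samples, and
reports the percentage of loci (per sample) or individuals (per species)
with ≥3 alleles so weakly supported tetraploid calls — say 2–15% of
individuals — are visible. Loci with no surviving allele set are excluded
from the per-sample denominator. The call is only ever a lower bound:
homozygosity, low allelic divergence and autopolyploidy all hide ploidy.

## Target selection from alignments

`scan_variable_regions()` looks for amplifiable targets in a plastome-scale
alignment: stretches of elevated divergence 400–1000 columns long flanked
on both sides by 25 conserved columns where a primer could sit. Divergence
is the mean pairwise difference per comparable (non-gap, non-N) site — the
metric is a documented knob, exposed per column via `column_divergence()`.
Flank columns must be conserved (`max_flank_div`, default 0), fully
occupied and free of ambiguity codes by default, since a primer site absent
from a taxon or containing an N cannot be trusted; an optional
homopolymer filter (`max_poly_x`) mirrors primer-design practice. The
implementation clusters variable-column runs (merging across internal
conserved stretches while the span stays within `max_len` — divergent
regions are rarely wall-to-wall variable), pads short clusters into their
conserved neighbourhoods to reach `min_len`, ranks by mean divergence
(ties → leftmost) and greedily keeps non-overlapping regions. For
conserved flanks this equals exhaustive window enumeration: extending a
window into invariant flanks only dilutes its mean divergence, so the
top-ranked windows are exactly the tight cluster spans.

`find_conserved_islands()` is the nuclear-side analogue: in a per-locus
alignment of reads from multiple taxa, an island is a maximal run of
columns covered by at least `min_taxa` taxa, and an island pair is a
primer-pair candidate when their separation — plus 100 columns per
predicted intron between them, introns being invisible in
transcript-derived references — falls within 400–800 columns.

`clean_alignment()` (drop columns under 50% occupancy; idempotent) and
`concat_alignments()` (gap-fill missing taxa, emit a 1-based inclusive
partition table) are the supermatrix utilities downstream of reduction.
Coordinates are 0-based half-open internally and 1-based inclusive in all
emitted tables.

## The simulator: what it emulates, and what it does not

`simulate_run()` draws, per (sample, target), an allele mixture from the
sample's ploidy: one copy for haploids, two for diploids (heterozygous with
probability `heterozygosity`, alleles differing at `allele_divergence`
substitutions/site with at least one difference guaranteed), and for
tetraploids two homeolog copies (diverged at `homeolog_divergence`) each
forming its own possibly-heterozygous pair — up to four distinct sequences,
with copy-number-weighted proportions. Pool depth is negative-binomial
(mean 50, size 8 by default; `Inf` gives constant depth) to emulate uneven
amplicon recovery. Reads carry substitution errors whose rate ramps
linearly toward the 3' end (mean `error_rate` 0.002, 3'/5' ratio
`error_ramp` 4); indexes carry their own low substitution rate. Truth
tables record every mixture, every read's source allele and injected error
count; the same seed reproduces a run byte for byte.

Default amplicons are 350–550 bp so 300 bp mates always overlap and every
insert position is observed — the geometry under which exact-match allele
identity is meaningful. What the simulator deliberately does *not* model:
PCR chimeras and polymerase errors (which replicate early and can pass the
frequency thresholds), indels, quality-score realism beyond the ramp,
cross-contamination, and primer-site mutations. Passing the simulation
benchmarks therefore demonstrates the pipeline's arithmetic and its
threshold logic, not robustness to every failure mode of real libraries.

`simulate_plastome_msa()` builds the target-selection fixture: an invariant
background with non-overlapping divergent blocks whose variable columns are
sprinkled at the density matching each block's target divergence (a
variable column splits the taxa into two base groups). A block's first and
last columns are always variable when its divergence is positive, so the
truth span is well defined for recovery scoring.

## Numerical and degenerate-input choices

- Ties are never broken arbitrarily: ambiguous barcode or primer matches →
  unassigned; modal-length tie → longer; consensus plurality tie →
  alphabetical; region rank tie → leftmost. Identical inputs and
  configuration give byte-identical outputs.
- Reads shorter than a primer never match it; empty pools and
  all-discarded pools reduce to category `failed` rather than erroring.
- Benchmarks in the test suite run at desk scale chosen once: the
  noise-free closure uses 8 samples × 6 targets at depth 50; noisy allele
  recovery uses 200 pools per allele-count class at depth 100 and 0.2%
  error; region recovery uses a 6-taxon, 125 kb alignment with 48 blocks
  at 0.8–7.5% divergence. `scripts/acceptance.R` recomputes all of them
  from scratch.

## Known limitations

Exact-match allele identity cannot merge reads carrying indel errors;
heavily indel-prone platforms need upstream correction. The minimum-ploidy
call is a lower bound, sensitive to the 5-read/5% thresholds at low depth.
The region scan's divergence metric treats all substitutions equally and
ignores phylogenetic structure; it ranks, it does not test. The island
scan relies on a user-supplied intron annotation track.
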