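---
title: "Methods: pooled barcode screening for cold acclimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled barcode screening for cold acclimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screen

`coldscreen` analyses pooled insertional-mutagenesis screens of the kind used
to find cold-acclimation genes in *Chlamydomonas reinhardtii*. A
transformation cassette carrying a unique DNA barcode integrates at random in
each mutant; the pooled library (sample **CK1**) is split into a
room-temperature control arm (one further round of growth, sample **CK2**)
and a cold-stress arm (growth at 10 °C, sample **S10**), with a recovery
culture grown out of the cold-stressed pool (**S10R**). Deep sequencing of
barcode-PCR amplicons measures each mutant's relative abundance in each
sample; paired reads linking the cassette barcode to adjacent genomic
sequence identify each mutant's insertion locus, and hence the disrupted
gene.

The screening statistic is the ratio of ratios on relative abundances,

$$ rr \;=\; \frac{S10/CK1}{CK2/CK1}, $$

which cancels a mutant's baseline representation and its control-arm growth,
isolating the cold-specific effect. A barcode is a **hit** when $rr > 3$
(enriched in cold relative to control) or $rr < 0.3$ (depleted), with strict
inequalities. Hits split into two groups: **group 1** (enriched hits with a
low control ratio: constitutively slow growers whose defect is relatively
alleviated in cold) and **group 2** (depleted hits with a normal control
ratio: mutants impaired specifically under cold). Group 2 contains the
cold-acclimation candidates of primary interest.

## Screen statistics: conventions and parameters

* **CK1 filter** (`min_ck1_count = 50` reads). Barcodes below 50 CK1 reads
  are excluded before any ratio is formed; ratio estimates at lower counts
  are dominated by sampling noise, and the threshold also removes the cloud
  of sequencing-error-derived barcodes that shadows every true barcode.
* **Normalisation.** Relative abundance is count / per-sample
  recognized-read total (reads with an extractable barcode). No
  between-sample normalisation beyond this is applied; spike-in or
  median-of-ratios schemes are out of scope.
* **Offset** (`offset = 0.001`). The published convention adds 0.001 to
  ratio values before log2 transformation for plotting. `coldscreen` also
  applies the same offset inside $rr$ (numerator and denominator), so that
  barcodes with zero S10 or CK2 counts — exactly the "nearly undetectable
  under cold" mutants the screen is designed to find — get a finite,
  classifiable statistic instead of 0/0. This extension is deliberate and is
  recorded in every run's output metadata (`offset_inside_rr`).
* **Strict thresholds** (`up_threshold = 3`, `down_threshold = 0.3`). Values
  exactly on a threshold are not hits, matching the printed inequalities.
* **Group split** (`group_split_log2 = -1`). The two groups are described
  qualitatively in the source screen; a quantitative cut is needed to code
  them. An enriched hit is group 1 when $\log_2(CK2/CK1 + 0.001) < -1$,
  i.e. the mutant lost more than half its relative abundance in the control
  arm — a constitutive growth defect. A depleted hit at or above the cut is
  group 2. The cut is config-exposed and reported in the manifest; hits
  matching neither pattern are reported ungrouped rather than forced.

## Insertion mapping

Flank-to-genome alignment is a package-authored k-mer seed-and-extend
(`map_params()`): every k-mer of a flank votes for a (chromosome, strand,
diagonal); diagonals with at least `min_seed_hits = 2` votes are verified by
ungapped comparison, and loci within `max_mismatch_frac = 0.1` are ranked by
score (matches − mismatches, ties by coordinate). Gapped alignment, split
reads and multi-insertion clones are out of scope. The reported position is
the genomic base aligned to the flank's first base — the first genomic base
adjacent to the cassette junction — so truth and call coordinates are
directly comparable.

Per barcode, record-level loci are clustered with ±3 bp slack; the modal
cluster must be strictly largest (ties → `ambiguous`), hold at least
`min_support = 2` records and at least `min_agree_frac = 0.8` of the
barcode's mapped records (otherwise `conflicting`). Barcodes that are not
`unique` are excluded from gene assignment: a multi-locus barcode would
nominate false candidate genes.

A note on seed size: with the default `k = 21`, two substitutions placed
~20 bp apart in a 60 bp flank can leave no intact seed k-mer, so
seed-and-extend can miss a locus an exhaustive scanner finds. At `k = 15`,
at least two intact seeds survive any two substitutions in 60 bp (a
pigeonhole argument over the three clean segments), and the tests verify
exact agreement with a full-scan Hamming aligner under that setting. The
default stays at 21 because real flanking reads are longer and cleaner than
this worst case and larger seeds keep the candidate list short.

## Insertion annotation

Positions are classified into six categories — 5′ UTR, exon, intron, 3′
UTR, potential promoter, intergenic — from one representative transcript
per gene (the longest; ties to the lexicographically smallest mRNA ID).
Rules, in priority order:

1. inside a transcript span: the matching stored sub-feature, else intron;
2. otherwise within `promoter_window = 1000` bp upstream of a TSS
   (strand-aware, boundary inclusive at exactly 1000 bp): potential
   promoter of the nearest-TSS gene;
3. otherwise intergenic.

Overlapping genes resolve to the nearest TSS, ties to the smaller gene ID;
insertion strand is ignored (location alone determines the category). The
promoter window is measured from the representative transcript's start; the
upstream-window reading of "within 1 kb" is inclusive at 1000 bp and
exclusive at 1001 bp, which the tests pin on both strands.

## The synthetic screen generator

The generator exists so the whole pipeline can be validated against ground
truth; the raw data of the motivating screen are not publicly deposited.
It emulates:

* a uniform-random genome with non-overlapping gene models, each with a 5′
  UTR, 2–4 exons separated by introns, and a 3′ UTR (so every annotation
  category is reachable);
* a barcoded library with insertions placed uniformly genome-wide and three
  fitness classes — neutral, cold-sensitive (near-neutral at 22 °C, fitness
  0.05–0.30 in cold) and constitutive (the mirror image, modelling
  group-1-type mutants);
* abundance evolution by multiplicative growth: over $g$ population
  doublings a mutant of relative fitness $f$ multiplies by $2^{fg}$ before
  renormalisation. CK2 applies $(f_{ctrl}, g_{ctrl}=4)$ to CK1, S10 applies
  $(f_{cold}, g_{cold}=6)$ to CK1, and S10R applies $(f_{ctrl}, g_{rec}=4)$
  to S10 — the recovery culture grows out of the cold-stressed pool. The
  doubling numbers reflect roughly two days of control growth versus four
  slower days in cold;
* sequencing as a single multinomial draw per sample (2×10⁵ barcode reads
  per sample, 2×10⁴ flank pairs per flank library) with per-base
  substitution noise at 0.001, constant base quality, and strand-aware
  flanks truncated at chromosome ends (flagged in the truth table).

Two consistency guarantees make truth tables trustworthy: the
`true_category` of every mutant is computed by the same classifier the
pipeline uses (they cannot disagree by construction), and the
`expected_group` is computed by applying the *screen's own* hit/group rules
to the closed-form noiseless abundances, so recovery tests compare noisy
calls against an analytically derived expectation.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: PCR amplification bias (one multinomial draw
stands in for the whole library-prep chain), indels and chimeric reads,
cassette-insertion site bias, multi-insertion clones, repetitive genome
sequence (uniform-random genomes make near-unique mapping artificially
easy), UTR-less or isoform-rich gene models, and library
cross-contamination. Results on real screens will be noisier in mapping and
in low-count ratio estimates than the synthetic benchmarks suggest.

## Numerical and degenerate-input choices

* Relative-abundance vectors renormalise to sum 1 (checked to 1e-9); all
  ratio arithmetic is double precision with the offset guaranteeing
  positivity.
* Anchor search in barcode extraction is best-score-then-leftmost, with an
  exact-match fast path; quality strings are ignored (the two anchors plus
  fixed barcode length already constrain calls).
* Empty FASTQ files, empty count matrices, barcodes absent from a sample
  (zero fill), chromosomes absent from gene models (intergenic with a
  warning, or an error on request), and flanks shorter than the seed size
  (unmapped) are all defined rather than error cases; malformed FASTQ
  records and mate-count mismatches fail loudly with the record index.
* All randomness derives from a single config seed through per-operation
  offsets, so each stage is independently reproducible and full reruns are
  byte-identical.

## Problem sizes used in validation

The shipped tests validate: exact hand arithmetic on an 8-barcode count
table; annotation against a brute-force interval scanner at 1000 random
positions on a 200 kb, 30-gene genome including both 1000/1001 bp promoter
boundaries; mapping against a full-scan Hamming aligner for 500 flanks with
0–2 substitutions on a 20 kb genome plus noiseless truth recovery;
neutral-screen calibration at 1000 mutants and 10⁵ reads/sample over three
seeds (mean $rr$ within three standard errors of 1, depleted-hit fraction
below 1%); and planted-effect recovery at the default study conditions over
three seeds (gene-level recall of cold-sensitive mutants and group-2
precision both ≥ 0.9, pre-verified against the noiseless closed-form
expectation). These sizes were chosen as the smallest at which each
property is sharply testable.

## Limitations

The ratio statistic carries the usual small positive bias of ratio
estimators (≈ $1/\lambda$ at mean count $\lambda$ in the control ratio);
at the default filter depth this is ~1% and immaterial against 3.3-fold
thresholds, but it is visible in the null calibration. No p-values or FDR
control are attempted — the screen is threshold-based and run once by
design, and replicate modelling is a non-goal. Sample-index demultiplexing,
UMI handling and adapter trimming beyond anchor location are assumed done
upstream.
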