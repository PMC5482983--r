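---
title: "Methods: multi-factor ChIP-seq peak-landscape analysis"
author: "peakscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-factor ChIP-seq peak-landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`peakscape` implements the downstream statistics that turn several sets of
called ChIP-seq peaks (one per transcription factor or histone mark, BED
format, one shared genome) into a description of the regulatory landscape:

1. **Mb-segment densities** — per 1 Mb segment and factor, the summed bp of
   peak–segment intersections `W_peaks`, a heat value `W / 5000`, TSS counts,
   and normalised densities (factor mean over retained segments = 1).
2. **Clustering statistics** — peak-width classes (singlet binding events
   produce peaks of width ~2× the chromatin fragment length, operationally
   < 500 bp with 150 bp fragments; unresolved site clusters produce
   "peak ranges" > 2000 bp), and inter-peak gap-size histograms compared
   with a random-occurrence null.
3. **TSS proximity** — the fraction of peaks within 50 kb of the nearest
   TSS, and anchor-offset aggregation profiles in 100 bp bins over a ±5 kb
   window with an analytic uniform-random baseline.
4. **Co-occupancy** — the asymmetric pairwise overlap matrix (percentage of
   anchor peaks overlapping ≥ 1 bp of a partner peak), co-bound region
   derivation, and Venn-style set comparisons.
5. **Histone signatures** — regulatory-state annotation by bp-wise mark
   intersection (active enhancer = H3K4me1 ∩ H3K27ac, poised enhancer =
   H3K4me1 ∩ H3K27me3, active promoter = H3K4me3 ∩ H3K27ac) and the
   fraction of peaks covered by each signature.
6. **Expression shift** — per-gene classification of two-condition
   expression change at a linear 2-fold cut-off, stratified by proximity
   (< 5 kb) of the TSS to signature-marked co-bound regions, with a TF-gene
   sub-stratum and a monotone-enrichment flag.

A seed-deterministic synthetic-landscape generator provides data with all
of the planted structure these analyses are designed to detect, so every
stage is testable end-to-end without external downloads.

## Coordinate conventions and the interval engine

All I/O uses the BED convention: 0-based, half-open `[start, end)`.
Internally peak sets are Bioconductor `GRanges` (1-based, closed), the
standard container of the R genomics stack; the conversion happens once at
each I/O boundary, and every user-facing quantity (starts, ends, midpoints,
distances) is reported on the 0-based grid. Key fixed definitions:

- **Overlap** requires ≥ 1 shared bp. Touching half-open intervals
  (`[x, y)` then `[y, z)`) do **not** overlap. Every co-occupancy number
  depends on this choice, so it is not configurable.
- **Midpoint** is `floor((start + end) / 2)` on the 0-based grid (integer
  determinism; no rounding ambiguity).
- **Point-to-interval distance** is 0 if the point lies inside the
  interval, else `min(|p − (end − 1)|, |start − p|)`: the distance to the
  nearest *covered base*, in bp. `GenomicRanges::distanceToNearest()`
  reports gap widths (adjacent = 0), so the engine adds 1 bp for
  non-overlapping pairs to restore the covered-base definition. Points on
  chromosomes carrying no interval get `Inf` and are flagged by callers.
- Within one peak set, overlapping intervals are rejected at construction:
  peak callers emit non-overlapping peaks, and an overlap indicates a
  corrupted input. Touching peaks are legal.
- Chromosome names are taken verbatim; a mismatch between files is an
  error, never a silent empty join.

The engine's operations delegate to IRanges/GenomicRanges; the test suite
checks them exactly against independent brute-force oracles (all-pairs
scans and a bp bitmap) on hundreds of random instances.

## Parameters that matter

| Parameter | Default | Unit | Role |
|---|---|---|---|
| `segment_bp` | 1,000,000 | bp | landscape segment width |
| `heat_divisor` | 5,000 | – | heat value `W / 5000` |
| width class edges | 500 / 1000 / 2000 | bp | singlet / intermediate / peak-range bins |
| fragment length L | 150 | bp | interpretive context: singlet width ≈ 2L |
| gap histogram bin | 0.1 | decade | log10 gap binning |
| TSS threshold | 50,000 | bp | gene-proximal vs gene-remote peaks |
| proximity threshold | 5,000 | bp | enhancer-proximal gene selection |
| profile bin / window | 100 / ±5,000 | bp | aggregation profiles |
| fold cut-off | 2 | – | activation / downregulation calls |

Distance thresholds are strict (`< threshold`); fold-change calls are
strict (`ratio > fold`, `ratio < 1/fold`), so a gene at exactly 2-fold is
"unchanged". The cut-off is applied to linear-scale ratios.

## The random-occurrence null for gap sizes

For n peaks placed uniformly on a chromosome of length G, inter-peak
spacings are approximately exponential with mean G/n, and the density of
log10(spacing) peaks at G/n. The null modal gap is therefore the
gap-count-weighted geometric mean of per-chromosome G/n; gaps are pooled
across chromosomes into one histogram. The observed modal gap is the
geometric mean of the gaps in the modal 0.1-decade bin — not the bin
centre — so degenerate inputs (a single gap) are exact, and ties between
bins break toward the smaller gap for determinism. The **clustering
ratio** (null / observed modal gap) is ~1 for dispersed factors and ≥ 10
for densely clustered ones. Note that under the exponential null the
0.1-decade bins around G/n have nearly equal probability, so the *identity*
of the modal bin fluctuates by a bin or two at n ~ 2000; the ratio, which
averages within the modal bin, is the stable statistic.

## Aggregation profiles and their baseline

For anchors A and targets T (peak midpoints, or TSS points), each
(anchor, target) pair with signed offset `o = target − anchor_midpoint`,
`−W ≤ o < W`, increments the bin containing o. Positive offsets are
higher coordinates; peaks are unstranded. Two normalisations are
available: `per_target` (fraction of target features per bin; default) and
`per_anchor` (local target density per anchor). The random baseline is
`n_other × bin_width / G` with `n_other` the non-normalising set's size:
the level two independent uniformly placed sets converge to, which the
test suite verifies against Poisson sampling error. The central summary
averages the two bins adjacent to offset 0 and divides by the baseline:
< 1 flags mutual exclusion, > 1 proximal co-occurrence. Because the
normalisation choice for this kind of plot is genuinely ambiguous, both
modes are implemented and the mode is recorded in the profile's metadata.

## Co-occupancy conventions

All overlap counts are **anchor-based and asymmetric**: the entry (a, b)
is the percentage of a's peaks overlapping ≥ 1 b peak, with an anchor peak
overlapping several partners counted once. The two directions differ
whenever widths or counts differ, which is exactly why direction-dependent
percentage pairs are reported; the merged-union alternative is not
implemented. Co-bound region sets embed their anchor convention as
metadata rather than hiding it. Gene-level overlap of two region sets uses
TSS-to-region distance and reports the chance expectation `n1 × n2 / N`
(the mean hypergeometric overlap of random subsets), validated against
Monte-Carlo subset draws in the tests.

## The synthetic landscape generator

The generator emulates, on a deliberately small genome, the features the
analyses consume:

- **Genome**: 2 chromosomes × 20 Mb. Large enough for ≥ 10 Mb-segments per
  domain class, small enough for seconds-scale tests.
- **Domains**: deterministic alternation of gene-rich / gene-poor blocks
  of 1 Mb (configurable period), starting rich at coordinate 0.
  Deterministic alternation (rather than random block lengths) makes the
  domain-recovery tests sharp.
- **Factors**: five sets of 1500 peaks with log-normal widths. Two
  clustered factors are generated by a parent–child (Neyman–Scott-style)
  process — parents uniform within the assigned domain type, children
  displaced by a 2 kb-sd Gaussian, 6 children per parent on average —
  confined to gene-rich (ZIC2-like) or gene-poor (POU3F1-like) blocks.
  Three dispersed factors are uniform genome-wide.
- **Co-binding**: for an ordered pair (a, b) with fraction p, exactly
  `round(p · n_a)` randomly chosen a-peaks are re-centred to a uniform
  position inside a randomly chosen b peak. Since the new midpoint lies
  inside b, ≥ 1 bp overlap is guaranteed, making p the exact expected
  overlap fraction — an analytic recovery target. Defaults: OTX2→ZIC2 0.5,
  POU5F1→POU3F1 0.4, SOX2→POU3F1 0.15.
- **Within-set overlaps** are resolved by iterative rejection resampling
  (re-planted peaks choose a new partner peak; free peaks a new position).
  If resolution fails after bounded retries a capacity error is raised —
  peak counts are never silently truncated.
- **Genes**: 5000 TSS points with a 4:1 rich:poor density ratio; 20%
  flagged as TF genes.
- **Histone marks**: the active-enhancer pair (H3K4me1, H3K27ac) covers a
  simple-random q-fraction (default 0.4) of the ZIC2–OTX2 co-bound peaks,
  plus 300 uniform background intervals per mark; H3K27me3 is background
  only. Signature intervals coincide with the marked peak span (zero
  padding): padded marks would bleed onto adjacent unmarked peaks of the
  clustered factor and make the planted fraction unrecoverable as an exact
  target. Real histone domains are broader than this.
- **Expression**: log-normal reference; per condition each gene draws a
  shift s ∈ {−1, 0, +1} with probabilities set by its stratum
  (background / proximal / proximal-TF downregulation probabilities
  0.33 / 0.43 / 0.59, activation 0.30 / 0.21 / 0.15), and the comparison
  value is `reference × fold^s` (fold 4) times multiplicative log-normal
  noise (sdlog 0.05, which cannot cross the 2-fold cut-off, so class
  recovery reflects the planted shifts exactly). `fold = 1` gives a null
  configuration.

Determinism: the landscape and the expression table are drawn from
separately seeded RNG streams (`seed` and `seed + 1`), and equal
(config, seed) produces byte-identical BED/TSV artifacts.

### Statistical sizing of the recovery tests

The test suite recovers planted parameters within 3 binomial standard
errors and requires the downregulation ordering all < proximal <
proximal-TF to hold on every seed tested. The instance used for the
expression-recovery test therefore raises the marked fraction (q = 0.8)
and TF-gene share (0.25) so the proximal-TF stratum reaches ~150–200
genes: at the planted 0.43 / 0.59 separation this puts the ordering
comparison at ≥ 3 standard errors, making an every-seed requirement a
meaningful test of the method rather than a coin flip. Co-binding
recovery uses dispersed factors on a 400 Mb genome so that chance overlap
(~0.3%) is negligible against the planted fractions.

### What the generator does not emulate

- Read-level effects: no FASTQ simulation, fragment pile-up or peak-caller
  emulation; the singlet "2L" width logic is exercised through the width
  distribution only.
- Chromosome-scale heterogeneity (centromeres, mappability gaps,
  chromosome-specific gene density) — domains alternate with a fixed
  period instead.
- Realistic gene spacing: at 5000 genes on 40 Mb nearly every peak is
  within 50 kb of some TSS, so the gene-proximal vs gene-remote dichotomy
  of factor classes is compressed; the TSS-distance machinery is instead
  validated by brute-force enumeration and boundary cases.
- Histone-domain breadth (see above) and inter-mark disagreement.

Passing tests therefore demonstrate correctness of the statistics and
recoverability of planted structure, not biological realism of the
synthetic data.

## Numerical and degenerate-input choices

- Segment tiling restarts at 0 on each chromosome; trailing partial
  segments are kept and *not* length-corrected (densities are "per
  segment"), but carry their true `end`, so users can exclude them.
- Segments with no peak of any factor are flagged `removed`; normalisation
  averages over retained segments by default (`normalize_over = "all"` is
  available), and rows are kept so width conservation is checkable.
- Factors with zero total width get `NA` normalised densities and are
  flagged, never divided by zero; constant density vectors yield `NA`
  correlations with a warning.
- Empty peak sets: width classes and TSS classes return flagged `NA`
  fractions; empty anchor rows of the overlap matrix are `NA` and listed.
- Zero-reference genes are excluded from fold-change classification and
  reported by id.
- Replicate reference expression columns are combined by arithmetic mean
  at read time.

## Limitations

- Cross-species comparisons consume pre-lifted BED files; no coordinate
  lifting is performed.
- No significance testing of overlaps beyond the `n1·n2/N` expectation,
  and no multiple-testing machinery: the analyses report fractions.
- Peaks are unstranded throughout; there are no TSS-directional metaplots.
- Wide "peak ranges" are not deconvolved into constituent binding sites.

## Problem sizes

Default test and pipeline runs use 2 × 20 Mb genomes, 1500 peaks per
factor and 5000 genes; oracle-equivalence tests use 100 instances of up to
200 intervals on a 100 kb toy genome; the co-binding calibration uses
2000-peak factors on 400 Mb. These sizes keep the full suite in the
low minutes on one CPU while leaving every recovery test adequately
powered.
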