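# peakscape

Downstream analysis of multi-factor ChIP-seq peak landscapes in R.

`peakscape` is for genomics analysts who have *called peaks* (BED files)
for several transcription factors and histone marks on one genome and want
the standard landscape-level statistics that sit between peak calling and
biological interpretation:

- **Mb-segment density landscapes.** Each chromosome is tiled into 1 Mb
  segments; per segment and factor the summed peak width W_peaks is scored
  (heat value = W_peaks / 5000), together with the number of gene TSSs.
  Normalised densities (per-factor mean = 1 over retained segments) expose
  Mb-scale domain structure, and Pearson correlations between per-segment
  densities quantify which factors share domains with each other and with
  genes.
- **Clustering statistics.** Peak-width classes (< 500 bp ≈ singlet
  binding events at fragment length L = 150, width ≈ 2L; > 2000 bp ≈
  unresolved "peak ranges") and inter-peak gap-size histograms. The gap
  between adjacent peaks is the distance of their midpoints; the
  random-occurrence null for n uniform peaks on a chromosome of length G
  has exponential spacings of mean G/n, giving the clustering ratio
  (null modal gap / observed modal gap): ~1 for dispersed factors, ≥ 10
  for densely clustered ones.
- **TSS proximity and aggregation profiles.** Fractions of peaks within
  50 kb of a TSS, and signed-offset profiles of target features around
  anchor-peak midpoints (100 bp bins, ±5 kb window) against the analytic
  uniform baseline n × bin / G. The central value / baseline ratio flags
  mutually exclusive binding (< 1) or co-occurrence (> 1).
- **Co-occupancy.** The asymmetric overlap matrix — entry (a, b) is the
  percentage of a's peaks overlapping ≥ 1 bp of a b peak — plus co-bound
  region sets, Venn-style comparisons, and gene-level overlap of two
  proximity-defined gene sets against the hypergeometric expectation
  n1 · n2 / N.
- **Histone signatures.** Active enhancer = H3K4me1 ∩ H3K27ac, poised
  enhancer = H3K4me1 ∩ H3K27me3, active promoter = H3K4me3 ∩ H3K27ac
  (bp-wise intersections), and signature coverage fractions of any peak
  set.
- **Expression shift.** Per-gene two-condition classification at a linear
  2-fold cut-off (strict inequalities), stratified as all genes / genes
  with a TSS < 5 kb from signature-marked co-bound regions / the TF-gene
  subset, with a monotone-downregulation flag.

A seed-deterministic synthetic-landscape generator plants all of this
structure (domain alternation, Neyman–Scott peak clustering, exact
co-binding fractions, signature-marked co-bound subsets, proximity-biased
expression shifts), so the whole pipeline is testable without external
data. See `vignettes/peak-landscape-methods.Rmd` for the methods account.

## Worked example

```r
library(peakscape)

cfg  <- landscape_config(seed = 7)        # 2 x 20 Mb, 5 factors, 5000 genes
land <- generate_landscape(cfg)

# co-occupancy: % of anchor (row) peaks overlapping the target (column)
round(overlap_matrix(land$peaks)$percent, 1)
#>         ZIC2  OTX2  SOX2 POU5F1 POU3F1
#> ZIC2   100.0  50.8   4.1    2.5    0.0
#> OTX2    51.6 100.0   3.8    2.6    1.8
#> SOX2     3.7   3.8 100.0    8.1   18.1
#> POU5F1   2.4   2.5   8.2  100.0   41.5
#> POU3F1   0.0   2.0  19.5   42.7  100.0

# domain structure: the clustered gene-rich factor tracks genes,
# the gene-poor factor anti-tracks it
seg <- segment_densities(land$peaks, land$annotation, land$genome)
r   <- domain_correlations(seg)
r["ZIC2", "genes"]; r["ZIC2", "POU3F1"]
#> [1] 0.93
#> [1] -0.881

# clustering: modal gap an order of magnitude below the uniform null
gap_profile(land$peaks$ZIC2, land$genome)$clustering_ratio
#> [1] 23.76

# expression shift around signature-marked co-bound regions
sigs   <- enhancer_signatures(land$marks)
cb     <- co_bound(land$peaks$ZIC2, land$peaks$OTX2)
marked <- co_bound(cb, sigs$active_enhancer)
prox   <- proximal_gene_set(marked, land$annotation)
expr   <- generate_expression(cfg, land$annotation, prox$gene_ids, prox$tf_gene_ids)
ss     <- shift_summary(classify_changes(expr, fold = 2),
                        list(proximal = prox$gene_ids,
                             proximal_tf = prox$tf_gene_ids))
ss[, c("stratum", "n_genes", "fraction_downregulated")]
#>       stratum n_genes fraction_downregulated
#> 1         all    5000              0.3422000
#> 2    proximal     441              0.4739229
#> 3 proximal_tf      90              0.5777778
```

Reading: the planted co-binding (OTX2→ZIC2 0.5, POU5F1→POU3F1 0.4,
SOX2→POU3F1 0.15) reappears as the off-diagonal overlap percentages; the
two domain-segregated clustered factors overlap ~0%; and genes near
active-signature co-bound regions are downregulated more often than
background (planted probabilities 0.33 / 0.43 / 0.59), increasing
monotonically toward the TF-gene stratum.

## Analysis workflow

The `analysis/` directory is a numbered, re-runnable walk through the full
study on the default synthetic landscape, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R            # dataset (BED/TSV) under results/dataset
Rscript analysis/02_domain_landscape.R    # Mb-segment densities + correlations
Rscript analysis/03_clustering_profiles.R # width classes + gap-size nulls
Rscript analysis/04_proximity_profiles.R  # TSS classes + aggregation profiles
Rscript analysis/05_cooccurrence.R        # overlap matrix, signatures, gene overlap
Rscript analysis/06_expression_shift.R    # stratified 2-fold shift summary
```

`run_pipeline(config, outdir)` runs the same stages in one call and writes
a machine-readable `run_summary.json`; reruns are byte-identical.

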