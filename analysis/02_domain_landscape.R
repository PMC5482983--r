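#!/usr/bin/env Rscript
# Megabase-segment peak/gene density landscape: tile the genome into 1 Mb
# segments, score summed peak width per factor and TSS counts per segment,
# and quantify the alternating domain structure via normalised-density
# spread and pairwise Pearson correlations.
source("analysis/_common.R")

peaks <- read_dataset_peaks()
genes <- read_dataset_genes()

seg <- segment_densities(peaks, genes, GENOME)
save_table(seg, "segment_densities.tsv")

dd <- density_distribution(seg)
save_table(dd, "density_distribution.tsv")

r <- domain_correlations(seg)
save_table(data.frame(factor = rownames(r), r, check.names = FALSE),
           "domain_correlations.tsv")

message("Segments: ", nrow(seg), " (", sum(seg$removed), " without peaks, flagged removed)")
message("Normalised-density spread (fraction of segments >5 / <0.1):")
for (i in seq_len(nrow(dd))) {
  message(sprintf("  %-7s %.3f / %.3f", dd$factor[i], dd$frac_gt5[i],
                  dd$frac_lt0.1[i]))
}
message("The clustered factors (ZIC2, POU3F1) show the broad spread; the")
message("dispersed factors concentrate near 1.")
message(sprintf("r(ZIC2, genes) = %.2f; r(POU3F1, genes) = %.2f; r(ZIC2, POU3F1) = %.2f",
                r["ZIC2", "genes"], r["POU3F1", "genes"], r["ZIC2", "POU3F1"]))
message("=> gene-rich domains carry the ZIC2-like factor, gene-poor the POU3F1-like one.")
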