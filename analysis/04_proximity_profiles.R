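#!/usr/bin/env Rscript
# TSS proximity of peaks (within / beyond 50 kb of the nearest TSS) and
# anchor-offset aggregation profiles in 100 bp bins with the analytic
# random baseline: central depletion flags mutually exclusive binding,
# central enrichment proximal co-occurrence.
source("analysis/_common.R")

peaks <- read_dataset_peaks()
genes <- read_dataset_genes()

tssc <- do.call(rbind, lapply(FACTORS, function(f) {
  t <- tss_distance_classes(peaks[[f]], genes)
  data.frame(factor = f, fraction_within_50kb = t$fraction_within,
             fraction_beyond_50kb = t$fraction_beyond, n_peaks = t$n_peaks)
}))
save_table(tssc, "tss_distance_classes.tsv")

# pairwise central-ratio summary plus the full ZIC2-anchored profiles
rows <- list()
for (a in FACTORS) for (b in FACTORS) {
  if (a == b) next
  pr <- aggregate_profile(peaks[[a]], peaks[[b]])
  if (a == "ZIC2") save_table(pr, paste0("profile_ZIC2_vs_", b, ".tsv"))
  s <- depletion_enrichment_summary(pr)
  rows[[paste(a, b)]] <- data.frame(anchor = a, target = b,
                                    ratio = s$ratio,
                                    interpretation = s$interpretation)
}
central <- do.call(rbind, rows)
save_table(central, "aggregation_central_ratios.tsv")

# TSS density around ZIC2 peaks (gene-proximal factor)
tss_prof <- aggregate_profile(peaks$ZIC2, genes, mode = "per_anchor")
save_table(tss_prof, "profile_ZIC2_vs_TSS.tsv")

message("Fraction of peaks within 50 kb of a TSS:")
for (i in seq_len(nrow(tssc))) {
  message(sprintf("  %-7s %.2f", tssc$factor[i],
                  tssc$fraction_within_50kb[i]))
}
message("Central-ratio extremes (profile value at offset 0 / random baseline):")
ord <- central[order(central$ratio), ]
message(sprintf("  most depleted:  %s vs %s (ratio %.2f)",
                ord$anchor[1], ord$target[1], ord$ratio[1]))
message(sprintf("  most enriched:  %s vs %s (ratio %.1f)",
                ord$anchor[nrow(ord)], ord$target[nrow(ord)],
                ord$ratio[nrow(ord)]))
message("=> the two domain-segregated clustered factors exclude each other;")
message("   planted co-binding pairs co-locate at offset zero.")
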