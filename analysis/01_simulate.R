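#!/usr/bin/env Rscript
# Generate the synthetic peak landscape that stands in for a deposited
# multi-TF ChIP-seq dataset: five factor peak sets (two clustered,
# domain-restricted; three dispersed), a gene annotation with a 4:1
# gene-rich:gene-poor density ratio over alternating 1 Mb blocks, and
# histone-mark interval sets marking 40% of ZIC2-OTX2 co-bound peaks as
# active enhancers. Everything is deterministic given the seed.
source("analysis/_common.R")

land <- generate_landscape(CONFIG)

for (f in FACTORS) {
  write_bed(land$peaks[[f]], file.path(DATASET_DIR, paste0("peaks_", f, ".bed")))
}
for (m in MARKS) {
  write_bed(land$marks[[m]], file.path(DATASET_DIR, paste0("mark_", m, ".bed")))
}
write_gene_table(land$annotation, file.path(DATASET_DIR, "genes.tsv"))

message("Simulated landscape (seed ", SEED, "):")
message("  genome: ", paste(CONFIG$genome$chroms, collapse = ", "),
        " (", sum(CONFIG$genome$lengths) / 1e6, " Mb total)")
message("  peaks per factor: ",
        paste(sprintf("%s=%d", FACTORS, sapply(land$peaks, length)),
              collapse = ", "))
message("  genes: ", nrow(land$annotation),
        " (TF genes: ", sum(land$annotation$is_tf), ")")
message("  planted co-binding: ",
        paste(names(land$truth$planted_co_binding),
              unlist(land$truth$planted_co_binding), collapse = ", "))
message("  ZIC2-OTX2 co-bound peaks: ", land$truth$n_co_bound,
        "; signature-marked: ", land$truth$n_marked)
message("Dataset written to ", DATASET_DIR)
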