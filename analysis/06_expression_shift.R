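#!/usr/bin/env Rscript
# Two-condition expression-shift analysis: classify per-gene changes with a
# 2-fold cut-off and stratify by proximity to signature-marked co-bound
# regions (all genes / proximal genes / proximal TF genes). On the
# synthetic landscape the proximal strata carry planted elevated
# downregulation probabilities, the signature of enhancers decommissioned
# in the comparison condition.
source("analysis/_common.R")

peaks <- read_dataset_peaks()
marks <- read_dataset_marks()
genes <- read_dataset_genes()

sigs <- enhancer_signatures(marks)
cb <- co_bound(peaks$ZIC2, peaks$OTX2)
marked <- co_bound(cb, sigs$active_enhancer)
prox <- proximal_gene_set(marked, genes, thresh = 5000)

expr <- generate_expression(CONFIG, genes, prox$gene_ids, prox$tf_gene_ids)
write_expression_table(expr, file.path(DATASET_DIR, "expression.tsv"))

cls <- classify_changes(expr, fold = 2)
save_table(cls, "expression_classes.tsv")

ss <- shift_summary(cls, list(proximal = prox$gene_ids,
                              proximal_tf = prox$tf_gene_ids))
save_table(ss, "shift_summary.tsv")

message(sprintf("Proximal genes (< 5 kb of a marked co-bound region): %d (%d TF genes)",
                length(prox$gene_ids), length(prox$tf_gene_ids)))
message("Downregulated / activated fractions per stratum:")
for (i in seq_len(nrow(ss))) {
  message(sprintf("  %-12s n=%5d  down %.2f  up %.2f", ss$stratum[i],
                  ss$n_genes[i], ss$fraction_downregulated[i],
                  ss$fraction_activated[i]))
}
message("Monotone enrichment (all < proximal < proximal TF): ",
        all(attr(ss, "monotone_down")))
message("=> proximity to active-signature co-bound regions biases genes")
message("   toward downregulation in the comparison condition.")
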