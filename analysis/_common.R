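# Shared setup for the numbered analysis drivers: one configuration, one
# seed, one dataset directory. Every driver can be run standalone from the
# repository root (01 must have been run first so the dataset exists).
suppressMessages(library(peakscape))
suppressMessages(library(data.table))

SEED <- 20260901L
DATASET_DIR <- "results/dataset"
TABLE_DIR <- "results/tables"

CONFIG <- landscape_config(seed = SEED)
GENOME <- genome_layout(CONFIG$genome$chroms, CONFIG$genome$lengths)
FACTORS <- names(CONFIG$factors)
MARKS <- c("H3K4me1", "H3K27ac", "H3K27me3")

dir.create(DATASET_DIR, recursive = TRUE, showWarnings = FALSE)
dir.create(TABLE_DIR, recursive = TRUE, showWarnings = FALSE)

read_dataset_peaks <- function() {
  sets <- lapply(FACTORS, function(f) {
    read_bed(file.path(DATASET_DIR, paste0("peaks_", f, ".bed")), GENOME, f)
  })
  names(sets) <- FACTORS
  sets
}

read_dataset_marks <- function() {
  sets <- lapply(MARKS, function(m) {
    read_bed(file.path(DATASET_DIR, paste0("mark_", m, ".bed")), GENOME, m)
  })
  names(sets) <- MARKS
  sets
}

read_dataset_genes <- function() {
  read_gene_table(file.path(DATASET_DIR, "genes.tsv"), GENOME)
}

save_table <- function(df, name) {
  path <- file.path(TABLE_DIR, name)
  fwrite(as.data.frame(df), path, sep = "\t", quote = FALSE)
  message("  wrote ", path)
}
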