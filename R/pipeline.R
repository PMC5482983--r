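#' Run the full peak-landscape pipeline on a synthetic dataset
#'
#' Generates the synthetic landscape for \code{config}, runs every analysis
#' stage in order (io -> landscape -> clustering -> proximity ->
#' co-occurrence -> expression shift) and writes all per-stage TSV/BED
#' outputs plus a machine-readable JSON summary into \code{outdir}. Outputs
#' contain no timestamps, so reruns with identical (config, seed) are
#' byte-identical.
#'
#' @param config A \code{\link{landscape_config}}.
#' @param outdir Output directory (created if needed).
#' @param skip_expression If TRUE the expression stage is skipped (recorded
#'   in the summary), mirroring a run without expression data.
#' @return Invisibly, a list with the in-memory stage results and
#'   \code{outdir}.
#' @export
run_pipeline <- function(config, outdir, skip_expression = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  land <- generate_landscape(config)
  genome <- land$genome
  peaks <- land$peaks
  fs <- names(peaks)

  # --- io: persist the dataset itself
  for (f in fs) write_bed(peaks[[f]], file.path(outdir, paste0("peaks_", f, ".bed")))
  for (m in names(land$marks)) {
    write_bed(land$marks[[m]], file.path(outdir, paste0("mark_", m, ".bed")))
  }
  write_gene_table(land$annotation, file.path(outdir, "genes.tsv"))

  # --- domain landscape
  seg <- segment_densities(peaks, land$annotation, genome)
  data.table::fwrite(as.data.frame(seg), file.path(outdir, "segment_densities.tsv"),
                     sep = "\t", quote = FALSE)
  dist_tab <- density_distribution(seg)
  data.table::fwrite(dist_tab, file.path(outdir, "density_distribution.tsv"),
                     sep = "\t", quote = FALSE)
  cors <- domain_correlations(seg)
  data.table::fwrite(data.frame(factor = rownames(cors), cors,
                                check.names = FALSE),
                     file.path(outdir, "domain_correlations.tsv"),
                     sep = "\t", quote = FALSE)

  # --- clustering profiles
  wc <- do.call(rbind, lapply(fs, function(f) {
    x <- width_classes(peaks[[f]])
    cbind(factor = f, x)
  }))
  data.table::fwrite(wc, file.path(outdir, "width_classes.tsv"),
                     sep = "\t", quote = FALSE)
  gp <- do.call(rbind, lapply(fs, function(f) {
    g <- gap_profile(peaks[[f]], genome)
    data.frame(factor = f, modal_gap = g$modal_gap,
               null_modal_gap = g$null_modal_gap,
               clustering_ratio = g$clustering_ratio, n_gaps = g$n_gaps)
  }))
  data.table::fwrite(gp, file.path(outdir, "gap_summary.tsv"),
                     sep = "\t", quote = FALSE)

  # --- proximity profiles
  tssc <- do.call(rbind, lapply(fs, function(f) {
    t <- tss_distance_classes(peaks[[f]], land$annotation)
    data.frame(factor = f, fraction_within = t$fraction_within,
               fraction_beyond = t$fraction_beyond, n_peaks = t$n_peaks)
  }))
  data.table::fwrite(tssc, file.path(outdir, "tss_distance_classes.tsv"),
                     sep = "\t", quote = FALSE)
  pair_rows <- list()
  for (a in fs) for (b in fs) {
    if (a == b) next
    pr <- aggregate_profile(peaks[[a]], peaks[[b]])
    s <- depletion_enrichment_summary(pr)
    pair_rows[[paste(a, b)]] <- data.frame(
      anchor = a, target = b, central_value = s$central_value,
      baseline = s$baseline, ratio = s$ratio,
      interpretation = s$interpretation)
  }
  data.table::fwrite(do.call(rbind, pair_rows),
                     file.path(outdir, "aggregation_central_ratios.tsv"),
                     sep = "\t", quote = FALSE)

  # --- co-occurrence
  om <- overlap_matrix(peaks)
  data.table::fwrite(data.frame(anchor = rownames(om$percent), om$percent,
                                check.names = FALSE),
                     file.path(outdir, "overlap_matrix_percent.tsv"),
                     sep = "\t", quote = FALSE)
  sigs <- enhancer_signatures(land$marks)
  for (s in names(sigs)) {
    write_bed(sigs[[s]], file.path(outdir, paste0("signature_", s, ".bed")))
  }
  pair <- config$signature$pair
  cb <- co_bound(peaks[[pair[1]]], peaks[[pair[2]]])
  write_bed(cb, file.path(outdir, "co_bound.bed"))
  sf <- signature_overlap_fractions(cb, sigs)
  data.table::fwrite(sf, file.path(outdir, "signature_fractions.tsv"),
                     sep = "\t", quote = FALSE)
  marked <- co_bound(cb, sigs$active_enhancer)
  glo <- gene_level_overlap(cb, 50000, marked, 5000, land$annotation)

  # --- expression shift
  expr_summary <- NULL
  if (!skip_expression) {
    prox <- proximal_gene_set(marked, land$annotation)
    expr <- generate_expression(config, land$annotation, prox$gene_ids,
                                prox$tf_gene_ids)
    write_expression_table(expr, file.path(outdir, "expression.tsv"))
    cls <- classify_changes(expr, fold = 2)
    data.table::fwrite(cls, file.path(outdir, "expression_classes.tsv"),
                       sep = "\t", quote = FALSE)
    expr_summary <- shift_summary(cls, list(proximal = prox$gene_ids,
                                            proximal_tf = prox$tf_gene_ids))
    data.table::fwrite(expr_summary, file.path(outdir, "shift_summary.tsv"),
                       sep = "\t", quote = FALSE)
  }

  summary <- list(
    seed = config$seed,
    parameters = list(segment_bp = 1e6, heat_divisor = 5000,
                      width_bins = c(500, 1000, 2000), tss_threshold = 50000,
                      proximity_threshold = 5000, bin_width = 100,
                      window = 5000, fold = 2),
    n_peaks = lapply(peaks, length),
    n_genes = nrow(land$annotation),
    n_segments = nrow(seg),
    n_segments_removed = sum(seg$removed),
    n_co_bound = length(cb),
    n_marked = length(marked),
    gene_overlap = glo[c("n1", "n2", "intersection", "expected")],
    expression_stage = if (skip_expression) "skipped" else "run",
    outputs = setdiff(list.files(outdir), "run_summary.json")
  )
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(outdir = outdir, landscape = land, segments = seg,
                 overlap = om, signatures = sigs, co_bound = cb,
                 marked = marked, gene_overlap = glo,
                 shift_summary = expr_summary))
}
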