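#' Classify per-gene expression changes against the reference
#'
#' Per gene and comparison condition, the linear ratio condition/reference
#' is scored with strict inequalities: ratio > fold is "activated",
#' ratio < 1/fold is "downregulated", anything else (including exactly
#' fold or 1/fold) is "unchanged". Genes with a zero reference value have
#' no defined ratio; they are excluded and reported.
#'
#' @param expr An \code{\link{expression_table}}.
#' @param fold Fold-change cut-off (> 1; default 2).
#' @return data.frame of class \code{expression_classes}: one row per
#'   classified gene x condition with \code{gene_id}, \code{condition},
#'   \code{ratio}, \code{label}; \code{attr(, "excluded")} lists
#'   zero-reference gene ids.
#' @export
classify_changes <- function(expr, fold = 2) {
  if (fold <= 1) stop("fold cut-off must be > 1")
  conds <- attr(expr, "conditions")
  if (is.null(conds)) expr <- expression_table(expr)
  conds <- attr(expr, "conditions")
  zero_ref <- expr$reference == 0
  kept <- expr[!zero_ref, , drop = FALSE]
  rows <- lapply(conds, function(cc) {
    ratio <- kept[[cc]] / kept$reference
    label <- ifelse(ratio > fold, "activated",
                    ifelse(ratio < 1 / fold, "downregulated", "unchanged"))
    data.frame(gene_id = kept$gene_id, condition = cc, ratio = ratio,
               label = label)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- expr$gene_id[zero_ref]
  attr(out, "fold") <- fold
  attr(out, "conditions") <- conds
  class(out) <- c("expression_classes", "data.frame")
  out
}

#' Genes proximal to a set of regions
#'
#' A gene is proximal when the distance from its TSS point to the nearest
#' region is < thresh (0 if the TSS lies inside a region). The TF-gene
#' subset is selected by the annotation's \code{is_tf} flag.
#'
#' @param regions A peak set (e.g. signature-marked co-bound regions).
#' @param annotation A \code{\link{gene_annotation}} with \code{is_tf} flags.
#' @param thresh Proximity threshold in bp (default 5000).
#' @return List: \code{gene_ids}, \code{tf_gene_ids} (subset of the former).
#' @export
proximal_gene_set <- function(regions, annotation, thresh = 5000) {
  d <- nearest_point_distance(annotation$chrom, annotation$tss, regions)
  prox <- is.finite(d) & d < thresh
  list(gene_ids = annotation$gene_id[prox],
       tf_gene_ids = annotation$gene_id[prox & annotation$is_tf])
}

#' Stratified expression-shift summary
#'
#' Per comparison condition and gene stratum, the fractions of classified
#' genes that are activated, downregulated and unchanged. Strata are named
#' gene-id sets and must be nested in the order given (each stratum a subset
#' of the previous; the implicit first stratum "all" is every classified
#' gene). The summary also flags, per condition, whether the downregulated
#' fraction increases monotonically along the strata — the signature of
#' regulatory regions whose target genes are preferentially shut down in
#' the comparison condition.
#'
#' @param classes A \code{\link{classify_changes}} result.
#' @param strata Named list of gene-id vectors, outermost first, e.g.
#'   \code{list(proximal = ..., proximal_tf = ...)}.
#' @return data.frame of class \code{shift_summary}: one row per condition x
#'   stratum with \code{n_genes}, \code{fraction_activated},
#'   \code{fraction_downregulated}, \code{fraction_unchanged},
#'   \code{flagged} (empty stratum); \code{attr(, "monotone_down")} is a
#'   named logical per condition.
#' @export
shift_summary <- function(classes, strata = list()) {
  conds <- attr(classes, "conditions")
  all_ids <- unique(classes$gene_id)
  strata_ids <- c(list(all = all_ids),
                  lapply(strata, function(s) intersect(s, all_ids)))
  # enforce nesting outermost -> innermost
  for (i in seq_along(strata_ids)[-1]) {
    extra <- setdiff(strata_ids[[i]], strata_ids[[i - 1]])
    if (length(extra)) {
      stop("stratum '", names(strata_ids)[i], "' is not nested within '",
           names(strata_ids)[i - 1], "'")
    }
  }
  rows <- list()
  monotone <- stats::setNames(rep(NA, length(conds)), conds)
  for (cc in conds) {
    sub <- classes[classes$condition == cc, , drop = FALSE]
    lab <- stats::setNames(sub$label, sub$gene_id)
    downs <- numeric(0)
    for (s in names(strata_ids)) {
      ids <- strata_ids[[s]]
      n <- length(ids)
      if (n == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cc, stratum = s, n_genes = 0L,
          fraction_activated = NA_real_, fraction_downregulated = NA_real_,
          fraction_unchanged = NA_real_, flagged = TRUE)
        downs <- c(downs, NA_real_)
        next
      }
      l <- lab[ids]
      fa <- mean(l == "activated")
      fd <- mean(l == "downregulated")
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cc, stratum = s, n_genes = n,
        fraction_activated = fa, fraction_downregulated = fd,
        fraction_unchanged = 1 - fa - fd, flagged = FALSE)
      downs <- c(downs, fd)
    }
    monotone[cc] <- if (anyNA(downs)) NA else all(diff(downs) > 0)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "monotone_down") <- monotone
  attr(out, "strata") <- names(strata_ids)
  class(out) <- c("shift_summary", "data.frame")
  out
}
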