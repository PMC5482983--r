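#' Megabase-segment peak-density and gene-density landscape
#'
#' Tiles every chromosome into fixed-width segments (default 1 Mb; each
#' chromosome is tiled independently from coordinate 0 and the trailing
#' partial segment is kept, flagged via its shorter width). Per segment and
#' factor, the summed bp of peak-segment intersections (W_peaks) is scored:
#' a peak spanning a boundary contributes its intersected width to each
#' segment, so summing W over all segments conserves total peak width
#' exactly. Gene density is the count of TSS points per segment.
#'
#' Segments without any peak of any factor are flagged \code{removed}
#' (mirroring heat-map practice of dropping empty tiles); the rows are
#' retained so conservation can still be checked. Per factor, a heat value
#' \code{W / heat_divisor} and a normalised density (density divided by the
#' factor's mean density over retained segments, so the retained-segment
#' mean is exactly 1) are added.
#'
#' @param peaksets Named list of peak sets, one per factor.
#' @param annotation A \code{\link{gene_annotation}} (or NULL to skip gene
#'   counts).
#' @param genome A \code{Seqinfo}.
#' @param segment_bp Segment width in bp (default 1e6).
#' @param heat_divisor Divisor for the heat value (default 5000).
#' @param normalize_over \code{"retained"} (default) or \code{"all"}:
#'   which segments enter the per-factor mean used for normalisation.
#' @return data.frame of class \code{segment_density_table}: one row per
#'   segment with \code{chrom}, \code{start}, \code{end} (0-based half-open),
#'   \code{removed}, \code{n_genes}, and per factor \code{W_<f>},
#'   \code{heat_<f>}, \code{norm_<f>}. Factors with zero total width get
#'   \code{NA} normalised densities and are listed in
#'   \code{attr(, "flagged_factors")}.
#' @export
segment_densities <- function(peaksets, annotation, genome,
                              segment_bp = 1e6, heat_divisor = 5000,
                              normalize_over = c("retained", "all")) {
  normalize_over <- match.arg(normalize_over)
  if (length(peaksets) == 0L) stop("need at least one factor")
  if (is.null(names(peaksets)) || any(names(peaksets) == "")) {
    names(peaksets) <- vapply(peaksets, factor_label, character(1))
  }
  if (segment_bp < 1) stop("segment_bp must be >= 1")
  lens <- .chrom_lengths(genome)
  if (length(lens) == 0L) stop("empty genome")
  tiles <- GenomicRanges::tileGenome(GenomeInfoDb::seqlengths(genome),
                                     tilewidth = segment_bp,
                                     cut.last.tile.in.chrom = TRUE)
  n_seg <- length(tiles)
  W <- matrix(0, nrow = n_seg, ncol = length(peaksets),
              dimnames = list(NULL, names(peaksets)))
  for (f in names(peaksets)) {
    ps <- peaksets[[f]]
    .check_same_genome(ps, genome)
    if (length(ps) == 0L) next
    h <- GenomicRanges::findOverlaps(tiles, ps, minoverlap = 1L,
                                     ignore.strand = TRUE)
    if (length(h) > 0L) {
      pw <- GenomicRanges::width(GenomicRanges::pintersect(
        tiles[S4Vectors::queryHits(h)], ps[S4Vectors::subjectHits(h)]))
      agg <- rowsum(as.numeric(pw), group = S4Vectors::queryHits(h))
      W[as.integer(rownames(agg)), f] <- agg[, 1]
    }
  }
  n_genes <- rep(0L, n_seg)
  if (!is.null(annotation)) {
    tss <- .point_granges(annotation$chrom, annotation$tss, genome)
    n_genes <- GenomicRanges::countOverlaps(tiles, tss, minoverlap = 1L)
  }
  removed <- rowSums(W) == 0
  keep <- if (normalize_over == "retained") !removed else rep(TRUE, n_seg)
  flagged <- character()
  norm <- matrix(NA_real_, nrow = n_seg, ncol = ncol(W),
                 dimnames = dimnames(W))
  for (f in colnames(W)) {
    m <- mean(W[keep, f])
    if (!is.finite(m) || m == 0) {
      flagged <- c(flagged, f)
    } else {
      norm[, f] <- W[, f] / m
    }
  }
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(tiles)),
    start = GenomicRanges::start(tiles) - 1,
    end = as.numeric(GenomicRanges::end(tiles)),
    removed = removed,
    n_genes = as.integer(n_genes),
    check.names = FALSE
  )
  for (f in colnames(W)) out[[paste0("W_", f)]] <- W[, f]
  for (f in colnames(W)) out[[paste0("heat_", f)]] <- W[, f] / heat_divisor
  for (f in colnames(W)) out[[paste0("norm_", f)]] <- norm[, f]
  attr(out, "factors") <- colnames(W)
  attr(out, "segment_bp") <- segment_bp
  attr(out, "heat_divisor") <- heat_divisor
  attr(out, "flagged_factors") <- flagged
  class(out) <- c("segment_density_table", "data.frame")
  out
}

#' Distribution of normalised per-segment peak densities
#'
#' Summarises, per factor, the spread of normalised densities over retained
#' segments: the fractions of segments above 5 and below 0.1 (the hallmarks
#' of a domain-structured, broadly spread density) plus variance and
#' quartiles. Factors whose normalisation was undefined are flagged.
#'
#' @param table A \code{\link{segment_densities}} result.
#' @return data.frame with one row per factor: \code{frac_gt5},
#'   \code{frac_lt0.1}, \code{variance}, \code{q25}, \code{median},
#'   \code{q75}, \code{flagged}.
#' @export
density_distribution <- function(table) {
  factors <- attr(table, "factors")
  flagged <- attr(table, "flagged_factors")
  keep <- !table$removed
  rows <- lapply(factors, function(f) {
    x <- table[[paste0("norm_", f)]][keep]
    if (f %in% flagged || all(is.na(x))) {
      return(data.frame(factor = f, frac_gt5 = NA_real_,
                        frac_lt0.1 = NA_real_, variance = NA_real_,
                        q25 = NA_real_, median = NA_real_, q75 = NA_real_,
                        flagged = TRUE))
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(factor = f, frac_gt5 = mean(x > 5), frac_lt0.1 = mean(x < 0.1),
               variance = stats::var(x), q25 = q[1], median = q[2],
               q75 = q[3], flagged = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise correlations of per-segment densities and gene counts
#'
#' Pearson correlation matrix over retained segments between the per-factor
#' peak densities (W columns) and the gene count, quantifying domain
#' alternation: factors occupying the same Mb-scale domains correlate
#' positively, factors occupying complementary domains negatively.
#'
#' @param table A \code{\link{segment_densities}} result with >= 2 retained
#'   segments.
#' @return Correlation matrix over factors plus \code{"genes"}; constant
#'   vectors give \code{NA} rows/columns (with a warning).
#' @export
domain_correlations <- function(table) {
  factors <- attr(table, "factors")
  keep <- !table$removed
  if (sum(keep) < 2L) stop("need at least 2 retained segments")
  m <- cbind(
    as.matrix(table[keep, paste0("W_", factors), drop = FALSE]),
    genes = table$n_genes[keep]
  )
  colnames(m) <- c(factors, "genes")
  const <- apply(m, 2, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("constant density vector(s), correlation undefined: ",
            paste(colnames(m)[const], collapse = ", "))
  }
  suppressWarnings(stats::cor(m, method = "pearson"))
}
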