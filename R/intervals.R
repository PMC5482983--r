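#' Pairwise interval overlaps between two peak sets
#'
#' Returns every (a, b) pair of peaks sharing at least 1 bp. Touching
#' intervals (half-open \code{[x, y)} followed by \code{[y, z)}) do NOT
#' overlap; this >= 1 shared-bp convention underlies every co-occupancy
#' number downstream and is therefore fixed, not configurable.
#'
#' @param a,b Peak sets on the same genome layout.
#' @return data.frame with columns \code{a_idx}, \code{b_idx} (1-based
#'   indices into the sorted sets), ordered by \code{a_idx}.
#' @export
overlap_hits <- function(a, b) {
  .check_same_genome(a, b)
  h <- GenomicRanges::findOverlaps(a, b, minoverlap = 1L, ignore.strand = TRUE)
  df <- data.frame(a_idx = S4Vectors::queryHits(h),
                   b_idx = S4Vectors::subjectHits(h))
  df[order(df$a_idx, df$b_idx), , drop = FALSE]
}

#' Base-pair-wise intersection of two peak sets
#'
#' Every output interval is contained in one interval of each input;
#' adjacent pieces arising from the same chain are merged.
#'
#' @param a,b Peak sets on the same genome layout.
#' @param label Factor label for the result (default "a^b").
#' @return A peak set \code{GRanges} of the intersections.
#' @export
intersect_regions <- function(a, b, label = NULL) {
  .check_same_genome(a, b)
  out <- GenomicRanges::intersect(a, b, ignore.strand = TRUE)
  if (is.null(label)) {
    label <- paste0(factor_label(a), "^", factor_label(b))
  }
  S4Vectors::metadata(out)$factor_label <- label
  out
}

#' Distance from points to the nearest peak
#'
#' For a point p (0-based bp) and a peak \code{[start, end)}: the distance is
#' 0 if the point lies inside the peak, otherwise
#' \code{min(|p - (end - 1)|, |start - p|)}, minimised over all peaks on the
#' point's chromosome. Chromosomes carrying no peak yield \code{Inf}.
#'
#' @param chrom,pos Chromosome names and 0-based positions of the points.
#' @param peaks A peak set on the same genome.
#' @return Numeric vector of distances in bp (\code{Inf} where undefined).
#' @export
nearest_point_distance <- function(chrom, pos, peaks) {
  genome <- .genome_of(peaks)
  pts <- .point_granges(chrom, pos, genome)
  d <- rep(Inf, length(pts))
  if (length(peaks) > 0L && length(pts) > 0L) {
    dn <- GenomicRanges::distanceToNearest(pts, peaks, ignore.strand = TRUE)
    # GRanges gap distance: adjacent = 0; we report edge-to-point distance,
    # i.e. gap + 1 for non-overlapping pairs and 0 inside.
    d[S4Vectors::queryHits(dn)] <- S4Vectors::mcols(dn)$distance + 1
    inside <- IRanges::overlapsAny(pts, peaks, minoverlap = 1L)
    d[inside] <- 0
  }
  d
}

#' Distance from each peak to the nearest annotated TSS
#'
#' Same edge-to-point distance as \code{\link{nearest_point_distance}}, with
#' roles swapped: per peak, the distance to the closest TSS point.
#'
#' @param peaks A peak set.
#' @param annotation A \code{\link{gene_annotation}} on the same genome.
#' @return Numeric vector, one distance per peak (\code{Inf} on TSS-less
#'   chromosomes).
#' @export
nearest_tss_distance <- function(peaks, annotation) {
  genome <- .genome_of(peaks)
  tss <- .point_granges(annotation$chrom, annotation$tss, genome)
  d <- rep(Inf, length(peaks))
  if (length(peaks) > 0L && length(tss) > 0L) {
    dn <- GenomicRanges::distanceToNearest(peaks, tss, ignore.strand = TRUE)
    d[S4Vectors::queryHits(dn)] <- S4Vectors::mcols(dn)$distance + 1
    inside <- IRanges::overlapsAny(peaks, tss, minoverlap = 1L)
    d[inside] <- 0
  }
  d
}

#' Inter-peak gap sizes
#'
#' The gap size between two adjacent peaks of one factor on a chromosome is
#' the distance between their midpoints. A chromosome with k peaks yields
#' max(k - 1, 0) gaps; because peaks never overlap within a set, all gaps
#' are >= 1.
#'
#' @param peaks A peak set.
#' @return Named list, one numeric vector of gaps per chromosome that
#'   carries at least one peak.
#' @export
gap_sizes <- function(peaks) {
  if (length(peaks) == 0L) return(stats::setNames(list(), character()))
  mids <- peak_midpoints(peaks)
  chr <- as.character(GenomicRanges::seqnames(peaks))
  lapply(split(mids, factor(chr, levels = unique(chr))),
         function(m) diff(sort(m)))
}
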