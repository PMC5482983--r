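#' Pairwise peak-overlap matrix
#'
#' For every ordered factor pair (a, b): the percentage of a's peaks that
#' overlap (>= 1 bp) at least one b peak. The measure is asymmetric — an
#' anchor peak overlapping several partner peaks counts once, and the two
#' directions differ whenever peak widths or counts differ — which is why
#' co-occupancy is conventionally reported as a pair of direction-dependent
#' percentages.
#'
#' @param peaksets Named list of >= 2 peak sets on one genome.
#' @return List with \code{percent} and \code{counts} matrices (rows =
#'   anchor factor), \code{n} peak counts per factor, and
#'   \code{flagged_rows} naming empty anchor sets (rows NA).
#' @export
overlap_matrix <- function(peaksets) {
  if (length(peaksets) < 2L) stop("need >= 2 factors")
  if (is.null(names(peaksets)) || any(names(peaksets) == "")) {
    names(peaksets) <- vapply(peaksets, factor_label, character(1))
  }
  fs <- names(peaksets)
  n <- vapply(peaksets, length, integer(1))
  counts <- matrix(NA_real_, length(fs), length(fs), dimnames = list(fs, fs))
  for (a in fs) for (b in fs) {
    .check_same_genome(peaksets[[a]], peaksets[[b]])
    counts[a, b] <- sum(IRanges::overlapsAny(peaksets[[a]], peaksets[[b]],
                                             minoverlap = 1L))
  }
  percent <- 100 * counts / n
  percent[n == 0, ] <- NA_real_
  list(percent = percent, counts = counts, n = n,
       flagged_rows = fs[n == 0])
}

#' Derive histone-signature regions from mark pairs
#'
#' A histone signature is the bp-wise intersection of two histone-mark
#' domain sets. The conventional regulatory-state signatures are
#' active enhancer = H3K4me1 ^ H3K27ac, poised enhancer = H3K4me1 ^
#' H3K27me3, active promoter = H3K4me3 ^ H3K27ac.
#'
#' @param mark1,mark2 Histone-mark peak sets on one genome.
#' @param label Signature label (default combines the mark labels).
#' @return A peak set \code{GRanges} of the intersections, with
#'   \code{metadata()$signature_definition} recording the mark pair.
#' @export
signature_regions <- function(mark1, mark2, label = NULL) {
  out <- intersect_regions(mark1, mark2, label = label)
  S4Vectors::metadata(out)$signature_definition <-
    paste(factor_label(mark1), "^", factor_label(mark2))
  out
}

#' Standard enhancer/promoter signatures from a set of histone marks
#'
#' @param marks Named list of histone-mark peak sets; recognised names are
#'   \code{H3K4me1}, \code{H3K27ac}, \code{H3K27me3}, \code{H3K4me3}.
#' @return Named list of signature peak sets (only signatures whose two
#'   marks are present): \code{active_enhancer}, \code{poised_enhancer},
#'   \code{active_promoter}.
#' @export
enhancer_signatures <- function(marks) {
  defs <- list(active_enhancer = c("H3K4me1", "H3K27ac"),
               poised_enhancer = c("H3K4me1", "H3K27me3"),
               active_promoter = c("H3K4me3", "H3K27ac"))
  out <- list()
  for (sig in names(defs)) {
    pair <- defs[[sig]]
    if (all(pair %in% names(marks))) {
      out[[sig]] <- signature_regions(marks[[pair[1]]], marks[[pair[2]]],
                                      label = sig)
    }
  }
  out
}

#' Fraction of peaks overlapping each histone signature
#'
#' @param peaks A non-empty peak set (e.g. one TF's peaks or a co-bound set).
#' @param signatures Named list of signature peak sets.
#' @return data.frame: \code{signature}, \code{fraction} (of peaks with
#'   >= 1 bp signature overlap), \code{n_overlap}, \code{flagged} (TRUE for
#'   an empty signature set).
#' @export
signature_overlap_fractions <- function(peaks, signatures) {
  if (length(peaks) == 0L) stop("empty peak set")
  rows <- lapply(names(signatures), function(s) {
    sig <- signatures[[s]]
    hit <- sum(IRanges::overlapsAny(peaks, sig, minoverlap = 1L))
    data.frame(signature = s, fraction = hit / length(peaks),
               n_overlap = hit, flagged = length(sig) == 0L)
  })
  do.call(rbind, rows)
}

#' Co-bound regions of a factor pair
#'
#' The peaks of the anchor factor that overlap (>= 1 bp) at least one
#' partner peak. The anchor convention is recorded in the result because
#' the count depends on which factor anchors the comparison.
#'
#' @param a,b Peak sets on one genome; \code{a} is the anchor.
#' @return A peak set \code{GRanges} (subset of \code{a});
#'   \code{metadata()$anchor_convention} documents the direction.
#' @export
co_bound <- function(a, b) {
  .check_same_genome(a, b)
  out <- a[IRanges::overlapsAny(a, b, minoverlap = 1L)]
  S4Vectors::metadata(out)$factor_label <-
    paste0(factor_label(a), "+", factor_label(b))
  S4Vectors::metadata(out)$anchor_convention <- paste0(
    "distinct ", factor_label(a), " peaks overlapping >=1 bp of ",
    factor_label(b), " peaks")
  out
}

#' Gene-level overlap of two region sets with random expectation
#'
#' Gene g enters set i when the distance from its TSS to the nearest region
#' of set i is < thresh_i. The expected chance overlap of the two gene sets
#' is n1 * n2 / N (the mean hypergeometric overlap of random subsets of
#' sizes n1 and n2 drawn from the N annotated genes).
#'
#' @param regions1,regions2 Peak sets on the annotation's genome.
#' @param thresh1,thresh2 Proximity thresholds in bp (>= 0).
#' @param annotation A non-empty \code{\link{gene_annotation}}.
#' @return List: \code{genes1}, \code{genes2} (gene-id vectors), \code{n1},
#'   \code{n2}, \code{intersection}, \code{expected}, \code{n_total}.
#' @export
gene_level_overlap <- function(regions1, thresh1, regions2, thresh2,
                               annotation) {
  N <- nrow(annotation)
  if (N == 0L) stop("empty gene annotation")
  if (thresh1 < 0 || thresh2 < 0) stop("thresholds must be >= 0")
  d1 <- nearest_point_distance(annotation$chrom, annotation$tss, regions1)
  d2 <- nearest_point_distance(annotation$chrom, annotation$tss, regions2)
  g1 <- annotation$gene_id[is.finite(d1) & d1 < thresh1]
  g2 <- annotation$gene_id[is.finite(d2) & d2 < thresh2]
  list(genes1 = g1, genes2 = g2,
       n1 = length(g1), n2 = length(g2),
       intersection = length(intersect(g1, g2)),
       expected = length(g1) * length(g2) / N,
       n_total = N)
}

#' Venn-style comparison of two peak sets
#'
#' Reports, for each anchoring direction, how many peaks overlap the other
#' set and how many are unique. The two anchored overlap counts differ
#' whenever widths differ; both are reported rather than hidden behind a
#' merged union.
#'
#' @param a,b Peak sets on one coordinate system (cross-species sets must be
#'   lifted beforehand).
#' @return List: \code{a_only}, \code{overlap_a_anchored}, \code{b_only},
#'   \code{overlap_b_anchored}, \code{pct_a_overlap}, \code{pct_b_overlap},
#'   \code{n_a}, \code{n_b}.
#' @export
cross_set_venn <- function(a, b) {
  .check_same_genome(a, b)
  oa <- sum(IRanges::overlapsAny(a, b, minoverlap = 1L))
  ob <- sum(IRanges::overlapsAny(b, a, minoverlap = 1L))
  list(a_only = length(a) - oa, overlap_a_anchored = oa,
       b_only = length(b) - ob, overlap_b_anchored = ob,
       pct_a_overlap = if (length(a)) 100 * oa / length(a) else NA_real_,
       pct_b_overlap = if (length(b)) 100 * ob / length(b) else NA_real_,
       n_a = length(a), n_b = length(b))
}
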