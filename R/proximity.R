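#' TSS-distance classes of a peak set
#'
#' Classifies each peak by the distance from its interval to the nearest
#' annotated TSS point (0 if a TSS falls inside the peak): "within" means
#' distance < threshold, "beyond" means at least threshold bp away. Peaks on
#' chromosomes without any TSS are counted as beyond and flagged.
#'
#' @param peaks A peak set.
#' @param annotation A non-empty \code{\link{gene_annotation}}.
#' @param threshold Distance threshold in bp (default 50000).
#' @return List: \code{fraction_within}, \code{fraction_beyond},
#'   \code{n_peaks}, \code{n_unreachable} (peaks on TSS-less chromosomes),
#'   \code{flagged} (TRUE for an empty peak set, fractions NA).
#' @export
tss_distance_classes <- function(peaks, annotation, threshold = 50000) {
  if (nrow(annotation) == 0L) stop("empty gene annotation")
  if (length(peaks) == 0L) {
    return(list(fraction_within = NA_real_, fraction_beyond = NA_real_,
                n_peaks = 0L, n_unreachable = 0L, flagged = TRUE))
  }
  d <- nearest_tss_distance(peaks, annotation)
  within <- is.finite(d) & d < threshold
  list(fraction_within = mean(within),
       fraction_beyond = mean(!within),
       n_peaks = length(peaks),
       n_unreachable = sum(is.infinite(d)),
       flagged = FALSE)
}

## internal: 0-based positions of targets (peak midpoints or TSS points)
.target_positions <- function(targets) {
  if (methods::is(targets, "GRanges")) {
    list(chrom = as.character(GenomicRanges::seqnames(targets)),
         pos = peak_midpoints(targets),
         n = length(targets))
  } else if (inherits(targets, "gene_annotation")) {
    list(chrom = targets$chrom, pos = targets$tss, n = nrow(targets))
  } else {
    stop("'targets' must be a peak set (GRanges) or a gene_annotation")
  }
}

#' Anchor-offset aggregation profile
#'
#' Bins the signed offsets of target positions (peak midpoints, or TSS
#' points when a gene annotation is supplied) relative to anchor-peak
#' midpoints: for every (anchor, target) pair with offset
#' \code{o = target_pos - anchor_midpoint} and \code{-window <= o < window},
#' the bin containing o is incremented. Positive offsets lie at higher
#' coordinates than the anchor; peaks are unstranded.
#'
#' Normalisation: \code{per_target} divides counts by the number of targets
#' (fraction of target features per bin), \code{per_anchor} by the number of
#' anchors (local target density per anchor). The analytic random baseline is
#' \code{n_other * bin_width / G} with \code{n_other} the size of the
#' non-normalising set and G the genome size: the level an independent,
#' uniformly placed pair of sets converges to far from the anchor.
#'
#' @param anchors A non-empty peak set (midpoints anchor the profile).
#' @param targets A non-empty peak set or \code{gene_annotation}.
#' @param bin_width Bin width in bp (default 100).
#' @param window Half-window in bp (default 5000); must be a positive
#'   multiple of \code{bin_width}.
#' @param mode \code{"per_target"} (default) or \code{"per_anchor"}.
#' @return data.frame of class \code{aggregation_profile}: one row per bin
#'   with \code{offset_low}, \code{offset_high}, \code{count},
#'   \code{normalized}, \code{baseline}; attributes record mode, counts,
#'   window and genome size.
#' @export
aggregate_profile <- function(anchors, targets, bin_width = 100,
                              window = 5000,
                              mode = c("per_target", "per_anchor")) {
  mode <- match.arg(mode)
  if (bin_width <= 0) stop("bin_width must be positive")
  if (window <= 0 || window %% bin_width != 0) {
    stop("window must be a positive multiple of bin_width")
  }
  if (length(anchors) == 0L) stop("empty anchor set")
  genome <- .genome_of(anchors)
  tg <- .target_positions(targets)
  if (tg$n == 0L) stop("empty target set")
  if (methods::is(targets, "GRanges")) .check_same_genome(anchors, targets)
  lens <- .chrom_lengths(genome)
  amid <- peak_midpoints(anchors)
  achr <- as.character(GenomicRanges::seqnames(anchors))
  win <- GenomicRanges::GRanges(
    achr,
    IRanges::IRanges(start = pmax(amid - window, 0) + 1,
                     end = pmin(amid + window, lens[achr])),
    seqinfo = genome
  )
  tpts <- .point_granges(tg$chrom, tg$pos, genome)
  h <- GenomicRanges::findOverlaps(tpts, win, minoverlap = 1L,
                                   ignore.strand = TRUE)
  o <- tg$pos[S4Vectors::queryHits(h)] - amid[S4Vectors::subjectHits(h)]
  o <- o[o >= -window & o < window]
  n_bins <- as.integer(2 * window / bin_width)
  counts <- tabulate(floor((o + window) / bin_width) + 1L, nbins = n_bins)
  offset_low <- seq(-window, window - bin_width, by = bin_width)
  n_norm <- if (mode == "per_target") tg$n else length(anchors)
  n_other <- if (mode == "per_target") length(anchors) else tg$n
  out <- data.frame(offset_low = offset_low,
                    offset_high = offset_low + bin_width,
                    count = as.integer(counts),
                    normalized = counts / n_norm,
                    baseline = n_other * bin_width / genome_size(genome))
  attr(out, "mode") <- mode
  attr(out, "n_anchor") <- length(anchors)
  attr(out, "n_target") <- tg$n
  attr(out, "bin_width") <- bin_width
  attr(out, "window") <- window
  attr(out, "genome_size") <- genome_size(genome)
  class(out) <- c("aggregation_profile", "data.frame")
  out
}

#' Central depletion / enrichment of an aggregation profile
#'
#' The normalised profile value at the anchor position (averaged over the two
#' bins adjacent to offset 0) divided by the random baseline. A ratio < 1
#' indicates central depletion (mutually exclusive binding), > 1 proximal
#' co-occurrence.
#'
#' @param profile An \code{\link{aggregate_profile}} result.
#' @return List: \code{central_value}, \code{baseline}, \code{ratio},
#'   \code{interpretation} ("depletion", "enrichment" or "neutral").
#' @export
depletion_enrichment_summary <- function(profile) {
  bw <- attr(profile, "bin_width")
  central <- profile$normalized[profile$offset_low %in% c(-bw, 0)]
  baseline <- profile$baseline[1]
  if (baseline == 0) stop("zero baseline: ratio undefined")
  cv <- mean(central)
  ratio <- cv / baseline
  list(central_value = cv, baseline = baseline, ratio = ratio,
       interpretation = if (ratio < 1) "depletion"
                        else if (ratio > 1) "enrichment" else "neutral")
}
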