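#' Peak-width classes
#'
#' Classifies peak widths into the standard interpretive classes: widths
#' below ~2x the chromatin fragment length (operationally < 500 bp with the
#' default 150 bp fragments) indicate singlet binding events, while wide
#' "peak ranges" (> 2000 bp) indicate unresolved clusters of binding sites.
#' Bins follow the <500 / <1000 / >2000 phrasing: [0, 500), [500, 1000),
#' [1000, 2000], (2000, Inf).
#'
#' @param peaks A peak set.
#' @param bins Increasing width thresholds (default \code{c(500, 1000, 2000)}).
#' @param fragment_length Library fragment length L in bp, recorded for
#'   interpretation (singlet peaks have width ~ 2L); default 150.
#' @return data.frame with one row per class: \code{class}, \code{count},
#'   \code{fraction}; attributes \code{factor}, \code{fragment_length},
#'   \code{flagged} (TRUE for an empty peak set, whose fractions are NA).
#' @export
width_classes <- function(peaks, bins = c(500, 1000, 2000),
                          fragment_length = 150) {
  if (length(bins) != 3L || any(diff(bins) <= 0)) {
    stop("'bins' must be 3 strictly increasing width thresholds")
  }
  w <- peak_widths(peaks)
  counts <- c(
    sum(w < bins[1]),
    sum(w >= bins[1] & w < bins[2]),
    sum(w >= bins[2] & w <= bins[3]),
    sum(w > bins[3])
  )
  labels <- c(paste0("lt", bins[1]),
              paste0(bins[1], "to", bins[2]),
              paste0(bins[2], "to", bins[3]),
              paste0("gt", bins[3]))
  frac <- if (length(w) > 0L) counts / length(w) else rep(NA_real_, 4L)
  out <- data.frame(class = labels, count = as.integer(counts),
                    fraction = frac)
  attr(out, "factor") <- factor_label(peaks)
  attr(out, "fragment_length") <- fragment_length
  attr(out, "flagged") <- length(w) == 0L
  out
}

#' Gap-size profile with a random-occurrence null
#'
#' Pools the midpoint-to-midpoint gaps of adjacent peaks across chromosomes
#' into a log10 histogram (0.1-decade bins) and compares the modal gap with
#' the gap expected under random (uniform) placement. For n peaks placed
#' uniformly on a chromosome of length G, inter-peak spacings are
#' approximately exponential with mean G/n, and the modal bin of the
#' log-spacing histogram sits at ~ G/n; the null modal gap is therefore the
#' gap-count-weighted geometric mean of per-chromosome G/n. The clustering
#' ratio (null / observed modal gap) is ~ 1 for dispersed factors and
#' >> 1 (an order of magnitude or more) for factors whose binding sites
#' cluster densely.
#'
#' The observed modal gap is the geometric mean of the gaps falling in the
#' modal histogram bin (ties between bins broken toward the smaller gap),
#' which keeps single-gap inputs exact rather than snapped to a bin centre.
#'
#' @param peaks A peak set with >= 2 peaks on at least one chromosome.
#' @param genome A \code{Seqinfo} (defaults to the peak set's own layout).
#' @param bin_decades Histogram bin width in log10 units (default 0.1).
#' @return List with \code{histogram} (data.frame: \code{bin_low},
#'   \code{bin_high}, \code{count}), \code{modal_gap},
#'   \code{null_modal_gap}, \code{clustering_ratio}, \code{n_gaps},
#'   \code{factor}.
#' @export
gap_profile <- function(peaks, genome = NULL, bin_decades = 0.1) {
  if (is.null(genome)) genome <- .genome_of(peaks)
  .check_same_genome(peaks, genome)
  gaps_by_chrom <- gap_sizes(peaks)
  gaps <- unlist(gaps_by_chrom, use.names = FALSE)
  if (length(gaps) == 0L) stop("no gaps: need >= 2 peaks on some chromosome")
  lg <- log10(gaps)
  idx <- floor(lg / bin_decades)
  rng <- seq(min(idx), max(idx))
  counts <- as.integer(table(factor(idx, levels = rng)))
  hist <- data.frame(bin_low = 10^(rng * bin_decades),
                     bin_high = 10^((rng + 1) * bin_decades),
                     count = counts)
  modal_bin <- rng[which.max(counts)]  # which.max: first max = smaller gap
  in_modal <- idx == modal_bin
  modal_gap <- exp(mean(log(gaps[in_modal])))
  # per-chromosome null G/n, weighted by that chromosome's gap count
  lens <- .chrom_lengths(genome)
  n_by_chrom <- lengths(gaps_by_chrom) + 1L
  wts <- lengths(gaps_by_chrom)
  use <- wts > 0L
  null_log <- sum(wts[use] * log(lens[names(gaps_by_chrom)[use]] /
                                   n_by_chrom[use])) / sum(wts[use])
  null_modal <- exp(null_log)
  list(histogram = hist,
       modal_gap = modal_gap,
       null_modal_gap = null_modal,
       clustering_ratio = null_modal / modal_gap,
       n_gaps = length(gaps),
       factor = factor_label(peaks))
}
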