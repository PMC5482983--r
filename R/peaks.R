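#' Construct a validated peak set
#'
#' A peak set is the universal currency of the pipeline: the called peaks of
#' one transcription factor or histone mark on one genome, held as a sorted
#' \link[GenomicRanges]{GRanges}. Coordinates are supplied in the BED
#' convention (0-based half-open); internally the object is an ordinary
#' 1-based GRanges so that all Bioconductor interval machinery applies.
#'
#' Peaks within one set may touch but must not overlap: peak callers emit
#' non-overlapping peaks, and an overlap almost always indicates a corrupted
#' or doubly-concatenated file, so it is rejected rather than merged.
#'
#' @param chrom Character vector of chromosome names.
#' @param start 0-based inclusive start coordinates.
#' @param end 0-based exclusive end coordinates (end > start).
#' @param genome A \code{Seqinfo} from \code{\link{genome_layout}}.
#' @param factor_label Label of the factor or mark (stored in metadata).
#' @param name,score Optional per-peak name / score columns.
#' @return A sorted \code{GRanges} with \code{metadata()$factor_label} set.
#' @examples
#' g <- genome_layout("chr1", 1e6)
#' ps <- peak_set("chr1", c(100, 500), c(300, 900), g, "ZIC2")
#' peak_widths(ps)
#' @export
peak_set <- function(chrom, start, end, genome,
                     factor_label = "peaks", name = NULL, score = NULL) {
  if (!methods::is(genome, "Seqinfo")) stop("'genome' must be a Seqinfo")
  n <- length(start)
  if (length(end) != n) stop("'start' and 'end' must have equal length")
  if (length(chrom) == 1L && n > 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n) {
    stop("'chrom' must have length 1 or length(start)")
  }
  if (n == 0L) {
    gr <- GenomicRanges::GRanges(seqinfo = genome)
    S4Vectors::metadata(gr)$factor_label <- factor_label
    return(gr)
  }
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  lens <- .chrom_lengths(genome)
  bad_chrom <- !(chrom %in% names(lens))
  if (any(bad_chrom)) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[bad_chrom]), collapse = ", "))
  }
  if (any(start < 0)) stop("interval start < 0")
  if (any(end <= start)) stop("interval with end <= start")
  if (any(end > lens[chrom])) {
    stop("interval extends past its chromosome length")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    seqinfo = genome
  )
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- as.character(name)
  if (!is.null(score)) S4Vectors::mcols(gr)$score <- as.numeric(score)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  self <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE, minoverlap = 1L)
  if (length(self) > 0L) {
    stop("peak set '", factor_label, "' contains ", length(self),
         " overlapping interval pair(s) within the same set")
  }
  S4Vectors::metadata(gr)$factor_label <- factor_label
  gr
}

#' Factor label of a peak set
#' @param peaks A peak set \code{GRanges}.
#' @return Character label (or \code{"peaks"} if unset).
#' @export
factor_label <- function(peaks) {
  lbl <- S4Vectors::metadata(peaks)$factor_label
  if (is.null(lbl)) "peaks" else lbl
}

#' Peak coordinate accessors (0-based half-open)
#'
#' \code{peak_starts}/\code{peak_ends} return 0-based half-open coordinates;
#' \code{peak_widths} the widths in bp; \code{peak_midpoints} the integer
#' midpoints \code{floor((start + end) / 2)} on the 0-based grid, the anchor
#' positions used by gap-size and aggregation analyses.
#'
#' @param peaks A peak set \code{GRanges}.
#' @return Numeric vector, one entry per peak.
#' @export
peak_starts <- function(peaks) GenomicRanges::start(peaks) - 1

#' @rdname peak_starts
#' @export
peak_ends <- function(peaks) as.numeric(GenomicRanges::end(peaks))

#' @rdname peak_starts
#' @export
peak_widths <- function(peaks) as.numeric(GenomicRanges::width(peaks))

#' @rdname peak_starts
#' @export
peak_midpoints <- function(peaks) {
  floor((peak_starts(peaks) + peak_ends(peaks)) / 2)
}

## internal: width-1 GRanges at 0-based positions
.point_granges <- function(chrom, pos, genome) {
  lens <- .chrom_lengths(genome)
  bad <- !(as.character(chrom) %in% names(lens))
  if (any(bad)) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[bad]), collapse = ", "))
  }
  if (any(pos < 0) || any(pos >= lens[as.character(chrom)])) {
    stop("point position outside chromosome bounds")
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, pos + 1),
                         seqinfo = genome)
}
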