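#' Define a genome layout
#'
#' A genome layout is the ordered set of chromosome names and lengths against
#' which every peak set, gene annotation and analysis window is validated.
#' It is represented as a Bioconductor \link[GenomeInfoDb]{Seqinfo} object.
#'
#' @param chroms Character vector of unique chromosome names, taken verbatim
#'   (no "chr" normalisation is ever applied; a naming mismatch between files
#'   is an error, not a silent empty join).
#' @param lengths Integer vector of chromosome lengths in bp (all >= 1).
#' @return A \code{Seqinfo} object.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2e7, 2e7))
#' @export
genome_layout <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) == 0L) stop("genome layout needs at least one chromosome")
  if (length(chroms) != length(lengths)) {
    stop("'chroms' and 'lengths' must have the same length")
  }
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths < 1)) {
    stop("chromosome lengths must be >= 1")
  }
  GenomeInfoDb::Seqinfo(seqnames = chroms, seqlengths = as.integer(lengths))
}

#' Total genome size
#'
#' @param genome A \code{Seqinfo} from \code{\link{genome_layout}}.
#' @return Total length G in bp (numeric).
#' @export
genome_size <- function(genome) {
  sum(as.numeric(GenomeInfoDb::seqlengths(genome)))
}

## internal: named lengths vector
.chrom_lengths <- function(genome) {
  stats::setNames(as.numeric(GenomeInfoDb::seqlengths(genome)),
                  GenomeInfoDb::seqnames(genome))
}

## internal: check two objects share one genome layout
.check_same_genome <- function(a, b) {
  la <- .chrom_lengths(.genome_of(a))
  lb <- .chrom_lengths(.genome_of(b))
  if (!identical(la, lb)) {
    stop("genome layouts differ between the two inputs")
  }
  invisible(TRUE)
}

.genome_of <- function(x) {
  if (methods::is(x, "GRanges")) GenomeInfoDb::seqinfo(x)
  else if (methods::is(x, "Seqinfo")) x
  else stop("cannot extract a genome layout from an object of class ",
            class(x)[1])
}
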