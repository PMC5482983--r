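#' Read a BED file of called peaks
#'
#' Reads a BED3+ file (tab-separated, 0-based half-open) into a validated
#' \code{\link{peak_set}}. Comment (\code{#}), \code{track} and \code{browser}
#' lines are skipped and counted; every other line must parse, so the reader
#' never silently drops data.
#'
#' @param path Path to the BED file.
#' @param genome A \code{Seqinfo} from \code{\link{genome_layout}}.
#' @param factor_label Label for the resulting peak set; defaults to the file
#'   base name.
#' @return A peak set \code{GRanges}; \code{metadata()$n_skipped} records the
#'   number of comment/track lines skipped.
#' @export
read_bed <- function(path, genome, factor_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(factor_label)) {
    factor_label <- sub("\\.bed$", "", basename(path))
  }
  lines <- readLines(path)
  is_skip <- grepl("^#", lines) | grepl("^track\\b", lines) |
    grepl("^browser\\b", lines) | lines == ""
  data_idx <- which(!is_skip)
  if (length(data_idx) == 0L) {
    ps <- peak_set(character(), numeric(), numeric(), genome, factor_label)
    S4Vectors::metadata(ps)$n_skipped <- sum(is_skip)
    return(ps)
  }
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- data_idx[which(nf < 3L)[1]]
    stop("malformed BED line ", bad, ": fewer than 3 tab-separated fields")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- data_idx[which(is.na(start) | is.na(end))[1]]
    stop("malformed BED line ", bad, ": non-numeric start/end")
  }
  if (any(end <= start)) {
    bad <- data_idx[which(end <= start)[1]]
    stop("malformed BED line ", bad, ": start >= end")
  }
  name <- if (all(nf >= 4L)) vapply(fields, `[[`, character(1), 4L) else NULL
  score <- if (all(nf >= 5L)) {
    suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5L)))
  } else NULL
  ps <- peak_set(chrom, start, end, genome, factor_label,
                 name = name, score = score)
  S4Vectors::metadata(ps)$n_skipped <- sum(is_skip)
  ps
}

#' Write a peak set to BED
#'
#' Writes sorted BED (tab-separated, 0-based half-open). Repeated writes of
#' the same set are bit-identical. Optional \code{name}/\code{score} columns
#' are emitted as BED4/BED5 when present.
#'
#' @param peaks A peak set \code{GRanges}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(peaks, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = format(peak_starts(peaks), scientific = FALSE, trim = TRUE),
    end = format(peak_ends(peaks), scientific = FALSE, trim = TRUE)
  )
  mc <- S4Vectors::mcols(peaks)
  if (!is.null(mc$name)) {
    dt$name <- as.character(mc$name)
    if (!is.null(mc$score)) dt$score <- mc$score
  }
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct / validate a gene annotation
#'
#' A gene annotation holds, per gene, a unique identifier, the chromosome,
#' the single-bp TSS coordinate (0-based), the strand, and a flag marking
#' transcription-factor genes (used for the TF-gene expression stratum).
#' If gene extents rather than TSS points are at hand, the TSS convention is:
#' strand \code{+} uses the interval start, strand \code{-} the last base
#' (\code{end - 1}).
#'
#' @param df data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{tss}, \code{strand}, \code{is_tf}.
#' @param genome A \code{Seqinfo}; TSS positions are checked against it.
#' @return The validated data.frame (ordered by chrom, tss) of class
#'   \code{gene_annotation}.
#' @export
gene_annotation <- function(df, genome) {
  need <- c("gene_id", "chrom", "tss", "strand", "is_tf")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  df$tss <- as.numeric(df$tss)
  df$strand <- as.character(df$strand)
  df$is_tf <- as.logical(as.integer(as.logical(df$is_tf)))
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in gene table: ",
         df$gene_id[anyDuplicated(df$gene_id)])
  }
  lens <- .chrom_lengths(genome)
  bad <- !(df$chrom %in% names(lens))
  if (any(bad)) stop("gene table references unknown chromosome(s): ",
                     paste(unique(df$chrom[bad]), collapse = ", "))
  if (any(df$tss < 0) || any(df$tss >= lens[df$chrom])) {
    stop("TSS position outside chromosome bounds")
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- df[order(df$chrom, df$tss, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "genome") <- genome
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read / write a gene annotation table
#'
#' TSV with header columns \code{gene_id}, \code{chrom}, \code{tss},
#' \code{strand}, \code{is_tf} (0/1).
#'
#' @param path File path.
#' @param genome A \code{Seqinfo}.
#' @return \code{read_gene_table}: a \code{\link{gene_annotation}}.
#' @export
read_gene_table <- function(path, genome) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, colClasses = list(
                            character = c("gene_id", "chrom", "strand")))
  gene_annotation(df, genome)
}

#' @rdname read_gene_table
#' @param annotation A \code{gene_annotation}.
#' @export
write_gene_table <- function(annotation, path) {
  out <- as.data.frame(annotation)
  out$is_tf <- as.integer(out$is_tf)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Construct / validate an expression table
#'
#' Per-gene linear-scale expression in a reference condition plus one or more
#' comparison conditions. All values must be >= 0; gene ids must be unique.
#'
#' @param df data.frame with columns \code{gene_id}, \code{reference}, then
#'   one column per comparison condition.
#' @return Validated data.frame of class \code{expression_table}; the
#'   comparison condition names are in \code{attr(, "conditions")}.
#' @export
expression_table <- function(df) {
  if (!all(c("gene_id", "reference") %in% names(df))) {
    stop("expression table needs 'gene_id' and 'reference' columns")
  }
  df <- as.data.frame(df)
  df$gene_id <- as.character(df$gene_id)
  conds <- setdiff(names(df), c("gene_id", "reference"))
  if (length(conds) == 0L) stop("expression table has no comparison condition")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in expression table")
  vals <- as.matrix(df[c("reference", conds)])
  if (!is.numeric(vals) || anyNA(vals)) stop("non-numeric expression values")
  if (any(vals < 0)) stop("negative expression values")
  rownames(df) <- NULL
  attr(df, "conditions") <- conds
  class(df) <- c("expression_table", "data.frame")
  df
}

#' Read / write an expression table
#'
#' TSV with header: \code{gene_id}, \code{reference}, then one column per
#' comparison condition. \code{ref_cols} may name several replicate reference
#' columns, which are combined by arithmetic mean into \code{reference}.
#'
#' @param path File path.
#' @param ref_cols Column name(s) holding the reference condition.
#' @return \code{read_expression_table}: an \code{\link{expression_table}}.
#' @export
read_expression_table <- function(path, ref_cols = "reference") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  miss <- setdiff(c("gene_id", ref_cols), names(df))
  if (length(miss)) stop("expression table missing column(s): ",
                         paste(miss, collapse = ", "))
  ref <- rowMeans(as.matrix(df[, ref_cols, drop = FALSE]))
  out <- data.frame(gene_id = df$gene_id, reference = ref,
                    df[setdiff(names(df), c("gene_id", ref_cols))],
                    check.names = FALSE)
  expression_table(out)
}

#' @rdname read_expression_table
#' @param expr An \code{expression_table}.
#' @export
write_expression_table <- function(expr, path) {
  data.table::fwrite(as.data.frame(expr), path, sep = "\t", quote = FALSE)
  invisible(path)
}
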