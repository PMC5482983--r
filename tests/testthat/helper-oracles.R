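# Brute-force oracles and random-instance builders, independent of the
# package's interval machinery: all arithmetic is on plain 0-based
# half-open data.frames.

toy_genome <- function(L = 1e5, chroms = "chr1") {
  genome_layout(chroms, rep(L, length(chroms)))
}

# n random non-overlapping intervals on [0, L): 2n distinct sorted
# breakpoints paired consecutively (touching allowed, overlap impossible)
rand_intervals <- function(n, L) {
  if (n == 0L) return(data.frame(start = numeric(), end = numeric()))
  pts <- sort(sample.int(L, 2L * n))
  data.frame(start = pts[seq(1, 2 * n, 2)] - 1, end = pts[seq(2, 2 * n, 2)])
}

rand_peak_set <- function(n, genome, label = "X") {
  lens <- setNames(as.numeric(GenomeInfoDb::seqlengths(genome)),
                   GenomeInfoDb::seqnames(genome))
  per <- table(factor(sample(names(lens), n, replace = TRUE),
                      levels = names(lens)))
  dfs <- lapply(names(lens), function(ch) {
    iv <- rand_intervals(per[[ch]], lens[[ch]])
    if (nrow(iv)) cbind(chrom = ch, iv) else NULL
  })
  df <- do.call(rbind, dfs)
  peak_set(df$chrom, df$start, df$end, genome, label)
}

peaks_as_df <- function(ps) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(ps)),
             start = peak_starts(ps), end = peak_ends(ps))
}

# all-pairs overlap scan (>= 1 shared bp, half-open)
bf_overlap_pairs <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(a_idx = integer(), b_idx = integer()))
  }
  same <- outer(a$chrom, b$chrom, "==")
  ov <- outer(a$start, b$start, pmax) < outer(a$end, b$end, pmin)
  idx <- which(same & ov, arr.ind = TRUE)
  out <- data.frame(a_idx = as.integer(idx[, 1]),
                    b_idx = as.integer(idx[, 2]))
  out[order(out$a_idx, out$b_idx), , drop = FALSE]
}

# bitmap intersection width on a toy genome
bf_intersect_width <- function(a, b, genome) {
  lens <- setNames(as.numeric(GenomeInfoDb::seqlengths(genome)),
                   GenomeInfoDb::seqnames(genome))
  total <- 0
  for (ch in names(lens)) {
    cov_a <- logical(lens[[ch]])
    cov_b <- logical(lens[[ch]])
    ai <- a[a$chrom == ch, , drop = FALSE]
    bi <- b[b$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(ai))) cov_a[(ai$start[i] + 1):ai$end[i]] <- TRUE
    for (i in seq_len(nrow(bi))) cov_b[(bi$start[i] + 1):bi$end[i]] <- TRUE
    total <- total + sum(cov_a & cov_b)
  }
  total
}

# min over all peaks of the point-to-interval distance
bf_nearest <- function(chrom, pos, peaks) {
  vapply(seq_along(pos), function(i) {
    p <- peaks[peaks$chrom == chrom[i], , drop = FALSE]
    if (nrow(p) == 0L) return(Inf)
    d <- ifelse(pos[i] >= p$start & pos[i] < p$end, 0,
                pmin(abs(pos[i] - (p$end - 1)), abs(p$start - pos[i])))
    min(d)
  }, numeric(1))
}

bf_gaps <- function(peaks) {
  mids <- floor((peaks$start + peaks$end) / 2)
  lapply(split(mids, peaks$chrom), function(m) diff(sort(m)))
}

# small uniform landscape config used by several calibration tests
uniform_config <- function(seed, n_peaks = 2000, L = 1e8, chroms = "chr1",
                           width_median = 400) {
  landscape_config(
    seed = seed,
    genome = list(chroms = chroms, lengths = rep(L, length(chroms))),
    factors = list(U = list(n_peaks = n_peaks, width_median = width_median,
                            width_sigma = 0.5, placement = "uniform")),
    co_binding = list(),
    genes = list(n_genes = 10, rich_poor_ratio = 1, tf_fraction = 0),
    signature = list(pair = c("U", "U"), q = 0,
                     pad = c(H3K4me1 = 0, H3K27ac = 0),
                     n_background = 10, background_width_median = 1000)
  )
}
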