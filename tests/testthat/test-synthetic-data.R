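small_config <- function(seed = 1, ...) {
  landscape_config(
    seed = seed,
    genome = list(chroms = c("chr1", "chr2"), lengths = c(5e6, 5e6)),
    factors = list(
      A = list(n_peaks = 300, width_median = 400, width_sigma = 0.5,
               placement = "uniform"),
      B = list(n_peaks = 300, width_median = 500, width_sigma = 0.5,
               placement = "clustered-rich", children_mean = 5,
               child_spread = 2000)
    ),
    co_binding = list(list(a = "A", b = "B", p = 0.3)),
    genes = list(n_genes = 400, rich_poor_ratio = 4, tf_fraction = 0.1),
    signature = list(pair = c("B", "A"), q = 0.4,
                     pad = c(H3K4me1 = 0, H3K27ac = 0),
                     n_background = 40, background_width_median = 1000),
    ...
  )
}

test_that("generation is byte-identical for equal (config, seed)", {
  land1 <- generate_landscape(small_config(seed = 5))
  land2 <- generate_landscape(small_config(seed = 5))
  for (f in names(land1$peaks)) {
    f1 <- tempfile(); f2 <- tempfile()
    write_bed(land1$peaks[[f]], f1); write_bed(land2$peaks[[f]], f2)
    expect_identical(readLines(f1), readLines(f2))
    unlink(c(f1, f2))
  }
  expect_identical(as.data.frame(land1$annotation),
                   as.data.frame(land2$annotation))
  land3 <- generate_landscape(small_config(seed = 6))
  expect_false(identical(peaks_as_df(land1$peaks$A),
                         peaks_as_df(land3$peaks$A)))
})

test_that("peak counts are conserved and sets are valid", {
  land <- generate_landscape(small_config(seed = 3))
  expect_equal(vapply(land$peaks, length, integer(1)), c(A = 300L, B = 300L))
  for (f in names(land$peaks)) {
    ps <- land$peaks[[f]]
    # re-validating through the constructor proves sortedness/no-overlap
    expect_silent(peak_set(as.character(GenomicRanges::seqnames(ps)),
                           peak_starts(ps), peak_ends(ps),
                           land$genome, f))
  }
})

test_that("n_peaks = 0 factors give empty sets while genes are still placed", {
  cfg <- small_config(seed = 4)
  cfg$factors$A$n_peaks <- 0
  cfg$factors$B$n_peaks <- 0
  cfg$co_binding <- list()
  land <- generate_landscape(cfg)
  expect_length(land$peaks$A, 0L)
  expect_length(land$peaks$B, 0L)
  expect_equal(nrow(land$annotation), 400L)
})

test_that("infeasible packing raises a capacity error, never silent truncation", {
  cfg <- landscape_config(
    seed = 1,
    genome = list(chroms = "chr1", lengths = 1e4),
    domain_period = 1e4,
    factors = list(A = list(n_peaks = 500, width_median = 400,
                            width_sigma = 0.3, placement = "uniform")),
    co_binding = list(),
    genes = list(n_genes = 5, rich_poor_ratio = 1, tf_fraction = 0),
    signature = list(pair = c("A", "A"), q = 0,
                     pad = c(H3K4me1 = 0, H3K27ac = 0),
                     n_background = 5, background_width_median = 1000)
  )
  expect_error(generate_landscape(cfg), "capacity")
})

test_that("planted co-binding fraction is recovered within 3 binomial SEs", {
  cfg <- landscape_config(
    seed = 8,
    genome = list(chroms = "chr1", lengths = 2e8),
    factors = list(
      A = list(n_peaks = 2000, width_median = 300, width_sigma = 0.5,
               placement = "uniform"),
      B = list(n_peaks = 2000, width_median = 300, width_sigma = 0.5,
               placement = "uniform")),
    co_binding = list(list(a = "A", b = "B", p = 0.3)),
    genes = list(n_genes = 10, rich_poor_ratio = 1, tf_fraction = 0),
    signature = list(pair = c("A", "B"), q = 0,
                     pad = c(H3K4me1 = 0, H3K27ac = 0),
                     n_background = 10, background_width_median = 1000)
  )
  land <- generate_landscape(cfg)
  om <- overlap_matrix(land$peaks)
  se <- sqrt(0.3 * 0.7 / 2000)
  expect_lt(abs(om$percent["A", "B"] / 100 - 0.3), 3 * se)
})

test_that("domain blocks alternate rich/poor deterministically", {
  g <- genome_layout("chr1", 3.5e6)
  b <- domain_blocks(g, 1e6)
  expect_equal(b$type, c("rich", "poor", "rich", "poor"))
  expect_equal(b$end[4], 3.5e6)  # trailing partial block kept
  expect_equal(b$start, c(0, 1e6, 2e6, 3e6))
})

test_that("gene placement respects the rich:poor density ratio", {
  land <- generate_landscape(small_config(seed = 12))
  blocks <- domain_blocks(land$genome, 1e6)
  rich <- blocks[blocks$type == "rich", ]
  in_rich <- vapply(seq_len(nrow(land$annotation)), function(i) {
    any(rich$chrom == land$annotation$chrom[i] &
          land$annotation$tss[i] >= rich$start &
          land$annotation$tss[i] < rich$end)
  }, logical(1))
  # expected 4/5 in rich; 3 binomial SEs at n = 400
  expect_lt(abs(mean(in_rich) - 0.8), 3 * sqrt(0.8 * 0.2 / 400))
})

test_that("invalid configurations are rejected", {
  expect_error(small_config(seed = 1, domain_period = 6e6), "domain_period")
  cfg <- small_config(seed = 1)
  cfg$factors$A$placement <- "ring"
  expect_error(generate_landscape(cfg), "placement")
  cfg2 <- small_config(seed = 1)
  cfg2$expression$p_down <- c(background = 0.8, proximal = 0.8,
                              proximal_tf = 0.8)
  expect_error(generate_landscape(cfg2), "probabilities")
  cfg3 <- small_config(seed = 1)
  cfg3$co_binding[[1]]$p <- 1.2
  expect_error(generate_landscape(cfg3), "co-binding")
})
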