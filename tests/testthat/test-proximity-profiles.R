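test_that("TSS distance classes: within/beyond threshold and flags", {
  g <- toy_genome(1e5)
  ann <- gene_annotation(data.frame(gene_id = "g1", chrom = "chr1", tss = 1000,
                                    strand = "+", is_tf = FALSE), g)
  inside <- peak_set("chr1", 900, 1100, g, "p")
  expect_equal(tss_distance_classes(inside, ann)$fraction_within, 1)
  ann0 <- gene_annotation(data.frame(gene_id = "g1", chrom = "chr1", tss = 0,
                                     strand = "+", is_tf = FALSE), g)
  far <- peak_set("chr1", 51000, 51400, g, "p")
  t <- tss_distance_classes(far, ann0)
  expect_equal(t$fraction_beyond, 1)
  expect_equal(t$fraction_within + t$fraction_beyond, 1)
  empty <- peak_set(character(), numeric(), numeric(), g, "p")
  expect_true(tss_distance_classes(empty, ann)$flagged)
})

test_that("TSS distance fractions equal brute-force enumeration", {
  g <- toy_genome(1e5)
  withr::local_seed(23)
  ps <- rand_peak_set(60, g, "p")
  tsspos <- sample(0:(1e5 - 1), 40)
  ann <- gene_annotation(data.frame(gene_id = sprintf("g%02d", 1:40),
                                    chrom = "chr1", tss = tsspos,
                                    strand = "+", is_tf = FALSE), g)
  t <- tss_distance_classes(ps, ann, threshold = 5000)
  pdf <- peaks_as_df(ps)
  bf <- vapply(seq_len(nrow(pdf)), function(i) {
    min(bf_nearest(rep("chr1", 40), ann$tss,
                   pdf[i, , drop = FALSE]))  # distance peak<->points symmetric
  }, numeric(1))
  expect_equal(t$fraction_within, mean(bf < 5000))
})

test_that("aggregation profile: single pair lands in the correct bin", {
  g <- toy_genome(1e5)
  anchor <- peak_set("chr1", 9900, 10100, g, "a")  # midpoint 10000
  target <- peak_set("chr1", 10000, 10100, g, "b") # midpoint 10050
  pr <- aggregate_profile(anchor, target)
  expect_equal(pr$normalized[pr$offset_low == 0], 1)
  expect_equal(sum(pr$count), 1L)
  far <- peak_set("chr1", 90000, 90100, g, "b")
  expect_equal(sum(aggregate_profile(anchor, far)$count), 0L)
  expect_error(aggregate_profile(anchor, target, bin_width = 0), "positive")
  expect_error(aggregate_profile(anchor, target, window = 5050), "multiple")
})

test_that("bin counts sum to the number of in-window pairs (all-pairs oracle)", {
  g <- toy_genome(1e5)
  withr::local_seed(31)
  a <- rand_peak_set(80, g, "a")
  b <- rand_peak_set(120, g, "b")
  W <- 5000
  pr <- aggregate_profile(a, b, window = W)
  amid <- peak_midpoints(a); bmid <- peak_midpoints(b)
  n_pairs <- sum(vapply(amid, function(m) {
    sum(bmid - m >= -W & bmid - m < W)
  }, numeric(1)))
  expect_equal(sum(pr$count), n_pairs)
  # per_anchor mode rescales the same counts by the anchor total
  pa <- aggregate_profile(a, b, window = W, mode = "per_anchor")
  expect_equal(pa$count, pr$count)
  expect_equal(pa$normalized * length(a), pr$normalized * length(b))
})

test_that("profiles are invariant under genome-wide translation", {
  g <- toy_genome(1e5)
  g2 <- toy_genome(2e5)
  withr::local_seed(37)
  a <- rand_peak_set(50, g, "a")
  b <- rand_peak_set(50, g, "b")
  shift <- 40000
  a2 <- peak_set(rep("chr1", length(a)), peak_starts(a) + shift,
                 peak_ends(a) + shift, g2, "a")
  b2 <- peak_set(rep("chr1", length(b)), peak_starts(b) + shift,
                 peak_ends(b) + shift, g2, "b")
  expect_equal(aggregate_profile(a2, b2)$count, aggregate_profile(a, b)$count)
})

test_that("central ratio flags self co-location and depletion", {
  g <- toy_genome(1e5)
  withr::local_seed(41)
  a <- rand_peak_set(100, g, "a")
  self <- aggregate_profile(a, a)
  s <- depletion_enrichment_summary(self)
  expect_gt(s$ratio, 1)
  expect_equal(s$interpretation, "enrichment")
  # central bins of a self profile carry the maximum
  central <- self$normalized[self$offset_low %in% c(-100, 0)]
  expect_equal(max(self$normalized), max(central))
})

test_that("TSS points can serve as aggregation targets", {
  g <- toy_genome(1e5)
  ann <- gene_annotation(data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                                    tss = c(10050, 80000), strand = "+",
                                    is_tf = FALSE), g)
  anchor <- peak_set("chr1", 9900, 10100, g, "a")
  pr <- aggregate_profile(anchor, ann)
  expect_equal(sum(pr$count), 1L)
  expect_equal(pr$count[pr$offset_low == 0], 1L)
})
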