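test_that("overlap matrix is asymmetric, anchor-based, diagonal 100", {
  g <- toy_genome(1e5)
  a <- peak_set("chr1", c(0, 500), c(100, 600), g, "a")
  b <- peak_set("chr1", 90, 110, g, "b")
  om <- overlap_matrix(list(a = a, b = b))
  expect_equal(om$percent["a", "b"], 50)
  expect_equal(om$percent["b", "a"], 100)
  expect_equal(diag(om$percent), c(a = 100, b = 100))
  # a peak overlapping two partner peaks counts once
  wide <- peak_set("chr1", 0, 1000, g, "w")
  two <- peak_set("chr1", c(100, 500), c(200, 600), g, "t")
  om2 <- overlap_matrix(list(w = wide, t = two))
  expect_equal(om2$counts["w", "t"], 1)
  expect_equal(om2$counts["t", "w"], 2)
  empty <- peak_set(character(), numeric(), numeric(), g, "e")
  om3 <- overlap_matrix(list(a = a, e = empty))
  expect_equal(om3$flagged_rows, "e")
  expect_true(all(is.na(om3$percent["e", ])))
})

test_that("co_bound returns anchor peaks with a partner overlap", {
  g <- toy_genome(1e5)
  a <- peak_set("chr1", c(0, 500, 2000), c(100, 600, 2100), g, "a")
  b <- peak_set("chr1", c(50, 550), c(60, 560), g, "b")
  cb <- co_bound(a, b)
  expect_length(cb, 2L)
  expect_match(S4Vectors::metadata(cb)$anchor_convention, "distinct a peaks")
  expect_length(co_bound(a, a), length(a))
})

test_that("signature regions are bp-wise mark intersections with named labels", {
  g <- toy_genome(1e5)
  k4me1 <- peak_set("chr1", 0, 1000, g, "H3K4me1")
  k27ac <- peak_set("chr1", 500, 1500, g, "H3K27ac")
  k27me3 <- peak_set("chr1", 5000, 6000, g, "H3K27me3")
  sigs <- enhancer_signatures(list(H3K4me1 = k4me1, H3K27ac = k27ac,
                                   H3K27me3 = k27me3))
  expect_named(sigs, c("active_enhancer", "poised_enhancer"))
  expect_equal(peaks_as_df(sigs$active_enhancer),
               data.frame(chrom = "chr1", start = 500, end = 1000))
  expect_length(sigs$poised_enhancer, 0L)
})

test_that("signature overlap fractions: full containment, empty signature flagged", {
  g <- toy_genome(1e5)
  peaks <- peak_set("chr1", c(100, 300), c(200, 400), g, "p")
  sig <- peak_set("chr1", 0, 1000, g, "active_enhancer")
  empty <- peak_set(character(), numeric(), numeric(), g, "poised")
  sf <- signature_overlap_fractions(peaks, list(ae = sig, pe = empty))
  expect_equal(sf$fraction, c(1, 0))
  expect_equal(sf$flagged, c(FALSE, TRUE))
  expect_error(signature_overlap_fractions(empty, list(ae = sig)), "empty")
})

test_that("cross_set_venn partitions each set exactly", {
  g <- toy_genome(1e5)
  withr::local_seed(13)
  for (i in 1:10) {
    a <- rand_peak_set(sample(1:80, 1), g, "a")
    b <- rand_peak_set(sample(1:80, 1), g, "b")
    v <- cross_set_venn(a, b)
    expect_equal(v$a_only + v$overlap_a_anchored, length(a))
    expect_equal(v$b_only + v$overlap_b_anchored, length(b))
    bf <- bf_overlap_pairs(peaks_as_df(a), peaks_as_df(b))
    expect_equal(v$overlap_a_anchored, length(unique(bf$a_idx)))
    expect_equal(v$overlap_b_anchored, length(unique(bf$b_idx)))
    # consistency with the overlap matrix
    om <- overlap_matrix(list(a = a, b = b))
    expect_equal(om$percent["a", "b"], 100 * v$overlap_a_anchored / length(a))
  }
  v <- cross_set_venn(peak_set("chr1", 0, 10, g, "a"),
                      peak_set("chr1", 50, 60, g, "b"))
  expect_equal(v$overlap_a_anchored + v$overlap_b_anchored, 0)
  ident <- rand_peak_set(20, g, "x")
  v2 <- cross_set_venn(ident, ident)
  expect_equal(v2$a_only + v2$b_only, 0)
})

test_that("gene-level overlap reports the hypergeometric-mean expectation", {
  g <- toy_genome(1e6)
  ann <- gene_annotation(data.frame(
    gene_id = sprintf("g%03d", 1:100), chrom = "chr1",
    tss = seq(0, 99) * 10000, strand = "+", is_tf = FALSE), g)
  # regions near the first 10 and last 10 TSSs
  r1 <- peak_set("chr1", seq(0, 9) * 10000, seq(0, 9) * 10000 + 100, g, "r1")
  r2 <- peak_set("chr1", seq(90, 99) * 10000, seq(90, 99) * 10000 + 100, g, "r2")
  glo <- gene_level_overlap(r1, 1000, r2, 1000, ann)
  expect_equal(glo$n1, 10L)
  expect_equal(glo$n2, 10L)
  expect_equal(glo$expected, 1.0)
  expect_equal(glo$intersection, 0L)
  empty <- peak_set(character(), numeric(), numeric(), g, "e")
  glo0 <- gene_level_overlap(empty, 1000, r2, 1000, ann)
  expect_equal(glo0$n1, 0L)
  expect_equal(glo0$expected, 0)
  expect_equal(glo0$intersection, 0L)
})
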