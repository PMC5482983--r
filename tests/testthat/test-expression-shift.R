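make_expr <- function(ref, cond, ids = sprintf("g%02d", seq_along(ref))) {
  expression_table(data.frame(gene_id = ids, reference = ref, cond = cond))
}

test_that("fold-change classification uses strict linear-ratio inequalities", {
  ex <- make_expr(c(10, 10, 10, 10, 10, 0),
                  c(25, 20, 5, 4.9, 10, 50))
  cls <- classify_changes(ex, fold = 2)
  expect_equal(attr(cls, "excluded"), "g06")  # zero reference excluded
  lab <- setNames(cls$label, cls$gene_id)
  expect_equal(unname(lab[c("g01", "g02", "g03", "g04", "g05")]),
               c("activated", "unchanged", "unchanged", "downregulated",
                 "unchanged"))
  expect_error(classify_changes(ex, fold = 1), "> 1")
})

test_that("classification partitions genes and is scale invariant", {
  withr::local_seed(19)
  ref <- rlnorm(200, log(50), 1)
  cond <- ref * 2^runif(200, -3, 3)
  ex <- make_expr(ref, cond)
  cls <- classify_changes(ex, 2)
  expect_equal(nrow(cls), 200L)
  expect_equal(sum(table(cls$label)), 200L)
  # direct per-gene enumeration oracle
  expect_equal(unname(table(cls$label)["downregulated"]),
               sum(cond / ref < 0.5))
  scaled <- make_expr(ref * 7, cond * 7)
  expect_equal(classify_changes(scaled, 2)$label, cls$label)
})

test_that("proximal gene sets use strict TSS-to-region distance", {
  g <- toy_genome(1e5)
  ann <- gene_annotation(data.frame(
    gene_id = c("near", "far", "tf"), chrom = "chr1",
    tss = c(1000, 90000, 6200), strand = "+",
    is_tf = c(FALSE, FALSE, TRUE)), g)
  region <- peak_set("chr1", 5500, 6000, g, "marked")
  prox <- proximal_gene_set(region, ann, thresh = 5000)
  expect_setequal(prox$gene_ids, c("near", "tf"))  # distances 4500 and 201
  expect_equal(prox$tf_gene_ids, "tf")
  region2 <- peak_set("chr1", 6100, 6500, g, "marked")
  expect_false("near" %in% proximal_gene_set(region2, ann, 5000)$gene_ids)
})

test_that("shift summary matches a hand-counted six-gene table", {
  ex <- make_expr(c(10, 10, 10, 10, 10, 10),
                  c(50, 2, 1, 11, 9, 45))
  cls <- classify_changes(ex, 2)
  ss <- shift_summary(cls, list(proximal = c("g02", "g03", "g04"),
                                proximal_tf = "g03"))
  expect_equal(ss$n_genes, c(6L, 3L, 1L))
  expect_equal(ss$fraction_activated, c(2/6, 0, 0))
  expect_equal(ss$fraction_downregulated, c(2/6, 2/3, 1))
  expect_equal(ss$fraction_activated + ss$fraction_downregulated +
                 ss$fraction_unchanged, rep(1, 3))
  expect_true(attr(ss, "monotone_down")[["cond"]])
})

test_that("strata must nest and empty strata are flagged not crashed", {
  ex <- make_expr(c(10, 10), c(50, 2))
  cls <- classify_changes(ex, 2)
  expect_error(shift_summary(cls, list(proximal = "g01",
                                       proximal_tf = "g02")),
               "not nested")
  ss <- shift_summary(cls, list(proximal = character()))
  expect_true(ss$flagged[ss$stratum == "proximal"])
  expect_true(is.na(attr(ss, "monotone_down")[["cond"]]))
})

test_that("null expression configuration yields no fold-change calls", {
  cfg <- landscape_config(seed = 2)
  cfg$expression$fold <- 1
  g <- toy_genome(1e5)
  ann <- gene_annotation(data.frame(
    gene_id = sprintf("g%03d", 1:300), chrom = "chr1",
    tss = seq_len(300) * 300, strand = "+", is_tf = FALSE), g)
  ex <- generate_expression(cfg, ann, proximal_ids = sprintf("g%03d", 1:50))
  cls <- classify_changes(ex, 2)
  # sdlog 0.05 noise cannot cross a 2-fold cut-off
  expect_true(all(cls$label == "unchanged"))
})

test_that("forced downregulation is classified at exactly 100%", {
  cfg <- landscape_config(seed = 2)
  cfg$expression$p_down <- c(background = 1, proximal = 1, proximal_tf = 1)
  cfg$expression$p_up <- c(background = 0, proximal = 0, proximal_tf = 0)
  cfg$expression$noise_sdlog <- 0
  g <- toy_genome(1e5)
  ann <- gene_annotation(data.frame(
    gene_id = sprintf("g%03d", 1:100), chrom = "chr1",
    tss = seq_len(100) * 900, strand = "+", is_tf = FALSE), g)
  ex <- generate_expression(cfg, ann, proximal_ids = sprintf("g%03d", 1:100))
  cls <- classify_changes(ex, 2)
  expect_true(all(cls$label == "downregulated"))
})
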