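test_that("gene_ths_pairing averages accessibility over paired THSs", {
  gn <- genome(c(chr1 = 100000))
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(10000, 50000),
                                                   c(12000, 52000)),
                                  strand = c("+", "-"))
  genes$gene_id <- c("g1", "g2")
  genes <- bind_genome(genes, gn)
  cons <- regions("chr1", c(9400, 11000, 30000), c(9600, 11200, 30200),
                  gn = gn)
  acc <- matrix(c(2, 4, 8, 1, 3, 5), 3, 2,
                dimnames = list(region_ids(cons), c("s1", "s2")))
  pr <- gene_ths_pairing(genes, cons, acc)
  expect_identical(rownames(pr$matrix), "g1")
  expect_equal(unname(pr$matrix["g1", ]), c(mean(c(2, 4)), mean(c(1, 3))))
  expect_identical(pr$n_unpaired, 1L)
  expect_error(gene_ths_pairing(genes, cons, acc[1:2, ]), "correspond")
})

test_that("integration_table restricts and cross-tabulates correctly", {
  levels_df <- data.frame(gene = paste0("g", 1:6),
                          ratio = c(0.1, 0.5, 0.59, 0.7, 0.2, 0.3),
                          log2fc = log2(c(0.1, 0.5, 0.59, 0.7, 0.2, 0.3)),
                          p = rep(0.001, 6),
                          bin = "x")
  access_df <- data.frame(log2fc = c(1, 1, -1, 1, 0.2, 1),
                          p = c(0.001, 0.001, 0.001, 0.001, 0.5, 0.001),
                          direction = c("increased", "increased", "decreased",
                                        "increased", "unchanged", "increased"),
                          row.names = paste0("g", 1:6))
  expr_df <- data.frame(gene = paste0("g", 1:6),
                        log2fc = 0, p = 1,
                        class = c("activated", "unaltered", "repressed",
                                  "activated", "unaltered", "activated"))
  cats <- data.frame(gene = paste0("g", 1:6),
                     category = c(rep("only-H2AK121ub", 5), "non-PcG"))
  it <- integration_table(levels_df, access_df, expr_df, cats,
                          category = "only-H2AK121ub")
  # g4 fails ratio < 0.6; g5 unchanged access; g6 wrong category
  # remaining: g1 inc/act, g2 inc/unalt, g3 dec/rep
  expect_identical(it$n, 3L)
  expect_identical(it$counts["increased", "activated"], 1L)
  expect_identical(it$counts["increased", "unaltered"], 1L)
  expect_identical(it$counts["decreased", "repressed"], 1L)
  expect_equal(sum(it$percent), 100)
  expect_identical(unname(it$excluded["wrong_category"]), 1L)
  expect_identical(unname(it$excluded["level_not_reduced"]), 1L)
  expect_identical(unname(it$excluded["accessibility_unchanged"]), 1L)
  expect_warning(
    z <- integration_table(levels_df[levels_df$ratio > 0.65, ], access_df,
                           expr_df, cats, category = "only-H2AK121ub"),
    "no genes left")
  expect_identical(z$n, 0L)
  expect_equal(sum(z$percent), 0)
})

test_that("scatter_table joins the three layers and tallies exclusions", {
  levels_df <- data.frame(gene = c("g1", "g2"), ratio = c(0.5, 0.7),
                          log2fc = c(-1, -0.5), p = 0.01, bin = "x")
  access_df <- data.frame(log2fc = c(2, 3), p = 0.01,
                          direction = "increased",
                          row.names = c("g1", "g3"))
  expr_df <- data.frame(gene = c("g1", "g2"), log2fc = 0, p = 1,
                        class = "unaltered")
  st <- scatter_table(levels_df, access_df, expr_df)
  expect_identical(st$gene, "g1")
  expect_equal(st$level_log2fc, -1)
  expect_equal(st$access_log2fc, 2)
  expect_identical(attr(st, "n_excluded"), 2L)
})

test_that("tss_window_means measures the window around each TSS", {
  gn <- genome(c(chr1 = 100000))
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(10000, 50000),
                                                   c(12000, 52000)),
                                  strand = c("+", "-"))
  genes$gene_id <- c("g1", "g2")
  genes <- bind_genome(genes, gn)
  seg <- regions("chr1", 9499, 10499, gn = gn)  # 1 kb centred on g1's TSS
  seg$score <- 6
  tr <- fill_track(seg, 0)
  wm <- tss_window_means(tr, genes, window = c(-500, 500))
  expect_equal(unname(wm["g1"]), 6)
  expect_equal(unname(wm["g2"]), 0)
})
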