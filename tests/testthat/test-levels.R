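make_genes <- function(gn) {
  g <- GenomicRanges::GRanges("chr1",
                              IRanges::IRanges(c(10000, 50000), c(12000, 52000)),
                              strand = c("+", "-"))
  g$gene_id <- c("g1", "g2")
  bind_genome(g, gn)
}

test_that("gene promoters are strand-aware and clamped", {
  gn <- genome(c(chr1 = 100000))
  genes <- make_genes(gn)
  p <- gene_promoters(genes, upstream = 750)
  expect_identical(GenomicRanges::start(p), c(9250L, 52001L))
  expect_identical(GenomicRanges::end(p), c(9999L, 52750L))
  # clamped at chromosome start
  g0 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 600),
                               strand = "+")
  g0$gene_id <- "g0"
  p0 <- gene_promoters(bind_genome(g0, gn))
  expect_identical(GenomicRanges::start(p0), 1L)
  sc <- gene_scope(genes)
  expect_identical(GenomicRanges::start(sc), c(9250L, 50000L))
  expect_identical(GenomicRanges::end(sc), c(12000L, 52750L))
  expect_identical(sc$gene_id, genes$gene_id)
})

test_that("peaks are assigned to genes by the body/promoter rule", {
  gn <- genome(c(chr1 = 100000))
  genes <- make_genes(gn)
  peaks <- regions("chr1",
                   c(9400, 11000, 30000, 52500),
                   c(9600, 11200, 30200, 52700), gn = gn)
  asn <- assign_peaks_to_genes(peaks, genes)
  expect_setequal(names(asn), c("g1", "g2"))
  expect_setequal(asn$g1, 1:2)   # promoter peak + body peak
  expect_identical(asn$g2, 4L)   # minus-strand promoter peak
})

test_that("gene_mark_table is the length-weighted mean over peak unions", {
  gn <- genome(c(chr1 = 100000))
  genes <- make_genes(gn)
  # two overlapping g1 peaks whose union is 9400-9800 (400 bp)
  peaks <- regions("chr1", c(9400, 9600, 52000), c(9700, 9800, 52400),
                   gn = gn)
  asn <- assign_peaks_to_genes(peaks, genes)
  seg <- regions("chr1", 9400, 9600, gn = gn)  # half of the g1 union
  seg$score <- 8
  tr <- fill_track(seg, background = 0)
  m <- gene_mark_table(asn, peaks, list(s1 = tr))
  expect_identical(rownames(m), c("g1", "g2"))
  expect_equal(unname(m["g1", "s1"]), 8 * 200 / 400)
  expect_equal(unname(m["g2", "s1"]), 0)
  expect_error(gene_mark_table(list(), peaks, list(s1 = tr)), "empty")
})

test_that("classify_levels bins ratios left-closed and flags zero-WT genes", {
  ratios <- c(0.19, 0.2, 0.59999, 0.6, 0.8, 1.19, 1.2, 2)
  ng <- length(ratios)
  wt <- rep(100, ng)
  m <- cbind(WT_r1 = wt, WT_r2 = wt,
             mut_r1 = wt * ratios, mut_r2 = wt * ratios)
  rownames(m) <- paste0("g", seq_len(ng))
  res <- classify_levels(m, cols_mut = c("mut_r1", "mut_r2"),
                         cols_wt = c("WT_r1", "WT_r2"))
  expect_identical(as.character(res$bin),
                   c("<20%", "20-40%", "40-60%", "60-80%", "80-120%",
                     "80-120%", ">120%", ">120%"))
  expect_equal(res$ratio, ratios)
  expect_equal(res$log2fc, log2(ratios))
  # the <60% superset is exactly log2fc < log2(0.6)
  expect_identical(res$ratio < 0.6,
                   res$log2fc < wt_fraction_cutoff_log2(0.6))
  m0 <- rbind(m, gz = c(0, 0, 5, 5))
  expect_warning(r0 <- classify_levels(m0, c("mut_r1", "mut_r2"),
                                       c("WT_r1", "WT_r2")),
                 "zero WT")
  expect_identical(attr(r0, "unclassifiable"), "gz")
  expect_false("gz" %in% r0$gene)
})

test_that("mark_categories partitions genes by any-WT-dataset marking", {
  gn <- genome(c(chr1 = 100000))
  genes <- make_genes(gn)
  h2a <- list(ds1 = regions("chr1", 9400, 9600, gn = gn),    # g1 promoter
              ds2 = regions("chr1", 30000, 30100, gn = gn))  # no gene
  k27 <- list(ds1 = regions("chr1", c(11000, 51000),
                            c(11500, 51500), gn = gn))       # g1 + g2 bodies
  cats <- mark_categories(h2a, k27, genes)
  got <- setNames(as.character(cats$category), cats$gene)
  expect_identical(unname(got["g1"]), "H2AK121ub/H3K27me3")
  expect_identical(unname(got["g2"]), "only-H3K27me3")
  expect_error(mark_categories(list(), k27, genes), ">= 1 WT dataset")
})

test_that("classify_expression uses inclusive fold-change, strict p", {
  # construct log2fc exactly at +1 with tiny variance -> activated
  m <- cbind(WT_r1 = c(10, 10, 10), WT_r2 = c(10, 10, 10),
             mut_r1 = c(20.5, 20.5, 10), mut_r2 = c(20.5, 20.5, 10))
  m[2, c("mut_r1", "mut_r2")] <- 20.4  # just below the 2x boundary
  rownames(m) <- c("at", "below", "flat")
  res <- classify_expression(m, cols_mut = c("mut_r1", "mut_r2"),
                             cols_wt = c("WT_r1", "WT_r2"),
                             pseudocount = 0.5)
  got <- setNames(as.character(res$class), res$gene)
  expect_identical(unname(got["at"]), "activated")   # log2fc exactly 1
  expect_identical(unname(got["below"]), "unaltered")
  expect_identical(unname(got["flat"]), "unaltered")
  expect_equal(res$log2fc[1], 1)
})
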