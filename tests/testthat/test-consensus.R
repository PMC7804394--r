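test_that("per-genotype THSs are the merged replicate intersection", {
  r1 <- regions("chr1", c(0, 1000), c(500, 1600))
  r2 <- regions("chr1", c(200, 1200, 5000), c(700, 1700, 5100))
  ths <- replicate_consensus(r1, r2)
  expect_identical(GenomicRanges::start(ths), c(201L, 1201L))
  expect_identical(GenomicRanges::end(ths), c(500L, 1600L))
  expect_identical(genotype_ths(list(r1, r2)), ths)
  expect_error(genotype_ths(list(r1)), "exactly 2 replicates")
  expect_error(genotype_ths(list(r1, r2, r1)), "exactly 2 replicates")
})

test_that("consensus records per-genotype provenance", {
  gts <- list(WT = regions("chr1", c(0, 5000), c(1000, 5500)),
              mut = regions("chr1", c(500, 9000), c(1500, 9200)))
  cons <- build_consensus(gts)
  expect_identical(length(cons), 3L)
  expect_identical(cons$provenance, c("WT,mut", "WT", "mut"))
  expect_identical(cons$n_genotypes, c(2, 1, 1))
  expect_error(build_consensus(list()), "no genotype")
  expect_error(build_consensus(unname(gts)), "named")
})

test_that("region ids use BED coordinates", {
  expect_identical(region_ids(regions("chr2", 100, 250)), "chr2:100-250")
})

test_that("build_matrix averages tracks over regions", {
  gn <- genome(c(chr1 = 10000))
  reg <- regions("chr1", c(0, 5000), c(1000, 6000), gn = gn)
  seg <- regions("chr1", 0, 1000, gn = gn); seg$score <- 4
  t1 <- fill_track(seg, background = 1)
  m <- build_matrix(reg, list(s1 = t1))
  expect_identical(rownames(m), region_ids(reg))
  expect_equal(unname(m[, "s1"]), c(4, 1))
  expect_error(build_matrix(reg, list(t1)), "named")
  # a track missing the chromosome warns and contributes 0
  t2 <- regions("chr9", 0, 10, sort = FALSE); t2$score <- 1
  expect_warning(m2 <- build_matrix(reg, list(s2 = t2)), "no signal")
  expect_equal(unname(m2[, "s2"]), c(0, 0))
})

test_that("filter_matrix drops low-signal rows by pooled percentile", {
  m <- matrix(c(10, 10, 0.1, 0.2, 5, 6, 0.05, 0.1), 4, 2, byrow = FALSE,
              dimnames = list(paste0("r", 1:4), c("a", "b")))
  out <- filter_matrix(m, percentile = 0.5)
  thr <- unname(quantile(as.numeric(m), 0.5, type = 7))
  expect_identical(attr(out, "threshold"), thr)
  expect_identical(rownames(out), rownames(m)[apply(m, 1, max) >= thr])
  out2 <- filter_matrix(m, threshold = 3)
  expect_identical(rownames(out2), c("r1", "r2"))
  expect_warning(filter_matrix(m, threshold = 100), "every row")
  expect_error(filter_matrix(m[0, , drop = FALSE]), "non-empty")
})

test_that("consensus_qpass requires both replicates below the cutoff", {
  cons <- regions("chr1", c(0, 5000), c(1000, 6000))
  pk <- function(q) {
    p <- regions("chr1", 0, 900)
    p$qvalue <- q
    p
  }
  reps <- list(gt1 = list(pk(0.01), pk(0.04)),
               gt2 = list(pk(0.01), pk(0.2)))
  qp <- consensus_qpass(cons, reps, q_cut = 0.05)
  expect_identical(unname(qp[, "gt1"]), c(TRUE, FALSE))
  expect_identical(unname(qp[, "gt2"]), c(FALSE, FALSE))
  noq <- list(gt = list(regions("chr1", 0, 10), regions("chr1", 0, 10)))
  expect_error(consensus_qpass(cons, noq), "qvalue")
})

test_that("differential_accessibility direction calls follow p and sign", {
  withr::local_seed(5)
  m <- rbind(up = c(40, 42, 4, 5), dn = c(1, 1.2, 30, 33),
             flat = c(10, 11, 10, 11))
  colnames(m) <- c("mut_r1", "mut_r2", "WT_r1", "WT_r2")
  res <- differential_accessibility(m, cols_mut = 1:2, cols_wt = 3:4)
  expect_identical(res["up", "direction"], "increased")
  expect_identical(res["dn", "direction"], "decreased")
  expect_identical(res["flat", "direction"], "unchanged")
})

test_that("tss_distribution bins region centers strand-awarely", {
  gn <- genome(c(chr1 = 100000))
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(20000, 60000),
                                                   c(25000, 65000)),
                                  strand = c("+", "-"))
  genes$gene_id <- c("gplus", "gminus")
  genes <- bind_genome(genes, gn)
  # centers: in gplus body; 500 bp upstream of gplus TSS; 2 kb upstream of
  # gminus TSS (upstream of a minus gene = to the right); 5 kb upstream of
  # gplus; downstream of gplus
  reg <- regions("chr1",
                 c(21950, 19450, 66950, 14950, 30950),
                 c(22050, 19550, 67050, 15050, 31050), gn = gn)
  d <- tss_distribution(reg, genes)
  got <- setNames(d$count, d$bin)
  expect_identical(unname(got["gene_body"]), 1L)
  expect_identical(unname(got["upstream_0-1kb"]), 1L)
  expect_identical(unname(got["upstream_1-3kb"]), 1L)
  expect_identical(unname(got["upstream_>3kb"]), 1L)
  expect_identical(unname(got["downstream"]), 1L)
  expect_equal(sum(d$percent), 100)
  expect_error(tss_distribution(reg[0], genes), "empty")
})

test_that("tss_profile mirrors minus-strand genes", {
  gn <- genome(c(chr1 = 100000))
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(20000, 60000),
                                                   c(25000, 65000)),
                                  strand = c("+", "-"))
  genes$gene_id <- c("a", "b")
  genes <- bind_genome(genes, gn)
  # signal downstream of each TSS (into the gene body)
  seg <- regions("chr1", c(19999, 64000), c(21000, 65000), gn = gn)
  seg$score <- 10
  tr <- fill_track(seg, 0)
  prof <- tss_profile(tr, genes, window = c(-1000, 1000), binsize = 100)
  expect_identical(nrow(prof), 20L)
  inside <- prof$mean_cpm[prof$pos >= 0]
  outside <- prof$mean_cpm[prof$pos < 0]
  expect_true(all(inside == 10))
  expect_true(all(outside == 0))
  expect_error(tss_profile(tr, genes, window = c(100, 1000)), "span the TSS")
  expect_error(tss_profile(tr, genes, window = c(-1000, 1000), binsize = 300),
               "divide")
})
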