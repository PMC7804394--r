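small_spec <- function(...) {
  sim_spec(chrom_sizes = stats::setNames(rep(4e5, 2), c("chr1", "chr2")),
           n_genes = 40, n_ths = 60, n_tfbs = 500, n_blacklist = 2, ...)
}

test_that("sim_spec validates overrides", {
  expect_error(sim_spec(not_a_field = 1), "unknown sim_spec field")
  sp <- sim_spec(n_genes = 7)
  expect_identical(sp$n_genes, 7)
  expect_s3_class(sp, "sim_spec")
})

test_that("simulated genes and THSs are reproducible and well-formed", {
  sp <- small_spec()
  gn <- simulate_genome(sp)
  g1 <- simulate_genes(sp, gn, seed = 3)
  g2 <- simulate_genes(sp, gn, seed = 3)
  expect_identical(GenomicRanges::start(g1), GenomicRanges::start(g2))
  expect_length(g1, 40L)
  expect_identical(anyDuplicated(g1$gene_id), 0L)
  ths <- simulate_ths(sp, gn, g1, seed = 3)
  expect_length(ths, 60L)
  expect_true(GenomicRanges::isDisjoint(ths))
  expect_true(all(GenomicRanges::width(ths) >= sp$ths_len_range[1]))
  expect_true(all(GenomicRanges::width(ths) <= sp$ths_len_range[2]))
  # promoter-linked THSs point at real, distinct genes
  linked <- ths$gene_id[!is.na(ths$gene_id)]
  expect_identical(anyDuplicated(linked), 0L)
  expect_true(all(linked %in% g1$gene_id))
  # capped at the number of genes (sampling without replacement)
  expect_length(linked, min(round(sp$ths_promoter_frac * sp$n_ths),
                            sp$n_genes))
})

test_that("replicates jitter and drop out but stay within the genome", {
  sp <- small_spec()
  gn <- simulate_genome(sp)
  ths <- simulate_ths(sp, gn, seed = 5)
  reps <- simulate_ths_replicates(sp, ths, gn, seed = 5)
  expect_setequal(names(reps), sp$genotypes)
  for (g in names(reps)) {
    expect_named(reps[[g]], c("rep1", "rep2"))
    for (r in reps[[g]]) {
      expect_true(length(r) <= length(ths))
      expect_true(all(!is.na(r$qvalue)))
      lens <- gn[as.character(GenomeInfoDb::seqnames(r))]
      expect_true(all(GenomicRanges::end(r) <= lens))
    }
  }
})

test_that("signal tracks tile the genome and honour multipliers", {
  sp <- small_spec(track_noise_sd = 0)
  gn <- simulate_genome(sp)
  ths <- simulate_ths(sp, gn, seed = 2)
  mult <- matrix(1, length(ths), length(sp$genotypes),
                 dimnames = list(NULL, sp$genotypes))
  mult[1, "bmi1abc"] <- 3
  tracks <- simulate_signal_tracks(sp, ths, gn, multipliers = mult, seed = 2)
  expect_length(tracks, 8L)  # 4 genotypes x 2 replicates
  for (tr in tracks)
    expect_identical(sum(as.numeric(GenomicRanges::width(tr))),
                     sum(as.numeric(gn)))
  at1 <- track_mean(tracks$bmi1abc_r1, ths[1])
  wt1 <- track_mean(tracks$WT_r1, ths[1])
  expect_equal(at1 / wt1, 3)
  expect_equal(wt1, sp$base_cpm)
})

test_that("simulate_tfbs plants the density mixture", {
  sp <- small_spec(n_tfbs = 2000)
  gn <- simulate_genome(sp)
  ths <- simulate_ths(sp, gn, seed = 8)
  t0 <- simulate_tfbs(sp, ths, gn, f = 0, seed = 8)
  expect_identical(attr(t0, "n_inside"), 0L)
  expect_identical(sum(t0$midpoint_inside), 0L)
  t5 <- simulate_tfbs(sp, ths, gn, f = 5, seed = 8)
  expect_length(t5, 2000L)
  expect_gt(attr(t5, "n_inside"), 0L)
  expect_error(simulate_tfbs(sp, ths, gn, f = -1, seed = 1), ">= 0")
})

test_that("gene-mark matrices carry planted multipliers in their truth", {
  sp <- small_spec(mark_noise_sd = 0)
  ids <- sprintf("g%02d", 1:30)
  sim <- simulate_gene_mark_matrix(sp, ids, genotypes = c("mutA", "mutB"),
                                   seed = 4)
  m <- sim$matrix
  expect_identical(dim(m), c(30L, 6L))
  r <- m[, "mutA_r1"] / m[, "WT_r1"]
  expect_equal(unname(r), sim$truth$multiplier_mutA)
  expect_true(all(sim$truth$multiplier_mutA %in% sp$level_multipliers))
})

test_that("expression matrices plant the requested classes", {
  sp <- small_spec(expr_noise_sd = 0)
  ids <- sprintf("g%02d", 1:20)
  de <- matrix("unaltered", 20, 1, dimnames = list(ids, "mutA"))
  de[1:3, 1] <- "activated"; de[4:5, 1] <- "repressed"
  sim <- simulate_expression(sp, ids, genotypes = "mutA", de_class = de,
                             seed = 6)
  fc <- log2(sim$matrix[, "mutA_r1"] / sim$matrix[, "WT_r1"])
  expect_equal(unname(fc[1:3]), rep(sp$de_effect, 3))
  expect_equal(unname(fc[4:5]), rep(-sp$de_effect, 2))
  expect_equal(unname(fc[6:20]), rep(0, 15))
  expect_identical(sim$truth$mutA, as.character(de[, 1]))
})

test_that("simulate_dataset is deterministic and internally consistent", {
  sp <- small_spec()
  d1 <- simulate_dataset(sp, seed = 9)
  d2 <- simulate_dataset(sp, seed = 9)
  expect_identical(GenomicRanges::start(d1$ths), GenomicRanges::start(d2$ths))
  expect_identical(d1$expression$matrix, d2$expression$matrix)
  expect_s3_class(d1, "sim_dataset")
  # categories drive mark carriers: every H2A-marked gene has an H2A WT peak
  h2a_genes <- d1$categories$gene[
    d1$categories$category %in% c("only-H2AK121ub", "H2AK121ub/H3K27me3")]
  expect_setequal(d1$mark_peaks_wt$H2AK121ub$ds1$gene_id, h2a_genes)
  # blacklist avoids THSs and genes
  expect_identical(sum(count_overlaps(d1$blacklist, d1$ths)), 0L)
  expect_identical(sum(count_overlaps(d1$blacklist, d1$genes)), 0L)
  # accessibility multipliers only boost mark-loss gene THSs
  expect_true(all(d1$truth$acc_mult[, "WT"] == 1))
})
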