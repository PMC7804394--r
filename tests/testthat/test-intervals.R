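test_that("regions translates BED coordinates to 1-based closed ranges", {
  gr <- regions("chr1", 0, 100)
  expect_identical(GenomicRanges::start(gr), 1L)
  expect_identical(GenomicRanges::end(gr), 100L)
  expect_identical(GenomicRanges::width(gr), 100L)
  expect_error(regions("chr1", 5, 5), "0 <= start < end")
  expect_error(regions("chr1", -1, 5), "0 <= start < end")
  expect_error(regions(c("chr1", "chr1"), 0, 10), "equal length")
})

test_that("regions sorts and deduplicates; bind_genome validates bounds", {
  gr <- regions(c("chr2", "chr1", "chr1"), c(0, 50, 50), c(10, 60, 60))
  expect_length(gr, 2L)
  expect_identical(as.character(GenomeInfoDb::seqnames(gr)),
                   c("chr1", "chr2"))
  gn <- genome(c(chr1 = 100, chr2 = 100))
  expect_error(bind_genome(regions("chr3", 0, 10), gn), "unknown chromosome")
  expect_error(bind_genome(regions("chr1", 0, 101), gn), "exceeds")
  ok <- bind_genome(regions("chr1", 0, 100), gn)
  expect_identical(unname(GenomeInfoDb::seqlengths(ok)), c(100L, 100L))
})

test_that("touching regions merge at gap 0 but do not overlap", {
  a <- regions("chr1", 0, 100)
  b <- regions("chr1", 100, 200)  # BED-touching
  m <- merge_regions(c(a, b))
  expect_length(m, 1L)
  expect_identical(GenomicRanges::width(m), 200L)
  expect_identical(count_overlaps(a, b), 0L)
  expect_identical(nearest_distance(a, b), 0L)
  expect_length(intersect_regions(a, b), 0L)
})

test_that("merge_regions bridges gaps up to `gap` bp only", {
  x <- regions("chr1", c(0, 110, 300), c(100, 200, 400))
  expect_length(merge_regions(x, gap = 9), 3L)
  expect_length(merge_regions(x, gap = 10), 2L)
  expect_length(merge_regions(x, gap = 100), 1L)
  expect_error(merge_regions(x, gap = -1), ">= 0")
})

test_that("subtract_regions removes covered bases and handles empties", {
  a <- regions("chr1", 0, 100)
  out <- subtract_regions(a, regions("chr1", 40, 60))
  expect_identical(GenomicRanges::start(out), c(1L, 61L))
  expect_identical(GenomicRanges::end(out), c(40L, 100L))
  expect_identical(GenomicRanges::width(subtract_regions(a, a[0])), 100L)
})

test_that("nearest_distance returns NA on subject-free chromosomes", {
  q <- regions(c("chr1", "chr2"), c(0, 0), c(10, 10))
  s <- regions("chr1", 100, 110)
  expect_identical(nearest_distance(q, s), c(90L, NA_integer_))
})

test_that("covered_bp counts overlapping bases once", {
  x <- regions("chr1", c(0, 50), c(100, 150), sort = FALSE)
  expect_identical(covered_bp(x), 150)
})

test_that("interval algebra matches the mask and all-pairs oracles", {
  withr::local_seed(401)
  for (rep in 1:25) {
    gn <- rand_genome()
    da <- rand_region_df(gn, sample(1:30, 1))
    db <- rand_region_df(gn, sample(1:30, 1))
    a <- regions(da$chrom, da$start0, da$end0, gn = gn, sort = FALSE)
    b <- regions(db$chrom, db$start0, db$end0, gn = gn, sort = FALSE)
    ma <- mask_of(a, gn); mb <- mask_of(b, gn)
    expect_same_regions(merge_regions(a), mask_bounds(ma))
    g <- sample(0:200, 1)
    expect_same_regions(merge_regions(a, gap = g),
                        close_gaps(mask_bounds(ma), g))
    inter <- mapply(`&`, ma, mb, SIMPLIFY = FALSE)
    expect_same_regions(intersect_regions(a, b), mask_bounds(inter))
    diffm <- mapply(function(x, y) x & !y, ma, mb, SIMPLIFY = FALSE)
    expect_same_regions(subtract_regions(a, b), mask_bounds(diffm))
    expect_identical(covered_bp(a), sum(vapply(ma, sum, numeric(1))))
    expect_identical(count_overlaps(a, b), oracle_counts(a, b))
    expect_identical(nearest_distance(a, b), oracle_nearest(a, b))
  }
})
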