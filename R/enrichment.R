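#' Monte Carlo matched-random-region enrichment test
#'
#' Tests whether a feature set (e.g. transcription-factor binding sites) is
#' enriched at a region set (e.g. consensus THSs) by comparing the median
#' per-region feature overlap count against the same statistic on sets of
#' random regions matched in number and length to the observed regions.
#' Random regions are placed uniformly: each draws a chromosome with
#' probability proportional to the number of feasible start positions
#' (chromosome length minus region length plus one) and then a uniform start;
#' random regions may overlap each other. Regions overlapping `exclude`
#' (typically the blacklist) are rejected and resampled.
#'
#' The empirical p-value uses the add-one form
#' \eqn{p = (1 + \#\{null \ge obs\}) / (n_{sets} + 1)}, so it is never 0 and
#' its floor \eqn{1/(n_{sets}+1)} reproduces a "p < 1/n_sets" call when the
#' observed statistic exceeds every null value. The enrichment ratio is
#' observed over the mean of the null medians (the median-of-null version is
#' also reported).
#'
#' @param ths Observed region set (`GRanges`), e.g. consensus THSs.
#' @param features Feature set (`GRanges`).
#' @param gn `genome` used for random placement.
#' @param n_sets Number of random sets (default 10000).
#' @param seed Integer seed; the test is a pure function of (inputs, seed).
#' @param exclude Optional `GRanges` the random regions must avoid.
#' @return An object of class `enrichment_result`: list with `observed`,
#'   `null` (numeric vector of length `n_sets`), `n_sets`, `enrichment`,
#'   `enrichment_median_null`, `p`, `seed`, `n_regions`.
#' @examples
#' gn <- genome(c(chr1 = 1e5))
#' ths <- regions("chr1", c(1000, 5000), c(1200, 5300))
#' feats <- regions("chr1", seq(0, 9e4, by = 5000), seq(0, 9e4, by = 5000) + 100)
#' mc_enrichment_test(ths, feats, gn, n_sets = 99, seed = 1)
#' @export
mc_enrichment_test <- function(ths, features, gn, n_sets = 10000, seed = NULL,
                               exclude = NULL) {
  if (length(ths) == 0L) stop("empty region set")
  if (n_sets < 1L) stop("n_sets must be >= 1")
  observed <- median_overlap_statistic(ths, features)
  widths <- GenomicRanges::width(ths)
  n <- length(ths)
  null <- withr::with_seed(
    seed = if (is.null(seed)) sample.int(.Machine$integer.max, 1L) else seed,
    code = {
      out <- numeric(n_sets)
      # chunk the sets so the scratch GRanges stays modest
      per_chunk <- max(1L, min(n_sets, as.integer(2e6 / n)))
      done <- 0L
      while (done < n_sets) {
        k <- min(per_chunk, n_sets - done)
        pos <- .sample_positions(gn, rep(widths, k), exclude = exclude)
        counts <- count_overlaps(pos, features)
        cm <- matrix(counts, nrow = n)
        out[done + seq_len(k)] <- apply(cm, 2L, stats::median)
        done <- done + k
      }
      out
    })
  mean_null <- mean(null)
  med_null <- stats::median(null)
  enr <- if (mean_null > 0) observed / mean_null
         else if (observed > 0) Inf else 1
  p <- if (mean_null == 0 && observed == 0) 1
       else (1 + sum(null >= observed)) / (n_sets + 1)
  structure(list(observed = observed, null = null, n_sets = n_sets,
                 enrichment = enr,
                 enrichment_median_null =
                   if (med_null > 0) observed / med_null
                   else if (observed > 0) Inf else 1,
                 p = p, seed = seed, n_regions = n),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Monte Carlo matched-region enrichment test\n")
  cat(sprintf("  regions: %d   random sets: %d\n", x$n_regions, x$n_sets))
  cat(sprintf("  observed median overlap: %g\n", x$observed))
  cat(sprintf("  null mean (median): %g (%g)\n",
              mean(x$null), stats::median(x$null)))
  cat(sprintf("  enrichment: %g   empirical p: %g\n", x$enrichment, x$p))
  invisible(x)
}

#' Median per-region overlap count
#'
#' The observed statistic of [mc_enrichment_test()]: the median (midpoint
#' convention for even counts) of the number of features overlapping each
#' region.
#'
#' @param reg Non-empty `GRanges`.
#' @param features `GRanges`.
#' @return Numeric scalar.
#' @export
median_overlap_statistic <- function(reg, features) {
  if (length(reg) == 0L) stop("empty region set")
  stats::median(count_overlaps(reg, features))
}

#' One random region set matched to a template
#'
#' Same number of regions and same multiset of lengths as `template`, placed
#' uniformly over the genome (see [mc_enrichment_test()] for the placement
#' rule).
#'
#' @param gn `genome`.
#' @param template `GRanges` whose lengths are matched.
#' @param seed Optional integer seed.
#' @param exclude Optional `GRanges` to avoid.
#' @return A `GRanges` of `length(template)` random regions.
#' @export
random_region_set <- function(gn, template, seed = NULL, exclude = NULL) {
  widths <- GenomicRanges::width(template)
  if (is.null(seed))
    .sample_positions(gn, widths, exclude = exclude)
  else
    withr::with_seed(seed, .sample_positions(gn, widths, exclude = exclude))
}

# vectorised placement of N regions with given widths; uses the current RNG
.sample_positions <- function(gn, widths, exclude = NULL, max_retries = 100L) {
  N <- length(widths)
  L <- as.numeric(gn)
  C <- length(L)
  if (any(widths > max(L)))
    stop("region length ", max(widths), " exceeds every chromosome")
  draw <- function(w) {
    n <- length(w)
    W <- vapply(L, function(len) pmax(len - w + 1, 0), numeric(n))
    W <- matrix(W, nrow = n)
    tot <- rowSums(W)
    u <- stats::runif(n) * tot
    idx <- integer(n)
    cum <- numeric(n)
    for (cc in seq_len(C)) {
      cum2 <- cum + W[, cc]
      sel <- idx == 0L & u <= cum2
      idx[sel] <- cc
      cum <- cum2
    }
    idx[idx == 0L] <- C
    start0 <- floor(stats::runif(n) * (L[idx] - w + 1))
    list(chrom = names(gn)[idx], start = start0, end = start0 + w)
  }
  d <- draw(widths)
  gr <- regions(d$chrom, d$start, d$end, gn = gn, sort = FALSE)
  if (!is.null(exclude) && length(exclude)) {
    for (i in seq_len(max_retries)) {
      bad <- which(count_overlaps(gr, exclude) > 0L)
      if (!length(bad)) break
      if (i == max_retries)
        stop("could not place ", length(bad),
             " regions outside the excluded set after ", max_retries,
             " retries")
      d <- draw(widths[bad])
      gr[bad] <- regions(d$chrom, d$start, d$end, gn = gn, sort = FALSE)
    }
  }
  gr
}
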