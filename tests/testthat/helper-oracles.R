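# Brute-force reference implementations ("oracles") used to validate the
# interval algebra and statistics against independent, obviously-correct
# computations on small inputs.

# per-base boolean coverage mask over a small genome
mask_of <- function(gr, gn) {
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  out <- lapply(names(gn), function(cc) {
    v <- logical(gn[[cc]])
    for (i in which(chr == cc)) v[st[i]:en[i]] <- TRUE
    v
  })
  names(out) <- names(gn)
  out
}

# TRUE runs of a mask as a chrom/start/end data.frame (1-based closed)
mask_bounds <- function(mask) {
  res <- lapply(names(mask), function(cc) {
    r <- rle(mask[[cc]])
    en <- cumsum(r$lengths)
    st <- en - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(chrom = cc, start = st[keep], end = en[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  out
}

# close gaps of at most `gap` bp between runs, per chromosome
close_gaps <- function(df, gap) {
  if (nrow(df) < 2L) return(df)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  keep_row <- rep(TRUE, nrow(df))
  for (i in 2:nrow(df)) {
    j <- max(which(keep_row[1:(i - 1)]))
    if (df$chrom[i] == df$chrom[j] && df$start[i] - df$end[j] - 1L <= gap) {
      df$end[j] <- max(df$end[j], df$end[i])
      keep_row[i] <- FALSE
    }
  }
  df[keep_row, , drop = FALSE]
}

expect_same_regions <- function(gr, df) {
  got <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  got <- got[order(got$chrom, got$start), , drop = FALSE]
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(got) <- rownames(df) <- NULL
  expect_equal(got, df, ignore_attr = TRUE)
}

# all-pairs nearest gap distance (0 = overlap or touching, NA = no subject
# on the query's chromosome)
oracle_nearest <- function(q, s) {
  qc <- as.character(GenomeInfoDb::seqnames(q))
  qs <- GenomicRanges::start(q); qe <- GenomicRanges::end(q)
  sc <- as.character(GenomeInfoDb::seqnames(s))
  ss <- GenomicRanges::start(s); se <- GenomicRanges::end(s)
  vapply(seq_along(qc), function(i) {
    j <- which(sc == qc[i])
    if (!length(j)) return(NA_integer_)
    d <- pmax(0L, pmax(ss[j] - qe[i], qs[i] - se[j]) - 1L)
    min(d)
  }, integer(1))
}

# all-pairs overlap counts (>= 1 shared base)
oracle_counts <- function(q, s) {
  qc <- as.character(GenomeInfoDb::seqnames(q))
  qs <- GenomicRanges::start(q); qe <- GenomicRanges::end(q)
  sc <- as.character(GenomeInfoDb::seqnames(s))
  ss <- GenomicRanges::start(s); se <- GenomicRanges::end(s)
  vapply(seq_along(qc), function(i)
    sum(sc == qc[i] & ss <= qe[i] & qs[i] <= se), integer(1))
}

# random genome and random BED-coordinate region set for property tests
rand_genome <- function(max_len = 1e5) {
  k <- sample(1:3, 1)
  genome(stats::setNames(sample(1000:max_len, k), paste0("chr", seq_len(k))))
}

rand_region_df <- function(gn, n) {
  chrom <- sample(names(gn), n, replace = TRUE)
  len <- pmin(sample(1:5000, n, replace = TRUE), gn[chrom])
  start0 <- floor(stats::runif(n) * (gn[chrom] - len + 1))
  data.frame(chrom = chrom, start0 = start0, end0 = start0 + len,
             stringsAsFactors = FALSE)
}

# exact Mann-Whitney one-sided p by full enumeration of group assignments
mw_enum <- function(x, y, direction) {
  v <- c(x, y)
  n <- length(x)
  rk <- rank(v)
  combs <- utils::combn(length(v), n)
  wstat <- function(idx) sum(rk[idx]) - n * (n + 1) / 2
  wobs <- wstat(seq_len(n))
  wperm <- apply(combs, 2, wstat)
  if (direction == "greater") mean(wperm >= wobs) else mean(wperm <= wobs)
}
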