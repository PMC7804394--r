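#' Per-genotype THSs from two replicates
#'
#' The per-genotype set of Tn5 hypersensitive sites is the base-pair
#' intersection of the THSs called in the two replicates (a region must show
#' significant signal accumulation in both replicates), merged into disjoint
#' regions.
#'
#' @param rep1,rep2 Replicate peak sets (`GRanges`), e.g. from
#'   [read_narrowpeak()].
#' @return A disjoint sorted `GRanges`.
#' @export
replicate_consensus <- function(rep1, rep2) {
  merge_regions(intersect_regions(rep1, rep2))
}

#' @rdname replicate_consensus
#' @param reps List of replicate peak sets; exactly two are supported (the
#'   two-replicate design of the study); other counts raise an error.
#' @export
genotype_ths <- function(reps) {
  if (length(reps) != 2L)
    stop("genotype_ths supports exactly 2 replicates (got ", length(reps),
         "); extend replicate_consensus for other designs")
  replicate_consensus(reps[[1L]], reps[[2L]])
}

#' Merge per-genotype THSs into consensus THSs
#'
#' The consensus set is the merged union of the genotype THS sets; each
#' consensus region records which genotypes contributed an overlapping THS.
#'
#' @param genotype_ths Named list of per-genotype THS `GRanges`.
#' @return A disjoint `GRanges` with metadata columns `provenance`
#'   (comma-separated genotype names) and `n_genotypes`.
#' @export
build_consensus <- function(genotype_ths) {
  if (length(genotype_ths) == 0L) stop("no genotype THS sets given")
  if (is.null(names(genotype_ths)) || any(names(genotype_ths) == ""))
    stop("genotype THS list must be named")
  cons <- merge_regions(do.call(c, lapply(unname(genotype_ths),
                                          GenomicRanges::granges)))
  prov <- matrix(FALSE, length(cons), length(genotype_ths),
                 dimnames = list(NULL, names(genotype_ths)))
  for (g in names(genotype_ths))
    prov[, g] <- count_overlaps(cons, genotype_ths[[g]]) > 0L
  cons$provenance <- apply(prov, 1L, function(z)
    paste(colnames(prov)[z], collapse = ","))
  cons$n_genotypes <- rowSums(prov)
  cons
}

#' Region identifiers in chrom:start-end (BED coordinate) form
#' @param gr A `GRanges`.
#' @return Character vector of ids.
#' @export
region_ids <- function(gr) {
  paste0(as.character(GenomeInfoDb::seqnames(gr)), ":",
         GenomicRanges::start(gr) - 1L, "-", GenomicRanges::end(gr))
}

#' Accessibility (or mark) signal matrix over regions
#'
#' Rows are regions, columns samples; entries the length-weighted mean CPM of
#' each sample track over the region. Samples lacking a chromosome contribute
#' 0 there, with a warning.
#'
#' @param reg Region `GRanges` (e.g. consensus THSs).
#' @param tracks Named list of signal-track `GRanges` (one per sample).
#' @return Numeric matrix with `region_ids(reg)` rownames.
#' @export
build_matrix <- function(reg, tracks) {
  if (is.null(names(tracks)) || any(names(tracks) == ""))
    stop("tracks must be a named list (one name per sample)")
  m <- matrix(0, nrow = length(reg), ncol = length(tracks),
              dimnames = list(region_ids(reg), names(tracks)))
  want <- unique(as.character(GenomeInfoDb::seqnames(reg)))
  for (s in names(tracks)) {
    have <- unique(as.character(GenomeInfoDb::seqnames(tracks[[s]])))
    miss <- setdiff(want, have)
    if (length(miss))
      warning("sample ", s, " has no signal on ",
              paste(miss, collapse = ", "), "; treated as 0 CPM")
    m[, s] <- track_mean(tracks[[s]], reg)
  }
  m
}

#' Low-signal row filter
#'
#' Removes rows whose maximum across samples falls below the lower
#' `percentile` of the pooled entry distribution (linear-interpolation
#' percentile), the noise filter applied to both the accessibility and the
#' gene-mark matrices. Pass `threshold` to use a fixed CPM cutoff (e.g. 3)
#' instead of the percentile.
#'
#' @param m Non-empty numeric matrix.
#' @param percentile Lower percentile in `[0, 1]` (default 0.05).
#' @param threshold Optional fixed CPM threshold overriding the percentile.
#' @return The filtered matrix; attributes `threshold` (value used) and
#'   `kept` (logical over input rows). Warns if everything is removed.
#' @export
filter_matrix <- function(m, percentile = 0.05, threshold = NULL) {
  if (!is.matrix(m) || nrow(m) == 0L) stop("matrix must be non-empty")
  thr <- if (is.null(threshold))
    unname(stats::quantile(as.numeric(m), probs = percentile, type = 7))
  else threshold
  keep <- apply(m, 1L, max) >= thr
  if (!any(keep)) warning("low-signal filter removed every row")
  out <- m[keep, , drop = FALSE]
  attr(out, "threshold") <- thr
  attr(out, "kept") <- keep
  out
}

#' Per-genotype q-value confidence over consensus regions
#'
#' A genotype "q-passes" a consensus region when both of its replicate peak
#' sets contain an overlapping peak with q-value below `q_cut`.
#'
#' @param cons Consensus `GRanges`.
#' @param replicate_peaks Named list (per genotype) of lists of two replicate
#'   peak `GRanges`, each with a `qvalue` column.
#' @param q_cut q-value cutoff (default 0.05).
#' @return Logical matrix, regions x genotypes.
#' @export
consensus_qpass <- function(cons, replicate_peaks, q_cut = 0.05) {
  out <- matrix(FALSE, length(cons), length(replicate_peaks),
                dimnames = list(region_ids(cons), names(replicate_peaks)))
  for (g in names(replicate_peaks)) {
    passes <- lapply(replicate_peaks[[g]], function(pk) {
      if (is.null(pk$qvalue)) stop("replicate peaks need a qvalue column")
      count_overlaps(cons, pk[!is.na(pk$qvalue) & pk$qvalue < q_cut]) > 0L
    })
    out[, g] <- Reduce(`&`, passes)
  }
  out
}

#' Differential accessibility (or mark signal) between genotypes
#'
#' Moderated comparison of a test genotype against the reference (WT) on the
#' log2(CPM + pseudocount) scale; rows are called `increased`/`decreased` at
#' `p < p_cut` with no fold-change floor, otherwise `unchanged`.
#'
#' @param m Signal matrix (linear CPM).
#' @param cols_mut,cols_wt Column names/indices of the two groups.
#' @param p_cut Significance cutoff (default 0.05).
#' @inheritParams moderated_diff
#' @return data.frame with `log2fc`, `t`, `df`, `p` and `direction`.
#' @export
differential_accessibility <- function(m, cols_mut, cols_wt, p_cut = 0.05,
                                       d0 = 4, pseudocount = 0.5) {
  res <- moderated_diff(m, cols_mut, cols_wt, d0 = d0,
                        pseudocount = pseudocount)
  res$direction <- ifelse(res$p < p_cut & res$log2fc > 0, "increased",
                   ifelse(res$p < p_cut & res$log2fc < 0, "decreased",
                          "unchanged"))
  res
}

#' TSS positions of gene models
#' @param genes Gene-model `GRanges` (stranded).
#' @return Integer vector of 1-based TSS positions.
#' @export
tss_positions <- function(genes) {
  ifelse(as.character(GenomicRanges::strand(genes)) == "+",
         GenomicRanges::start(genes), GenomicRanges::end(genes))
}

#' Distribution of regions relative to gene TSSs
#'
#' Assigns each region (by its center) to one positional class relative to
#' its nearest gene: inside a gene body; upstream of the nearest TSS within
#' the configured distance windows (strand-aware, so "upstream" respects gene
#' orientation); beyond the largest upstream window; or downstream of the
#' gene (past its 3' end). Percentages sum to 100.
#'
#' @param reg Region `GRanges` (e.g. consensus THSs); must be non-empty.
#' @param genes Gene-model `GRanges`; must be non-empty.
#' @param upstream_edges Increasing upstream window edges in bp
#'   (default `c(1000, 3000)` giving 0-1 kb and 1-3 kb upstream classes).
#' @return data.frame with `bin`, `count`, `percent`.
#' @export
tss_distribution <- function(reg, genes, upstream_edges = c(1000, 3000)) {
  if (length(reg) == 0L) stop("empty region set")
  if (length(genes) == 0L) stop("no gene models")
  centers <- GenomicRanges::resize(GenomicRanges::granges(reg), width = 1L,
                                   fix = "center")
  in_body <- count_overlaps(centers, genes) > 0L
  al <- .align_seqlevels(centers, genes)
  hits <- GenomicRanges::distanceToNearest(al$a, al$b, select = "all",
                                           ignore.strand = TRUE)
  first <- !duplicated(S4Vectors::queryHits(hits))  # leftmost nearest gene
  qh <- S4Vectors::queryHits(hits)[first]
  sh <- S4Vectors::subjectHits(hits)[first]
  gene_tss <- tss_positions(genes)
  gene_str <- as.character(GenomicRanges::strand(genes))
  delta <- rep(NA_real_, length(reg))
  pos <- GenomicRanges::start(centers)[qh]
  delta[qh] <- ifelse(gene_str[sh] == "+",
                      pos - gene_tss[sh], gene_tss[sh] - pos)
  lab_up <- c(paste0("upstream_", c(0, utils::head(upstream_edges, -1)) / 1000,
                     "-", upstream_edges / 1000, "kb"),
              paste0("upstream_>", max(upstream_edges) / 1000, "kb"))
  bin <- character(length(reg))
  bin[in_body] <- "gene_body"
  up <- !in_body & !is.na(delta) & delta < 0
  d <- -delta
  cls <- findInterval(d, c(0, upstream_edges), left.open = TRUE)
  cls <- pmin(cls, length(lab_up))
  bin[up] <- lab_up[cls[up]]
  bin[!in_body & !is.na(delta) & delta >= 0] <- "downstream"
  bin[bin == ""] <- "unassigned"
  lv <- c(rev(lab_up), "gene_body", "downstream")
  counts <- table(factor(bin, levels = lv))
  data.frame(bin = names(counts), count = as.integer(counts),
             percent = 100 * as.integer(counts) / length(reg),
             row.names = NULL)
}

#' Strand-aware average signal profile around gene TSSs
#'
#' Mean CPM per position bin relative to the TSS, averaged over genes; minus-
#' strand genes are mirrored. Bins truncated by a chromosome edge are dropped
#' from their position's mean.
#'
#' @param track Signal-track `GRanges`.
#' @param genes Gene-model `GRanges` bound to a genome.
#' @param window Two integers, window around the TSS in bp (default
#'   `c(-2000, 2000)`).
#' @param binsize Bin width in bp; must divide the window span.
#' @return data.frame with bin start `pos` (bp relative to TSS) and
#'   `mean_cpm`.
#' @export
tss_profile <- function(track, genes, window = c(-2000, 2000), binsize = 100) {
  if (window[1] >= 0 || window[2] <= 0) stop("window must span the TSS")
  span <- window[2] - window[1]
  if (span %% binsize != 0) stop("binsize must divide the window span")
  nb <- span %/% binsize
  rel <- window[1] + (seq_len(nb) - 1L) * binsize
  tssp <- tss_positions(genes)
  strp <- as.character(GenomicRanges::strand(genes)) == "+"
  chr <- as.character(GenomeInfoDb::seqnames(genes))
  ng <- length(genes)
  rel_all <- rep(rel, times = ng)
  tss_all <- rep(tssp, each = nb)
  plus_all <- rep(strp, each = nb)
  chr_all <- rep(chr, each = nb)
  st <- ifelse(plus_all, tss_all + rel_all, tss_all - rel_all - binsize + 1L)
  en <- st + binsize - 1L
  lens <- GenomeInfoDb::seqlengths(genes)[chr_all]
  ok <- st >= 1L & !is.na(lens) & en <= lens
  gr <- GenomicRanges::GRanges(chr_all[ok],
                               IRanges::IRanges(st[ok], en[ok]))
  vals <- track_mean(track, gr)
  binidx <- rep(seq_len(nb), times = ng)[ok]
  mean_cpm <- tapply(vals, binidx, mean)
  out <- data.frame(pos = rel, mean_cpm = NA_real_)
  out$mean_cpm[as.integer(names(mean_cpm))] <- as.numeric(mean_cpm)
  out
}
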