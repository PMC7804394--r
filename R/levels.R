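#' Promoters and gene scopes
#'
#' The promoter is the `upstream` bp (default 750) immediately upstream of
#' the TSS, strand-aware and truncated at chromosome edges; the gene scope is
#' the union of gene body and promoter, the window used to associate peaks
#' and THSs with genes.
#'
#' @param genes Stranded gene-model `GRanges`.
#' @param upstream Promoter length in bp (default 750).
#' @return A `GRanges` parallel to `genes` (gene order and `gene_id` kept).
#' @export
gene_promoters <- function(genes, upstream = 750) {
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  gs <- GenomicRanges::start(genes)
  ge <- GenomicRanges::end(genes)
  st <- ifelse(plus, gs - upstream, ge + 1L)
  en <- ifelse(plus, gs - 1L, ge + upstream)
  # clamp at the chromosome edges (promoters may be truncated there)
  st <- pmax(st, 1L)
  lens <- GenomeInfoDb::seqlengths(genes)[
    as.character(GenomeInfoDb::seqnames(genes))]
  en <- ifelse(is.na(lens), en, pmin(en, lens))
  en <- pmax(en, st - 1L)  # fully truncated promoter -> zero width
  p <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                              IRanges::IRanges(st, en),
                              strand = GenomicRanges::strand(genes),
                              seqinfo = GenomeInfoDb::seqinfo(genes))
  S4Vectors::mcols(p) <- S4Vectors::mcols(genes)
  p
}

#' @rdname gene_promoters
#' @export
gene_scope <- function(genes, upstream = 750) {
  prom <- gene_promoters(genes, upstream)
  sc <- GenomicRanges::punion(GenomicRanges::granges(genes),
                              GenomicRanges::granges(prom), fill.gap = TRUE)
  sc$gene_id <- genes$gene_id
  sc
}

#' Associate peaks with genes via the body/promoter rule
#'
#' A gene is associated with every peak overlapping its gene body or its
#' promoter (750 bp upstream of the TSS by default).
#'
#' @param peaks Peak `GRanges`.
#' @param genes Gene-model `GRanges` with `gene_id`.
#' @param upstream Promoter length in bp.
#' @return Named list (only genes with >= 1 peak) of integer indices into
#'   `peaks`.
#' @export
assign_peaks_to_genes <- function(peaks, genes, upstream = 750) {
  sc <- gene_scope(genes, upstream)
  al <- .align_seqlevels(sc, peaks)
  hits <- GenomicRanges::findOverlaps(al$a, al$b, ignore.strand = TRUE)
  split(S4Vectors::subjectHits(hits),
        genes$gene_id[S4Vectors::queryHits(hits)])
}

#' Per-gene mark signal matrix
#'
#' For each gene with associated mark peaks, the signal in each sample is
#' the length-weighted mean CPM over the base-pair union of its peaks (each
#' base counted once). Apply [filter_matrix()] afterwards to drop low-signal
#' genes (the 3 CPM / lower 5th percentile rule).
#'
#' @param assignment Output of [assign_peaks_to_genes()].
#' @param peaks The peak `GRanges` the assignment indexes into.
#' @param tracks Named list of signal-track `GRanges` (one per sample).
#' @return Numeric matrix, genes x samples.
#' @export
gene_mark_table <- function(assignment, peaks, tracks) {
  if (length(assignment) == 0L) stop("empty gene-peak assignment")
  all_idx <- unlist(assignment, use.names = FALSE)
  grp <- rep(seq_along(assignment), times = lengths(assignment))
  pk <- GenomicRanges::granges(peaks)[all_idx]
  # one grouped reduce instead of a per-gene loop
  red <- GenomicRanges::reduce(
    GenomicRanges::split(pk, grp), ignore.strand = TRUE)
  flat <- unlist(red, use.names = FALSE)
  gidx <- as.integer(rep(names(red), times = lengths(red)))
  w <- GenomicRanges::width(flat)
  totw <- rowsum(as.numeric(w), gidx)[, 1L]
  m <- matrix(0, nrow = length(assignment), ncol = length(tracks),
              dimnames = list(names(assignment), names(tracks)))
  for (s in names(tracks)) {
    v <- track_mean(tracks[[s]], flat)
    m[, s] <- rowsum(v * w, gidx)[, 1L] / totw
  }
  m
}

#' Classify per-gene mark levels relative to WT
#'
#' The linear ratio mean(mutant)/mean(WT) is binned into percent-of-WT
#' classes (left-closed, right-open): `<20%`, `20-40%`, `40-60%`, `60-80%`,
#' `80-120%` (WT-like) and `>120%`. The log2 fold-change and moderated
#' p-value are carried along; the "<60% of WT" superset corresponds to
#' `log2fc <= log2(0.6) = -0.74` (2 decimals).
#'
#' @param m Gene x sample matrix of linear CPM.
#' @param cols_mut,cols_wt Column names/indices of mutant and WT samples.
#' @param breaks Ratio bin edges (default `c(0, .2, .4, .6, .8, 1.2, Inf)`).
#' @inheritParams moderated_diff
#' @return data.frame with `gene`, `ratio`, `log2fc`, `p`, `bin`. Genes with
#'   WT mean 0 are excluded; their ids are in attribute `unclassifiable`.
#' @export
classify_levels <- function(m, cols_mut, cols_wt,
                            breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1.2, Inf),
                            d0 = 4, pseudocount = 0.5) {
  wt_mean <- rowMeans(m[, cols_wt, drop = FALSE])
  mut_mean <- rowMeans(m[, cols_mut, drop = FALSE])
  bad <- wt_mean == 0
  if (any(bad))
    warning(sum(bad), " gene(s) with zero WT signal excluded from level",
            " classification")
  mm <- m[!bad, , drop = FALSE]
  ratio <- mut_mean[!bad] / wt_mean[!bad]
  labs <- .ratio_bin_labels(breaks)
  bin <- labs[findInterval(ratio, breaks, left.open = FALSE,
                           rightmost.closed = FALSE)]
  md <- moderated_diff(mm, cols_mut, cols_wt, d0 = d0,
                       pseudocount = pseudocount)
  out <- data.frame(gene = rownames(mm), ratio = ratio,
                    log2fc = log2(ratio), p = md$p,
                    bin = factor(bin, levels = labs), row.names = NULL)
  attr(out, "unclassifiable") <- rownames(m)[bad]
  out
}

.ratio_bin_labels <- function(breaks) {
  pct <- function(x) paste0(round(100 * x), "%")
  n <- length(breaks) - 1L
  labs <- character(n)
  labs[1L] <- paste0("<", pct(breaks[2L]))
  labs[n] <- paste0(">", pct(breaks[n]))
  if (n > 2L)
    for (i in 2L:(n - 1L))
      labs[i] <- paste0(round(100 * breaks[i]), "-", pct(breaks[i + 1L]))
  labs
}

#' Polycomb mark categories of genes
#'
#' A gene carries a mark when it is associated (body/promoter rule) with a
#' peak of that mark in any of the provided WT datasets; the two booleans
#' define the partition only-H2AK121ub / H2AK121ub+H3K27me3 / only-H3K27me3 /
#' non-PcG.
#'
#' @param h2a_wt List of WT H2AK121ub peak `GRanges` (>= 1 dataset).
#' @param k27_wt List of WT H3K27me3 peak `GRanges` (>= 1 dataset).
#' @param genes Gene-model `GRanges` with `gene_id`.
#' @param upstream Promoter length in bp.
#' @return data.frame with `gene`, `category` (factor).
#' @export
mark_categories <- function(h2a_wt, k27_wt, genes, upstream = 750) {
  if (!length(h2a_wt) || !length(k27_wt))
    stop("need >= 1 WT dataset per mark")
  marked <- function(peaksets) {
    Reduce(`|`, lapply(peaksets, function(pk)
      genes$gene_id %in% names(assign_peaks_to_genes(pk, genes, upstream))))
  }
  a <- marked(h2a_wt)
  k <- marked(k27_wt)
  lv <- c("only-H2AK121ub", "H2AK121ub/H3K27me3", "only-H3K27me3", "non-PcG")
  cat <- ifelse(a & k, lv[2L], ifelse(a, lv[1L], ifelse(k, lv[3L], lv[4L])))
  data.frame(gene = genes$gene_id, category = factor(cat, levels = lv),
             row.names = NULL)
}

#' Differential expression classification
#'
#' Moderated comparison of mutant versus WT expression; genes are `activated`
#' when log2FC >= `log2fc_cut` with p < `p_cut`, `repressed` when log2FC <=
#' -`log2fc_cut` with p < `p_cut`, otherwise `unaltered` (fold-change
#' boundary inclusive, p strictly below the cutoff).
#'
#' @param expr Gene x sample expression matrix (FPKM-like, linear).
#' @param cols_mut,cols_wt Column names/indices of the two groups.
#' @param log2fc_cut Fold-change cutoff (default 1).
#' @param p_cut p-value cutoff (default 0.05).
#' @inheritParams moderated_diff
#' @return data.frame with `gene`, `log2fc`, `p`, `class`.
#' @export
classify_expression <- function(expr, cols_mut, cols_wt, log2fc_cut = 1,
                                p_cut = 0.05, d0 = 4, pseudocount = 0.5) {
  md <- moderated_diff(expr, cols_mut, cols_wt, d0 = d0,
                       pseudocount = pseudocount)
  cls <- ifelse(md$p < p_cut & md$log2fc >= log2fc_cut, "activated",
         ifelse(md$p < p_cut & md$log2fc <= -log2fc_cut, "repressed",
                "unaltered"))
  data.frame(gene = rownames(expr), log2fc = md$log2fc, p = md$p,
             class = factor(cls,
                            levels = c("activated", "unaltered", "repressed")),
             row.names = NULL)
}
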