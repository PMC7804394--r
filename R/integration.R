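#' Pair genes with consensus THSs and summarise accessibility per gene
#'
#' A gene is paired with every consensus THS overlapping its gene body or
#' promoter (same 750 bp rule as peak assignment). The per-gene accessibility
#' signal in each sample is the mean of the accessibility-matrix rows of its
#' paired THSs; genes with no paired THS are excluded and tallied.
#'
#' @param genes Gene-model `GRanges` with `gene_id`.
#' @param cons Consensus THS `GRanges` (rows of `acc_matrix`, same order).
#' @param acc_matrix Accessibility matrix over `cons` (regions x samples).
#' @param upstream Promoter length in bp.
#' @return List with `matrix` (gene x sample), `pairs` (named list of THS row
#'   indices per gene) and `n_unpaired`.
#' @export
gene_ths_pairing <- function(genes, cons, acc_matrix, upstream = 750) {
  if (length(cons) != nrow(acc_matrix))
    stop("acc_matrix rows must correspond to cons regions")
  sc <- gene_scope(genes, upstream)
  al <- .align_seqlevels(sc, cons)
  hits <- GenomicRanges::findOverlaps(al$a, al$b, ignore.strand = TRUE)
  pairs <- split(S4Vectors::subjectHits(hits),
                 genes$gene_id[S4Vectors::queryHits(hits)])
  m <- t(vapply(pairs, function(idx)
    colMeans(acc_matrix[idx, , drop = FALSE]),
    numeric(ncol(acc_matrix))))
  colnames(m) <- colnames(acc_matrix)
  list(matrix = m, pairs = pairs,
       n_unpaired = length(genes) - length(pairs))
}

#' Cross-tabulate mark loss, accessibility change and expression change
#'
#' Restricts to the genes of one Polycomb mark category whose mark level in
#' the mutant is below `ratio_cut` of WT (the "<60%" subset, log2FC <=
#' log2(0.6)) and whose accessibility changed significantly, then
#' cross-tabulates accessibility direction (increased/decreased) against
#' expression class (activated/unaltered/repressed). The six percentages sum
#' to 100 of the restricted set.
#'
#' @param levels_df Output of [classify_levels()] for the mutant and mark.
#' @param access_df Output of [differential_accessibility()] on the per-gene
#'   accessibility matrix (rownames = gene ids).
#' @param expr_df Output of [classify_expression()] for the mutant.
#' @param categories_df Output of [mark_categories()].
#' @param category Category to restrict to (e.g. `"only-H2AK121ub"`), or
#'   `NULL` for all marked categories pooled.
#' @param ratio_cut Mark-level restriction (default 0.6).
#' @return List with `counts` and `percent` (2 x 3 matrices, direction x
#'   expression class), `n` (restricted genes) and `excluded` (tally of genes
#'   dropped at each restriction step).
#' @export
integration_table <- function(levels_df, access_df, expr_df, categories_df,
                              category = NULL, ratio_cut = 0.6) {
  genes0 <- Reduce(intersect, list(levels_df$gene, rownames(access_df),
                                   expr_df$gene, categories_df$gene))
  cat_of <- stats::setNames(as.character(categories_df$category),
                            categories_df$gene)
  g <- genes0
  excl <- c(not_in_all_layers = NA_integer_, wrong_category = 0L,
            level_not_reduced = 0L, accessibility_unchanged = 0L)
  excl["not_in_all_layers"] <-
    length(unique(c(levels_df$gene, expr_df$gene, categories_df$gene))) -
    length(genes0)
  if (!is.null(category)) {
    keep <- cat_of[g] == category
    excl["wrong_category"] <- sum(!keep)
    g <- g[keep]
  }
  ratio <- stats::setNames(levels_df$ratio, levels_df$gene)[g]
  keep <- !is.na(ratio) & ratio < ratio_cut
  excl["level_not_reduced"] <- sum(!keep)
  g <- g[keep]
  dir_of <- stats::setNames(access_df$direction, rownames(access_df))[g]
  keep <- dir_of != "unchanged"
  excl["accessibility_unchanged"] <- sum(!keep)
  g <- g[keep]
  dirs <- c("increased", "decreased")
  cls <- c("activated", "unaltered", "repressed")
  expr_of <- stats::setNames(as.character(expr_df$class), expr_df$gene)[g]
  counts <- table(factor(dir_of[g], levels = dirs),
                  factor(expr_of, levels = cls))
  counts <- matrix(as.integer(counts), 2L, 3L, dimnames = list(dirs, cls))
  if (length(g) == 0L)
    warning("no genes left after restriction; table of zeros")
  pct <- if (length(g)) 100 * counts / length(g) else counts * 0
  list(counts = counts, percent = pct, n = length(g), excluded = excl)
}

#' Per-gene table for accessibility-vs-mark-level scatter plots
#'
#' One row per gene carrying the mark-level log2FC, the accessibility log2FC
#' and the expression class; genes missing any of the three layers are
#' excluded and tallied.
#'
#' @inheritParams integration_table
#' @return data.frame with `gene`, `level_log2fc`, `access_log2fc`,
#'   `expression`; attribute `n_excluded`.
#' @export
scatter_table <- function(levels_df, access_df, expr_df) {
  g <- Reduce(intersect, list(levels_df$gene, rownames(access_df),
                              expr_df$gene))
  all_g <- unique(c(levels_df$gene, rownames(access_df), expr_df$gene))
  out <- data.frame(
    gene = g,
    level_log2fc = stats::setNames(levels_df$log2fc, levels_df$gene)[g],
    access_log2fc = stats::setNames(access_df$log2fc,
                                    rownames(access_df))[g],
    expression = stats::setNames(as.character(expr_df$class),
                                 expr_df$gene)[g],
    row.names = NULL)
  attr(out, "n_excluded") <- length(all_g) - length(g)
  out
}

#' Mean signal in a window around each gene's TSS
#'
#' The per-gene scalar compared between mark-level groups in
#' [profile_group_test()].
#'
#' @param track Signal-track `GRanges`.
#' @param genes Gene-model `GRanges` with `gene_id`.
#' @param window Window around the TSS in bp (default `c(-500, 500)`).
#' @return Named numeric vector (gene ids).
#' @export
tss_window_means <- function(track, genes, window = c(-500, 500)) {
  tssp <- tss_positions(genes)
  st <- pmax(tssp + window[1], 1L)
  en <- tssp + window[2] - 1L
  lens <- GenomeInfoDb::seqlengths(genes)[
    as.character(GenomeInfoDb::seqnames(genes))]
  en <- ifelse(is.na(lens), en, pmin(en, lens))
  gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                               IRanges::IRanges(st, en))
  stats::setNames(track_mean(track, gr), genes$gene_id)
}
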