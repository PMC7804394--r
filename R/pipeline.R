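#' Simulate a complete synthetic study
#'
#' Generates every layer of a coherent synthetic PcG study from one spec and
#' one seed: genome, gene models, per-gene Polycomb mark categories, WT mark
#' peak sets (two datasets per mark), per-gene mark matrices with planted
#' percent-of-WT multipliers per mutant, mark signal tracks, true THSs
#' (placed preferentially at promoters of marked genes), two ATAC replicates
#' per genotype, accessibility tracks in which THSs of genes that lost a
#' mark (multiplier < 0.6) gain accessibility in that mutant, TF-binding
#' sites with a planted enrichment factor, expression with planted coupling
#' ("mark loss" genes are activated with probability `frac_up_given_loss`,
#' otherwise unaltered), and a blacklist placed away from all features.
#'
#' @param spec A [sim_spec()].
#' @param seed Integer seed; the dataset is a pure function of (spec, seed).
#' @return A list of class `sim_dataset` with components `genome`, `genes`,
#'   `categories`, `mark_peaks_wt`, `gene_mark`, `mark_tracks`, `ths`,
#'   `replicate_peaks`, `acc_tracks`, `tfbs`, `expression`, `blacklist` and
#'   `truth` (planted multipliers, mark-loss matrix, expression classes).
#' @export
simulate_dataset <- function(spec, seed) {
  gn <- simulate_genome(spec)
  genes <- simulate_genes(spec, gn, seed)
  mutants <- setdiff(spec$genotypes, "WT")
  ng <- length(genes)

  categories <- withr::with_seed(.stage_seed(seed, "categories"), {
    lv <- names(spec$category_probs)
    factor(sample(lv, ng, replace = TRUE, prob = spec$category_probs),
           levels = lv)
  })
  has_h2a <- categories %in% c("only-H2AK121ub", "H2AK121ub/H3K27me3")
  has_k27 <- categories %in% c("only-H3K27me3", "H2AK121ub/H3K27me3")
  carriers <- list(H2AK121ub = has_h2a, H3K27me3 = has_k27)

  # WT mark peaks at marked genes: H2AK121ub around the TSS, H3K27me3 over
  # the gene body; the second WT dataset is an edge-jittered copy
  mark_peaks_wt <- withr::with_seed(.stage_seed(seed, "wtpeaks"), {
    tssp <- tss_positions(genes)
    lens <- gn[as.character(GenomeInfoDb::seqnames(genes))]
    mk_pk <- function(st, en, sel) {
      st <- pmax(st, 1L)[sel]; en <- pmin(en, lens)[sel]
      pk <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes)[sel],
                                   IRanges::IRanges(st, en))
      pk$gene_id <- genes$gene_id[sel]
      pk$qvalue <- stats::runif(length(pk), spec$qvalue_range[1],
                                spec$qvalue_range[2])
      bind_genome(pk, gn)
    }
    jitter_pk <- function(pk) {
      d <- round(stats::rnorm(length(pk), 0, 30))
      GenomicRanges::start(pk) <- pmax(GenomicRanges::start(pk) + d, 1L)
      GenomicRanges::end(pk) <- pmax(GenomicRanges::end(pk) +
                                       round(stats::rnorm(length(pk), 0, 30)),
                                     GenomicRanges::start(pk))
      pk
    }
    wh2a <- round(exp(spec$marks$H2AK121ub$len_meanlog))
    h2a1 <- mk_pk(tssp - wh2a %/% 2, tssp + wh2a %/% 2, has_h2a)
    k27_1 <- mk_pk(GenomicRanges::start(genes) - 250L,
                   GenomicRanges::end(genes) + 250L, has_k27)
    list(H2AK121ub = list(ds1 = h2a1, ds2 = jitter_pk(h2a1)),
         H3K27me3 = list(ds1 = k27_1, ds2 = jitter_pk(k27_1)))
  })

  # planted percent-of-WT multipliers, gene x mutant, per mark
  gene_mark <- list(); mark_tracks <- list()
  mult <- list()
  for (mi in seq_along(carriers)) {
    mk <- names(carriers)[mi]
    ids <- genes$gene_id[carriers[[mk]]]
    sim <- simulate_gene_mark_matrix(spec, ids, genotypes = mutants,
                                     seed = seed + 101L * mi)
    gene_mark[[mk]] <- sim
    mult[[mk]] <- as.matrix(sim$truth[paste0("multiplier_", mutants)])
    dimnames(mult[[mk]]) <- list(ids, mutants)
    seg <- mark_peaks_wt[[mk]]$ds1
    tr <- list()
    for (cn in colnames(sim$matrix)) {
      s <- seg
      s$score <- sim$matrix[s$gene_id, cn]
      s$gene_id <- NULL; s$qvalue <- NULL
      tr[[cn]] <- fill_track(s, background = 0.05)
    }
    mark_tracks[[mk]] <- tr
  }

  # mark loss per gene per mutant: any carried mark with multiplier < 0.6
  loss <- matrix(FALSE, ng, length(mutants),
                 dimnames = list(genes$gene_id, mutants))
  for (mk in names(mult))
    loss[rownames(mult[[mk]]), ] <- loss[rownames(mult[[mk]]), ] |
      (mult[[mk]] < 0.6)

  weights <- ifelse(categories == "non-PcG", 1, 4)
  ths <- simulate_ths(spec, gn, genes, gene_weights = weights, seed = seed)

  acc_mult <- matrix(1, length(ths), length(spec$genotypes),
                     dimnames = list(NULL, spec$genotypes))
  linked <- !is.na(ths$gene_id)
  for (g in mutants)
    acc_mult[linked, g] <-
      ifelse(loss[ths$gene_id[linked], g], spec$access_up, 1)

  replicate_peaks <- simulate_ths_replicates(spec, ths, gn, seed)
  acc_tracks <- simulate_signal_tracks(spec, ths, gn, multipliers = acc_mult,
                                       seed = seed)
  tfbs <- simulate_tfbs(spec, ths, gn, seed = seed)

  de_class <- withr::with_seed(.stage_seed(seed, "declass"), {
    dc <- matrix("unaltered", ng, length(mutants),
                 dimnames = list(genes$gene_id, mutants))
    for (g in mutants) {
      up <- loss[, g] & stats::runif(ng) < spec$frac_up_given_loss
      dc[up, g] <- "activated"
      u <- stats::runif(ng)
      bg_up <- !loss[, g] & u < spec$de_frac / 2
      bg_dn <- !loss[, g] & u >= spec$de_frac / 2 & u < spec$de_frac
      dc[bg_up, g] <- "activated"
      dc[bg_dn, g] <- "repressed"
    }
    dc
  })
  expression <- simulate_expression(spec, genes$gene_id, genotypes = mutants,
                                    de_class = de_class, seed = seed)

  blacklist <- withr::with_seed(.stage_seed(seed, "blacklist"), {
    avoid <- merge_regions(c(GenomicRanges::granges(ths),
                             GenomicRanges::granges(genes)), gap = 3000)
    .sample_positions(gn, rep(spec$blacklist_len, spec$n_blacklist),
                      exclude = avoid)
  })

  structure(list(
    spec = spec, seed = seed, genome = gn, genes = genes,
    categories = data.frame(gene = genes$gene_id, category = categories),
    mark_peaks_wt = mark_peaks_wt, gene_mark = gene_mark,
    mark_tracks = mark_tracks, ths = ths,
    replicate_peaks = replicate_peaks, acc_tracks = acc_tracks,
    tfbs = tfbs, expression = expression, blacklist = blacklist,
    truth = list(multipliers = mult, loss = loss, de_class = de_class,
                 acc_mult = acc_mult)),
    class = "sim_dataset")
}

#' Default analysis parameters of the pipeline
#' @return Named list of thresholds (q cutoff, signal percentile, promoter
#'   bp, DE cutoffs, Monte Carlo set count, distance edges, etc.).
#' @export
default_params <- function() {
  list(q_cut = 0.05, signal_percentile = 0.05, promoter_bp = 750,
       de_log2fc = 1, de_p = 0.05, p_cut = 0.05, d0 = 4, pseudocount = 0.5,
       mc_sets = 1000, dist_edges = c(0, 100, 500, 1000, 2000),
       coloc_d = 2000, ratio_cut = 0.6, tss_window = c(-500, 500))
}

#' Run the full integrative pipeline on a (synthetic or loaded) dataset
#'
#' Executes every stage in order: blacklist-aware per-genotype replicate
#' intersection, consensus construction with signal and q-value filters,
#' TSS distribution, mark distance-interval association and co-localization,
#' Monte Carlo TFBS enrichment, per-gene mark quantification and
#' percent-of-WT classification, mark categories, expression classification,
#' gene-THS pairing with per-gene differential accessibility, profile-group
#' rank tests, and the marks/accessibility/expression integration tables.
#'
#' @param data A `sim_dataset` (or an equivalently shaped list loaded from
#'   files).
#' @param params Analysis parameters; see [default_params()].
#' @param seed Integer seed for the Monte Carlo stage.
#' @return A list of stage results (see the README walk-through).
#' @export
run_pipeline <- function(data, params = default_params(), seed = 1L) {
  p <- utils::modifyList(default_params(), params)
  gts <- names(data$replicate_peaks)
  mutants <- setdiff(gts, "WT")

  gts_ths <- lapply(data$replicate_peaks, function(reps)
    subtract_regions(genotype_ths(reps), data$blacklist))
  cons <- build_consensus(gts_ths)
  acc <- build_matrix(cons, data$acc_tracks)
  qp <- consensus_qpass(cons, data$replicate_peaks, q_cut = p$q_cut)
  accf <- filter_matrix(acc, percentile = p$signal_percentile)
  keep <- attr(accf, "kept") & rowSums(qp) >= 1L
  consensus <- cons[keep]
  acc_matrix <- acc[keep, , drop = FALSE]

  tssdist <- tss_distribution(consensus, data$genes)
  assoc <- lapply(data$mark_peaks_wt, function(mk)
    distance_bin_percentages(consensus,
                             merge_regions(c(GenomicRanges::granges(mk$ds1),
                                             GenomicRanges::granges(mk$ds2))),
                             edges = p$dist_edges))
  venn <- colocalization_venn(
    consensus,
    merge_regions(c(GenomicRanges::granges(data$mark_peaks_wt$H2AK121ub$ds1),
                    GenomicRanges::granges(data$mark_peaks_wt$H2AK121ub$ds2))),
    merge_regions(c(GenomicRanges::granges(data$mark_peaks_wt$H3K27me3$ds1),
                    GenomicRanges::granges(data$mark_peaks_wt$H3K27me3$ds2))),
    d = p$coloc_d)
  enrich <- mc_enrichment_test(consensus, data$tfbs, data$genome,
                               n_sets = p$mc_sets, seed = seed,
                               exclude = data$blacklist)

  # per-gene mark levels: assignment via WT peaks, signal from mark tracks
  marklevels <- list()
  for (mk in names(data$mark_peaks_wt)) {
    pk <- c(GenomicRanges::granges(data$mark_peaks_wt[[mk]]$ds1),
            GenomicRanges::granges(data$mark_peaks_wt[[mk]]$ds2))
    asn <- assign_peaks_to_genes(pk, data$genes, upstream = p$promoter_bp)
    tab <- gene_mark_table(asn, pk, data$mark_tracks[[mk]])
    tabf <- filter_matrix(tab, percentile = p$signal_percentile)
    lv <- lapply(mutants, function(g)
      classify_levels(tabf, cols_mut = grep(paste0("^", g, "_r"),
                                            colnames(tabf), value = TRUE),
                      cols_wt = grep("^WT_r", colnames(tabf), value = TRUE),
                      d0 = p$d0, pseudocount = p$pseudocount))
    names(lv) <- mutants
    marklevels[[mk]] <- list(table = tabf, levels = lv)
  }

  categories <- mark_categories(
    h2a_wt = data$mark_peaks_wt$H2AK121ub,
    k27_wt = data$mark_peaks_wt$H3K27me3,
    genes = data$genes, upstream = p$promoter_bp)

  expr <- lapply(mutants, function(g)
    classify_expression(data$expression$matrix,
                        cols_mut = grep(paste0("^", g, "_r"),
                                        colnames(data$expression$matrix),
                                        value = TRUE),
                        cols_wt = grep("^WT_r",
                                       colnames(data$expression$matrix),
                                       value = TRUE),
                        log2fc_cut = p$de_log2fc, p_cut = p$de_p,
                        d0 = p$d0, pseudocount = p$pseudocount))
  names(expr) <- mutants

  pairing <- gene_ths_pairing(data$genes, consensus, acc_matrix,
                              upstream = p$promoter_bp)
  acc_gene <- lapply(mutants, function(g)
    differential_accessibility(pairing$matrix,
                               cols_mut = paste0(g, "_r", 1:2),
                               cols_wt = paste0("WT_r", 1:2),
                               p_cut = p$p_cut, d0 = p$d0,
                               pseudocount = p$pseudocount))
  names(acc_gene) <- mutants

  integration <- list(); group_tests <- list()
  for (mk in names(marklevels)) {
    integration[[mk]] <- list(); group_tests[[mk]] <- list()
    for (g in mutants) {
      integration[[mk]][[g]] <- integration_table(
        marklevels[[mk]]$levels[[g]], acc_gene[[g]], expr[[g]], categories,
        category = NULL, ratio_cut = p$ratio_cut)
      lv <- marklevels[[mk]]$levels[[g]]
      wm <- tss_window_means(data$acc_tracks[[paste0(g, "_r1")]], data$genes,
                             window = p$tss_window)
      low <- lv$gene[lv$ratio < p$ratio_cut]
      wtl <- lv$gene[lv$bin == "80-120%"]
      group_tests[[mk]][[g]] <-
        if (length(low) && length(wtl))
          profile_group_test(wm[low], wm[wtl], direction = "greater")
        else NULL
    }
  }

  list(params = p, seed = seed, genotype_ths = gts_ths,
       consensus = consensus, acc_matrix = acc_matrix,
       signal_threshold = attr(accf, "threshold"),
       tss_distribution = tssdist, association = assoc, venn = venn,
       enrichment = enrich, marklevels = marklevels,
       categories = categories, expression = expr, pairing = pairing,
       accessibility_gene = acc_gene, integration = integration,
       group_tests = group_tests)
}

#' Write the main pipeline result tables as TSV files
#'
#' @param res Result of [run_pipeline()].
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outdir, ...)
  write_bed(res$consensus, fp("consensus_ths.bed"))
  write_matrix_tsv(res$acc_matrix, fp("accessibility_matrix.tsv"))
  utils::write.table(res$tss_distribution, fp("tss_distribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (mk in names(res$association)) {
    utils::write.table(res$association[[mk]]$bins,
                       fp(paste0("distance_bins_", mk, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  venn_df <- data.frame(cell = names(res$venn$counts),
                        count = as.integer(res$venn$counts))
  utils::write.table(venn_df, fp("colocalization_venn.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  enr <- res$enrichment
  utils::write.table(
    data.frame(observed = enr$observed, enrichment = enr$enrichment,
               p = enr$p, n_sets = enr$n_sets, seed = enr$seed),
    fp("tfbs_enrichment.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  for (mk in names(res$marklevels))
    for (g in names(res$marklevels[[mk]]$levels))
      utils::write.table(res$marklevels[[mk]]$levels[[g]],
                         fp(paste0("levels_", mk, "_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$categories, fp("mark_categories.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (g in names(res$expression))
    utils::write.table(res$expression[[g]],
                       fp(paste0("expression_", g, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  for (mk in names(res$integration))
    for (g in names(res$integration[[mk]])) {
      it <- res$integration[[mk]][[g]]
      df <- data.frame(direction = rep(rownames(it$counts), 3),
                       expression = rep(colnames(it$counts), each = 2),
                       count = as.integer(it$counts),
                       percent = as.numeric(it$percent))
      utils::write.table(df, fp(paste0("integration_", mk, "_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  invisible(outdir)
}

#' Default run configuration (simulation-driven)
#' @return Named list mirroring the YAML config consumed by the CLI.
#' @export
default_config <- function() {
  c(list(seed = 1L, outdir = "pcgaccess_out",
         sim = list(n_genes = 400, n_ths = 400,
                    chrom_sizes = stats::setNames(rep(8e5, 5),
                                                  paste0("chr", 1:5)))),
    default_params())
}
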