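#' Specification of a synthetic Polycomb accessibility study
#'
#' Bundles every tunable of the synthetic-data generator with defaults that
#' emulate the downstream products of an Arabidopsis PcG-mutant study at
#' desk scale: a 5-chromosome 10 Mb genome, ~1 THS per 10 kb, two ATAC
#' replicates per genotype with boundary jitter and drop-outs, CPM signal
#' tracks, H2AK121ub/H3K27me3 peak structure (H3K27me3 domains longer than
#' H2AK121ub, proximity fractions mirroring the reported 50%/80%/40%/96%
#' figures), TF-binding-site sets with a planted enrichment factor, per-gene
#' mark levels at controlled fractions of WT, and expression with planted
#' differential effects.
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(...) {
  spec <- list(
    # genome & genes
    chrom_sizes = stats::setNames(rep(2e6, 5), paste0("chr", 1:5)),
    n_genes = 1000,
    gene_len = 1500,
    promoter_bp = 750,
    # THSs
    n_ths = 1000,
    ths_len_meanlog = log(300), ths_len_sdlog = 0.4,
    ths_len_range = c(100, 3000),
    ths_promoter_frac = 0.7,
    ths_promoter_offset = 300,   # THS center this many bp upstream of TSS
    ths_margin = 5000,
    # ATAC replicates
    rep_jitter_sd = 20, rep_dropout = 0.05,
    qvalue_range = c(1e-8, 0.04),
    # accessibility signal
    base_cpm = 8, background_cpm = 0.5, track_noise_sd = 0.1,
    genotypes = c("WT", "bmi1abc", "clf28swn7", "emf1-2"),
    access_up = 1.8,             # at THSs of mark-loss genes in that mutant
    # gene mark categories (fractions of all genes)
    category_probs = c("only-H2AK121ub" = 0.15,
                       "H2AK121ub/H3K27me3" = 0.20,
                       "only-H3K27me3" = 0.10,
                       "non-PcG" = 0.55),
    # THS-centric mark distance structure (Fig 2b/c style planting);
    # bins are {overlap, (0,100], (100,500], (500,1000], (1000,2000]} bp,
    # remaining mass = no nearby peak
    marks = list(
      H2AK121ub = list(bin_probs = c(0.30, 0.20, 0.12, 0.08, 0.10),
                       len_meanlog = log(500), len_sdlog = 0.3),
      H3K27me3 = list(bin_probs = c(0.12, 0.08, 0.06, 0.06, 0.08),
                      len_meanlog = log(2000), len_sdlog = 0.3,
                      coloc_with = "H2AK121ub", coloc_share = 0.96)),
    mark_bin_edges = c(0, 100, 500, 1000, 2000),
    # TFBS
    n_tfbs = 10000, tfbs_width = 200, tfbs_factor = 5,
    # gene-level mark signal
    wt_mark_meanlog = log(10), wt_mark_sdlog = 0.5,
    level_multipliers = c(0.1, 0.3, 0.5, 0.7, 1.0, 1.5),
    level_probs = c(0.10, 0.15, 0.15, 0.10, 0.40, 0.10),
    mark_reps = 2, mark_noise_sd = 0.1, mark_noise_df = Inf,
    # expression
    expr_meanlog = log(20), expr_sdlog = 1,
    expr_reps = 3, expr_noise_sd = 0.2,
    de_effect = 2, de_frac = 0.05,
    frac_up_given_loss = 0.4,    # activated fraction among mark-loss genes
    # blacklist
    n_blacklist = 10, blacklist_len = 1000)
  over <- list(...)
  unknown <- setdiff(names(over), names(spec))
  if (length(unknown)) stop("unknown sim_spec field: ", unknown[1L])
  spec[names(over)] <- over
  structure(spec, class = "sim_spec")
}

# distinct, reproducible sub-streams per generator stage
.stage_seed <- function(seed, tag) {
  (abs(seed) %% 1000003L) * 1009L + sum(utf8ToInt(tag)) %% 1009L
}

#' Simulate a genome
#' @param spec A [sim_spec()].
#' @return A `genome` with the spec's chromosome sizes.
#' @export
simulate_genome <- function(spec) genome(spec$chrom_sizes)

#' Simulate gene models on a regular layout
#'
#' Genes of fixed length are laid out on per-chromosome grids (count
#' proportional to chromosome length) with random strands, leaving room for
#' promoters and upstream THSs between neighbours.
#'
#' @param spec A [sim_spec()].
#' @param gn A `genome`.
#' @param seed Integer seed.
#' @return Gene-model `GRanges` with `gene_id`, bound to `gn`.
#' @export
simulate_genes <- function(spec, gn, seed) {
  withr::with_seed(.stage_seed(seed, "genes"), {
    L <- as.numeric(gn)
    n_per <- round(spec$n_genes * L / sum(L))
    n_per[length(n_per)] <- spec$n_genes - sum(utils::head(n_per, -1))
    chrom <- rep(names(gn), n_per)
    slot <- unlist(lapply(seq_along(L), function(i) {
      usable <- L[i] - 2 * spec$ths_margin
      if (usable < n_per[i] * (spec$gene_len + 2 * spec$promoter_bp))
        stop("genome too small for ", n_per[i], " genes on ", names(gn)[i])
      w <- floor(usable / max(n_per[i], 1L))
      spec$ths_margin + (seq_len(n_per[i]) - 1) * w + floor(w / 2)
    }))
    strand <- sample(c("+", "-"), spec$n_genes, replace = TRUE)
    gr <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = slot, width = spec$gene_len),
      strand = strand)
    gr$gene_id <- sprintf("gene%04d", seq_len(spec$n_genes))
    bind_genome(gr, gn)
  })
}

#' Simulate true THS locations
#'
#' THS lengths are log-normal (clamped to `ths_len_range`); a configurable
#' fraction sits in gene promoters (center ~`ths_promoter_offset` bp upstream
#' of the TSS of distinct genes, PcG-marked genes preferred when
#' `gene_weights` are given), the rest is placed uniformly away from genes.
#' THSs are disjoint by construction.
#'
#' @param spec A [sim_spec()].
#' @param gn A `genome`.
#' @param genes Optional gene models; without them all THSs are intergenic.
#' @param gene_weights Optional per-gene sampling weights for promoter THSs.
#' @param seed Integer seed.
#' @return THS `GRanges` with `ths_id` and `gene_id` (NA when unlinked).
#' @export
simulate_ths <- function(spec, gn, genes = NULL, gene_weights = NULL, seed) {
  withr::with_seed(.stage_seed(seed, "ths"), {
    n <- spec$n_ths
    len <- round(stats::rlnorm(n, spec$ths_len_meanlog, spec$ths_len_sdlog))
    len <- pmin(pmax(len, spec$ths_len_range[1]), spec$ths_len_range[2])
    chrom <- character(n); start0 <- numeric(n); link <- rep(NA_character_, n)
    n_prom <- if (is.null(genes)) 0L else
      min(round(spec$ths_promoter_frac * n), length(genes))
    if (n_prom > 0L) {
      pick <- sample(seq_along(genes), n_prom, prob = gene_weights)
      tssp <- tss_positions(genes)[pick]
      plus <- as.character(GenomicRanges::strand(genes))[pick] == "+"
      center <- ifelse(plus, tssp - spec$ths_promoter_offset,
                       tssp + spec$ths_promoter_offset) +
        round(stats::rnorm(n_prom, 0, 50))
      chrom[seq_len(n_prom)] <-
        as.character(GenomeInfoDb::seqnames(genes))[pick]
      start0[seq_len(n_prom)] <- pmax(center - floor(len[seq_len(n_prom)] / 2),
                                      1) - 1
      link[seq_len(n_prom)] <- genes$gene_id[pick]
    }
    n_bg <- n - n_prom
    if (n_bg > 0L) {
      avoid <- if (is.null(genes)) NULL else
        merge_regions(GenomicRanges::granges(genes), gap = 2 * spec$promoter_bp)
      bg <- .sample_positions(gn, len[n_prom + seq_len(n_bg)], exclude = avoid)
      chrom[n_prom + seq_len(n_bg)] <-
        as.character(GenomeInfoDb::seqnames(bg))
      start0[n_prom + seq_len(n_bg)] <- GenomicRanges::start(bg) - 1
    }
    gr <- regions(chrom, start0, start0 + len, gn = gn, sort = FALSE)
    gr$ths_id <- sprintf("ths%05d", seq_len(n))
    gr$gene_id <- link
    # enforce disjointness: resample background positions colliding with
    # anything already placed
    for (i in 1:50) {
      ov <- GenomicRanges::countOverlaps(gr, gr, ignore.strand = TRUE) > 1L
      bad <- which(ov & is.na(gr$gene_id))
      bad <- bad[bad > n_prom]
      if (!length(bad)) break
      rep2 <- .sample_positions(gn, GenomicRanges::width(gr)[bad])
      GenomeInfoDb::seqlevels(rep2) <- GenomeInfoDb::seqlevels(gr)
      GenomeInfoDb::seqinfo(rep2) <- GenomeInfoDb::seqinfo(gr)
      gr[bad] <- .copy_mcols(rep2, gr[bad])
      if (i == 50 && !GenomicRanges::isDisjoint(gr))
        stop("could not place disjoint THSs; genome too crowded")
    }
    o <- order(gr)
    gr[o]
  })
}

.copy_mcols <- function(gr, from) {
  S4Vectors::mcols(gr) <- S4Vectors::mcols(from)
  gr
}

#' Simulate two ATAC replicates per genotype from true THSs
#'
#' Each replicate is the true THS set with independent Gaussian boundary
#' jitter and Bernoulli drop-outs, plus a MACS2-style q-value per surviving
#' peak.
#'
#' @param spec A [sim_spec()].
#' @param ths True THS `GRanges`.
#' @param gn A `genome`.
#' @param seed Integer seed.
#' @return Named list per genotype of `list(rep1, rep2)` peak `GRanges` with
#'   `qvalue`.
#' @export
simulate_ths_replicates <- function(spec, ths, gn, seed) {
  withr::with_seed(.stage_seed(seed, "replicates"), {
    out <- lapply(spec$genotypes, function(g) {
      reps <- lapply(1:2, function(r) {
        keep <- stats::runif(length(ths)) >= spec$rep_dropout
        x <- ths[keep]
        st <- GenomicRanges::start(x) +
          round(stats::rnorm(length(x), 0, spec$rep_jitter_sd))
        en <- GenomicRanges::end(x) +
          round(stats::rnorm(length(x), 0, spec$rep_jitter_sd))
        lens <- gn[as.character(GenomeInfoDb::seqnames(x))]
        st <- pmax(st, 1L)
        en <- pmin(pmax(en, st), lens)
        pk <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(x),
                                     IRanges::IRanges(st, en))
        pk$qvalue <- stats::runif(length(pk), spec$qvalue_range[1],
                                  spec$qvalue_range[2])
        GenomicRanges::sort(bind_genome(pk, gn), ignore.strand = TRUE)
      })
      names(reps) <- c("rep1", "rep2")
      reps
    })
    names(out) <- spec$genotypes
    out
  })
}

#' Simulate per-sample accessibility tracks (CPM)
#'
#' Each genotype gets `2` replicate tracks: background CPM everywhere except
#' at true THSs, where the level is `base_cpm` times an optional per-THS,
#' per-genotype multiplier, with log-normal replicate noise.
#'
#' @param spec A [sim_spec()].
#' @param ths True THS `GRanges`.
#' @param gn A `genome`.
#' @param multipliers Optional numeric matrix, `length(ths)` x genotypes.
#' @param seed Integer seed.
#' @return Named list of signal-track `GRanges` (`<genotype>_r1`, ...).
#' @export
simulate_signal_tracks <- function(spec, ths, gn, multipliers = NULL, seed) {
  withr::with_seed(.stage_seed(seed, "tracks"), {
    gts <- spec$genotypes
    if (is.null(multipliers))
      multipliers <- matrix(1, length(ths), length(gts),
                            dimnames = list(NULL, gts))
    out <- list()
    for (g in gts) for (r in 1:2) {
      mu <- spec$base_cpm * multipliers[, g]
      score <- mu * 2^stats::rnorm(length(ths), 0, spec$track_noise_sd)
      seg <- GenomicRanges::granges(ths)
      seg$score <- score
      out[[paste0(g, "_r", r)]] <- fill_track(seg, spec$background_cpm)
    }
    out
  })
}

#' Simulate mark peaks at controlled distances from THSs
#'
#' Plants, for each histone mark, the distance-interval structure used in
#' THS-mark association analyses: each THS is assigned to the overlap bin,
#' one of the gap bins, or "no nearby peak", according to the mark's
#' `bin_probs`; a peak of mark-specific log-normal length is then placed at
#' the drawn gap. A mark with `coloc_with` draws its associated THSs
#' preferentially (share `coloc_share`) from THSs already associated with the
#' other mark, planting the co-localization structure.
#'
#' @param spec A [sim_spec()].
#' @param ths THS `GRanges`.
#' @param gn A `genome`.
#' @param seed Integer seed.
#' @return Named list per mark: `list(peaks, truth)` where `truth` is a
#'   data.frame with per-THS `bin` ("overlap", "(0,100]", ..., "none") and
#'   planted `distance`.
#' @export
simulate_mark_peaks <- function(spec, ths, gn, seed) {
  withr::with_seed(.stage_seed(seed, "marks"), {
    edges <- spec$mark_bin_edges
    inner <- utils::tail(edges, -1L)
    labs <- c("overlap", paste0("(", utils::head(edges, -1L), ",", inner, "]"))
    n <- length(ths)
    assoc <- list()
    out <- list()
    for (mk in names(spec$marks)) {
      mp <- spec$marks[[mk]]
      pr <- mp$bin_probs
      if (length(pr) != length(labs))
        stop("bin_probs must have ", length(labs), " entries")
      if (sum(pr) > 1) stop("bin_probs must sum to <= 1")
      if (!is.null(mp$coloc_with)) {
        base <- assoc[[mp$coloc_with]]
        if (is.null(base)) stop("coloc_with mark not yet simulated: ",
                                mp$coloc_with)
        n_assoc <- round(sum(pr) * n)
        n_in <- min(round(mp$coloc_share * n_assoc), sum(base))
        sel <- c(sample(which(base), n_in),
                 sample(which(!base), n_assoc - n_in))
        bin <- rep(0L, n)  # 0 = none
        bin[sel] <- sample(seq_along(labs), length(sel), replace = TRUE,
                           prob = pr / sum(pr))
      } else {
        bin <- sample(c(seq_along(labs), 0L), n, replace = TRUE,
                      prob = c(pr, 1 - sum(pr)))
      }
      len <- round(stats::rlnorm(n, mp$len_meanlog, mp$len_sdlog))
      len <- pmax(len, 50L)
      has <- bin > 0L
      dist <- rep(NA_real_, n)
      dist[bin == 1L] <- 0
      gapbin <- which(bin > 1L)
      if (length(gapbin)) {
        lo <- edges[bin[gapbin] - 1L]
        hi <- edges[bin[gapbin]]
        dist[gapbin] <- lo + ceiling(stats::runif(length(gapbin)) * (hi - lo))
      }
      idx <- which(has)
      tst <- GenomicRanges::start(ths)[idx]
      ten <- GenomicRanges::end(ths)[idx]
      chr <- as.character(GenomeInfoDb::seqnames(ths))[idx]
      lens <- gn[chr]
      w <- len[idx]
      side <- sample(c(-1, 1), length(idx), replace = TRUE)
      st <- integer(length(idx))
      for (k in seq_along(idx)) {
        i <- idx[k]
        if (bin[i] == 1L) {
          center <- tst[k] + floor(stats::runif(1) * (ten[k] - tst[k] + 1))
          s <- center - floor(w[k] / 2)
        } else {
          s <- if (side[k] > 0) ten[k] + dist[i] + 1 else
            tst[k] - dist[i] - w[k]
          if (s < 1 || s + w[k] - 1 > lens[k])  # flip side at chromosome edge
            s <- if (side[k] > 0) tst[k] - dist[i] - w[k] else
              ten[k] + dist[i] + 1
        }
        st[k] <- max(1L, min(s, lens[k] - w[k] + 1L))
      }
      pk <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, st + w - 1L))
      pk$name <- paste0(mk, "_", seq_along(pk))
      pk <- GenomicRanges::sort(bind_genome(pk, gn), ignore.strand = TRUE)
      assoc[[mk]] <- has
      out[[mk]] <- list(
        peaks = pk,
        truth = data.frame(ths_id = ths$ths_id,
                           bin = ifelse(has, labs[pmax(bin, 1L)], "none"),
                           distance = dist))
    }
    out
  })
}

#' Simulate TF-binding sites with a planted enrichment factor
#'
#' Fixed-width sites whose midpoints are placed by a two-component mixture
#' so that the expected site density (sites per bp) inside THSs is `f` times
#' the density outside: with probability \eqn{fT/(fT + (G-T))} (T = THS bp,
#' G = genome bp) a midpoint falls uniformly inside THS bases, otherwise
#' uniformly in non-THS bases. `f = 1` is uniform placement; `f = 0` puts no
#' site in a THS.
#'
#' @param spec A [sim_spec()] (uses `n_tfbs`, `tfbs_width`).
#' @param ths THS `GRanges`.
#' @param gn A `genome`.
#' @param f Planted enrichment factor (default `spec$tfbs_factor`).
#' @param seed Integer seed.
#' @return TFBS `GRanges`; attribute `n_inside` counts midpoints planted
#'   inside THSs.
#' @export
simulate_tfbs <- function(spec, ths, gn, f = spec$tfbs_factor, seed) {
  withr::with_seed(.stage_seed(seed, "tfbs"), {
    if (f < 0) stop("f must be >= 0")
    thsr <- merge_regions(ths)
    T <- sum(as.numeric(GenomicRanges::width(thsr)))
    G <- sum(as.numeric(gn))
    if (f > 0 && T == 0) stop("f > 0 requires non-empty THS set")
    q <- if (T == 0) 0 else f * T / (f * T + (G - T))
    n <- spec$n_tfbs
    inside <- stats::runif(n) < q
    chrom <- character(n); mid <- numeric(n)
    if (any(inside)) {
      wdt <- as.numeric(GenomicRanges::width(thsr))
      pick <- sample(length(thsr), sum(inside), replace = TRUE, prob = wdt)
      off <- floor(stats::runif(sum(inside)) * wdt[pick])
      chrom[inside] <- as.character(GenomeInfoDb::seqnames(thsr))[pick]
      mid[inside] <- GenomicRanges::start(thsr)[pick] + off
    }
    n_out <- sum(!inside)
    if (n_out) {
      pts <- .sample_positions(gn, rep(1L, n_out), exclude = thsr)
      chrom[!inside] <- as.character(GenomeInfoDb::seqnames(pts))
      mid[!inside] <- GenomicRanges::start(pts)
    }
    half <- floor(spec$tfbs_width / 2)
    lens <- gn[chrom]
    st <- pmax(mid - half, 1)
    en <- pmin(st + spec$tfbs_width - 1, lens)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st, en))
    gr$midpoint_inside <- inside
    gr <- bind_genome(gr, gn)
    attr(gr, "n_inside") <- sum(inside)
    GenomicRanges::sort(gr, ignore.strand = TRUE)
  })
}

#' Simulate a per-gene mark signal matrix with planted multipliers
#'
#' WT gene means are log-normal CPM; each mutant's mean is the WT mean times
#' a planted per-gene multiplier. Every genotype contributes `mark_reps`
#' replicate columns with log-normal noise (`mark_noise_sd` on the log2
#' scale); a finite `mark_noise_df` draws per-gene noise SDs from a
#' scaled-inverse-chi-square family (gene-wise noise heterogeneity),
#' `Inf` keeps a constant SD.
#'
#' @param spec A [sim_spec()].
#' @param gene_ids Character vector of gene ids (matrix rows).
#' @param genotypes Mutant genotypes (columns beside WT).
#' @param multipliers Optional matrix genes x genotypes of planted
#'   multipliers; drawn from `level_multipliers`/`level_probs` when absent.
#' @param seed Integer seed.
#' @return List: `matrix` (genes x samples, columns `WT_r1..`,
#'   `<genotype>_r1..`), `truth` (data.frame of planted multipliers and the
#'   corresponding percent-of-WT bin per genotype).
#' @export
simulate_gene_mark_matrix <- function(spec, gene_ids,
                                      genotypes = setdiff(spec$genotypes,
                                                          "WT"),
                                      multipliers = NULL, seed) {
  withr::with_seed(.stage_seed(seed, "genemark"), {
    ng <- length(gene_ids)
    wt_mean <- stats::rlnorm(ng, spec$wt_mark_meanlog, spec$wt_mark_sdlog)
    if (is.null(multipliers)) {
      multipliers <- matrix(
        sample(spec$level_multipliers, ng * length(genotypes),
               replace = TRUE, prob = spec$level_probs),
        ng, length(genotypes), dimnames = list(gene_ids, genotypes))
    }
    sd_g <- if (is.finite(spec$mark_noise_df))
      spec$mark_noise_sd *
        sqrt(spec$mark_noise_df / stats::rchisq(ng, spec$mark_noise_df))
    else rep(spec$mark_noise_sd, ng)
    cols <- c(paste0("WT_r", seq_len(spec$mark_reps)),
              unlist(lapply(genotypes, function(g)
                paste0(g, "_r", seq_len(spec$mark_reps)))))
    m <- matrix(0, ng, length(cols), dimnames = list(gene_ids, cols))
    for (r in seq_len(spec$mark_reps))
      m[, paste0("WT_r", r)] <-
        wt_mean * 2^stats::rnorm(ng, 0, sd_g)
    for (g in genotypes) for (r in seq_len(spec$mark_reps))
      m[, paste0(g, "_r", r)] <-
        wt_mean * multipliers[, g] * 2^stats::rnorm(ng, 0, sd_g)
    breaks <- c(0, 0.2, 0.4, 0.6, 0.8, 1.2, Inf)
    labs <- .ratio_bin_labels(breaks)
    truth <- data.frame(gene = gene_ids, wt_mean = wt_mean)
    for (g in genotypes) {
      truth[[paste0("multiplier_", g)]] <- multipliers[, g]
      truth[[paste0("bin_", g)]] <-
        labs[findInterval(multipliers[, g], breaks)]
    }
    list(matrix = m, truth = truth)
  })
}

#' Simulate an expression matrix with planted differential effects
#'
#' Baseline FPKM is log-normal; each mutant applies planted log2 effects
#' (`+de_effect` for activated, `-de_effect` for repressed genes) and every
#' genotype contributes `expr_reps` replicate columns with log-normal noise.
#'
#' @param spec A [sim_spec()].
#' @param gene_ids Character vector of gene ids.
#' @param genotypes Mutant genotypes.
#' @param de_class Optional character matrix genes x genotypes with entries
#'   in `{activated, repressed, unaltered}`; drawn at `de_frac` (half up,
#'   half down) when absent.
#' @param seed Integer seed.
#' @return List: `matrix` (genes x samples), `truth` (planted class per
#'   genotype).
#' @export
simulate_expression <- function(spec, gene_ids,
                                genotypes = setdiff(spec$genotypes, "WT"),
                                de_class = NULL, seed) {
  withr::with_seed(.stage_seed(seed, "expression"), {
    ng <- length(gene_ids)
    base <- stats::rlnorm(ng, spec$expr_meanlog, spec$expr_sdlog)
    if (is.null(de_class)) {
      de_class <- matrix("unaltered", ng, length(genotypes),
                         dimnames = list(gene_ids, genotypes))
      for (g in genotypes) {
        u <- stats::runif(ng)
        de_class[u < spec$de_frac / 2, g] <- "activated"
        de_class[u >= spec$de_frac / 2 & u < spec$de_frac, g] <- "repressed"
      }
    }
    cols <- c(paste0("WT_r", seq_len(spec$expr_reps)),
              unlist(lapply(genotypes, function(g)
                paste0(g, "_r", seq_len(spec$expr_reps)))))
    m <- matrix(0, ng, length(cols), dimnames = list(gene_ids, cols))
    for (r in seq_len(spec$expr_reps))
      m[, paste0("WT_r", r)] <- base * 2^stats::rnorm(ng, 0, spec$expr_noise_sd)
    for (g in genotypes) {
      eff <- ifelse(de_class[, g] == "activated", spec$de_effect,
             ifelse(de_class[, g] == "repressed", -spec$de_effect, 0))
      for (r in seq_len(spec$expr_reps))
        m[, paste0(g, "_r", r)] <-
          base * 2^(eff + stats::rnorm(ng, 0, spec$expr_noise_sd))
    }
    truth <- data.frame(gene = gene_ids, de_class,
                        check.names = FALSE)
    list(matrix = m, truth = truth)
  })
}
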