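#' Length-weighted mean signal over regions
#'
#' Computes, for each query region, the mean of a piecewise-constant CPM
#' track over that region. Bases not covered by any track segment contribute
#' 0 CPM, so the denominator is always the full region width. This is the
#' quantity behind every signal matrix in the pipeline ("average signal"
#' over a THS or a mark peak).
#'
#' @param track Signal-track `GRanges` with numeric `score`; segments must be
#'   disjoint.
#' @param reg Query `GRanges`.
#' @return Numeric vector, one mean CPM per query region.
#' @examples
#' tr <- regions("chr1", 0, 100); tr$score <- 2
#' track_mean(tr, regions("chr1", 0, 50))
#' @export
track_mean <- function(track, reg) {
  if (is.null(track$score)) stop("track has no score column")
  if (!GenomicRanges::isDisjoint(track)) stop("track segments overlap")
  al <- .align_seqlevels(reg, track)
  hits <- GenomicRanges::findOverlaps(al$a, al$b, ignore.strand = TRUE)
  out <- numeric(length(reg))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- pmin(GenomicRanges::end(al$a)[q], GenomicRanges::end(al$b)[s]) -
      pmax(GenomicRanges::start(al$a)[q], GenomicRanges::start(al$b)[s]) + 1L
    contrib <- rowsum(as.numeric(track$score[s]) * ov, group = q)
    out[as.integer(rownames(contrib))] <- contrib[, 1L]
  }
  out / GenomicRanges::width(reg)
}

#' Assemble a piecewise-constant track from scored regions
#'
#' Fills the gaps between (disjoint) scored regions with a constant
#' background level so the track covers each chromosome end to end.
#'
#' @param reg Disjoint `GRanges` with a `score` column, bound to a genome
#'   (Seqinfo with lengths).
#' @param background Background CPM for uncovered bases.
#' @return A disjoint signal-track `GRanges` covering the genome.
#' @export
fill_track <- function(reg, background = 0) {
  if (!GenomicRanges::isDisjoint(reg)) stop("regions overlap")
  if (any(is.na(GenomeInfoDb::seqlengths(reg))))
    stop("regions must carry chromosome lengths (see bind_genome)")
  o <- GenomicRanges::order(reg)
  chr <- as.character(GenomeInfoDb::seqnames(reg))[o]
  st <- GenomicRanges::start(reg)[o]
  en <- GenomicRanges::end(reg)[o]
  sc <- as.numeric(reg$score)[o]
  lens <- GenomeInfoDb::seqlengths(reg)
  gchr <- character(0); gst <- integer(0); gen <- integer(0)
  for (cc in names(lens)) {
    i <- which(chr == cc)
    # complement: stretch after each previous end up to each next start
    lo <- c(0L, en[i]) + 1L
    hi <- c(st[i], lens[[cc]] + 1L) - 1L
    ok <- hi >= lo
    gchr <- c(gchr, rep(cc, sum(ok)))
    gst <- c(gst, lo[ok]); gen <- c(gen, hi[ok])
  }
  out <- GenomicRanges::GRanges(
    c(chr, gchr), IRanges::IRanges(c(st, gst), c(en, gen)),
    seqinfo = GenomeInfoDb::seqinfo(reg))
  out$score <- c(sc, rep(background, length(gchr)))
  GenomicRanges::sort(out, ignore.strand = TRUE)
}
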