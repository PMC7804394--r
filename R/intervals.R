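#' Build a region set from BED-style coordinates
#'
#' Constructs a validated, sorted, deduplicated [GenomicRanges::GRanges] from
#' BED-convention coordinates (0-based start, exclusive end). All package
#' functions exchange GRanges; this constructor (and the file readers) are the
#' places where the BED convention is translated to the 1-based closed GRanges
#' convention.
#'
#' @param chrom Character vector of chromosome names; a single name is
#'   recycled to the length of `start`.
#' @param start,end Numeric vectors, 0-based half-open span per region
#'   (`0 <= start < end`).
#' @param name Optional region labels.
#' @param score Optional numeric scores.
#' @param strand Optional strand (`+`, `-` or `.`/`*`).
#' @param qvalue Optional linear q-values in `[0, 1]`.
#' @param gn Optional `genome`; when given, coordinates are checked against
#'   chromosome bounds and the Seqinfo is attached.
#' @param sort Sort and collapse exact duplicates (default `TRUE`).
#' @return A `GRanges`.
#' @examples
#' regions("chr1", c(0, 50), c(100, 150))
#' @export
regions <- function(chrom, start, end, name = NULL, score = NULL,
                    strand = NULL, qvalue = NULL, gn = NULL, sort = TRUE) {
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop("invalid interval at record ", bad[1L], ": ",
         chrom[bad[1L]], ":", start[bad[1L]], "-", end[bad[1L]],
         " (require 0 <= start < end)")
  if (is.null(strand)) strand <- "*"
  strand <- ifelse(strand == ".", "*", strand)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    strand = strand)
  if (!is.null(name)) gr$name <- as.character(name)
  if (!is.null(score)) gr$score <- as.numeric(score)
  if (!is.null(qvalue)) {
    if (any(qvalue < 0 | qvalue > 1, na.rm = TRUE))
      stop("q-values must lie in [0, 1]")
    gr$qvalue <- as.numeric(qvalue)
  }
  if (!is.null(gn)) gr <- bind_genome(gr, gn)
  else gr <- GenomeInfoDb::sortSeqlevels(gr)
  if (sort) gr <- unique(GenomicRanges::sort(gr, ignore.strand = TRUE))
  gr
}

#' Attach a genome to a region set, validating coordinates
#'
#' @param gr A `GRanges`.
#' @param gn A `genome`.
#' @return `gr` with Seqinfo set; errors if any region falls on an unknown
#'   chromosome or beyond its end.
#' @export
bind_genome <- function(gr, gn) {
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  unknown <- !(chr %in% names(gn))
  if (any(unknown))
    stop("region on unknown chromosome: ", chr[unknown][1L])
  over <- GenomicRanges::end(gr) > gn[chr]
  if (any(over)) {
    i <- which(over)[1L]
    stop("region exceeds chromosome end: ", chr[i], ":",
         GenomicRanges::start(gr)[i] - 1L, "-", GenomicRanges::end(gr)[i],
         " (", chr[i], " length ", gn[chr[i]], ")")
  }
  GenomeInfoDb::seqlevels(gr) <- names(gn)
  GenomeInfoDb::seqinfo(gr) <- genome_seqinfo(gn)
  gr
}

# put two region sets on a common seqlevel universe so set operations work
.align_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a = a, b = b)
}

#' Interval algebra on region sets
#'
#' Strand-blind set operations used throughout the pipeline.
#' `merge_regions` collapses a region set into disjoint sorted regions,
#' bridging gaps of at most `gap` bp. `intersect_regions` returns the
#' base-pair intersection, `subtract_regions` removes every base covered by
#' `blacklist`. Two regions that merely touch (BED `end == start`) share no
#' base pair: they are merged at `gap = 0`, are 0 bp apart for
#' [nearest_distance()], but do not count as overlapping.
#'
#' @param x,a,b,blacklist `GRanges`.
#' @param gap Maximum gap in bp bridged by `merge_regions` (default 0).
#' @return A disjoint, sorted `GRanges` (metadata columns are dropped, as the
#'   result regions no longer correspond one-to-one to inputs).
#' @examples
#' a <- regions("chr1", 0, 100)
#' b <- regions("chr1", 40, 60)
#' subtract_regions(a, b)
#' @export
merge_regions <- function(x, gap = 0) {
  if (gap < 0) stop("gap must be >= 0")
  GenomicRanges::reduce(x, min.gapwidth = gap + 1L, ignore.strand = TRUE)
}

#' @rdname merge_regions
#' @export
intersect_regions <- function(a, b) {
  al <- .align_seqlevels(a, b)
  GenomicRanges::intersect(al$a, al$b, ignore.strand = TRUE)
}

#' @rdname merge_regions
#' @export
subtract_regions <- function(a, blacklist) {
  if (length(blacklist) == 0L) return(merge_regions(a))
  al <- .align_seqlevels(a, blacklist)
  GenomicRanges::setdiff(al$a, al$b, ignore.strand = TRUE)
}

#' Distance from each query region to its nearest subject region
#'
#' Edge-to-edge gap in bp; overlapping (or touching) regions are at distance
#' 0. Queries on chromosomes with no subject region get `NA` (never 0).
#'
#' @param query,subject `GRanges`.
#' @return Integer vector, one entry per query region.
#' @export
nearest_distance <- function(query, subject) {
  al <- .align_seqlevels(query, subject)
  hits <- GenomicRanges::distanceToNearest(al$a, al$b, ignore.strand = TRUE)
  out <- rep(NA_integer_, length(query))
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out
}

#' Number of subject regions overlapping each query region
#'
#' Overlap means sharing at least one base pair.
#'
#' @param query,subject `GRanges`.
#' @return Integer vector, one count per query region.
#' @export
count_overlaps <- function(query, subject) {
  al <- .align_seqlevels(query, subject)
  GenomicRanges::countOverlaps(al$a, al$b, ignore.strand = TRUE)
}

#' Total base pairs covered by a region set
#' @param x A `GRanges`.
#' @return Numeric scalar, bp covered (overlaps counted once).
#' @export
covered_bp <- function(x) sum(as.numeric(GenomicRanges::width(merge_regions(x))))
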