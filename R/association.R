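#' Distance-interval association between THSs and a mark peak set
#'
#' For each consensus THS, the edge-to-edge distance to the nearest histone
#' mark peak is binned into non-overlapping intervals: overlap (distance 0),
#' the configured gap intervals, and a terminal bin for THSs whose nearest
#' peak is beyond the last edge (or that have no peak on their chromosome).
#' A cumulative summary ("within d bp", overlap included) is also emitted.
#'
#' @param cons Non-empty consensus `GRanges`.
#' @param marks Mark peak `GRanges` (may be empty: everything falls in the
#'   terminal bin).
#' @param edges Strictly increasing bp edges; the first must be 0 (the
#'   overlap bin). Default `c(0, 100, 500, 1000, 2000)`.
#' @return List with `bins` (data.frame: `bin`, `count`, `percent`),
#'   `cumulative` (data.frame: `within_bp`, `count`, `percent`) and `total`.
#' @export
distance_bin_percentages <- function(cons, marks,
                                     edges = c(0, 100, 500, 1000, 2000)) {
  if (length(cons) == 0L) stop("empty consensus set")
  if (edges[1] != 0 || is.unsorted(edges, strictly = TRUE))
    stop("edges must be strictly increasing and start at 0")
  d <- nearest_distance(cons, marks)
  inner <- utils::tail(edges, -1L)
  labs <- c("overlap",
            paste0("(", utils::head(edges, -1L), ",", inner, "]"),
            paste0(">", max(edges), "_or_none"))
  bin <- rep(labs[length(labs)], length(cons))
  has <- !is.na(d)
  bin[has & d == 0] <- labs[1L]
  gap <- has & d > 0
  cls <- findInterval(d, c(0, inner), left.open = TRUE)
  inside <- gap & cls <= length(inner)
  bin[inside] <- labs[1L + cls[inside]]
  counts <- table(factor(bin, levels = labs))
  cum <- vapply(edges, function(e) sum(has & d <= e), integer(1L))
  list(
    bins = data.frame(bin = names(counts), count = as.integer(counts),
                      percent = 100 * as.integer(counts) / length(cons),
                      row.names = NULL),
    cumulative = data.frame(within_bp = edges, count = cum,
                            percent = 100 * cum / length(cons)),
    total = length(cons))
}

#' Co-localization of two mark sets around THSs
#'
#' Classifies each THS by whether its nearest peak of mark A and of mark B
#' lies within `d` bp (overlap counts), yielding the four Venn cells and the
#' co-localization shares (e.g. the fraction of B-associated THSs that are
#' also A-associated).
#'
#' @param cons Consensus `GRanges`.
#' @param marksA,marksB Mark peak `GRanges`.
#' @param d Distance cutoff in bp (default 2000).
#' @return List with `counts` (named: `both`, `A_only`, `B_only`, `neither`),
#'   `share_A_in_B` = both/(both + B_only), `share_B_in_A` =
#'   both/(both + A_only), and `total`.
#' @export
colocalization_venn <- function(cons, marksA, marksB, d = 2000) {
  if (d < 0) stop("d must be >= 0")
  da <- nearest_distance(cons, marksA)
  db <- nearest_distance(cons, marksB)
  a <- !is.na(da) & da <= d
  b <- !is.na(db) & db <= d
  counts <- c(both = sum(a & b), A_only = sum(a & !b),
              B_only = sum(!a & b), neither = sum(!a & !b))
  list(counts = counts,
       share_A_in_B = if (sum(b)) unname(counts["both"]) / sum(b) else NA_real_,
       share_B_in_A = if (sum(a)) unname(counts["both"]) / sum(a) else NA_real_,
       total = length(cons))
}
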