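#' Empirical-Bayes moderated two-group comparison
#'
#' Row-wise two-sample comparison on log2 signal with variance shrinkage
#' toward a common prior, the statistic behind differential accessibility,
#' differential mark levels and differential expression in this package.
#' Per row, the pooled variance \eqn{s_g^2} (df \eqn{d_g = n_a + n_b - 2}) is
#' shrunk to \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)} and
#' the t-statistic referred to a t distribution on \eqn{d_0 + d_g} df. The
#' prior scale \eqn{s_0^2} is estimated by the bias-corrected moment
#' estimator \eqn{\mathrm{mean}(s_g^2)\,(d_0-2)/d_0} (for \eqn{d_0 > 2}; the
#' mean of sample variances estimates \eqn{s_0^2\, d_0/(d_0-2)} under the
#' scaled-inverse-chi-square prior). The prior df \eqn{d_0} is fixed rather
#' than estimated, which keeps the statistic deterministic at 2-3 replicates;
#' `d0 = 0` reduces exactly to the ordinary pooled two-sample t-test.
#'
#' @param m Numeric matrix, rows = genes/regions, columns = samples. Linear
#'   CPM unless `log_input = TRUE`.
#' @param cols_a,cols_b Column names or indices of the two groups (a is the
#'   test group, b the reference; `log2fc` is a minus b).
#' @param d0 Prior degrees of freedom (default 4).
#' @param pseudocount Added before log2 when `log_input = FALSE`.
#' @param log_input Set `TRUE` if `m` is already log2 scale.
#' @return data.frame with `log2fc`, `t`, `df`, `p` per row. Rows with zero
#'   variance everywhere and zero difference get `t = 0`, `p = 1`.
#' @export
moderated_diff <- function(m, cols_a, cols_b, d0 = 4, pseudocount = 0.5,
                           log_input = FALSE) {
  a <- m[, cols_a, drop = FALSE]
  b <- m[, cols_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) stop("need >= 2 samples per group")
  if (!log_input) {
    a <- log2(a + pseudocount)
    b <- log2(b + pseudocount)
  }
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- .row_vars(a); vb <- .row_vars(b)
  dg <- na + nb - 2L
  sg2 <- ((na - 1L) * va + (nb - 1L) * vb) / dg
  if (d0 == 0) {
    st2 <- sg2
  } else {
    s02 <- if (d0 > 2) mean(sg2) * (d0 - 2) / d0 else mean(sg2)
    st2 <- (d0 * s02 + dg * sg2) / (d0 + dg)
  }
  se <- sqrt(st2 * (1 / na + 1 / nb))
  tt <- (ma - mb) / se
  tt[se == 0 & ma == mb] <- 0
  df <- d0 + dg
  p <- 2 * stats::pt(-abs(tt), df = df)
  p[se == 0 & ma == mb] <- 1
  data.frame(log2fc = ma - mb, t = tt, df = df, p = p,
             row.names = rownames(m))
}

.row_vars <- function(x) {
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (ncol(x) - 1L)
}

#' One-sided rank-sum comparison of two gene groups
#'
#' Mann-Whitney-Wilcoxon test between per-gene scalars (typically mean
#' accessibility in a TSS window) of a comparison group versus a reference
#' group. Exact when both groups are small (min n <= 8) and untied, normal
#' approximation with continuity and tie correction otherwise.
#'
#' @param x Per-gene values of the comparison group.
#' @param ref Per-gene values of the reference (e.g. WT-like) group.
#' @param direction `"greater"` tests whether `x` tends to exceed `ref`,
#'   `"less"` the opposite.
#' @return List with `p`, the rank-sum statistic `w`, `exact` (logical), and
#'   `low_power` (`TRUE` when either group has < 3 members).
#' @export
profile_group_test <- function(x, ref, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (!length(x) || !length(ref)) stop("both groups must be non-empty")
  exact <- min(length(x), length(ref)) <= 8 && !anyDuplicated(c(x, ref))
  res <- suppressWarnings(
    stats::wilcox.test(x, ref, alternative = direction, exact = exact,
                       correct = TRUE))
  list(p = unname(res$p.value), w = unname(res$statistic),
       exact = exact, low_power = min(length(x), length(ref)) < 3)
}

#' log2-scale cutoff for a fraction-of-WT boundary
#'
#' The level-classification boundary "less than `frac` of WT" expressed in
#' log2 fold-change space; for the 60% boundary this is
#' \eqn{\log_2 0.6 = -0.7369656}.
#'
#' @param frac Fraction of WT (default 0.6).
#' @return Numeric scalar `log2(frac)`.
#' @export
wt_fraction_cutoff_log2 <- function(frac = 0.6) log2(frac)
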