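# Self-contained statistical kernel used throughout the package.
# Conventions: all tests two-sided; no continuity corrections; BH for FDR.

#' Pooled two-proportion z test
#'
#' Compares two binomial proportions `k1/n1` and `k2/n2` with the pooled-variance
#' z statistic `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` where
#' `p = (k1 + k2)/(n1 + n2)`, and a two-sided normal p-value. No continuity
#' correction is applied, so `z^2` equals the 2x2 chi-square statistic without
#' Yates correction. When the pooled proportion is 0 or 1 the variance is
#' degenerate; the statistic is defined as 0 with p = 1.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param k1,n1 Successes and trials in the first group (`0 <= k1 <= n1`, `n1 > 0`).
#' @param k2,n2 Successes and trials in the second group.
#' @return A data.frame with columns `statistic` (z), `p_value`, `effect`
#'   (`k1/n1 - k2/n2`), `n1`, `n2`.
#' @examples
#' two_prop_z(30, 40, 10, 40)
#' @export
two_prop_z <- function(k1, n1, k2, n2) {
  m <- max(length(k1), length(n1), length(k2), length(n2))
  k1 <- rep_len(as.numeric(k1), m); n1 <- rep_len(as.numeric(n1), m)
  k2 <- rep_len(as.numeric(k2), m); n2 <- rep_len(as.numeric(n2), m)
  if (any(n1 <= 0) || any(n2 <= 0)) stop("group sizes must be positive")
  if (any(k1 < 0 | k1 > n1) || any(k2 < 0 | k2 > n2))
    stop("counts must satisfy 0 <= k <= n")
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  degenerate <- pp <= 0 | pp >= 1
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- ifelse(degenerate, 0, (p1 - p2) / se)
  p <- ifelse(degenerate, 1, 2 * stats::pnorm(-abs(z)))
  data.frame(statistic = z, p_value = p, effect = p1 - p2, n1 = n1, n2 = n2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment with monotone enforcement; the mapping is
#' order-preserving with respect to the input vector. NA p-values propagate.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# all C(n1+n2, n1) group assignments of the pooled sample; two-sided p is the
# share of assignments whose U is at least as far from the null mean as observed
mwu_exact_p <- function(pooled, n1, u_obs) {
  r <- rank(pooled)
  idx <- utils::combn(length(pooled), n1)
  u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * (length(pooled) - n1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. For small samples
#' (`n1 + n2 <= exact_max_n`) the null distribution of U is enumerated exactly
#' over all group assignments of the pooled values (ties handled via mid-ranks).
#' Larger samples use the tie-corrected normal approximation with continuity
#' correction, matching the defaults of the standard rank-sum implementation.
#'
#' @param x,y Numeric samples, each nonempty.
#' @param exact_max_n Total size at or below which the exact branch is used.
#' @param force_method Optional `"exact"` or `"normal"` to override the size rule
#'   (used for cross-validating the two branches).
#' @return A data.frame with `statistic` (U of `x`), `p_value`, `effect`
#'   (median(x) - median(y)), `n1`, `n2`, `method`.
#' @export
mwu <- function(x, y, exact_max_n = 10L, force_method = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be nonempty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  method <- if (!is.null(force_method)) {
    match.arg(force_method, c("exact", "normal"))
  } else if (n1 + n2 <= exact_max_n) "exact" else "normal"
  if (method == "exact") {
    p <- mwu_exact_p(pooled, n1, u1)
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    tie_cor <- sum(tie_tab^3 - tie_tab)
    sig2 <- n1 * n2 / 12 * ((n + 1) - tie_cor / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      d <- max(0, abs(u1 - mu) - 0.5)   # continuity correction
      p <- min(1, 2 * stats::pnorm(-d / sqrt(sig2)))
    }
  }
  data.frame(statistic = u1, p_value = p,
             effect = stats::median(x) - stats::median(y),
             n1 = n1, n2 = n2, method = method)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks. Returns NA when either variable has zero
#' rank variance (constant input).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation coefficient rho, or NA.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Spearman correlation with large-sample p-value
#'
#' rho from [spearman_rho()] with a two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @inheritParams spearman_rho
#' @return A data.frame with `statistic` (rho), `p_value`, `effect` (rho), `n1`, `n2`.
#' @export
spearman_test <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  n <- sum(keep)
  rho <- spearman_rho(x, y)
  if (is.na(rho) || n < 4L) {
    p <- NA_real_
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  data.frame(statistic = rho, p_value = p, effect = rho, n1 = n, n2 = n)
}

#' Hypergeometric overlap test
#'
#' Upper-tail hypergeometric probability `P(X >= k)` for the overlap of two sets
#' drawn from a common universe, with fold enrichment relative to the expected
#' overlap `set1 * set2 / universe`.
#'
#' @param k Observed overlap.
#' @param set1_size,set2_size Sizes of the two sets.
#' @param universe Size of the universe both sets are drawn from.
#' @return A data.frame with `statistic` (k), `p_value`, `effect` (fold
#'   enrichment), `n1`, `n2`.
#' @export
hypergeom_overlap <- function(k, set1_size, set2_size, universe) {
  if (max(set1_size, set2_size) > universe)
    stop("set sizes cannot exceed the universe")
  if (k > min(set1_size, set2_size) || k < max(0, set1_size + set2_size - universe))
    stop("impossible overlap k for the given set sizes")
  p <- stats::phyper(k - 1, set1_size, universe - set1_size, set2_size,
                     lower.tail = FALSE)
  expected <- set1_size * set2_size / universe
  fold <- if (expected > 0) k / expected else NA_real_
  data.frame(statistic = k, p_value = p, effect = fold,
             n1 = set1_size, n2 = set2_size)
}

#' Windowed overlap of point sites with genomic intervals
#'
#' Flags each single-base site whose position lies within `window` nt of any
#' interval (strand-agnostic, 0-based half-open intervals). A site at position
#' p overlaps an interval \[s, e) iff `s <= p + window` and `e >= p - window + 1`,
#' i.e. the gap between the site base and the nearest covered base is at most
#' `window` nt; a site `window + 1` nt from the nearest interval edge does not
#' overlap. This mirrors the report-once semantics of windowed BED intersection.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based site base).
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param window Flank in nt added on each side of the site.
#' @return Logical vector, one element per row of `sites`.
#' @export
window_overlap <- function(sites, intervals, window = 5L) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)),
            all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(sites) == 0L) return(logical(0))
  if (nrow(intervals) == 0L) return(rep(FALSE, nrow(sites)))
  lv <- union(unique(as.character(sites$chrom)),
              unique(as.character(intervals$chrom)))
  q <- GenomicRanges::GRanges(
    factor(sites$chrom, levels = lv),
    IRanges::IRanges(start = pmax(1L, sites$pos + 1L - window),
                     end = sites$pos + 1L + window))
  s <- GenomicRanges::GRanges(
    factor(intervals$chrom, levels = lv),
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end))
  GenomicRanges::countOverlaps(q, s, ignore.strand = TRUE) > 0L
}

#' Compare windowed RBP-overlap proportions across site categories
#'
#' Computes, per site category, the proportion of sites having an interval
#' (e.g. an RNA-binding-protein binding site) within `window` nt, and performs a
#' pooled two-proportion z test for every pair of categories.
#'
#' @param site_sets Named list of site data.frames (`chrom`, `pos`).
#' @param intervals Interval data.frame (`chrom`, `start`, `end`); callers are
#'   expected to pre-filter intervals to the desired evidence level.
#' @param window Flank in nt.
#' @return List with `proportions` (per-category data.frame) and `tests`
#'   (pairwise z tests with BH-adjusted p).
#' @export
rbp_window_overlap <- function(site_sets, intervals, window = 5L) {
  stopifnot(is.list(site_sets), length(site_sets) >= 1L,
            !is.null(names(site_sets)))
  hits <- lapply(site_sets, window_overlap, intervals = intervals, window = window)
  prop <- data.frame(
    category = names(site_sets),
    n_sites = vapply(hits, length, integer(1)),
    n_overlap = vapply(hits, sum, integer(1)),
    row.names = NULL)
  prop$proportion <- ifelse(prop$n_sites > 0, prop$n_overlap / prop$n_sites, NA_real_)
  tests <- NULL
  if (length(site_sets) >= 2L) {
    pairs <- utils::combn(names(site_sets), 2L)
    res <- two_prop_z(prop$n_overlap[match(pairs[1, ], prop$category)],
                      prop$n_sites[match(pairs[1, ], prop$category)],
                      prop$n_overlap[match(pairs[2, ], prop$category)],
                      prop$n_sites[match(pairs[2, ], prop$category)])
    tests <- cbind(data.frame(category_a = pairs[1, ], category_b = pairs[2, ]), res)
    tests$fdr <- bh_fdr(tests$p_value)
  }
  list(proportions = prop, tests = tests)
}
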