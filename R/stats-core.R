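# Self-contained statistical primitives used by every analysis stage.
# Each is written to be checkable against a brute-force oracle (full
# enumeration of sign vectors / group labelings / hypergeometric tails),
# and against the corresponding base-R routine as an independent reference.

#' Two-tailed Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (classic Wilcoxon handling). With n <= 12
#' nonzero differences and no ties in their absolute values the two-sided
#' p-value is exact, computed from the full distribution of the positive-rank
#' sum over all 2^n sign assignments; otherwise a normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param differences Numeric vector of paired differences (NAs removed).
#' @param exact_max Largest n for which the exact distribution is used.
#' @return List with `statistic` (positive-rank sum W), `p_value`,
#'   `n_effective` (nonzero differences used), `method_note`.
#' @export
wilcoxon_signed_rank <- function(differences, exact_max = 12L) {
  d <- differences[!is.na(differences)]
  if (length(d) == 0) stop("no non-missing differences", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences zero: test undefined", call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= exact_max && !ties) {
    # exact null distribution of W by rank-sum convolution
    counts <- signed_rank_counts(n)          # counts[w+1] over w = 0..n(n+1)/2
    total <- 2^n
    p_lo <- sum(counts[seq_len(W + 1)]) / total
    p_hi <- sum(counts[(W + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_lo, p_hi))
    note <- "exact (full sign enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) stop("degenerate variance in signed-rank test", call. = FALSE)
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    note <- if (ties) "normal approximation (ties)" else "normal approximation"
  }
  list(statistic = W, p_value = p, n_effective = n, method_note = note)
}

# number of sign subsets attaining each rank sum 0..n(n+1)/2
signed_rank_counts <- function(n) {
  counts <- 1
  for (k in seq_len(n)) {
    shifted <- c(rep(0, k), counts)
    counts <- c(counts, rep(0, k)) + shifted
  }
  counts
}

#' Two-tailed Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact two-sided p by enumeration of all group labelings when
#' `length(x) + length(y) <= 12` and there are no ties; otherwise a normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric vectors (NAs removed), both non-empty.
#' @param exact_max Largest combined n for which enumeration is used.
#' @return List with `statistic` (Mann-Whitney U for x), `p_value`,
#'   `n_effective`, `method_note`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (N <= exact_max && !ties) {
    # enumerate every choice of nx ranks out of N
    combos <- utils::combn(N, nx)
    stats_all <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    total <- ncol(combos)
    p_lo <- sum(stats_all <= U) / total
    p_hi <- sum(stats_all >= U) / total
    p <- min(1, 2 * min(p_lo, p_hi))
    note <- "exact (labeling enumeration)"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    sigma2 <- nx * ny / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) stop("degenerate variance in rank-sum test", call. = FALSE)
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    note <- if (ties) "normal approximation (ties)" else "normal approximation"
  }
  list(statistic = U, p_value = p, n_effective = N, method_note = note)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q_(i) = min over j >= i of m * p_(j) / j, capped at 1, returned in the
#' input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p_values[o]))[ro]
  q
}

#' Fisher's exact test on a 2x2 table with conditional-MLE odds ratio
#'
#' Two-sided p-value as the sum of hypergeometric point probabilities not
#' exceeding that of the observed table (with a small relative tolerance, as
#' in standard practice). The odds ratio is the conditional
#' maximum-likelihood estimate under the noncentral hypergeometric model;
#' it is 0 or +Inf when the observed count sits at the edge of its support.
#'
#' @param a,b,c,d Non-negative integer cell counts of the table
#'   \[\[a, b\], \[c, d\]\].
#' @return List with `table`, `p_value`, `odds_ratio`, `log2_odds_ratio`.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop("degenerate table: a zero margin leaves the test undefined",
         call. = FALSE)
  }
  m <- a + b          # row-1 total
  k <- a + c          # col-1 total
  N <- a + b + c + d
  support <- max(0, k - (N - m)):min(k, m)
  dens <- stats::dhyper(support, m, N - m, k)
  obs <- stats::dhyper(a, m, N - m, k)
  p <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  or <- cmle_odds_ratio(a, support, dens)
  list(table = matrix(counts, 2, 2, byrow = TRUE),
       p_value = p, odds_ratio = or, log2_odds_ratio = log2(or))
}

# conditional MLE: psi with E[X | psi] = a under the noncentral
# hypergeometric likelihood proportional to dens * psi^support
cmle_odds_ratio <- function(a, support, dens) {
  if (a == min(support)) return(0)
  if (a == max(support)) return(Inf)
  mean_at <- function(log_psi) {
    w <- log(dens) + support * log_psi
    w <- exp(w - max(w))
    sum(support * w) / sum(w) - a
  }
  # E[X | psi] is increasing in psi; bracket then root-find on log scale
  lo <- -1; hi <- 1
  while (mean_at(lo) > 0) lo <- lo * 2
  while (mean_at(hi) < 0) hi <- hi * 2
  exp(stats::uniroot(mean_at, c(lo, hi), tol = 1e-10)$root)
}

#' Spearman rank correlation with mid-ranks
#'
#' Pearson correlation of average ranks on pairwise-complete observations.
#' Returns NA (flagged missing) when fewer than 3 complete pairs remain or
#' when either rank vector has zero variance.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in \[-1, 1\], or NA when undefined.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NA_real_)
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}
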