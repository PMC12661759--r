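# Statistical primitives against brute-force oracles and base-R references.

test_that("signed-rank test is exact for small samples and matches enumeration", {
  res <- wilcoxon_signed_rank(c(1.2, 0.5, 2.1, 0.9, 1.7, 0.3))
  expect_equal(res$p_value, 2 / 64)          # all-positive n = 6 tail
  expect_equal(res$n_effective, 6)

  res <- wilcoxon_signed_rank(c(1, -1.5, 2, -2.5))
  expect_gt(res$p_value, 0.6)                # near-symmetric sample

  set.seed(11)
  for (n in 3:10) {
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    if (length(d) < 2 || any(duplicated(abs(d)))) next
    expect_equal(wilcoxon_signed_rank(d)$p_value, oracle_signed_rank_p(d),
                 tolerance = 1e-12)
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("signed-rank zero handling and error cases follow the Wilcoxon convention", {
  res <- wilcoxon_signed_rank(c(0, 0, 1, 2, -0.5))
  expect_equal(res$n_effective, 3)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "zero")
  expect_error(wilcoxon_signed_rank(numeric()), "no non-missing")
})

test_that("signed-rank approximation agrees with Monte-Carlo permutation at n = 20 with ties", {
  set.seed(21)
  d <- round(rnorm(20, 0.3), 1)               # rounding makes ties
  d <- d[d != 0]
  p_approx <- wilcoxon_signed_rank(d)$p_value
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  B <- 1e5
  signs <- matrix(runif(B * length(d)) < 0.5, B)
  W_mc <- signs %*% r
  mu <- sum(r) / 2
  p_mc <- min(1, 2 * min(mean(W_mc <= W_obs + 1e-9),
                         mean(W_mc >= W_obs - 1e-9)))
  expect_lt(abs(p_approx - p_mc), 0.01)
})

test_that("rank-sum test matches enumeration, symmetry, and the large-sample oracle", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 2 / 6, tolerance = 1e-12)

  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(wilcoxon_rank_sum(x, x)$p_value, 1)

  set.seed(5)
  for (i in 1:10) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- round(rnorm(nx), 3); y <- round(rnorm(ny), 3)
    if (any(duplicated(c(x, y))) || nx + ny > 12) next
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_rank_sum_p(x, y),
                 tolerance = 1e-12)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }

  set.seed(6)
  x <- rnorm(25, 0.5); y <- rnorm(30)
  p_approx <- wilcoxon_rank_sum(x, y)$p_value
  r_all <- rank(c(x, y))
  U_obs <- sum(r_all[1:25]) - 25 * 26 / 2
  U_mc <- replicate(1e4, {
    idx <- sample(55, 25)
    sum(r_all[idx]) - 25 * 26 / 2
  })
  p_mc <- min(1, 2 * min(mean(U_mc <= U_obs), mean(U_mc >= U_obs)))
  expect_lt(abs(p_approx - p_mc), 0.01)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
})

test_that("BH adjustment reproduces the hand step-up and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= 0 & q <= 1))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-12))    # monotone in p
  }
})

test_that("fisher_2x2 matches hypergeometric tail sums and fisher.test", {
  res <- fisher_2x2(1, 9, 11, 3)
  expect_equal(res$p_value, oracle_fisher_p(1, 9, 11, 3), tolerance = 1e-12)
  expect_equal(res$p_value, fisher.test(matrix(c(1, 9, 11, 3), 2,
                                               byrow = TRUE))$p.value,
               tolerance = 1e-9)
  expect_lt(res$odds_ratio, 1)

  res <- fisher_2x2(5, 5, 5, 5)
  expect_equal(res$p_value, 1)
  expect_equal(res$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(res$log2_odds_ratio, 0, tolerance = 1e-6)

  res <- fisher_2x2(10, 0, 0, 10)
  expect_equal(res$p_value, oracle_fisher_p(10, 0, 0, 10), tolerance = 1e-12)
  expect_identical(res$odds_ratio, Inf)
  expect_identical(res$log2_odds_ratio, Inf)

  expect_error(fisher_2x2(0, 0, 3, 4), "degenerate")

  set.seed(13)
  for (i in 1:50) {
    t <- rmultinom(1, sample(8:40, 1), rep(0.25, 4))
    if ((t[1] + t[2]) == 0 || (t[3] + t[4]) == 0 ||
        (t[1] + t[3]) == 0 || (t[2] + t[4]) == 0) next
    mine <- fisher_2x2(t[1], t[2], t[3], t[4])
    expect_equal(mine$p_value, oracle_fisher_p(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-10)
    ref <- fisher.test(matrix(t, 2, byrow = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-7)
    expect_equal(mine$odds_ratio, unname(ref$estimate), tolerance = 1e-3)
  }
})

test_that("spearman equals mid-rank Pearson with pairwise-complete handling", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(spearman(x, exp(x)), 1)                 # monotone transform
  expect_equal(spearman(x, -x), -1)
  set.seed(17)
  for (i in 1:10) {
    x <- sample(1:6, 30, replace = TRUE)               # heavy ties
    y <- sample(1:6, 30, replace = TRUE) + 0.3 * x
    expect_equal(spearman(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_true(is.na(spearman(c(1, 2, NA), c(NA, 1, 2))))  # < 3 complete
  expect_true(is.na(spearman(rep(1, 5), 1:5)))             # zero rank variance
})
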