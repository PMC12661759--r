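# Detection, overlap, tiers, correlation, PCA and rank-abundance.

test_that("detection counts include all-missing samples and match a median oracle", {
  v <- matrix(c(1, 2, NA, NA, NA, NA, 3, NA, 4), 3,
              dimnames = list(paste0("F", 1:3), NULL))
  qm <- make_qm(v, "A")
  dc <- detection_counts(list(A = qm))
  expect_equal(dc$per_sample$n_detected, c(2, 0, 2))   # all-missing still listed
  set.seed(70)
  mats <- list()
  for (w in c("A", "B")) {
    v <- matrix(ifelse(runif(60) < 0.4, NA, rnorm(60)), 10)
    mats[[w]] <- make_qm(v, w)
  }
  rownames(mats$A$values) <- rownames(mats$B$values) <- paste0("F", 1:10)
  dc <- detection_counts(mats)
  sort_median <- function(x) {       # sort-based oracle
    s <- sort(x); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  for (w in c("A", "B")) {
    counts <- dc$per_sample$n_detected[dc$per_sample$workflow == w]
    expect_equal(
      dc$per_workflow$median_detected[dc$per_workflow$workflow == w],
      sort_median(counts))
  }
})

test_that("membership regions partition the union and match per-feature classification", {
  mk <- function(feats, w) {
    v <- matrix(1, length(feats), 2, dimnames = list(feats, NULL))
    make_qm(v, w)
  }
  ms <- membership_sets(list(A = mk(c("f1", "f2"), "A"),
                             B = mk(c("f2", "f3"), "B")))
  expect_equal(ms$union_size, 3)
  expect_equal(sum(ms$regions$n), ms$union_size)
  expect_equal(ms$regions$n[ms$regions$combination == "A&B"], 1)
  expect_equal(ms$regions$n[ms$regions$combination == "A"], 1)

  set.seed(71)
  for (rep in 1:5) {
    k <- sample(3:5, 1)
    wf <- LETTERS[1:k]
    feats <- paste0("f", 1:40)
    mats <- lapply(wf, function(w) mk(sample(feats, sample(5:30, 1)), w))
    names(mats) <- wf
    ms <- membership_sets(mats)
    orc <- oracle_regions(ms$universes)
    expect_equal(sum(ms$regions$n), ms$union_size)
    got <- setNames(ms$regions$n, ms$regions$combination)
    expect_equal(got[names(orc)], unclass(orc)[names(orc)],
                 ignore_attr = TRUE)
  }
})

test_that("detection tiers use half-open intervals and partition detected features", {
  v <- matrix(NA_real_, 4, 19, dimnames = list(paste0("F", 1:4), NULL))
  v[1, ] <- 1                      # f = 19/19 -> top tier
  v[2, 1:9] <- 1                   # f = 9/19 ~ 0.474 -> (0.1, 0.5]
  v[3, 1:18] <- 1                  # f ~ 0.947 -> (0.9, 1]
  v[4, 1] <- 1                     # f ~ 0.053 -> (0, 0.1]
  td <- detection_tiers(make_qm(v, "A"))
  tiers <- setNames(td$tiers$n, td$tiers$tier)
  expect_equal(unname(tiers["(0.9,1]"]), 2)
  expect_equal(unname(tiers["(0.1,0.5]"]), 1)
  expect_equal(unname(tiers["(0,0.1]"]), 1)
  expect_equal(sum(td$tiers$n), 4)
  set.seed(72)
  v <- matrix(ifelse(runif(200) < 0.5, NA, 1), 20)
  td <- detection_tiers(make_qm(v, "A"))
  expect_equal(sum(td$tiers$n), sum(rowSums(!is.na(v)) > 0))
})

test_that("correlation matrix is symmetric with unit diagonal and defined gaps", {
  set.seed(73)
  v <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("F", 1:10), NULL))
  v[, 4] <- v[, 3]                         # duplicated sample
  qm <- make_qm(v, "A")
  cm <- correlation_matrix(qm)
  expect_equal(cm$r, t(cm$r))
  expect_true(all(diag(cm$r) == 1))
  expect_equal(cm$r[3, 4], 1)
  # a sample sharing < 3 features with another -> missing entry
  v2 <- v
  v2[3:10, 1] <- NA
  v2[1:2, 2] <- NA
  cm2 <- correlation_matrix(make_qm(v2, "A"))
  expect_true(is.na(cm2$r[1, 2]))
  expect_length(cm2$order, 4)
})

test_that("PCA matches the covariance eigen-oracle and normalizes variance", {
  set.seed(74)
  v <- matrix(rnorm(50), 5, 10, dimnames = list(paste0("F", 1:5), NULL))
  qm <- make_qm(v, "A")
  p <- pca_scores(qm, n_components = 4)
  expect_equal(sum(p$explained_all), 1, tolerance = 1e-9)
  x <- scale(t(v), center = TRUE, scale = FALSE)
  ev <- eigen(cov(x))
  scores_oracle <- x %*% ev$vectors[, 1:4]
  for (k in 1:4) {
    expect_equal(abs(cor(p$scores[, k], scores_oracle[, k])), 1,
                 tolerance = 1e-8)
  }
  # identical samples coincide
  v[, 2] <- v[, 1]
  p <- pca_scores(make_qm(v, "A"))
  expect_equal(p$scores[1, ], p$scores[2, ], tolerance = 1e-9)
  # complete-feature filtering
  v[1, 3] <- NA
  expect_equal(pca_scores(make_qm(v, "A"))$n_features, 4)
  v[, ] <- NA
  expect_error(pca_scores(make_qm(v, "A")), "complete")
})

test_that("rank-abundance ranks by median with deterministic ties and marker flags", {
  v <- matrix(c(10, 10, 10, 10, 1, 1), 3, byrow = TRUE,
              dimnames = list(c("b", "a", "c"), NULL))
  ra <- rank_abundance(make_qm(v, "A"), marker_panel = c("c", "ghost"))
  expect_equal(ra$ranking$feature_id, c("a", "b", "c"))  # tie -> lexicographic
  expect_equal(ra$ranking$rank, 1:3)
  expect_true(ra$ranking$is_marker[3])
  m <- ra$markers
  expect_equal(m$detected_fraction[m$marker == "ghost"], 0)
  expect_false(m$in_matrix[m$marker == "ghost"])
  expect_equal(m$detected_fraction[m$marker == "c"], 1)
})
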