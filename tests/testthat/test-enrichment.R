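# Fraction-unique/-elevated classification and over-representation analysis.

test_that("location consolidation follows the packaged scheme", {
  ann <- list(kind = "subcellular",
              map = list(G1 = c("Nucleoplasm", "Cytosol"),
                         G2 = "Midbody",
                         G3 = "Vesicles",
                         G4 = "SomewhereUnknown"))
  cons <- consolidate_locations(ann)
  expect_setequal(cons$G1, c("Nucleus", "Cytosol"))
  expect_equal(cons$G2, "Cell division")
  expect_equal(cons$G3, "Vesicles")            # identity for top-level labels
  expect_false("G4" %in% names(cons))
  expect_equal(attr(cons, "n_unmapped"), 1L)
  scheme <- subcellular_scheme()
  expect_length(attr(scheme, "analyzed"), 11)
  expect_equal(unname(scheme["Kinetochore"]), "Nucleus")
})

test_that("planted-shift proteins are called elevated only when they beat every other workflow", {
  set.seed(80)
  wf <- c("A", "B", "C")
  planted <- c("A", rep(NA, 29))               # PR001 elevated in A
  mats <- make_paired_matrices(30, wf, 19, planted = planted, effect = 2)
  res <- classify_fraction_proteins(mats)
  expect_equal(res$calls$class[res$calls$protein == "PR001"], "elevated")
  expect_equal(res$calls$workflow[res$calls$protein == "PR001"], "A")
  expect_true("PR001" %in% res$enriched$A)
  # no protein can be elevated in two workflows
  ev <- res$calls[res$calls$class == "elevated", ]
  expect_equal(anyDuplicated(ev$protein), 0)
})

test_that("a protein significant against only some workflows is not elevated", {
  set.seed(81)
  wf <- c("A", "B", "C")
  prot <- sprintf("PR%03d", 1:10)
  pat <- sprintf("PT%02d", 1:19)
  mu <- rnorm(10, 20, 1)
  b <- matrix(rnorm(10 * 19, 0, 0.4), 10)
  mk <- function(shift1) {
    v <- mu + b + matrix(rnorm(10 * 19, 0, 0.5), 10)
    v[1, ] <- v[1, ] + shift1
    dimnames(v) <- list(prot, NULL)
    v
  }
  # PR001 clearly above B but identical to C
  mats <- list(A = make_qm(mk(2), "A", pat), B = make_qm(mk(0), "B", pat),
               C = make_qm(mk(2), "C", pat))
  res <- classify_fraction_proteins(mats)
  expect_false(identical(res$calls$class[res$calls$protein == "PR001"],
                         "elevated"))
})

test_that("workflow-exclusive detection yields class unique regardless of tests", {
  set.seed(82)
  mats <- make_paired_matrices(10, c("A", "B"), 6)
  mats$B$values["PR003", ] <- NA               # only in A
  res <- classify_fraction_proteins(mats)
  expect_equal(res$calls$class[res$calls$protein == "PR003"], "unique")
  expect_equal(res$calls$workflow[res$calls$protein == "PR003"], "A")
  expect_true("PR003" %in% res$enriched$A)
})

test_that("comparisons below the pairing or detection thresholds are untestable", {
  set.seed(83)
  mats <- make_paired_matrices(6, c("A", "B"), 8)
  mats$A$values["PR002", 4:8] <- NA            # 3/8 detected < 50%
  res <- classify_fraction_proteins(mats)
  expect_false("PR002" %in% res$comparisons$protein)
  mats <- make_paired_matrices(6, c("A", "B"), 6)
  mats$A$values["PR001", 1:3] <- NA            # 50% detected, only 3 pairs
  res <- classify_fraction_proteins(mats, min_detect = 0.5)
  row <- res$comparisons[res$comparisons$protein == "PR001" &
                           res$comparisons$workflow == "A", ]
  expect_false(row$testable)
  expect_false("PR001" %in% res$enriched$A)
})

test_that("ORA direction and degenerate identities behave as constructed", {
  categories <- list(G1 = "Vesicles", G2 = "Vesicles", G3 = "Nucleus",
                     G4 = "Nucleus", G5 = "Cytosol", G6 = "Cytosol",
                     G7 = "Vesicles", G8 = "Nucleus")
  background <- paste0("G", 1:8)
  # set = all vesicle members -> over-representation
  out <- ora(c("G1", "G2", "G7"), background, categories)
  ves <- out[out$category == "Vesicles", ]
  expect_gt(ves$odds_ratio, 1)
  expect_equal(ves$direction, "over")
  # disjoint set -> under-representation
  nuc <- out[out$category == "Nucleus", ]
  expect_lt(nuc$odds_ratio, 1)
  expect_equal(nuc$direction, "under")
  # hypergeometric check of the constructed table
  expect_equal(ves$p, oracle_fisher_p(3, 0, 0, 5), tolerance = 1e-12)
  # set = background -> OR 1, p 1 everywhere
  out <- ora(background, background, categories)
  expect_true(all(out$p == 1))
  expect_true(all(abs(out$log2_odds_ratio) < 1e-6))
  expect_error(ora(character(), background, categories), "empty")
  expect_error(ora("GX", background, categories), "subset")
})
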