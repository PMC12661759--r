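# Protein-group assembly and intensity-sum quantification.

one_col <- function(x) matrix(x, length(x), 1, dimnames = list(NULL, "S1"))

test_that("identical peptide sets merge and sparse proteins are dropped", {
  tab <- make_peptide_table(c("AAAK", "CCCK", "AAAK", "CCCK"),
                            c("P1", "P1", "P2", "P2"),
                            one_col(c(1, 2, 1, 2)))
  g <- group_peptides(tab)
  expect_length(g, 1)
  expect_equal(g[[1]]$members, c("P1", "P2"))
  expect_equal(g[[1]]$group_id, "P1")
  expect_length(g[[1]]$peptides, 2)

  tab <- make_peptide_table("AAAK", "P1", one_col(5))
  expect_length(group_peptides(tab), 0)          # < 2 peptides
})

test_that("strict-subset proteins are absorbed into their superset group", {
  tab <- make_peptide_table(c("AK", "BK", "CK", "BK"),
                            c("P1", "P1", "P1", "P2"),
                            one_col(c(1, 1, 1, 1)))
  g <- group_peptides(tab)
  expect_length(g, 1)
  expect_equal(g[[1]]$members, c("P1", "P2"))
  expect_length(g[[1]]$peptides, 3)
})

test_that("shared peptides go to the group with most distinct peptides, ties lexicographic", {
  tab <- make_peptide_table(
    c("AK", "BK", "CK", "DK", "EK", "CK"),
    c("P1", "P1", "P1;P2", "P2", "P2", "P2"),
    one_col(rep(1, 6)))
  # P1 = {AK,BK,CK}; P2 = {CK,DK,EK}: tie on 3 -> CK goes to P1 (lexicographic)
  g <- group_peptides(tab)
  expect_length(g, 2)
  byid <- setNames(g, vapply(g, `[[`, "", "group_id"))
  expect_true("CK" %in% byid$P1$peptides)
  expect_false("CK" %in% byid$P2$peptides)
  expect_length(intersect(byid$P1$peptides, byid$P2$peptides), 0)
})

test_that("group quantification sums raw intensities with the missing contract", {
  ints <- matrix(c(100, 300, NA, NA, NA, 40), 2, 3,
                 dimnames = list(NULL, c("S1", "S2", "S3")))
  tab <- make_peptide_table(c("AAAK", "CCCK"), c("P1", "P1"), ints)
  g <- group_peptides(tab)
  qm <- quantify_groups(g, tab)
  expect_equal(qm$values["P1", "S1"], log2(400), tolerance = 1e-10)
  expect_equal(unname(qm$values["P1", "S1"]), 8.6439, tolerance = 1e-4)
  expect_true(is.na(qm$values["P1", "S2"]))      # both peptides absent
  expect_equal(qm$values["P1", "S3"], log2(40))  # only observed one counts
})

test_that("assembly conserves intensity, is order-independent, and recovers synthetic proteins", {
  set.seed(40)
  for (rep in 1:5) {
    n_pep <- sample(6:14, 1)
    prot <- sample(c("P1", "P2", "P3"), n_pep, replace = TRUE)
    seqs <- paste0(vapply(seq_len(n_pep),
                          function(i) random_peptide(6,
                            alphabet = c("A", "C", "D", "E", "F", "G")), ""),
                   "K")
    ints <- matrix(ifelse(runif(n_pep * 2) < 0.3, NA, rexp(n_pep * 2, 1e-3)),
                   n_pep, 2, dimnames = list(NULL, c("S1", "S2")))
    tab <- make_peptide_table(seqs, prot, ints)
    g <- group_peptides(tab)
    qm <- quantify_groups(g, tab)
    # conservation: grouped raw totals never exceed peptide totals
    for (s in c("S1", "S2")) {
      tot_g <- sum(2^qm$values[, s], na.rm = TRUE)
      tot_p <- sum(ints[, s], na.rm = TRUE)
      expect_lte(tot_g, tot_p + 1e-6)
    }
    # determinism under row permutation
    perm <- sample(n_pep)
    tab2 <- make_peptide_table(seqs[perm], prot[perm],
                               ints[perm, , drop = FALSE])
    g2 <- group_peptides(tab2)
    expect_equal(lapply(g, `[`, c("group_id", "members", "peptides")),
                 lapply(g2, `[`, c("group_id", "members", "peptides")))
    # no shared sequences: every protein with >= 2 distinct observed peptides
    # yields exactly one group
    if (!anyDuplicated(seqs)) {
      expected <- sum(table(prot) >= 2)
      expect_length(g, expected)
    }
  }
})

test_that("quantify_groups rejects groups referencing unknown peptides", {
  tab <- make_peptide_table(c("AAAK", "CCCK"), c("P1", "P1"), one_col(c(1, 2)))
  g <- group_peptides(tab)
  g[[1]]$peptides <- c(g[[1]]$peptides, "GHOSTK")
  expect_error(quantify_groups(g, tab), "absent from the table")
})
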