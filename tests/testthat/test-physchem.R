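# In-silico digestion and MW / GRAVY / pI profiling.

test_that("digest follows trypsin rules including the proline exception", {
  expect_setequal(digest("GKGRGG", 0, TRUE)$sequence, c("GK", "GR", "GG"))
  expect_setequal(digest("GKPGG", 0, TRUE)$sequence, "GKPGG")
  expect_setequal(digest("GKPGG", 0, FALSE)$sequence, c("GK", "PGG"))
  expect_setequal(digest("GGG", 0, TRUE)$sequence, "GGG")
  d <- digest("GKGRGG", 1, TRUE)
  expect_setequal(d$sequence, c("GK", "GR", "GG", "GKGR", "GRGG"))
  expect_equal(sort(unique(d$missed_cleavages)), c(0L, 1L))
})

test_that("digest matches the exhaustive cut-set oracle and coordinates are faithful", {
  set.seed(60)
  for (i in 1:150) {
    s <- random_peptide(sample(1:12, 1), alphabet = c("A", "K", "R", "P", "G"))
    mm <- sample(0:3, 1)
    pr <- sample(c(TRUE, FALSE), 1)
    mine <- digest(s, mm, pr)
    expect_setequal(mine$sequence, oracle_digest(s, mm, pr))
    expect_true(all(substring(s, mine$start, mine$end) == mine$sequence))
    # 0-missed products tile the parent exactly
    zero <- mine[mine$missed_cleavages == 0, ]
    zero <- zero[order(zero$start), ]
    expect_equal(paste(zero$sequence, collapse = ""), s)
  }
})

test_that("MW and GRAVY reproduce hand-summed values", {
  p <- peptide_properties("GG")
  expect_equal(p$molecular_weight, 132.0535, tolerance = 1e-4)
  expect_equal(p$molecular_weight, 2 * 57.02146 + 18.010565, tolerance = 1e-9)
  expect_equal(peptide_properties("AAA")$gravy, 1.8)
  expect_error(peptide_properties("AZA"), "'Z' at position 2")
})

test_that("GRAVY of concatenations is the length-weighted mean of parts", {
  set.seed(61)
  for (i in 1:20) {
    a <- random_peptide(sample(1:15, 1)); b <- random_peptide(sample(1:15, 1))
    ga <- peptide_properties(a)$gravy; gb <- peptide_properties(b)$gravy
    gc <- peptide_properties(paste0(a, b))$gravy
    expect_equal(gc, (nchar(a) * ga + nchar(b) * gb) / (nchar(a) + nchar(b)),
                 tolerance = 1e-12)
  }
})

test_that("net charge at the returned pI is ~0 and pI responds monotonically to charged residues", {
  set.seed(62)
  for (i in 1:200) {
    s <- random_peptide(sample(3:25, 1))
    pi <- peptide_properties(s)$isoelectric_point
    if (pi > 0 && pi < 14) expect_lt(abs(net_charge(s, pi)), 1e-3)
    # acidic residues never raise pI; basic never lower it
    expect_lte(peptide_properties(paste0(s, sample(c("D", "E"), 1)))$isoelectric_point,
               pi + 1e-3)
    expect_gte(peptide_properties(paste0(s, sample(c("K", "R"), 1)))$isoelectric_point,
               pi - 1e-3)
  }
})

test_that("vectorized property table equals the scalar path", {
  set.seed(63)
  seqs <- vapply(1:25, function(i) random_peptide(sample(2:30, 1)), "")
  tab <- csfbench:::physchem_table(seqs)
  for (i in seq_along(seqs)) {
    p <- peptide_properties(seqs[i])
    expect_equal(tab$mw[i], p$molecular_weight, tolerance = 1e-9)
    expect_equal(tab$gravy[i], p$gravy, tolerance = 1e-12)
    expect_equal(tab$pi[i], p$isoelectric_point, tolerance = 2e-4)
  }
})

test_that("reference digest counts, filters and cardinalities are correct", {
  proteome <- c(A1 = "MAGKLLRPWDK", B2 = "GGKAAAAAAAR")
  ref <- reference_distribution(proteome, max_missed = 0,
                                length_range = c(1, 1e6), unique_only = FALSE)
  n_oracle <- length(oracle_digest("MAGKLLRPWDK", 0, TRUE)) +
    length(oracle_digest("GGKAAAAAAAR", 0, TRUE))
  expect_equal(nrow(ref$peptides), n_oracle)      # identity filter keeps all
  expect_equal(nrow(ref$proteins), 2)             # one row per accession
  expect_setequal(ref$proteins$id, c("A1", "B2"))
  ref2 <- reference_distribution(proteome, max_missed = 0,
                                 length_range = c(7, 35), unique_only = FALSE)
  expect_true(all(nchar(ref2$peptides$id) >= 7))
})

test_that("distribution comparison detects planted shifts and respects exchangeability", {
  set.seed(64)
  base <- rnorm(500, 0, 0.5)
  obs <- list(Glyco = list(gravy = base + 0.5),
              Other = list(gravy = rnorm(500, 0, 0.5)))
  ref <- list(gravy = rnorm(500, 0, 0.5))
  out <- compare_distributions(obs, ref)
  row <- out[out$method == "Glyco" & out$contrast == "rest", ]
  expect_gt(row$shift, 0.3)
  expect_lt(row$adjusted_p, 0.05)
  expect_equal(nrow(out), 4)                      # (1 property) x 2 methods x 2
  # identical distributions: exchangeable, p near 1
  x <- rnorm(300)
  obs <- list(A = list(mw = x), B = list(mw = x))
  out <- compare_distributions(obs, list(mw = x))
  expect_true(all(out$p > 0.9))
  expect_true(all(abs(out$shift) < 1e-9))
})
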