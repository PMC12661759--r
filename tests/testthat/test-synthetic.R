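# Synthetic cohort generator: determinism, self-compatibility with the
# readers, degenerate limits, and calibration of the abundance model.

test_that("generation is fully deterministic under a fixed seed", {
  cfg <- tiny_config()
  pr1 <- generate_proteome(cfg, seed = 5)
  pr2 <- generate_proteome(cfg, seed = 5)
  expect_identical(pr1, pr2)
  expect_length(pr1$proteome, 20)
  co1 <- generate_cohort(cfg, pr1, seed = 5)
  co2 <- generate_cohort(cfg, pr2, seed = 5)
  expect_identical(co1$peptide_tables, co2$peptide_tables)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(pr1, co1, d1)
  write_cohort(pr2, co2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  pr3 <- generate_proteome(cfg, seed = 6)
  expect_false(identical(pr1$proteome, pr3$proteome))
})

test_that("emitted files are accepted by every reader (self-compatibility)", {
  cfg <- tiny_config()
  pr <- generate_proteome(cfg, seed = 8)
  co <- generate_cohort(cfg, pr, seed = 8)
  d <- tempfile()
  write_cohort(pr, co, d)
  ch <- load_cohort(d)
  expect_setequal(names(ch$peptide_tables), cfg$workflows)
  expect_equal(length(ch$proteome), cfg$n_proteins)
  expect_equal(nrow(ch$sample_sheet),
               cfg$n_patients * length(cfg$workflows))
  expect_s3_class(ch$site_table, "site_table")
  expect_length(ch$nta_files, 2)
  for (f in ch$nta_files) expect_silent(load_nta(f))
  # round-trip of a peptide table preserves intensities
  w <- cfg$workflows[1]
  orig <- co$peptide_tables[[w]]
  back <- ch$peptide_tables[[w]]
  s <- attr(orig, "samples")[1]
  expect_equal(back[[s]], orig[[s]], tolerance = 1e-6)
})

test_that("the noise-free single-sample limit reproduces exact peptide shares", {
  cfg <- sim_config(n_proteins = 5L, n_patients = 1L, workflows = "Only",
                    total_variance = 0, baseline_sd = 0, dropout = FALSE,
                    planted_fraction = 0, protein_length = c(100L, 150L),
                    glyco_workflow = "none")
  pr <- generate_proteome(cfg, seed = 9)
  co <- generate_cohort(cfg, pr, seed = 9)
  tab <- co$peptide_tables$Only
  s <- attr(tab, "samples")
  shares <- co$truth$peptide_shares
  for (acc in names(pr$proteome)) {
    pi <- shares[[acc]]
    rows <- tab[tab$accessions == acc, ]
    expect_equal(nrow(rows), nrow(pi))
    got <- rows[[s]][match(pi$sequence, rows$sequence)]
    expect_equal(got, pi$share * 2^cfg$baseline_mean, tolerance = 1e-9)
  }
})

test_that("empirical variance fractions of generated abundances match the configuration", {
  cfg <- sim_config(n_proteins = 2000L, n_patients = 50L,
                    variance_fractions = c(method = 0.6, patient = 0.2,
                                           residual = 0.2),
                    planted_fraction = 0)
  pr <- list(proteome = setNames(rep("MK", cfg$n_proteins),
                                 sprintf("SYN%04d", 1:cfg$n_proteins)))
  co <- generate_cohort(cfg, pr, seed = 10, tables = FALSE)
  y <- co$truth$protein_log2
  # Henderson moments per protein on the balanced array, averaged
  nm <- dim(y)[2]; np <- dim(y)[3]
  est <- vapply(seq_len(dim(y)[1]), function(p) {
    m <- y[p, , ]
    msa <- np * var(rowMeans(m))
    msb <- nm * var(colMeans(m))
    mse <- (sum((m - outer(rowMeans(m), colMeans(m), `+`) + mean(m))^2)) /
      ((nm - 1) * (np - 1))
    c((msa - mse) / np, (msb - mse) / nm, mse)   # unbiased ANOVA components
  }, numeric(3))
  comp <- rowMeans(est)       # average components, then form fractions
  avg <- comp / sum(comp)
  expect_lt(abs(avg[1] - 0.6), 0.02)
  expect_lt(abs(avg[2] - 0.2), 0.02)
  expect_lt(abs(avg[3] - 0.2), 0.02)
})

test_that("planted ground truth is traceable and disjoint across workflows", {
  cfg <- sim_config(n_proteins = 50L, n_patients = 6L)
  pr <- generate_proteome(cfg, seed = 12)
  co <- generate_cohort(cfg, pr, seed = 12)
  planted <- co$truth$planted[!is.na(co$truth$planted)]
  expect_length(planted, round(0.1 * 50))
  expect_true(all(planted %in% cfg$workflows))
  # planted shift is present in the abundance array
  y <- co$truth$protein_log2
  for (acc in names(planted)) {
    w <- planted[[acc]]
    others <- setdiff(cfg$workflows, w)
    gap <- mean(y[acc, w, ]) - mean(y[acc, others, ])
    expect_gt(gap, 0.3)       # 1.5 planted minus noise
  }
})
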