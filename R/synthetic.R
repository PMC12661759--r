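# Synthetic multi-workflow CSF-style cohort generator with known ground
# truth for every downstream stage. Protein log2 abundance follows a crossed
# random-effects model y = mu_p + a_method + b_patient + delta_planted + e
# with configurable variance fractions; peptide intensities split the
# protein's raw intensity by fixed Dirichlet shares over its tryptic
# peptides; detection loss is missing-not-at-random via a logistic function
# of log2 intensity; deamidation site tables carry sequon and decoy sites
# with mixture-drawn localization probabilities; NTA exports are produced
# with known dilution factors.

#' Default simulation configuration
#'
#' The defaults describe the emulated study design: 5 workflows, 19
#' patients, 200 proteins; baseline protein log2 abundance N(20, 2); total
#' within-protein variance 0.5 (log2 scale) split (method, patient,
#' residual) = (0, 0.5, 0.5), i.e. patient and residual SD of 0.5 log2
#' units each, so that planted effects are the only true method
#' differences; 10% of proteins
#' planted as method-elevated with a 1.5 log2-unit effect; MNAR dropout with
#' logistic midpoint 14 and steepness 1.
#'
#' @param ... Overrides for any default field.
#' @return List of configuration fields.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_proteins = 200L,
    n_patients = 19L,
    workflows = c("MStern", "Seer", "N-Gp", "P20-EV", "P150-EV"),
    variance_fractions = c(method = 0, patient = 0.5, residual = 0.5),
    total_variance = 0.5,
    baseline_mean = 20, baseline_sd = 2,
    planted_fraction = 0.1, effect_size = 1.5,
    capture_prob = NULL,            # workflow x category matrix, default 1
    dropout = TRUE, dropout_midpoint = 14, dropout_steepness = 1,
    protein_length = c(150L, 450L),
    kr_density = 0.1,               # tryptic site every ~10 residues
    sequon_density = 0.01,          # planted sequons per residue
    decoy_site_rate = 0.3,          # non-sequon N positions emitted as decoys
    ploc_high_shape = c(20, 1), ploc_low_shape = c(2, 2),
    ploc_high_weight = 0.9,         # sequon sites drawn from the high mode
    peptide_length_range = c(7L, 35L),
    glyco_workflow = "N-Gp",
    nta = list(bins = seq(5, 500, by = 5), n_videos = 3L,
               dilution = c("P150-EV" = 4, "P20-EV" = 5),
               total_particles = c("P150-EV" = 2e9, "P20-EV" = 8e8),
               mode_nm = c("P150-EV" = 120, "P20-EV" = 150),
               sd_log = 0.35, video_cv = 0.1))
  over <- list(...)
  cfg[names(over)] <- over
  fr <- cfg$variance_fractions
  stopifnot(abs(sum(fr) - 1) < 1e-8, all(fr >= 0))
  cfg
}

# residue sampling weights: K+R at kr_density, rest uniform; P slightly
# down-weighted so the proline rule stays a minor perturbation
residue_weights <- function(kr_density) {
  w <- stats::setNames(rep(1, length(AA_ALPHABET)), AA_ALPHABET)
  w[c("K", "R")] <- 0
  w <- w / sum(w) * (1 - kr_density)
  w[c("K", "R")] <- kr_density / 2
  w
}

#' Generate a synthetic proteome with annotations and ground truth
#'
#' Random protein sequences with a configured tryptic-site density and
#' planted N-glycosylation sequons; every sequon present in the final
#' sequence (planted or chance-formed) is recorded in the ground truth.
#' Each protein receives one subcellular category (raw labels drawn from
#' the packaged consolidation scheme) and a brain-enriched-style gene list
#' is sampled.
#'
#' @param config From [sim_config()].
#' @param seed Integer seed (mandatory; all randomness derives from it).
#' @return List: `proteome` (named vector), `subcellular_raw` (named list
#'   id -> raw labels), `categories` (named vector id -> category),
#'   `gene_list`, `gene_sets`, `truth` (per-protein sequon positions).
#' @export
generate_proteome <- function(config = sim_config(), seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  n <- config$n_proteins
  w <- residue_weights(config$kr_density)
  accs <- sprintf("SYN%04d", seq_len(n))
  lens <- sample(config$protein_length[1]:config$protein_length[2], n,
                 replace = TRUE)
  xnotp <- setdiff(AA_ALPHABET, c("P", "K", "R"))
  proteome <- vapply(seq_len(n), function(i) {
    chars <- sample(names(w), lens[i], replace = TRUE, prob = w)
    n_seq <- stats::rbinom(1, lens[i], config$sequon_density)
    if (n_seq > 0) {
      starts <- sample(seq_len(max(1, lens[i] - 2)), min(n_seq, lens[i] %/% 3))
      for (s in starts) {
        chars[s] <- "N"
        chars[s + 1] <- sample(xnotp, 1)
        chars[s + 2] <- sample(c("S", "T"), 1)
      }
    }
    paste(chars, collapse = "")
  }, "")
  names(proteome) <- accs
  scheme <- subcellular_scheme()
  analyzed <- attr(scheme, "analyzed")
  categories <- stats::setNames(sample(analyzed, n, replace = TRUE), accs)
  subcellular_raw <- lapply(accs, function(a) {
    raw_members <- names(scheme)[scheme == categories[[a]]]
    sample(raw_members, min(length(raw_members), sample(1:2, 1)))
  })
  names(subcellular_raw) <- accs
  gene_list <- sort(sample(accs, max(1L, round(0.15 * n))))
  gene_sets <- lapply(split(accs, categories[accs]), unname)
  truth <- lapply(proteome, scan_sequons)
  list(proteome = proteome, subcellular_raw = subcellular_raw,
       categories = categories, gene_list = gene_list,
       gene_sets = gene_sets, truth = list(sequon_positions = truth))
}

# Dirichlet(1) shares
rdirichlet1 <- function(k) {
  g <- stats::rgamma(k, 1)
  g / sum(g)
}

#' Generate a full synthetic cohort over a proteome
#'
#' Draws the protein-level log2 abundance array under the crossed
#' random-effects model, splits protein intensity over tryptic peptides,
#' applies MNAR dropout, emits per-workflow peptide tables, a deamidation
#' site table for the glyco workflow, the sample sheet, and NTA exports,
#' together with a complete ground-truth record.
#'
#' @param config From [sim_config()].
#' @param proteome_obj From [generate_proteome()].
#' @param seed Integer seed.
#' @param tables Emit peptide/site/NTA tables (default). With FALSE only the
#'   sample sheet and ground truth (including the protein log2 abundance
#'   array) are produced -- a lightweight mode for large-n calibration
#'   checks of the abundance model itself.
#' @return List: `peptide_tables` (workflow -> `peptide_table`),
#'   `site_table`, `sample_sheet`, `nta` (fraction -> list(bins, counts,
#'   dilution)), `truth` (planted flags, variance fractions, protein log2
#'   abundance array, glycosite records).
#' @export
generate_cohort <- function(config = sim_config(), proteome_obj, seed,
                            tables = TRUE) {
  stopifnot(!missing(seed))
  set.seed(seed + 1L)
  proteome <- proteome_obj$proteome
  accs <- names(proteome)
  n <- length(accs)
  wf <- config$workflows
  patients <- sprintf("PT%02d", seq_len(config$n_patients))
  sample_sheet <- do.call(rbind, lapply(wf, function(w) {
    data.frame(sample_id = paste(w, patients, sep = "."), method = w,
               patient = patients, stringsAsFactors = FALSE)
  }))
  fr <- config$variance_fractions * config$total_variance
  sdm <- sqrt(fr[["method"]]); sdp <- sqrt(fr[["patient"]])
  sde <- sqrt(fr[["residual"]])
  # planted method-elevated proteins: disjoint across workflows
  n_planted <- round(config$planted_fraction * n)
  planted <- stats::setNames(rep(NA_character_, n), accs)
  if (n_planted > 0) {
    chosen <- sample(accs, n_planted)
    planted[chosen] <- rep(wf, length.out = n_planted)
  }
  mu <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  a <- matrix(stats::rnorm(n * length(wf), 0, sdm), n,
              dimnames = list(accs, wf))
  b <- matrix(stats::rnorm(n * length(patients), 0, sdp), n,
              dimnames = list(accs, patients))
  y <- array(NA_real_, c(n, length(wf), length(patients)),
             dimnames = list(accs, wf, patients))
  for (m in seq_along(wf)) {
    delta <- ifelse(!is.na(planted) & planted == wf[m], config$effect_size, 0)
    for (i in seq_along(patients)) {
      y[, m, i] <- mu + a[, m] + b[, i] + delta +
        stats::rnorm(n, 0, sde)
    }
  }
  if (!tables) {
    return(list(peptide_tables = NULL, site_table = NULL,
                sample_sheet = sample_sheet, nta = NULL,
                truth = list(planted = planted,
                             variance_fractions = config$variance_fractions,
                             protein_log2 = y)))
  }
  # per-protein capture by workflow (subcellular-category dependent)
  captured <- matrix(TRUE, n, length(wf), dimnames = list(accs, wf))
  if (!is.null(config$capture_prob)) {
    cats <- proteome_obj$categories[accs]
    for (m in wf) {
      p <- config$capture_prob[m, cats]
      captured[, m] <- stats::runif(n) < p
    }
  }
  # tryptic peptides and fixed Dirichlet shares
  lr <- config$peptide_length_range
  pep_info <- lapply(accs, function(acc) {
    d <- digest(proteome[[acc]], max_missed = 0L, proline_rule = TRUE)
    len <- nchar(d$sequence)
    d <- d[len >= lr[1] & len <= lr[2], , drop = FALSE]
    d$share <- if (nrow(d)) rdirichlet1(nrow(d)) else numeric()
    d
  })
  names(pep_info) <- accs
  detect <- function(log2_int) {
    if (!config$dropout) return(rep(TRUE, length(log2_int)))
    stats::runif(length(log2_int)) <
      stats::plogis(config$dropout_steepness *
                      (log2_int - config$dropout_midpoint))
  }
  peptide_tables <- stats::setNames(lapply(seq_along(wf), function(m) {
    samples <- sample_sheet$sample_id[sample_sheet$method == wf[m]]
    rows <- list()
    for (p_idx in seq_len(n)) {
      acc <- accs[p_idx]
      if (!captured[p_idx, m]) next
      pi <- pep_info[[acc]]
      if (!nrow(pi)) next
      raw_prot <- 2^y[acc, m, ]                     # per patient
      int <- outer(pi$share, raw_prot)              # peptide x patient
      li <- log2(int)
      keep <- matrix(detect(as.vector(li)), nrow(int))
      int[!keep] <- NA_real_
      observed <- rowSums(keep) > 0
      if (!any(observed)) next
      block <- data.frame(sequence = pi$sequence[observed],
                          accessions = acc, modifications = "",
                          stringsAsFactors = FALSE)
      im <- int[observed, , drop = FALSE]
      colnames(im) <- samples
      rows[[length(rows) + 1L]] <- cbind(block, as.data.frame(im))
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      cbind(data.frame(sequence = character(), accessions = character(),
                       modifications = character(), stringsAsFactors = FALSE),
            stats::setNames(as.data.frame(matrix(numeric(), 0, length(samples))),
                            samples))
    rownames(tab) <- NULL
    structure(tab, samples = samples, dialect = "generic_tsv",
              class = c("peptide_table", "data.frame"))
  }), wf)
  # deamidation site table for the glyco workflow
  gw <- config$glyco_workflow
  site_table <- NULL
  glyco_truth <- NULL
  if (gw %in% wf) {
    m <- match(gw, wf)
    samples <- sample_sheet$sample_id[sample_sheet$method == gw]
    srows <- list()
    for (p_idx in seq_len(n)) {
      acc <- accs[p_idx]
      if (!captured[p_idx, m]) next
      seqpos <- proteome_obj$truth$sequon_positions[[acc]]
      chars <- strsplit(proteome[[acc]], "")[[1]]
      decoy_pool <- setdiff(which(chars == "N"), seqpos)
      decoys <- decoy_pool[stats::runif(length(decoy_pool)) <
                             config$decoy_site_rate]
      pos <- c(seqpos, decoys)
      if (!length(pos)) next
      is_seq <- c(rep(TRUE, length(seqpos)), rep(FALSE, length(decoys)))
      hi <- is_seq & (stats::runif(length(pos)) < config$ploc_high_weight)
      ploc <- numeric(length(pos))
      ploc[hi] <- stats::rbeta(sum(hi), config$ploc_high_shape[1],
                               config$ploc_high_shape[2])
      ploc[!hi] <- stats::rbeta(sum(!hi), config$ploc_low_shape[1],
                                config$ploc_low_shape[2])
      shares <- rdirichlet1(length(pos))
      raw_prot <- 2^y[acc, m, ]
      int <- outer(shares, raw_prot)
      keep <- matrix(detect(as.vector(log2(int))), nrow(int))
      int[!keep] <- NA_real_
      observed <- rowSums(keep) > 0
      if (!any(observed)) next
      block <- data.frame(accession = acc, position = pos[observed],
                          localization_probability = round(ploc[observed], 6),
                          sequence_window = vapply(pos[observed], function(s) {
                            substr(proteome[[acc]], max(1, s - 3), s + 3)
                          }, ""), stringsAsFactors = FALSE)
      im <- int[observed, , drop = FALSE]
      colnames(im) <- samples
      srows[[length(srows) + 1L]] <- list(
        table = cbind(block, as.data.frame(im)),
        truth = data.frame(accession = acc, position = pos[observed],
                           is_sequon = is_seq[observed],
                           localization_probability = round(ploc[observed], 6),
                           stringsAsFactors = FALSE))
    }
    tabs <- lapply(srows, `[[`, "table")
    site_table <- if (length(tabs)) do.call(rbind, tabs) else NULL
    if (!is.null(site_table)) {
      rownames(site_table) <- NULL
      site_table <- structure(site_table, samples = samples,
                              class = c("site_table", "data.frame"))
    }
    glyco_truth <- if (length(srows))
      do.call(rbind, lapply(srows, `[[`, "truth")) else NULL
  }
  # NTA exports with known dilution factors
  ntacfg <- config$nta
  nta <- stats::setNames(lapply(names(ntacfg$dilution), function(fraction) {
    bins <- ntacfg$bins
    dens <- stats::dlnorm(bins, log(ntacfg$mode_nm[[fraction]]) +
                            ntacfg$sd_log^2, ntacfg$sd_log)
    true_conc <- dens / sum(dens) * ntacfg$total_particles[[fraction]]
    counts <- vapply(seq_len(ntacfg$n_videos), function(v) {
      true_conc / ntacfg$dilution[[fraction]] *
        exp(stats::rnorm(length(bins), 0, ntacfg$video_cv))
    }, numeric(length(bins)))
    list(bins = bins, counts = counts,
         dilution = ntacfg$dilution[[fraction]], true_conc = true_conc)
  }), names(ntacfg$dilution))
  list(peptide_tables = peptide_tables, site_table = site_table,
       sample_sheet = sample_sheet, nta = nta,
       truth = list(planted = planted,
                    variance_fractions = config$variance_fractions,
                    protein_log2 = y, captured = captured,
                    glycosites = glyco_truth,
                    peptide_shares = pep_info))
}

#' Write a generated cohort to a directory
#'
#' Emits `proteome.fasta`, `peptides_<workflow>.tsv`, `sites_<workflow>.tsv`,
#' `sample_sheet.tsv`, `subcellular.tsv`, `brain_enriched.tsv`,
#' `gene_sets.gmt`, `nta_<fraction>-ExperimentSummary.csv` and
#' `ground_truth.json`.
#'
#' @param proteome_obj From [generate_proteome()].
#' @param cohort From [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(proteome_obj, cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_fasta(proteome_obj$proteome, fp("proteome.fasta"))
  for (w in names(cohort$peptide_tables)) {
    write_peptide_table(cohort$peptide_tables[[w]],
                        fp(sprintf("peptides_%s.tsv", w)))
  }
  if (!is.null(cohort$site_table)) {
    write_site_table(cohort$site_table, fp("sites.tsv"))
  }
  utils::write.table(cohort$sample_sheet, fp("sample_sheet.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sub_lines <- vapply(names(proteome_obj$subcellular_raw), function(a) {
    paste0(a, "\t", paste(proteome_obj$subcellular_raw[[a]], collapse = ";"))
  }, "")
  writeLines(sub_lines, fp("subcellular.tsv"))
  writeLines(paste0(proteome_obj$gene_list, "\tbrain_enriched"),
             fp("brain_enriched.tsv"))
  gmt <- vapply(names(proteome_obj$gene_sets), function(s) {
    paste(c(s, "synthetic category set", proteome_obj$gene_sets[[s]]),
          collapse = "\t")
  }, "")
  writeLines(gmt, fp("gene_sets.gmt"))
  for (fraction in names(cohort$nta)) {
    x <- cohort$nta[[fraction]]
    lines <- c(sprintf("Sample,%s", fraction),
               sprintf("DilutionFactor,%s", x$dilution),
               paste(c("BinCenter",
                       paste0("Video", seq_len(ncol(x$counts)))),
                     collapse = ","),
               vapply(seq_along(x$bins), function(i) {
                 paste(c(format(x$bins[i]),
                         format(x$counts[i, ], digits = 10)), collapse = ",")
               }, ""))
    writeLines(lines, fp(sprintf("nta_%s-ExperimentSummary.csv", fraction)))
  }
  truth <- cohort$truth
  jsonlite::write_json(
    list(planted = as.list(truth$planted[!is.na(truth$planted)]),
         variance_fractions = as.list(truth$variance_fractions),
         n_proteins = length(proteome_obj$proteome),
         glycosites = truth$glycosites,
         categories = as.list(proteome_obj$categories)),
    fp("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
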