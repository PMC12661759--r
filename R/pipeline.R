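# End-to-end pipeline: load a cohort directory (as written by
# write_cohort(), or any data laid out in the same dialects), run every
# analysis stage, and write all stage outputs as TSV plus a JSON run
# summary. The pipeline itself is deterministic: all randomness lives in
# the generator.

stage_log <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- expr
  message(sprintf("[csfbench] stage %-10s %6.2fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Load a cohort directory into memory
#'
#' @param dir Directory produced by [write_cohort()] (or equivalent files).
#' @return List: `proteome`, `peptide_tables`, `site_table` (or NULL),
#'   `sample_sheet`, `annotations`, `gene_list`, `gene_sets`, `nta_files`.
#' @export
load_cohort <- function(dir) {
  fp <- function(...) file.path(dir, ...)
  sheet <- read_sample_sheet(fp("sample_sheet.tsv"))
  wf <- unique(sheet$method)
  pep <- stats::setNames(lapply(wf, function(w) {
    read_peptide_table(fp(sprintf("peptides_%s.tsv", w)))
  }), wf)
  site_path <- fp("sites.tsv")
  site <- if (file.exists(site_path)) read_site_table(site_path) else NULL
  ann <- read_annotation(fp("subcellular.tsv"), "subcellular")
  gl <- read_annotation(fp("brain_enriched.tsv"), "gene_list")
  gs <- read_annotation(fp("gene_sets.gmt"), "gene_sets")
  nta_files <- list.files(dir, pattern = "-ExperimentSummary\\.csv$",
                          full.names = TRUE)
  list(proteome = read_fasta(fp("proteome.fasta")), peptide_tables = pep,
       site_table = site, sample_sheet = sheet, annotations = ann,
       gene_list = names(gl$map), gene_sets = gs$map, nta_files = nta_files)
}

#' Run the full analysis pipeline on a cohort
#'
#' Chains protein-group assembly, glycosite calling, physicochemical
#' profiling, comparative statistics, fraction-enrichment classification
#' with subcellular ORA, variance partitioning, and NTA processing, writing
#' each stage's tables under `out_dir` and returning the in-memory results.
#'
#' @param cohort From [load_cohort()] (or the same structure built in
#'   memory).
#' @param out_dir Output directory for stage TSVs and `run_summary.json`.
#' @param glyco_workflow Workflow whose protein matrix comes from glycosite
#'   (rather than peptide-group) quantification; NULL disables.
#' @param nta_dilutions Named vector fraction label -> dilution factor used
#'   for any NTA files found.
#' @param alpha,min_detect Passed to [classify_fraction_proteins()].
#' @return List with every stage's results (`protein_matrices`,
#'   `peptide_matrices`, `glyco`, `physchem`, `compare`, `enrichment`,
#'   `ora`, `varpart`, `nta`, `summary`).
#' @export
run_pipeline <- function(cohort, out_dir,
                         glyco_workflow = "N-Gp",
                         nta_dilutions = c("P150-EV" = 4, "P20-EV" = 5),
                         alpha = 0.05, min_detect = 0.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  sheet <- cohort$sample_sheet
  wf <- unique(sheet$method)
  info_for <- function(samples) sheet[match(samples, sheet$sample_id), ]

  # --- assemble: peptide matrices + protein-group matrices per workflow
  assembled <- stage_log("assemble", {
    lapply(stats::setNames(wf, wf), function(w) {
      tab <- cohort$peptide_tables[[w]]
      samples <- attr(tab, "samples")
      groups <- group_peptides(tab)
      # group_id (smallest member accession) is the cross-workflow feature id
      list(groups = groups, protein = quantify_groups(groups, tab,
                                                      info_for(samples)))
    })
  })
  peptide_matrices <- lapply(stats::setNames(wf, wf), function(w) {
    tab <- cohort$peptide_tables[[w]]
    samples <- attr(tab, "samples")
    vals <- as.matrix(tab[, samples, drop = FALSE])
    obs <- rowsum((!is.na(vals)) * 1, tab$sequence)
    summed <- rowsum(vals, tab$sequence, na.rm = TRUE)
    summed[obs == 0] <- NA_real_
    quant_matrix(log2(summed), info_for(samples))
  })
  protein_matrices <- lapply(assembled, `[[`, "protein")
  for (w in wf) {
    tsv <- assembled[[w]]$groups
    df <- data.frame(
      group_id = vapply(tsv, `[[`, "", "group_id"),
      members = vapply(tsv, function(g) paste(g$members, collapse = ";"), ""),
      n_peptides = vapply(tsv, function(g) length(g$peptides), 0L),
      stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(protein_matrices[[w]]$values))
    utils::write.table(df, fp(sprintf("protein_groups_%s.tsv", w)),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }

  # --- glyco: call sites, quantify glycoproteins, swap in for that workflow
  glyco <- NULL
  if (!is.null(cohort$site_table) && !is.null(glyco_workflow) &&
      glyco_workflow %in% wf) {
    glyco <- stage_log("glyco", {
      siteset <- call_glycosites(cohort$site_table, cohort$proteome)
      audit_glycosites(siteset, cohort$proteome)
      gq <- quantify_glycoproteins(
        siteset, info_for(attr(cohort$site_table, "samples")))
      utils::write.table(
        cbind(siteset[c("accession", "position", "sequon",
                        "localization_probability")],
              as.data.frame(log2(as.matrix(
                siteset[, attr(siteset, "samples"), drop = FALSE])))),
        fp("glycosites.tsv"), sep = "\t", quote = FALSE, row.names = FALSE,
        na = "")
      list(siteset = siteset, quant = gq,
           rejected = attr(siteset, "rejected"))
    })
    protein_matrices[[glyco_workflow]] <- glyco$quant
  }
  for (w in wf) write_quant_matrix(protein_matrices[[w]],
                                   fp(sprintf("protein_matrix_%s.tsv", w)))

  # --- physchem: observed distributions vs in-silico reference digest
  physchem <- stage_log("physchem", {
    ref <- reference_distribution(cohort$proteome)
    observed_pep <- lapply(stats::setNames(wf, wf), function(w) {
      seqs <- rownames(peptide_matrices[[w]]$values)
      as.list(physchem_table(seqs))
    })
    observed_prot <- lapply(stats::setNames(wf, wf), function(w) {
      accs <- intersect(rownames(protein_matrices[[w]]$values),
                        names(cohort$proteome))
      as.list(physchem_table(unname(cohort$proteome[accs])))
    })
    ref_pep <- list(mw = ref$peptides$mw, gravy = ref$peptides$gravy,
                    pi = ref$peptides$pi)
    ref_prot <- list(mw = ref$proteins$mw, gravy = ref$proteins$gravy,
                     pi = ref$proteins$pi)
    tests_pep <- compare_distributions(observed_pep, ref_pep)
    tests_prot <- compare_distributions(observed_prot, ref_prot)
    tests_pep$level <- "peptide"; tests_prot$level <- "protein"
    tests <- rbind(tests_pep, tests_prot)
    utils::write.table(tests, fp("physchem_tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    list(reference = ref, tests = tests)
  })

  # --- comparative statistics
  compare <- stage_log("compare", {
    counts_prot <- detection_counts(protein_matrices)
    counts_pep <- detection_counts(peptide_matrices)
    memb_prot <- membership_sets(protein_matrices)
    memb_pep <- membership_sets(peptide_matrices)
    tiers <- lapply(protein_matrices, detection_tiers)
    tier_df <- do.call(rbind, lapply(wf, function(w) {
      cbind(workflow = w, tiers[[w]]$tiers)
    }))
    combined <- combine_matrices(protein_matrices)
    corr <- correlation_matrix(combined)
    pca <- tryCatch(pca_scores(combined), error = function(e) NULL)
    ra <- rank_abundance(combined, cohort$gene_list)
    utils::write.table(memb_prot$regions, fp("upset_proteins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(memb_pep$regions, fp("upset_peptides.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tier_df, fp("detection_tiers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cbind(sample_id = rownames(corr$r),
                             as.data.frame(corr$r)),
                       fp("correlation.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    if (!is.null(pca)) {
      utils::write.table(cbind(sample_id = rownames(pca$scores),
                               as.data.frame(pca$scores)),
                         fp("pca_scores.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    utils::write.table(ra$ranking, fp("rank_abundance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(counts_protein = counts_prot, counts_peptide = counts_pep,
         membership_protein = memb_prot, membership_peptide = memb_pep,
         tiers = tiers, correlation = corr, pca = pca, rank_abundance = ra)
  })

  # --- enrichment classification + subcellular ORA
  enrichment <- stage_log("enrich", {
    classify_fraction_proteins(protein_matrices, alpha = alpha,
                               min_detect = min_detect)
  })
  utils::write.table(enrichment$calls, fp("enrichment_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(enrichment$comparisons, fp("enrichment_comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  ora_tables <- stage_log("ora", {
    categories <- consolidate_locations(cohort$annotations)
    background <- sort(unique(unlist(lapply(protein_matrices, function(qm) {
      rownames(qm$values)[rowSums(!is.na(qm$values)) > 0]
    }))))
    out <- list()
    for (w in wf) {
      set <- intersect(enrichment$enriched[[w]], background)
      if (!length(set)) next
      tab <- ora(set, background, categories,
                 attr(subcellular_scheme(), "analyzed"))
      tab$workflow <- w
      out[[w]] <- tab
      utils::write.table(tab, fp(sprintf("ora_%s.tsv", w)), sep = "\t",
                         quote = FALSE, row.names = FALSE, na = "")
    }
    out
  })

  # --- variance partitioning
  varpart <- stage_log("varpart", {
    long <- long_observations(protein_matrices)
    fractions <- fit_variance_components_all(long)
    summary <- summarize_fractions(fractions)
    utils::write.table(fractions, fp("variance_fractions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    utils::write.table(summary, fp("variance_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(fractions = fractions, summary = summary)
  })

  # --- NTA
  nta <- NULL
  if (length(cohort$nta_files)) {
    nta <- stage_log("nta", {
      dists <- list()
      for (f in cohort$nta_files) {
        fraction <- sub("^nta_(.*)-ExperimentSummary\\.csv$", "\\1",
                        basename(f))
        dil <- if (fraction %in% names(nta_dilutions))
          nta_dilutions[[fraction]] else 1
        dists[[fraction]] <- normalize_and_summarize(load_nta(f), dil,
                                                     fraction)
      }
      merged <- if (length(dists) >= 2)
        merge_distributions(dists[[1]], dists[[2]]) else NULL
      tidy <- do.call(rbind, dists)
      utils::write.table(tidy, fp("nta_summary.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, na = "")
      if (!is.null(merged)) {
        utils::write.table(merged, fp("nta_merged.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE, na = "")
      }
      list(distributions = dists, merged = merged)
    })
  }

  summary <- list(
    workflows = wf,
    n_samples = nrow(sheet),
    n_protein_features = vapply(protein_matrices,
                                function(m) nrow(m$values), 0L),
    n_peptide_features = vapply(peptide_matrices,
                                function(m) nrow(m$values), 0L),
    n_glycosites = if (!is.null(glyco)) nrow(glyco$siteset) else 0L,
    glyco_rejected = if (!is.null(glyco)) as.list(glyco$rejected) else NULL,
    n_enriched = lapply(enrichment$enriched, length),
    protein_union = compare$membership_protein$union_size)
  jsonlite::write_json(summary, fp("run_summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(protein_matrices = protein_matrices,
                 peptide_matrices = peptide_matrices, assembled = assembled,
                 glyco = glyco, physchem = physchem, compare = compare,
                 enrichment = enrichment, ora = ora_tables,
                 varpart = varpart, nta = nta, summary = summary))
}

#' Combine per-workflow quantification matrices into one matrix
#'
#' Features are aligned by id over the union; samples are concatenated.
#' @param matrices Named list (workflow -> `quant_matrix`).
#' @return A single `quant_matrix`.
#' @export
combine_matrices <- function(matrices) {
  feats <- sort(unique(unlist(lapply(matrices,
                                     function(m) rownames(m$values)))))
  blocks <- lapply(matrices, function(m) {
    out <- matrix(NA_real_, length(feats), ncol(m$values),
                  dimnames = list(feats, colnames(m$values)))
    out[rownames(m$values), ] <- m$values
    out
  })
  info <- do.call(rbind, lapply(matrices, `[[`, "sample_info"))
  quant_matrix(do.call(cbind, blocks), info)
}
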