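# In-code fixture builders shared across test files.

# build a peptide_table object directly (bypassing the parser)
make_peptide_table <- function(sequence, accessions, intensities) {
  stopifnot(is.matrix(intensities))
  df <- data.frame(sequence = sequence, accessions = accessions,
                   modifications = "", stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(intensities))
  structure(df, samples = colnames(intensities), dialect = "generic_tsv",
            class = c("peptide_table", "data.frame"))
}

make_site_table <- function(accession, position, ploc, intensities) {
  df <- data.frame(accession = accession, position = position,
                   localization_probability = ploc, sequence_window = "",
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(intensities))
  structure(df, samples = colnames(intensities),
            class = c("site_table", "data.frame"))
}

make_qm <- function(values, method, patient = NULL) {
  if (is.null(patient)) patient <- paste0("P", seq_len(ncol(values)))
  if (is.null(colnames(values))) {
    colnames(values) <- paste(method, patient, sep = ".")
  }
  quant_matrix(values, data.frame(sample_id = colnames(values),
                                  method = method, patient = patient,
                                  stringsAsFactors = FALSE))
}

# per-workflow quant matrices with planted method shifts, paired patients
make_paired_matrices <- function(n_proteins, workflows, n_patients,
                                 planted = NULL, effect = 1.5,
                                 sd_patient = sqrt(0.3),
                                 sd_resid = sqrt(0.7), mean_log2 = 20) {
  prot <- sprintf("PR%03d", seq_len(n_proteins))
  pat <- sprintf("PT%02d", seq_len(n_patients))
  mu <- rnorm(n_proteins, mean_log2, 2)
  b <- matrix(rnorm(n_proteins * n_patients, 0, sd_patient), n_proteins)
  out <- lapply(workflows, function(w) {
    delta <- if (!is.null(planted)) {
      ifelse(!is.na(planted) & planted == w, effect, 0)
    } else 0
    v <- mu + delta + b + matrix(rnorm(n_proteins * n_patients, 0, sd_resid),
                                 n_proteins)
    dimnames(v) <- list(prot, paste(w, pat, sep = "."))
    make_qm(v, w, pat)
  })
  names(out) <- workflows
  out
}

tiny_config <- function(...) {
  sim_config(n_proteins = 20L, n_patients = 4L,
             protein_length = c(100L, 200L), ...)
}
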