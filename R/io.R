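# Readers and writers for the pipeline's file dialects: peptide tables
# (generic TSV and MaxQuant peptides.txt column subsets), modification-site
# tables, FASTA (UniProt headers tolerated), sample sheets, annotation TSVs
# and GMT gene sets. Zero / empty intensity means "not detected" and is
# carried as NA throughout; all downstream math works on log2 intensities.

DEFAULT_DROP_PREFIXES <- c("REV__", "CON__")

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0 && ncol(df) == 0) stop(sprintf("empty %s file: %s", what, path), call. = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s is missing mandatory column(s): %s", what,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}

# intensity columns: "Intensity <sample>" (MaxQuant) or "Intensity.<sample>"
intensity_samples <- function(cols) {
  hits <- grepl("^Intensity[ .]", cols)
  ids <- sub("^Intensity[ .]", "", cols[hits])
  stats::setNames(cols[hits], ids)
}

parse_intensity_columns <- function(df, what) {
  int_cols <- intensity_samples(names(df))
  if (!length(int_cols)) {
    stop(sprintf("%s has no 'Intensity <sample>' columns", what), call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow(df), length(int_cols),
                dimnames = list(NULL, names(int_cols)))
  for (j in seq_along(int_cols)) {
    raw <- df[[int_cols[j]]]
    absent <- is.na(raw) | raw == "" | raw == "NA" | raw == "0"
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!absent & (!is.finite(val) | val < 0))
    if (length(bad)) {
      stop(sprintf("%s: unparseable intensity '%s' in row %d (column %s)",
                   what, raw[bad[1]], bad[1], int_cols[j]), call. = FALSE)
    }
    val[absent | val == 0] <- NA_real_
    mat[, j] <- val
  }
  mat
}

#' Read a peptide quantification table
#'
#' Parses a search-engine peptide table (one row per peptide, per-sample
#' intensity columns). Zero or empty intensities are recorded as absent (NA);
#' rows whose every accession carries a decoy/contaminant prefix, or matches
#' a spike-in standard accession, are dropped.
#'
#' @param path TSV path. Mandatory columns `Sequence` and `Proteins`
#'   (";"-separated accessions); optional `Modifications`
#'   (";"-separated `position:name` entries); intensity columns named
#'   `Intensity <sample>` (MaxQuant style) or `Intensity.<sample>`.
#' @param dialect `"generic_tsv"` or `"maxquant"` (same column subset; kept
#'   for provenance in the result's attributes).
#' @param drop_prefixes Accession prefixes marking reverse decoys and
#'   contaminants.
#' @param standards Exact accessions of spike-in standards to remove.
#' @return A `peptide_table`: data.frame with columns `sequence`,
#'   `accessions`, `modifications` plus one numeric column per sample id;
#'   attribute `samples` lists the sample ids.
#' @export
read_peptide_table <- function(path, dialect = c("generic_tsv", "maxquant"),
                               drop_prefixes = DEFAULT_DROP_PREFIXES,
                               standards = character()) {
  dialect <- match.arg(dialect)
  df <- read_tsv_checked(path, c("Sequence", "Proteins"), "peptide table")
  mat <- parse_intensity_columns(df, "peptide table")
  seqs <- toupper(df$Sequence)
  bad <- which(!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seqs))
  if (length(bad)) {
    stop(sprintf("peptide table: invalid sequence in row %d", bad[1]), call. = FALSE)
  }
  accs <- strsplit(df$Proteins, ";", fixed = TRUE)
  if (any(lengths(accs) == 0)) {
    stop("peptide table: row with no accession", call. = FALSE)
  }
  keep_acc <- lapply(accs, function(a) {
    drop <- Reduce(`|`, lapply(drop_prefixes, startsWith, x = a), FALSE) |
      a %in% standards
    a[!drop]
  })
  keep <- lengths(keep_acc) > 0
  mods <- if ("Modifications" %in% names(df)) df$Modifications else ""
  out <- data.frame(sequence = seqs,
                    accessions = vapply(keep_acc, paste, "", collapse = ";"),
                    modifications = mods, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(mat))[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, samples = colnames(mat), dialect = dialect,
            class = c("peptide_table", "data.frame"))
}

#' Write a peptide table in the generic TSV dialect
#' @param table A `peptide_table`.
#' @param path Output path.
#' @export
write_peptide_table <- function(table, path) {
  samples <- attr(table, "samples")
  out <- table[c("sequence", "accessions", "modifications")]
  names(out) <- c("Sequence", "Proteins", "Modifications")
  for (s in samples) {
    v <- table[[s]]
    v[is.na(v)] <- 0
    out[[paste0("Intensity ", s)]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a modification-site table
#'
#' Parses a deamidation-site table: one row per (protein, position) with a
#' localization probability and per-sample intensities.
#'
#' @param path TSV path with mandatory columns `Protein`, `Position`,
#'   `Localization prob` (or `Localization.prob`), optional
#'   `Sequence window`, and intensity columns as in [read_peptide_table()].
#' @inheritParams read_peptide_table
#' @return A `site_table` data.frame: `accession`, `position`,
#'   `localization_probability`, `sequence_window` plus sample columns.
#' @export
read_site_table <- function(path, drop_prefixes = DEFAULT_DROP_PREFIXES,
                            standards = character()) {
  df <- read_tsv_checked(path, c("Protein", "Position"), "site table")
  loc_col <- intersect(c("Localization prob", "Localization.prob",
                         "Localization_prob"), names(df))
  if (!length(loc_col)) {
    stop("site table is missing mandatory column(s): Localization prob",
         call. = FALSE)
  }
  mat <- parse_intensity_columns(df, "site table")
  pos <- suppressWarnings(as.integer(df$Position))
  if (any(is.na(pos) | pos < 1)) {
    stop(sprintf("site table: invalid position in row %d",
                 which(is.na(pos) | pos < 1)[1]), call. = FALSE)
  }
  loc <- suppressWarnings(as.numeric(df[[loc_col[1]]]))
  if (any(is.na(loc) | loc < 0 | loc > 1)) {
    stop(sprintf("site table: localization probability outside [0, 1] in row %d",
                 which(is.na(loc) | loc < 0 | loc > 1)[1]), call. = FALSE)
  }
  win_col <- intersect(c("Sequence window", "Sequence.window"), names(df))
  win <- if (length(win_col)) df[[win_col[1]]] else ""
  drop <- Reduce(`|`, lapply(drop_prefixes, startsWith, x = df$Protein), FALSE) |
    df$Protein %in% standards
  out <- data.frame(accession = df$Protein, position = pos,
                    localization_probability = loc, sequence_window = win,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(mat))[!drop, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, samples = colnames(mat),
            class = c("site_table", "data.frame"))
}

#' Write a site table
#' @param table A `site_table`.
#' @param path Output path.
#' @export
write_site_table <- function(table, path) {
  samples <- attr(table, "samples")
  out <- data.frame(Protein = table$accession, Position = table$position,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out[["Localization prob"]] <- table$localization_probability
  out[["Sequence window"]] <- table$sequence_window
  for (s in samples) {
    v <- table[[s]]
    v[is.na(v)] <- 0
    out[[paste0("Intensity ", s)]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein FASTA file
#'
#' Headers are reduced to an accession: the first whitespace-delimited token,
#' with UniProt `sp|ACC|NAME` / `tr|ACC|NAME` forms unwrapped to `ACC`.
#'
#' @param path FASTA path.
#' @return Named character vector accession -> uppercase sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("empty FASTA file", call. = FALSE)
  acc <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1L)
  uni <- grepl("^(sp|tr)\\|", acc)
  acc[uni] <- vapply(strsplit(acc[uni], "|", fixed = TRUE), `[[`, "", 2L)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop(sprintf("empty sequence for accession %s", acc[!nzchar(seqs)][1]),
         call. = FALSE)
  }
  dup <- unique(acc[duplicated(acc)])
  if (length(dup)) {
    stop(sprintf("duplicate accession(s) in FASTA: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  stats::setNames(unname(seqs), acc)
}

#' Write a proteome to FASTA
#' @param proteome Named character vector accession -> sequence.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(proteome, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (acc in names(proteome)) {
    writeLines(paste0(">", acc), con)
    s <- proteome[[acc]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read the sample sheet mapping samples to workflow and patient
#'
#' @param path TSV with columns `sample_id`, `method`, `patient`.
#' @return data.frame with those columns.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "method", "patient"),
                         "sample sheet")
  if (any(!nzchar(df$method)) || any(!nzchar(df$patient))) {
    stop("sample sheet: empty method or patient label", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("sample sheet: duplicated sample_id", call. = FALSE)
  }
  df[c("sample_id", "method", "patient")]
}

#' Read an annotation map
#'
#' Three dialects: `subcellular` and `gene_list` are two-column TSVs
#' (id, label) where multi-label entries use ";" and ids repeated on several
#' lines take the union of labels; `gene_sets` is GMT
#' (set name, description, members, tab-separated).
#'
#' @param path Input path.
#' @param kind One of `"subcellular"`, `"gene_list"`, `"gene_sets"`.
#' @return List with `kind` and `map`: for TSV kinds a named list
#'   id -> character vector of labels; for GMT a named list
#'   set name -> character vector of members (description in attribute
#'   `descriptions`).
#' @export
read_annotation <- function(path, kind = c("subcellular", "gene_list",
                                           "gene_sets")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop(sprintf("empty annotation file: %s", path), call. = FALSE)
  if (kind == "gene_sets") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3)
    if (length(short)) {
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", short[1]),
           call. = FALSE)
    }
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(sets) <- vapply(fields, `[[`, "", 1L)
    attr(sets, "descriptions") <- stats::setNames(
      vapply(fields, `[[`, "", 2L), names(sets))
    return(list(kind = kind, map = sets))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) {
    stop(sprintf("malformed annotation line %d: expected id<TAB>label",
                 which(lengths(fields) < 2)[1]), call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  labels <- strsplit(vapply(fields, `[[`, "", 2L), ";", fixed = TRUE)
  map <- tapply(labels, ids, function(l) unique(unlist(l)), simplify = FALSE)
  list(kind = kind, map = map[unique(ids)])
}

#' Write a quantification matrix as TSV
#'
#' One row per feature; missing entries written as empty fields.
#' @param qm A `quant_matrix` (see [quant_matrix()]).
#' @param path Output path.
#' @export
write_quant_matrix <- function(qm, path) {
  df <- data.frame(feature_id = rownames(qm$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(qm$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a quantification matrix written by [write_quant_matrix()]
#' @param path TSV path.
#' @param sample_info data.frame with `sample_id`, `method`, `patient`.
#' @return A `quant_matrix`.
#' @export
read_quant_matrix <- function(path, sample_info) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  quant_matrix(m, sample_info[match(colnames(m), sample_info$sample_id), ])
}
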