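# N-glycosite calling from PNGase-F deamidation evidence: sites are retained
# when the deamidated asparagine sits in the canonical sequon N-[!P]-[STC]
# of the protein sequence and the localization probability strictly exceeds
# the threshold (default 0.8). Glycoproteins are quantified by summing
# intensities across their retained glycosites.

#' Scan a protein sequence for N-glycosylation sequons
#'
#' Reports every 1-based position i with residue N at i, anything but P at
#' i+1, and S/T/C at i+2. Overlapping sequons are all reported; the last two
#' residues of a sequence cannot start a sequon.
#'
#' @param protein_sequence Amino-acid sequence (may be empty).
#' @return Integer vector of sequon start positions (possibly empty).
#' @export
scan_sequons <- function(protein_sequence) {
  if (!nzchar(protein_sequence)) return(integer())
  chars <- check_sequence(protein_sequence)
  n <- length(chars)
  if (n < 3) return(integer())
  i <- seq_len(n - 2L)
  i[chars[i] == "N" & chars[i + 1L] != "P" & chars[i + 2L] %in% c("S", "T", "C")]
}

#' Call N-glycosites from a deamidation site table
#'
#' Retains sites whose localization probability strictly exceeds `threshold`
#' and whose protein position is a sequon start in the reference sequence.
#' Sites are deduplicated to unique (accession, position).
#'
#' @param sites A `site_table` from [read_site_table()].
#' @param proteome Named character vector accession -> sequence; every site
#'   accession must be present.
#' @param threshold Localization-probability cutoff in \[0, 1\] (strict ">").
#' @return A `glycosite_set`: data.frame `accession`, `position`, `sequon`
#'   (3-residue context), `localization_probability` plus raw intensity
#'   sample columns; attributes `samples`, `threshold`, and `rejected`
#'   (counts by reason).
#' @export
call_glycosites <- function(sites, proteome, threshold = 0.8) {
  stopifnot(threshold >= 0, threshold <= 1)
  samples <- attr(sites, "samples")
  missing_acc <- setdiff(unique(sites$accession), names(proteome))
  if (length(missing_acc)) {
    stop(sprintf("accession(s) absent from proteome: %s",
                 paste(missing_acc, collapse = ", ")), call. = FALSE)
  }
  plen <- nchar(proteome)[sites$accession]
  beyond <- which(sites$position > plen)
  if (length(beyond)) {
    stop(sprintf("site position %d beyond length of %s",
                 sites$position[beyond[1]], sites$accession[beyond[1]]),
         call. = FALSE)
  }
  sequon_pos <- lapply(proteome[unique(sites$accession)], scan_sequons)
  in_sequon <- mapply(function(a, p) p %in% sequon_pos[[a]],
                      sites$accession, sites$position, USE.NAMES = FALSE)
  pass_loc <- sites$localization_probability > threshold
  keep <- in_sequon & pass_loc
  rejected <- c(low_localization = sum(!pass_loc),
                non_sequon = sum(pass_loc & !in_sequon))
  out <- sites[keep, , drop = FALSE]
  out$sequon <- substr(proteome[out$accession], out$position, out$position + 2L)
  out <- out[!duplicated(paste(out$accession, out$position)), , drop = FALSE]
  out <- out[order(out$accession, out$position),
             c("accession", "position", "sequon", "localization_probability",
               samples), drop = FALSE]
  rownames(out) <- NULL
  structure(out, samples = samples, threshold = threshold, rejected = rejected,
            class = c("glycosite_set", "data.frame"))
}

#' Quantify N-glycoproteins by summing glycosite intensities
#'
#' Per protein and sample, the raw sum over its retained glycosites'
#' intensities, then log2; missing when no site is observed. Single-site
#' proteins are kept (no minimum-peptide threshold at the glycoprotein
#' level).
#'
#' @param siteset A `glycosite_set` from [call_glycosites()].
#' @param sample_info Optional data.frame (`sample_id`, `method`, `patient`).
#' @return A `quant_matrix`, one row per glycoprotein accession.
#' @export
quantify_glycoproteins <- function(siteset, sample_info = NULL) {
  if (nrow(siteset) == 0) stop("empty glycosite set", call. = FALSE)
  samples <- attr(siteset, "samples")
  if (is.null(sample_info)) {
    sample_info <- data.frame(sample_id = samples, method = "unknown",
                              patient = samples, stringsAsFactors = FALSE)
  }
  accs <- sort(unique(siteset$accession))
  int <- as.matrix(siteset[, samples, drop = FALSE])
  raw <- matrix(NA_real_, length(accs), length(samples),
                dimnames = list(accs, samples))
  for (a in accs) {
    sub <- int[siteset$accession == a, , drop = FALSE]
    s <- colSums(sub, na.rm = TRUE)
    s[colSums(!is.na(sub)) == 0] <- NA_real_
    raw[a, ] <- s
  }
  quant_matrix(log2(raw), sample_info)
}

#' Audit a glycosite set against the reference proteome
#'
#' Re-checks every retained site: residue N at the position, no proline at
#' +1, S/T/C at +2, and probability above the recorded threshold.
#'
#' @inheritParams quantify_glycoproteins
#' @param proteome Named character vector accession -> sequence.
#' @return TRUE invisibly; errors on the first violation.
#' @export
audit_glycosites <- function(siteset, proteome) {
  thr <- attr(siteset, "threshold")
  for (i in seq_len(nrow(siteset))) {
    ctx <- substr(proteome[[siteset$accession[i]]],
                  siteset$position[i], siteset$position[i] + 2L)
    ok <- nchar(ctx) == 3 && substr(ctx, 1, 1) == "N" &&
      substr(ctx, 2, 2) != "P" && substr(ctx, 3, 3) %in% c("S", "T", "C") &&
      siteset$localization_probability[i] > thr
    if (!ok) {
      stop(sprintf("glycosite audit failed at %s position %d",
                   siteset$accession[i], siteset$position[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}
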