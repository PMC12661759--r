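# In-silico tryptic digestion and peptide/protein physicochemical profiling:
# monoisotopic molecular weight, GRAVY hydropathy, and isoelectric point.

#' In-silico tryptic digest of one protein sequence
#'
#' Cleaves after K or R (optionally not before proline, the classic trypsin
#' rule) and emits every product carrying up to `max_missed` retained internal
#' cleavage sites, terminal fragments included. A sequence with no cleavage
#' site yields itself as a single peptide.
#'
#' @param sequence Protein sequence (uppercase one-letter amino acids).
#' @param max_missed Maximum number of missed cleavages per peptide (>= 0).
#' @param proline_rule If TRUE, K/R followed by P is not cleaved.
#' @return data.frame with columns `sequence`, `missed_cleavages`, `start`,
#'   `end` (1-based inclusive coordinates in the parent).
#' @export
digest <- function(sequence, max_missed = 2L, proline_rule = TRUE) {
  chars <- check_sequence(sequence)
  n <- length(chars)
  stopifnot(max_missed >= 0)
  # cut points: after position i
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n]
  if (proline_rule && length(cut_after)) {
    cut_after <- cut_after[chars[cut_after + 1L] != "P"]
  }
  bounds <- c(0L, cut_after, n)          # fragment i spans bounds[i]+1 .. bounds[i+1]
  nf <- length(bounds) - 1L
  out <- vector("list", 0L)
  for (i in seq_len(nf)) {
    for (k in 0:min(max_missed, nf - i)) {
      s <- bounds[i] + 1L
      e <- bounds[i + 1L + k]
      out[[length(out) + 1L]] <- list(
        sequence = paste(chars[s:e], collapse = ""),
        missed_cleavages = k, start = s, end = e)
    }
  }
  do.call(rbind.data.frame, c(out, list(stringsAsFactors = FALSE)))
}

#' Physicochemical profile of a peptide or protein sequence
#'
#' Computes monoisotopic molecular weight (sum of residue masses plus one
#' water), GRAVY (mean Kyte-Doolittle hydropathy) and the predicted
#' isoelectric point (pH of zero net charge under a Henderson-Hasselbalch
#' model over both termini and the D, E, C, Y, H, K, R side chains, located
#' by bisection on \[0, 14\]).
#'
#' @param sequence Amino-acid sequence, length >= 1.
#' @param pka pKa table; see [PKA_BJELLQVIST] for the structure.
#' @param tol Bisection tolerance on pH (pH units).
#' @return List with `molecular_weight` (Da), `gravy`, `isoelectric_point`.
#' @export
peptide_properties <- function(sequence, pka = PKA_BJELLQVIST, tol = 1e-4) {
  chars <- check_sequence(sequence)
  mw <- sum(MONOISOTOPIC_MASSES[chars]) + WATER_MONO
  gravy <- mean(KYTE_DOOLITTLE[chars])
  list(molecular_weight = unname(mw), gravy = unname(gravy),
       isoelectric_point = isoelectric_point(chars, pka = pka, tol = tol))
}

#' Net charge of a sequence at a given pH
#' @param chars Character vector of residues (or a single string).
#' @inheritParams peptide_properties
#' @param pH pH at which to evaluate.
#' @return Net charge (elementary charges).
#' @export
net_charge <- function(chars, pH, pka = PKA_BJELLQVIST) {
  if (length(chars) == 1L && nchar(chars) > 1L) chars <- check_sequence(chars)
  counts_pos <- c(Nterm = 1, table(factor(chars, levels = names(pka$positive))))
  counts_pos <- counts_pos[names(pka$positive)]
  counts_pos[is.na(counts_pos)] <- 0
  counts_neg <- c(Cterm = 1, table(factor(chars, levels = names(pka$negative))))
  counts_neg <- counts_neg[names(pka$negative)]
  counts_neg[is.na(counts_neg)] <- 0
  pos <- sum(counts_pos / (1 + 10^(pH - pka$positive)))
  neg <- sum(counts_neg / (1 + 10^(pka$negative - pH)))
  unname(pos - neg)
}

# net charge is strictly decreasing in pH, so bisection is safe
isoelectric_point <- function(chars, pka = PKA_BJELLQVIST, tol = 1e-4) {
  lo <- 0; hi <- 14
  if (net_charge(chars, lo, pka) <= 0) return(lo)
  if (net_charge(chars, hi, pka) >= 0) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(chars, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Reference physicochemical distributions from a digested proteome
#'
#' Digests every protein, filters peptides to a detectability length window,
#' optionally deduplicates peptide sequences proteome-wide, and returns
#' molecular weight, GRAVY and pI tables at both the peptide and the protein
#' level (protein properties are computed on the full sequence).
#'
#' @param proteome Named character vector, accession -> sequence.
#' @param max_missed,proline_rule Digest configuration; see [digest()].
#' @param length_range Length-2 integer vector, inclusive peptide length
#'   window (default 7-35 residues, a typical MS detectability window).
#' @param unique_only Deduplicate peptide sequences across the proteome.
#' @return List of two data.frames, `peptides` (id, accession, mw, gravy, pi)
#'   and `proteins` (one row per input accession).
#' @export
reference_distribution <- function(proteome, max_missed = 2L,
                                   proline_rule = TRUE,
                                   length_range = c(7L, 35L),
                                   unique_only = TRUE) {
  stopifnot(length(proteome) > 0, !is.null(names(proteome)))
  peps <- lapply(names(proteome), function(acc) {
    d <- digest(proteome[[acc]], max_missed = max_missed,
                proline_rule = proline_rule)
    d$accession <- acc
    d
  })
  peps <- do.call(rbind, peps)
  len <- nchar(peps$sequence)
  peps <- peps[len >= length_range[1] & len <= length_range[2], , drop = FALSE]
  if (unique_only) peps <- peps[!duplicated(peps$sequence), , drop = FALSE]
  pep_props <- physchem_table(peps$sequence)
  peptides <- cbind(data.frame(id = peps$sequence,
                               accession = peps$accession,
                               stringsAsFactors = FALSE), pep_props)
  prot_props <- physchem_table(unname(unlist(proteome)))
  proteins <- cbind(data.frame(id = names(proteome),
                               stringsAsFactors = FALSE), prot_props)
  rownames(peptides) <- rownames(proteins) <- NULL
  list(peptides = peptides, proteins = proteins)
}

# vectorized properties for many sequences: residue counts once, then
# bisection on the whole pH vector at once
physchem_table <- function(sequences, pka = PKA_BJELLQVIST, tol = 1e-4) {
  if (!length(sequences)) {
    return(data.frame(mw = numeric(), gravy = numeric(), pi = numeric()))
  }
  chars <- strsplit(sequences, "", fixed = TRUE)
  lens <- lengths(chars)
  fac <- factor(unlist(chars), levels = AA_ALPHABET)
  if (anyNA(fac)) stop("invalid residue in sequence set", call. = FALSE)
  counts <- unclass(table(factor(rep(seq_along(sequences), lens),
                                 levels = seq_along(sequences)), fac))
  mw <- as.vector(counts %*% MONOISOTOPIC_MASSES[AA_ALPHABET]) + WATER_MONO
  gravy <- as.vector(counts %*% KYTE_DOOLITTLE[AA_ALPHABET]) / lens
  pos_res <- setdiff(names(pka$positive), "Nterm")
  neg_res <- setdiff(names(pka$negative), "Cterm")
  cpos <- cbind(Nterm = 1, counts[, pos_res, drop = FALSE])
  cneg <- cbind(Cterm = 1, counts[, neg_res, drop = FALSE])
  pka_pos <- pka$positive[colnames(cpos)]
  pka_neg <- pka$negative[colnames(cneg)]
  # vector bisection: each sequence carries its own bracket
  nc <- function(pH) {
    rowSums(cpos / (1 + 10^outer(pH, pka_pos, `-`))) -
      rowSums(cneg / (1 + 10^outer(-pH, pka_neg, `+`)))
  }
  lo <- rep(0, length(sequences)); hi <- rep(14, length(sequences))
  while (max(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    positive <- nc(mid) > 0
    lo[positive] <- mid[positive]
    hi[!positive] <- mid[!positive]
  }
  data.frame(mw = mw, gravy = gravy, pi = (lo + hi) / 2)
}

#' Compare per-method physicochemical distributions against each other and a
#' reference
#'
#' For each property and each method, runs a two-sided rank-sum test of that
#' method's values versus the pooled other methods and versus the reference
#' digest, reporting group medians, a median-difference shift estimate, and
#' BH-adjusted p-values across the whole comparison family.
#'
#' @param observed Named list (method -> named list of numeric property
#'   vectors, e.g. `list(mw =, gravy =, pi =)`).
#' @param reference Named list of numeric property vectors for the reference.
#' @return data.frame, one row per (property, method, contrast).
#' @export
compare_distributions <- function(observed, reference) {
  stopifnot(length(observed) >= 1)
  props <- names(reference)
  rows <- list()
  for (pr in props) {
    for (m in names(observed)) {
      x <- observed[[m]][[pr]]
      others <- unlist(lapply(observed[names(observed) != m],
                              function(o) o[[pr]]), use.names = FALSE)
      for (contrast in c("rest", "reference")) {
        y <- if (contrast == "rest") others else reference[[pr]]
        degenerate <- length(x) < 3 || length(y) < 3 ||
          (length(unique(c(x, y))) < 2)
        if (degenerate) {
          rows[[length(rows) + 1L]] <- data.frame(
            property = pr, method = m, contrast = contrast,
            n_method = length(x), n_other = length(y),
            median_method = stats::median(x), median_other = stats::median(y),
            shift = NA_real_, p = NA_real_, degenerate = TRUE,
            stringsAsFactors = FALSE)
          next
        }
        tst <- wilcoxon_rank_sum(x, y)
        rows[[length(rows) + 1L]] <- data.frame(
          property = pr, method = m, contrast = contrast,
          n_method = length(x), n_other = length(y),
          median_method = stats::median(x), median_other = stats::median(y),
          shift = stats::median(x) - stats::median(y),
          p = tst$p_value, degenerate = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$adjusted_p[ok] <- bh_adjust(out$p[ok])
  out
}
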