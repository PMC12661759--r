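# Fraction-unique / fraction-elevated classification and Fisher's-exact
# over-representation of protein sets against subcellular categories or
# user gene sets. "Elevated in W" requires, against EVERY other workflow, a
# positive mean paired log2 difference and a BH-adjusted signed-rank p below
# alpha; BH families are per workflow-pair across proteins. The enriched set
# of a workflow is the union of its unique and elevated proteins.

#' The consolidated subcellular category scheme
#'
#' Reads the packaged raw-label -> category mapping (Human-Protein-Atlas
#' style location labels consolidated into main categories; top-level
#' category names map to themselves).
#'
#' @param path Optional path to an alternative two-column TSV
#'   (raw_label, category).
#' @return Named character vector raw label -> category; attribute
#'   `analyzed` lists the 11 categories used for over-representation.
#' @export
subcellular_scheme <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "subcellular_consolidation.tsv",
                        package = "csfbench", mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  scheme <- stats::setNames(df$category, df$raw_label)
  attr(scheme, "analyzed") <- c(
    "Vesicles", "Plasma membrane", "Nucleus", "Mitochondria", "Lysosomes",
    "Golgi apparatus", "Endoplasmic reticulum", "Cytosol", "Cell adhesion",
    "Cytoskeleton", "Cytoplasmic bodies")
  scheme
}

#' Consolidate raw subcellular labels into main categories
#'
#' @param raw_annotations Annotation map of kind `subcellular` (see
#'   [read_annotation()]): named list id -> raw labels.
#' @param scheme Named vector raw label -> category; see
#'   [subcellular_scheme()].
#' @return Named list id -> unique category vector; unmapped labels are
#'   dropped and counted in attribute `n_unmapped`.
#' @export
consolidate_locations <- function(raw_annotations, scheme = subcellular_scheme()) {
  map <- raw_annotations$map
  n_unmapped <- 0L
  out <- lapply(map, function(labels) {
    hit <- labels %in% names(scheme)
    n_unmapped <<- n_unmapped + sum(!hit)
    unique(unname(scheme[labels[hit]]))
  })
  out <- out[lengths(out) > 0]
  structure(out, n_unmapped = n_unmapped)
}

# paired per-patient log2 differences of one protein between two workflows
paired_differences <- function(va, vb, info_a, info_b) {
  pa <- stats::setNames(va, info_a$patient)
  pb <- stats::setNames(vb, info_b$patient)
  common <- intersect(info_a$patient, info_b$patient)
  d <- pa[common] - pb[common]
  d[!is.na(d)]
}

#' Classify proteins as fraction-unique, fraction-elevated, or neither
#'
#' Unique: detected (>= 1 sample) in exactly one workflow. Elevated in W:
#' for each other workflow V, restricted to proteins detected in at least
#' `min_detect` of samples within both W and V, the per-patient paired log2
#' differences give a two-tailed signed-rank p (BH-adjusted across proteins
#' within the (W, V) family) and a mean difference (the log2 fold change);
#' the protein must have log2FC > 0 and adjusted p < `alpha` in every
#' comparison. Comparisons with fewer than `min_pairs` complete pairs are
#' untestable and block elevation.
#'
#' @param matrices Named list (workflow -> `quant_matrix`), >= 2 workflows
#'   with patient-paired samples.
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @param min_detect Minimum detection fraction within each compared
#'   workflow (default 0.5).
#' @param min_pairs Minimum complete pairs per comparison (default 4).
#' @return List with `calls` (protein, class, workflow), `comparisons`
#'   (protein, workflow, other_method, log2FC, p, adjusted_p, n_pairs,
#'   testable), and `enriched` (workflow -> union of unique and elevated
#'   protein ids).
#' @export
classify_fraction_proteins <- function(matrices, alpha = 0.05,
                                       min_detect = 0.5, min_pairs = 4L) {
  stopifnot(length(matrices) >= 2)
  wf <- names(matrices)
  detected_in <- lapply(matrices, function(qm) {
    rownames(qm$values)[rowSums(!is.na(qm$values)) > 0]
  })
  all_prot <- sort(unique(unlist(detected_in)))
  n_wf_detected <- rowSums(vapply(detected_in, function(u) all_prot %in% u,
                                  logical(length(all_prot))))
  unique_tab <- data.frame(protein = all_prot, stringsAsFactors = FALSE)
  unique_tab$unique_in <- NA_character_
  only <- all_prot[n_wf_detected == 1]
  for (w in wf) {
    hit <- only[only %in% detected_in[[w]]]
    unique_tab$unique_in[unique_tab$protein %in% hit] <- w
  }
  det_frac <- lapply(matrices, function(qm) {
    rowSums(!is.na(qm$values)) / ncol(qm$values)
  })
  # pairwise comparisons, one BH family per ordered (W, V) pair
  comp_rows <- list()
  for (w in wf) {
    for (v in setdiff(wf, w)) {
      qa <- matrices[[w]]; qb <- matrices[[v]]
      cand <- intersect(names(det_frac[[w]])[det_frac[[w]] >= min_detect],
                        names(det_frac[[v]])[det_frac[[v]] >= min_detect])
      if (!length(cand)) next
      res <- lapply(cand, function(p) {
        d <- paired_differences(qa$values[p, ], qb$values[p, ],
                                qa$sample_info, qb$sample_info)
        if (length(d) < min_pairs || all(d == 0)) {
          return(list(log2FC = if (length(d)) mean(d) else NA_real_,
                      p = NA_real_, n_pairs = length(d), testable = FALSE))
        }
        tst <- wilcoxon_signed_rank(d)
        list(log2FC = mean(d), p = tst$p_value, n_pairs = length(d),
             testable = TRUE)
      })
      fam <- data.frame(protein = cand, workflow = w, other_method = v,
                        log2FC = vapply(res, `[[`, 0, "log2FC"),
                        p = vapply(res, `[[`, 0, "p"),
                        n_pairs = vapply(res, function(r) as.integer(r$n_pairs), 0L),
                        testable = vapply(res, `[[`, TRUE, "testable"),
                        stringsAsFactors = FALSE)
      fam$adjusted_p <- NA_real_
      if (any(fam$testable)) {
        fam$adjusted_p[fam$testable] <- bh_adjust(fam$p[fam$testable])
      }
      comp_rows[[paste(w, v)]] <- fam
    }
  }
  comparisons <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame(protein = character(), workflow = character(),
               other_method = character(), log2FC = numeric(), p = numeric(),
               n_pairs = integer(), testable = logical(),
               adjusted_p = numeric(), stringsAsFactors = FALSE)
  rownames(comparisons) <- NULL
  # elevated: every comparison of W vs each other workflow passes
  elevated <- stats::setNames(vector("list", length(wf)), wf)
  for (w in wf) {
    sub <- comparisons[comparisons$workflow == w, , drop = FALSE]
    if (!nrow(sub)) { elevated[[w]] <- character(); next }
    by_prot <- split(sub, sub$protein)
    ok <- vapply(by_prot, function(d) {
      nrow(d) == length(wf) - 1 && all(d$testable) &&
        all(d$log2FC > 0) && all(d$adjusted_p < alpha)
    }, TRUE)
    elevated[[w]] <- names(by_prot)[ok]
  }
  calls <- data.frame(protein = all_prot, class = "none",
                      workflow = NA_character_, stringsAsFactors = FALSE)
  for (w in wf) {
    hit <- calls$protein %in% elevated[[w]]
    calls$class[hit] <- "elevated"
    calls$workflow[hit] <- w
  }
  uq <- !is.na(unique_tab$unique_in)
  calls$class[uq] <- "unique"
  calls$workflow[uq] <- unique_tab$unique_in[uq]
  enriched <- stats::setNames(lapply(wf, function(w) {
    sort(unique(c(elevated[[w]], unique_tab$protein[
      !is.na(unique_tab$unique_in) & unique_tab$unique_in == w])))
  }), wf)
  list(calls = calls, comparisons = comparisons, enriched = enriched)
}

#' Fisher's-exact over-representation analysis
#'
#' For each category, builds the 2x2 table {in set & in category, in set &
#' not, not in set & in category, not in set & not} over the background,
#' tests it with [fisher_2x2()], and BH-adjusts across categories. Direction
#' is the sign of the log2 conditional-MLE odds ratio.
#'
#' @param protein_set Character vector, a subset of `background`.
#' @param background Character vector: the detected-anywhere universe.
#' @param categories Named list id -> category vector (see
#'   [consolidate_locations()]) or an annotation `map`.
#' @param category_names Categories to test; defaults to all categories
#'   present in the background's annotations.
#' @return data.frame: category, counts, odds_ratio, log2_odds_ratio, p,
#'   adjusted_p, direction ("over"/"under"/"none"); categories without
#'   background members are skipped (attribute `skipped`).
#' @export
ora <- function(protein_set, background, categories, category_names = NULL) {
  if (!length(protein_set)) stop("empty protein set", call. = FALSE)
  if (!all(protein_set %in% background)) {
    stop("protein set must be a subset of the background", call. = FALSE)
  }
  bg_cat <- categories[intersect(names(categories), background)]
  if (is.null(category_names)) {
    category_names <- sort(unique(unlist(bg_cat)))
  }
  rows <- list(); skipped <- character()
  for (cat in category_names) {
    members <- names(bg_cat)[vapply(bg_cat, function(x) cat %in% x, TRUE)]
    if (!length(members)) { skipped <- c(skipped, cat); next }
    a <- sum(protein_set %in% members)
    b <- length(protein_set) - a
    cc <- length(setdiff(members, protein_set))
    d <- length(background) - a - b - cc
    ft <- if ((cc + d) == 0 || (a + b) == 0 || (b + d) == 0) {
      # set identical to the background (or a category spanning it):
      # membership carries no information, the exchangeable identity holds
      list(odds_ratio = 1, log2_odds_ratio = 0, p_value = 1)
    } else {
      fisher_2x2(a, b, cc, d)
    }
    rows[[cat]] <- data.frame(
      category = cat, in_set_in_cat = a, in_set_not = b,
      not_set_in_cat = cc, not_set_not = d,
      odds_ratio = ft$odds_ratio, log2_odds_ratio = ft$log2_odds_ratio,
      p = ft$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$adjusted_p <- bh_adjust(out$p)
  out$direction <- ifelse(out$odds_ratio > 1, "over",
                          ifelse(out$odds_ratio < 1, "under", "none"))
  structure(out, skipped = skipped)
}
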