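# Cross-workflow comparisons: per-sample detection counts, exclusive
# membership (UpSet-style) regions, reproducibility tiers by detection
# frequency, pairwise sample correlation, PCA, and rank-abundance tables.

#' Per-sample detection counts and per-workflow medians
#'
#' @param matrices Named list (workflow -> `quant_matrix`).
#' @return List with `per_sample` (workflow, sample_id, n_detected) and
#'   `per_workflow` (workflow, median_detected).
#' @export
detection_counts <- function(matrices) {
  per_sample <- do.call(rbind, lapply(names(matrices), function(w) {
    qm <- matrices[[w]]
    data.frame(workflow = w, sample_id = colnames(qm$values),
               n_detected = colSums(!is.na(qm$values)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  per_workflow <- do.call(rbind, lapply(split(per_sample, per_sample$workflow),
    function(d) data.frame(workflow = d$workflow[1],
                           median_detected = stats::median(d$n_detected),
                           stringsAsFactors = FALSE)))
  rownames(per_workflow) <- NULL
  list(per_sample = per_sample, per_workflow = per_workflow)
}

#' Exclusive-intersection membership counts across workflows
#'
#' A feature belongs to a workflow's universe when detected in at least one
#' of its samples. Every feature is assigned to exactly one of the 2^k - 1
#' non-empty workflow combinations.
#'
#' @param matrices Named list (workflow -> `quant_matrix`), length >= 2.
#' @return List with `universes` (workflow -> feature ids), `regions`
#'   (data.frame: combination label "A&B", n, plus one logical column per
#'   workflow), and `union_size`.
#' @export
membership_sets <- function(matrices) {
  stopifnot(length(matrices) >= 2)
  universes <- lapply(matrices, function(qm) {
    rownames(qm$values)[rowSums(!is.na(qm$values)) > 0]
  })
  all_feats <- sort(unique(unlist(universes)))
  memb <- vapply(universes, function(u) all_feats %in% u,
                 logical(length(all_feats)))
  if (length(all_feats) == 1L) memb <- matrix(memb, nrow = 1,
                                              dimnames = list(NULL, names(universes)))
  key <- apply(memb, 1, function(row) paste(names(universes)[row], collapse = "&"))
  tab <- table(key)
  regions <- data.frame(combination = names(tab), n = as.integer(tab),
                        stringsAsFactors = FALSE)
  for (w in names(universes)) {
    regions[[w]] <- vapply(strsplit(regions$combination, "&", fixed = TRUE),
                           function(s) w %in% s, TRUE)
  }
  regions <- regions[order(-regions$n, regions$combination), , drop = FALSE]
  rownames(regions) <- NULL
  list(universes = universes, regions = regions,
       union_size = length(all_feats))
}

#' Reproducibility tiers by detection frequency
#'
#' Detection frequency f = detected samples / total samples per feature;
#' tiers are the half-open intervals (0.9, 1\], (0.5, 0.9\], (0.1, 0.5\],
#' (0, 0.1\] so every detected feature lands in exactly one tier.
#'
#' @param matrix A `quant_matrix` for one workflow.
#' @param cuts Descending interior cut points (default 0.9, 0.5, 0.1).
#' @return List with `frequencies` (named per feature) and `tiers`
#'   (data.frame tier label, n).
#' @export
detection_tiers <- function(matrix, cuts = c(0.9, 0.5, 0.1)) {
  v <- matrix$values
  stopifnot(ncol(v) >= 1)
  f <- rowSums(!is.na(v)) / ncol(v)
  f <- f[f > 0]
  breaks <- c(0, rev(cuts), 1)
  labels <- paste0("(", utils::head(breaks, -1), ",", breaks[-1], "]")
  tier <- cut(f, breaks = breaks, labels = labels, right = TRUE)
  tiers <- data.frame(tier = rev(labels),
                      n = as.integer(rev(table(tier))),
                      stringsAsFactors = FALSE)
  list(frequencies = f, tiers = tiers)
}

#' Pairwise Spearman correlation across all samples with clustering order
#'
#' Correlations use pairwise-complete features (present in both samples);
#' pairs sharing fewer than 3 features are missing. Display order comes from
#' average-linkage hierarchical clustering of 1 - r.
#'
#' @param qm A `quant_matrix` combining all workflows (>= 2 samples).
#' @return List with `r` (symmetric matrix, unit diagonal) and `order`
#'   (dendrogram leaf order).
#' @export
correlation_matrix <- function(qm) {
  v <- qm$values
  ns <- ncol(v)
  stopifnot(ns >= 2)
  r <- diag(1, ns)
  dimnames(r) <- list(colnames(v), colnames(v))
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      r[i, j] <- r[j, i] <- spearman(v[, i], v[, j])
    }
  }
  d <- 1 - r
  d[is.na(d)] <- 2  # maximal dissimilarity for undefined pairs
  ord <- stats::hclust(stats::as.dist(d), method = "average")$order
  list(r = r, order = colnames(v)[ord])
}

#' PCA of samples on complete features
#'
#' Features with any missing value are removed; the remaining matrix is
#' transposed (samples as observations), column-centered, and decomposed by
#' SVD. No scaling or imputation.
#'
#' @param qm A `quant_matrix` with >= 3 samples.
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x components), `explained` (variance
#'   fraction per returned component; all fractions sum to 1 over the full
#'   decomposition), `n_features` used.
#' @export
pca_scores <- function(qm, n_components = 2L) {
  v <- qm$values
  stopifnot(ncol(v) >= 3)
  complete <- v[rowSums(is.na(v)) == 0, , drop = FALSE]
  if (nrow(complete) < 2) {
    stop("fewer than 2 complete features: PCA undefined", call. = FALSE)
  }
  x <- scale(t(complete), center = TRUE, scale = FALSE)
  sv <- svd(x)
  k <- min(n_components, length(sv$d))
  scores <- x %*% sv$v[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  explained <- sv$d^2 / sum(sv$d^2)
  list(scores = scores, explained = explained[seq_len(k)],
       explained_all = explained, n_features = nrow(complete))
}

#' Rank-abundance table with marker-panel flags
#'
#' Features ranked by descending median intensity across samples (ties
#' broken lexicographically by feature id). Each marker-panel member is
#' reported with its detection fraction (0 when absent from the matrix).
#'
#' @param qm A `quant_matrix`.
#' @param marker_panel Character vector of feature ids of interest.
#' @return List with `ranking` (feature_id, median_log2, rank, is_marker)
#'   and `markers` (marker, detected_fraction, in_matrix).
#' @export
rank_abundance <- function(qm, marker_panel = character()) {
  v <- qm$values
  med <- apply(v, 1, stats::median, na.rm = TRUE)
  ord <- order(-med, rownames(v))
  ranking <- data.frame(feature_id = rownames(v)[ord],
                        median_log2 = med[ord],
                        rank = seq_along(ord),
                        is_marker = rownames(v)[ord] %in% marker_panel,
                        stringsAsFactors = FALSE, row.names = NULL)
  det_frac <- rowSums(!is.na(v)) / ncol(v)
  markers <- data.frame(marker = marker_panel,
                        detected_fraction = ifelse(
                          marker_panel %in% rownames(v),
                          det_frac[marker_panel], 0),
                        in_matrix = marker_panel %in% rownames(v),
                        stringsAsFactors = FALSE, row.names = NULL)
  list(ranking = ranking, markers = markers)
}
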