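# Assembly of peptide evidence into protein groups and intensity-sum
# quantification. The grouping algorithm (merge identical peptide sets,
# absorb strict subsets, assign shared peptides greedily to the group with
# the most distinct peptides) is a parsimony scheme chosen to be
# deterministic and order-independent; groups need >= 2 assigned peptides.

#' Log2 quantification matrix with sample metadata
#'
#' @param values Numeric matrix, features x samples, log2 intensities with NA
#'   for not-detected; finite otherwise.
#' @param sample_info data.frame with columns `sample_id`, `method`,
#'   `patient`, one row per column of `values`.
#' @return A `quant_matrix` list with elements `values` and `sample_info`.
#' @export
quant_matrix <- function(values, sample_info) {
  stopifnot(is.matrix(values),
            all(c("sample_id", "method", "patient") %in% names(sample_info)),
            ncol(values) == nrow(sample_info))
  if (any(!is.finite(values[!is.na(values)]))) {
    stop("quant matrix values must be finite or NA", call. = FALSE)
  }
  colnames(values) <- sample_info$sample_id
  rownames(sample_info) <- NULL
  structure(list(values = values, sample_info = sample_info),
            class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix: %d features x %d samples (%d method(s), %d patient(s))\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_info$method)),
              length(unique(x$sample_info$patient))))
  invisible(x)
}

#' Assemble peptides into protein groups
#'
#' Steps: (1) collect each accession's observed peptide set; (2) merge
#' accessions with identical sets into one group; (3) absorb any group whose
#' peptide set is a strict subset of another's (ties resolved toward the
#' larger set, then lexicographically smallest group id); (4) assign each
#' peptide shared between remaining groups to the group with the most
#' distinct peptides, ties broken lexicographically; (5) drop groups left
#' with fewer than `min_peptides` assigned peptides.
#'
#' @param table A `peptide_table` from [read_peptide_table()].
#' @param min_peptides Minimum peptides per retained group (default 2).
#' @return List of groups, each a list with `group_id` (lexicographically
#'   smallest member accession), `members`, `peptides` (assigned sequences,
#'   disjoint across groups).
#' @export
group_peptides <- function(table, min_peptides = 2L) {
  if (nrow(table) == 0) return(list())
  accs <- strsplit(table$accessions, ";", fixed = TRUE)
  pep_by_acc <- list()
  for (i in seq_len(nrow(table))) {
    for (a in accs[[i]]) pep_by_acc[[a]] <- c(pep_by_acc[[a]], table$sequence[i])
  }
  pep_by_acc <- lapply(pep_by_acc, function(p) sort(unique(p)))
  pep_by_acc <- pep_by_acc[order(names(pep_by_acc))]
  # (2) merge identical observed peptide sets
  keys <- vapply(pep_by_acc, paste, "", collapse = "\r")
  members <- split(names(pep_by_acc), keys)
  groups <- lapply(members, function(m) {
    list(members = sort(m), set = pep_by_acc[[m[1]]])
  })
  names(groups) <- NULL
  # (3) subsumption: absorb strict subsets into their (best) superset
  sizes <- vapply(groups, function(g) length(g$set), 0L)
  gid <- vapply(groups, function(g) g$members[1], "")
  ord <- order(sizes, gid)  # process smallest sets first
  absorbed_into <- rep(NA_integer_, length(groups))
  for (i in ord) {
    cand <- integer()
    for (j in seq_along(groups)) {
      if (i == j || !is.na(absorbed_into[j])) next
      if (sizes[j] > sizes[i] && all(groups[[i]]$set %in% groups[[j]]$set)) {
        cand <- c(cand, j)
      }
    }
    if (length(cand)) {
      best <- cand[order(-sizes[cand], gid[cand])][1]
      absorbed_into[i] <- best
    }
  }
  # follow absorption chains to a surviving root
  root <- function(i) { while (!is.na(absorbed_into[i])) i <- absorbed_into[i]; i }
  for (i in seq_along(groups)) {
    if (!is.na(absorbed_into[i])) {
      r <- root(i)
      groups[[r]]$members <- sort(unique(c(groups[[r]]$members,
                                           groups[[i]]$members)))
    }
  }
  groups <- groups[is.na(absorbed_into)]
  gid <- vapply(groups, function(g) g$members[1], "")
  groups <- groups[order(gid)]
  gid <- sort(gid)
  # (4) assign shared peptides: most distinct peptides wins, then lexicographic
  n_distinct <- vapply(groups, function(g) length(g$set), 0L)
  owner <- list()
  for (k in seq_along(groups)) {
    for (p in groups[[k]]$set) {
      cur <- owner[[p]]
      if (is.null(cur) ||
          n_distinct[k] > n_distinct[cur] ||
          (n_distinct[k] == n_distinct[cur] && gid[k] < gid[cur])) {
        owner[[p]] <- k
      }
    }
  }
  assigned <- vector("list", length(groups))
  for (p in names(owner)) {
    k <- owner[[p]]
    assigned[[k]] <- c(assigned[[k]], p)
  }
  out <- list()
  for (k in seq_along(groups)) {
    peps <- sort(assigned[[k]])
    if (length(peps) >= min_peptides) {
      out[[length(out) + 1L]] <- list(group_id = gid[k],
                                      members = groups[[k]]$members,
                                      peptides = peps)
    }
  }
  out
}

#' Quantify protein groups by summing constituent peptide intensities
#'
#' Group intensity per sample is the sum of the raw intensities of its
#' assigned peptides observed in that sample (log of sums, not sum of logs);
#' samples where no assigned peptide is observed are missing.
#'
#' @param groups Output of [group_peptides()] on the same table.
#' @param table The `peptide_table` the groups came from.
#' @param sample_info data.frame (`sample_id`, `method`, `patient`); defaults
#'   to unlabeled samples when omitted.
#' @return A `quant_matrix` of log2 summed intensities, one row per group.
#' @export
quantify_groups <- function(groups, table, sample_info = NULL) {
  samples <- attr(table, "samples")
  if (is.null(sample_info)) {
    sample_info <- data.frame(sample_id = samples, method = "unknown",
                              patient = samples, stringsAsFactors = FALSE)
  }
  known <- unique(table$sequence)
  raw <- matrix(NA_real_, length(groups), length(samples),
                dimnames = list(vapply(groups, `[[`, "", "group_id"), samples))
  int <- as.matrix(table[, samples, drop = FALSE])
  for (k in seq_along(groups)) {
    peps <- groups[[k]]$peptides
    if (!all(peps %in% known)) {
      stop(sprintf("group %s references peptide(s) absent from the table",
                   groups[[k]]$group_id), call. = FALSE)
    }
    rows <- which(table$sequence %in% peps)
    sub <- int[rows, , drop = FALSE]
    s <- colSums(sub, na.rm = TRUE)
    s[colSums(!is.na(sub)) == 0] <- NA_real_
    raw[k, ] <- s
  }
  quant_matrix(log2(raw), sample_info)
}
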