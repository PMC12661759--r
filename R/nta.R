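# Nanoparticle-tracking-analysis processing: parse ExperimentSummary-style
# CSV exports (bin centers x per-video concentrations), normalize by the
# sample dilution factor, summarize replicate videos as mean +/- SE, and
# align two fractions on exact bin centers for comparison.

#' Load a raw NTA export
#'
#' Minimal assumed dialect: a CSV whose first column is the size-bin center
#' (nm, strictly increasing) and every further column one video capture's
#' particle concentration. Leading metadata lines (fewer comma-separated
#' fields than the header of the data block, or non-numeric first field) are
#' preserved as header metadata.
#'
#' @param path CSV path.
#' @return List with `bins` (numeric vector), `counts` (matrix bins x
#'   videos), `metadata` (character vector of skipped lines).
#' @export
load_nta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  first_num <- suppressWarnings(
    as.numeric(vapply(strsplit(lines, ",", fixed = TRUE), `[[`, "", 1L)))
  data_start <- which(is.finite(first_num))[1]
  if (is.na(data_start)) stop("no numeric data rows in NTA file", call. = FALSE)
  metadata <- if (data_start > 1) lines[seq_len(data_start - 1L)] else character()
  fields <- strsplit(lines[data_start:length(lines)], ",", fixed = TRUE)
  ncols <- max(lengths(fields))
  if (ncols < 2) stop("NTA file has no video concentration columns", call. = FALSE)
  mat <- matrix(NA_real_, length(fields), ncols)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    v <- suppressWarnings(as.numeric(f))
    bad <- which(is.na(v) & nzchar(trimws(f)))
    if (length(bad)) {
      stop(sprintf("non-numeric NTA cell '%s' at data row %d, column %d",
                   f[bad[1]], i, bad[1]), call. = FALSE)
    }
    mat[i, seq_along(v)] <- v
  }
  bins <- mat[, 1]
  if (any(diff(bins) <= 0)) {
    stop("NTA bin centers must be strictly increasing", call. = FALSE)
  }
  counts <- mat[, -1, drop = FALSE]
  colnames(counts) <- paste0("video", seq_len(ncol(counts)))
  list(bins = bins, counts = counts, metadata = metadata)
}

#' Dilution-normalize and summarize an NTA measurement
#'
#' Multiplies every count by the dilution factor, then reports per-bin mean
#' and standard error (sample SD / sqrt(n videos)) across technical
#' replicate videos; SE is missing with a single video.
#'
#' @param raw Output of [load_nta()].
#' @param dilution_factor Positive scalar (e.g. 4 for a P150-EV fraction,
#'   5 for P20-EV).
#' @param fraction Label carried into the output.
#' @return A `size_distribution` data.frame: `fraction`, `bin_center_nm`,
#'   `concentration_mean`, `concentration_se`; attribute `dilution_factor`.
#' @export
normalize_and_summarize <- function(raw, dilution_factor, fraction = "sample") {
  stopifnot(dilution_factor > 0)
  norm <- raw$counts * dilution_factor
  nv <- ncol(norm)
  se <- if (nv > 1) apply(norm, 1, stats::sd) / sqrt(nv) else
    rep(NA_real_, nrow(norm))
  out <- data.frame(fraction = fraction, bin_center_nm = raw$bins,
                    concentration_mean = rowMeans(norm),
                    concentration_se = se, stringsAsFactors = FALSE)
  structure(out, dilution_factor = dilution_factor,
            class = c("size_distribution", "data.frame"))
}

#' Merge two size distributions on bin centers
#'
#' Outer join with exact center matching (tolerance 1e-9 nm); bins present
#' in only one fraction carry missing values for the other. Warns (but still
#' joins) when the grids share no bin.
#'
#' @param a,b `size_distribution` objects.
#' @return data.frame: `bin_center_nm`, then mean/SE columns suffixed by the
#'   two fraction labels.
#' @export
merge_distributions <- function(a, b) {
  key <- function(x) round(x / 1e-9) * 1e-9
  ka <- key(a$bin_center_nm); kb <- key(b$bin_center_nm)
  if (!length(intersect(ka, kb))) {
    warning("size distributions share no bin centers; emitting outer join")
  }
  la <- a$fraction[1]; lb <- b$fraction[1]
  if (identical(la, lb)) lb <- paste0(lb, ".2")
  centers <- sort(unique(c(ka, kb)))
  out <- data.frame(bin_center_nm = centers)
  out[[paste0("mean_", la)]] <- a$concentration_mean[match(centers, ka)]
  out[[paste0("se_", la)]] <- a$concentration_se[match(centers, ka)]
  out[[paste0("mean_", lb)]] <- b$concentration_mean[match(centers, kb)]
  out[[paste0("se_", lb)]] <- b$concentration_se[match(centers, kb)]
  out
}
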