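# Per-protein decomposition of log2-intensity variance into method, patient
# and residual components under a crossed random-intercepts model
# y = mu + a_method + b_patient + e, fitted by EM-REML (components
# non-negative by construction). Missing cells are simply omitted
# observations; no imputation.

#' Fit variance components for one protein
#'
#' EM-REML for the crossed random-intercepts model, iterated to a tolerance
#' of `tol` on the restricted log-likelihood (at most `max_iter` iterations).
#' Reported fractions are each component's variance over the total.
#'
#' @param observations data.frame with columns `method`, `patient`, `value`
#'   (finite log2 intensities).
#' @param min_obs Minimum observations required (default 6).
#' @param tol Convergence tolerance on the restricted log-likelihood.
#' @param max_iter Iteration cap.
#' @return List with `fraction_method`, `fraction_patient`,
#'   `fraction_residual`, `sigma2` (the three variance components),
#'   `n_observations`, `converged`, `status` ("ok", "degenerate", or a skip
#'   reason).
#' @export
fit_variance_components <- function(observations, min_obs = 6L,
                                    tol = 1e-8, max_iter = 500L) {
  obs <- observations[is.finite(observations$value), , drop = FALSE]
  n <- nrow(obs)
  skip <- function(reason) list(
    fraction_method = NA_real_, fraction_patient = NA_real_,
    fraction_residual = NA_real_, sigma2 = c(method = NA, patient = NA,
                                             residual = NA),
    n_observations = n, converged = FALSE, status = reason)
  if (n < min_obs) return(skip("too few observations"))
  meth <- factor(obs$method); pat <- factor(obs$patient)
  if (nlevels(meth) < 2) return(skip("single method"))
  if (nlevels(pat) < 2) return(skip("single patient"))
  y <- obs$value
  if (stats::var(y) == 0) {
    return(list(fraction_method = 0, fraction_patient = 0,
                fraction_residual = 1,
                sigma2 = c(method = 0, patient = 0, residual = 0),
                n_observations = n, converged = TRUE, status = "degenerate"))
  }
  Z1 <- stats::model.matrix(~ meth - 1)
  Z2 <- stats::model.matrix(~ pat - 1)
  q1 <- ncol(Z1); q2 <- ncol(Z2)
  W <- cbind(1, Z1, Z2)
  WtW <- crossprod(W); Wty <- crossprod(W, y); yty <- sum(y * y)
  idx1 <- 1 + seq_len(q1); idx2 <- 1 + q1 + seq_len(q2)
  vy <- stats::var(y)
  s2 <- c(vy / 3, vy / 3, vy / 3)   # method, patient, residual
  floor_s2 <- vy * 1e-12
  ll_old <- -Inf; converged <- FALSE
  dWtW <- diag(WtW)
  for (it in seq_len(max_iter)) {
    gam <- pmax(s2[1:2], floor_s2) / s2[3]
    M <- WtW
    diag(M)[idx1] <- dWtW[idx1] + 1 / gam[1]
    diag(M)[idx2] <- dWtW[idx2] + 1 / gam[2]
    ch <- chol(M)
    C <- chol2inv(ch)
    sol <- C %*% Wty
    ssr <- yty - sum(sol * Wty)          # y'y - s'W'y = sigma_e^2 * y'Py
    # restricted log-likelihood at the current s2 (Henderson identity:
    # log|V| + log|X'V^-1 X| = (n-1) log s2e + sum_i qi log gamma_i + log|M|)
    ll <- -0.5 * ((n - 1) * log(s2[3]) + q1 * log(gam[1]) +
                    q2 * log(gam[2]) + 2 * sum(log(diag(ch))) + ssr / s2[3])
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    u1 <- sol[idx1]; u2 <- sol[idx2]
    s2 <- pmax(c(
      (sum(u1^2) + s2[3] * sum(diag(C)[idx1])) / q1,
      (sum(u2^2) + s2[3] * sum(diag(C)[idx2])) / q2,
      ssr / (n - 1)), floor_s2)
  }
  s2[s2 <= floor_s2 * 2] <- 0
  total <- sum(s2)
  fr <- if (total > 0) s2 / total else c(0, 0, 1)
  list(fraction_method = fr[1], fraction_patient = fr[2],
       fraction_residual = fr[3],
       sigma2 = c(method = s2[1], patient = s2[2], residual = s2[3]),
       n_observations = n, converged = converged, status = "ok")
}

#' Henderson method-of-moments (ANOVA) estimators on a balanced design
#'
#' Closed-form cross-check for [fit_variance_components()] on complete
#' m-method x p-patient designs with one observation per cell; may return
#' negative components (not truncated).
#'
#' @inheritParams fit_variance_components
#' @return Numeric vector (method, patient, residual).
#' @export
henderson_moments <- function(observations) {
  meth <- factor(observations$method); pat <- factor(observations$patient)
  y <- observations$value
  a <- nlevels(meth); b <- nlevels(pat)
  stopifnot(nrow(observations) == a * b)
  fit <- stats::aov(y ~ meth + pat)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  mse <- ms[3]
  c(method = (ms[1] - mse) / b, patient = (ms[2] - mse) / a, residual = mse)
}

#' Fit variance fractions for every protein in a long table
#'
#' @param long data.frame with columns `protein`, `method`, `patient`,
#'   `value`.
#' @param ... Passed to [fit_variance_components()].
#' @return data.frame, one row per protein, with the fraction columns,
#'   `n_observations`, `converged`, `status`.
#' @export
fit_variance_components_all <- function(long, ...) {
  by_prot <- split(long, long$protein)
  rows <- lapply(names(by_prot), function(p) {
    f <- fit_variance_components(by_prot[[p]], ...)
    data.frame(protein = p, fraction_method = f$fraction_method,
               fraction_patient = f$fraction_patient,
               fraction_residual = f$fraction_residual,
               sigma2_method = unname(f$sigma2["method"]),
               sigma2_patient = unname(f$sigma2["patient"]),
               sigma2_residual = unname(f$sigma2["residual"]),
               n_observations = f$n_observations, converged = f$converged,
               status = f$status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize variance fractions across proteins
#'
#' Median, quartiles and mean of each component over fitted proteins,
#' reported as percentages. Component medians need not sum to 100 (they are
#' medians of different orderings), and no such property is assumed.
#'
#' @param fractions data.frame from [fit_variance_components_all()].
#' @return data.frame: component, median_pct, q25_pct, q75_pct, mean_pct, n.
#' @export
summarize_fractions <- function(fractions) {
  ok <- fractions[fractions$status %in% c("ok", "degenerate") &
                    fractions$converged, , drop = FALSE]
  if (!nrow(ok)) stop("no converged records to summarize", call. = FALSE)
  comps <- c(method = "fraction_method", patient = "fraction_patient",
             residual = "fraction_residual")
  out <- do.call(rbind, lapply(names(comps), function(nm) {
    x <- ok[[comps[[nm]]]] * 100
    data.frame(component = nm, median_pct = stats::median(x),
               q25_pct = unname(stats::quantile(x, 0.25)),
               q75_pct = unname(stats::quantile(x, 0.75)),
               mean_pct = mean(x), n = length(x), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Build the long observation table from per-workflow quantification matrices
#'
#' @param matrices Named list (workflow -> `quant_matrix`).
#' @return data.frame `protein`, `method`, `patient`, `value` with missing
#'   entries omitted.
#' @export
long_observations <- function(matrices) {
  rows <- lapply(names(matrices), function(w) {
    qm <- matrices[[w]]
    v <- qm$values
    idx <- which(!is.na(v), arr.ind = TRUE)
    data.frame(protein = rownames(v)[idx[, 1]],
               method = qm$sample_info$method[idx[, 2]],
               patient = qm$sample_info$patient[idx[, 2]],
               value = v[idx], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
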