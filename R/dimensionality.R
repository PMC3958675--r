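#' Horn's parallel analysis
#'
#' Factor-retention by comparing the eigenvalues of the observed
#' inter-item correlation matrix with the distribution of eigenvalues
#' from random data of the same shape. The retained count is the number
#' of observed eigenvalues exceeding the chosen percentile (default
#' 95th) of the corresponding random eigenvalue; the random mean is
#' reported alongside. This replaces the eigenvalue-greater-than-1 rule,
#' which is known to over-factor.
#'
#' @param matrix persons-by-items numeric matrix (raw responses or
#'   residuals). Constant columns are dropped with a warning;
#'   correlations use pairwise-complete observations.
#' @param n_reps number of random datasets (at least 100).
#' @param percentile reference percentile of the random eigenvalues,
#'   in percent.
#' @param seed optional integer seed for the random reference data.
#' @return A list of class \code{"parallel_analysis"}: \code{n_factors},
#'   and a data frame \code{eigenvalues} with columns \code{observed},
#'   \code{random_mean}, \code{random_percentile}.
#' @examples
#' sim <- generate_responses(population_spec(n = 200, seed = 3), naqr_bank())
#' parallel_analysis(sim$responses, n_reps = 100, seed = 3)$n_factors
#' @export
parallel_analysis <- function(matrix, n_reps = 500L, percentile = 95,
                              seed = NULL) {
  X <- as.matrix(matrix)
  if (n_reps < 100L) stop("n_reps must be at least 100")
  keep <- apply(X, 2, function(v) stats::sd(v, na.rm = TRUE) > 0)
  if (!all(keep)) {
    warning(sum(!keep), " constant column(s) dropped")
    X <- X[, keep, drop = FALSE]
  }
  n <- nrow(X); p <- ncol(X)
  obs <- eigen(stats::cor(X, use = "pairwise.complete.obs"),
               symmetric = TRUE, only.values = TRUE)$values
  if (!is.null(seed)) set.seed(seed)
  rand <- matrix(0, n_reps, p)
  for (r in seq_len(n_reps)) {
    Z <- matrix(stats::rnorm(n * p), n, p)
    rand[r, ] <- eigen(stats::cor(Z), symmetric = TRUE,
                       only.values = TRUE)$values
  }
  ref <- apply(rand, 2, stats::quantile, probs = percentile / 100)
  ref_mean <- colMeans(rand)
  # count leading eigenvalues above reference, stopping at first failure
  above <- obs > ref
  n_factors <- if (above[1]) which.min(c(above, FALSE)) - 1L else 0L
  structure(list(n_factors = as.integer(n_factors),
                 eigenvalues = data.frame(observed = obs,
                                          random_mean = ref_mean,
                                          random_percentile = ref),
                 percentile = percentile, n_reps = n_reps),
            class = "parallel_analysis")
}

#' @export
print.parallel_analysis <- function(x, ...) {
  cat("Horn's parallel analysis (", x$n_reps, " reps, ", x$percentile,
      "th percentile): ", x$n_factors, " factor(s)\n", sep = "")
  print(utils::head(round(x$eigenvalues, 3), 5))
  invisible(x)
}

#' Principal components analysis of standardized Rasch residuals
#'
#' After the rating-scale model is removed from the data, the
#' standardized residuals of a unidimensional instrument should be
#' unstructured noise. This runs an eigendecomposition of the
#' item-by-item correlation matrix of standardized residuals and
#' returns the first contrast: its eigenvalue (in item units) and the
#' per-item loadings. A large first-contrast eigenvalue with loadings
#' split by sign across item clusters indicates a secondary dimension.
#'
#' @param residuals a [rasch_residuals()] table (or any list with a
#'   \code{z} matrix).
#' @return A list of class \code{"residual_pca"}: \code{eigenvalue}
#'   (first contrast), \code{loadings} (per item, in item order, each
#'   in \code{[-1, 1]}), \code{eigenvalues} (all), and
#'   \code{low_rank} flag (more items than persons).
#' @export
residual_pca <- function(residuals) {
  Z <- residuals$z
  if (is.null(Z)) stop("residuals must carry a z matrix")
  if (nrow(Z) < ncol(Z))
    warning("fewer persons than items; residual PCA is low rank")
  sds <- apply(Z, 2, stats::sd, na.rm = TRUE)
  if (all(!is.finite(sds)) || all(sds < 1e-12)) {
    # deterministic fit leaves a zero residual matrix: no contrast
    return(structure(list(eigenvalue = 0,
                          loadings = rep(0, ncol(Z)),
                          eigenvalues = rep(0, ncol(Z)),
                          low_rank = nrow(Z) < ncol(Z)),
                     class = "residual_pca"))
  }
  C <- stats::cor(Z, use = "pairwise.complete.obs")
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  e <- eigen(C, symmetric = TRUE)
  v1 <- e$vectors[, 1]
  # orient so the largest-magnitude loading is positive (sign is arbitrary)
  if (v1[which.max(abs(v1))] < 0) v1 <- -v1
  loadings <- v1 * sqrt(max(e$values[1], 0))
  loadings <- pmax(pmin(loadings, 1), -1)
  names(loadings) <- colnames(Z)
  structure(list(eigenvalue = e$values[1], loadings = loadings,
                 eigenvalues = e$values, low_rank = nrow(Z) < ncol(Z)),
            class = "residual_pca")
}

#' Smith's person-level subset t test of unidimensionality
#'
#' Splits the items into two subsets using the first-contrast loadings
#' (by default the 5 most positive versus the 5 most negative), derives
#' each person's measure separately on each subset, and tests the
#' per-person difference
#' \eqn{t_n = (\hat\theta_n^{A} - \hat\theta_n^{B}) /
#' \sqrt{SE_A^2 + SE_B^2}}. Under a single dimension the two subset
#' measures estimate the same quantity, so fewer than 5\% of persons
#' should fall outside \eqn{\pm 1.96}.
#'
#' @param matrix persons-by-items response matrix.
#' @param bank the calibrated [item_bank].
#' @param loadings per-item first-contrast loadings (from
#'   [residual_pca()]).
#' @param n_subset items per subset (default 5, minimum 3).
#' @return A list of class \code{"smith_ttest"}: \code{t} (per person,
#'   NA where a subset measure is inestimable without adjustment),
#'   \code{proportion_outside} (share with \eqn{|t| > 1.96}),
#'   \code{subset_a}, \code{subset_b}, and \code{applicable}.
#' @export
smith_subset_ttest <- function(matrix, bank, loadings, n_subset = 5L) {
  stopifnot(inherits(bank, "item_bank"))
  X <- as.matrix(matrix)
  if (length(loadings) != length(bank$item_ids))
    stop("one loading per bank item required")
  n_subset <- max(3L, as.integer(n_subset))
  ord <- order(loadings, decreasing = TRUE)
  pos <- ord[seq_len(n_subset)]
  neg <- rev(ord)[seq_len(n_subset)]
  if (any(loadings[pos] <= 0) || any(loadings[neg] >= 0)) {
    return(structure(list(t = rep(NA_real_, nrow(X)),
                          proportion_outside = NA_real_,
                          subset_a = bank$item_ids[pos],
                          subset_b = bank$item_ids[neg],
                          applicable = FALSE),
                     class = "smith_ttest"))
  }
  est_subset <- function(rows_idx) {
    res <- lapply(seq_len(nrow(X)), function(n)
      mle_theta(X[n, rows_idx], bank, items = rows_idx))
    list(theta = vapply(res, `[[`, numeric(1), "theta"),
         se = vapply(res, `[[`, numeric(1), "se"),
         extreme = vapply(res, `[[`, logical(1), "extreme_adjusted"),
         n = vapply(res, `[[`, integer(1), "n_items"))
  }
  a <- est_subset(pos); b <- est_subset(neg)
  usable <- a$n > 0 & b$n > 0 & is.finite(a$theta) & is.finite(b$theta)
  t <- ifelse(usable, (a$theta - b$theta) / sqrt(a$se^2 + b$se^2),
              NA_real_)
  structure(list(t = t,
                 proportion_outside = mean(abs(t[usable]) > 1.96),
                 subset_a = bank$item_ids[pos],
                 subset_b = bank$item_ids[neg],
                 applicable = TRUE),
            class = "smith_ttest")
}

#' Full three-step unidimensionality report
#'
#' Convenience wrapper running the complete workflow on a response
#' matrix: (1) Horn's parallel analysis on the raw responses, (2) a
#' rating-scale calibration with infit/outfit fit statistics, and (3)
#' post-hoc checks on the calibrated model — PCA of standardized
#' residuals and Smith's subset t tests.
#'
#' @param matrix persons-by-items response matrix.
#' @param bank optional anchored [item_bank]; calibrated from the data
#'   when omitted.
#' @param n_reps,percentile,seed passed to [parallel_analysis()].
#' @return A list of class \code{"dimensionality_report"} with elements
#'   \code{parallel}, \code{calibration} (NULL if \code{bank} given),
#'   \code{item_fit}, \code{pca}, \code{smith}.
#' @examples
#' sim <- generate_responses(population_spec(n = 150, seed = 11), naqr_bank())
#' rep <- dimensionality_report(sim$responses, n_reps = 100, seed = 11)
#' rep$parallel$n_factors
#' @export
dimensionality_report <- function(matrix, bank = NULL, n_reps = 500L,
                                  percentile = 95, seed = NULL) {
  pa <- parallel_analysis(matrix, n_reps = n_reps,
                          percentile = percentile, seed = seed)
  cal <- NULL
  if (is.null(bank)) {
    cal <- jmle_calibrate(matrix)
    bank <- cal$bank
    thetas <- cal$persons$theta
    item_fit <- cal$item_fit
    resid <- cal$residuals
  } else {
    thetas <- estimate_all(matrix, bank)$theta
    item_fit <- fit_statistics(matrix, bank, thetas)$item
    resid <- rasch_residuals(matrix, bank, thetas)
  }
  pca <- residual_pca(resid)
  smith <- smith_subset_ttest(matrix, bank, pca$loadings)
  structure(list(parallel = pa, calibration = cal, item_fit = item_fit,
                 pca = pca, smith = smith),
            class = "dimensionality_report")
}

#' @export
print.dimensionality_report <- function(x, ...) {
  cat("Unidimensionality workflow\n")
  cat("  1. parallel analysis:", x$parallel$n_factors, "factor(s)\n")
  cat(sprintf("  2. item fit: infit %.2f-%.2f, outfit %.2f-%.2f\n",
              min(x$item_fit$infit), max(x$item_fit$infit),
              min(x$item_fit$outfit), max(x$item_fit$outfit)))
  cat(sprintf("  3. residual PCA first contrast eigenvalue %.2f; Smith |t|>1.96: %s\n",
              x$pca$eigenvalue,
              if (isTRUE(x$smith$applicable))
                sprintf("%.1f%%", 100 * x$smith$proportion_outside)
              else "not applicable"))
  invisible(x)
}
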