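#' Joint maximum-likelihood calibration of the rating scale model
#'
#' Estimates person measures, item difficulties and the shared Andrich
#' thresholds from a persons-by-items matrix of polytomous responses by
#' alternating Newton-Raphson updates (the estimation scheme of the
#' classic Rasch calibration programs). Each outer cycle updates all
#' person measures, then all item difficulties
#' (\eqn{\delta_i \leftarrow \delta_i + \sum_n (E_{ni} - x_{ni}) /
#' \sum_n W_{ni}}), then each threshold (a diagonal Newton step on the
#' cumulative category probabilities), and re-applies the
#' identification constraints: thresholds sum to zero and item
#' difficulties average zero, with the absorbed shifts moved into the
#' person measures. Iteration stops when the largest absolute parameter
#' change falls below \code{tol}.
#'
#' Persons with all-floor or all-ceiling response strings carry no
#' information about item parameters; they are excluded from the item
#' and threshold updates and re-anchored afterwards with
#' extreme-score-adjusted maximum-likelihood estimates on the final
#' bank. Items observed in a single category are rejected.
#'
#' @param matrix persons-by-items integer matrix (external categories
#'   \code{1..K}; \code{NA} = not administered).
#' @param K number of response categories (default: inferred from the
#'   data as \code{max(matrix)}).
#' @param max_cycles maximum outer cycles (default 200).
#' @param tol convergence tolerance on parameter change, logits.
#' @param correct_bias apply the \eqn{(L-1)/L} shrinkage to the item
#'   difficulties (a standard correction for the finite-test bias of
#'   joint estimation); default \code{FALSE}.
#' @param verbose print cycle-level progress.
#'
#' @return A list of class \code{"calibration_result"} with
#'   \code{bank} (centered [item_bank]), \code{persons} (data frame as
#'   from [estimate_all()], anchored on the final bank), \code{item_fit}
#'   (per-item infit/outfit and point-measure correlation),
#'   \code{person_reliability}, \code{cronbach_alpha}, \code{converged},
#'   \code{cycles}, and \code{n_extreme_persons}.
#'
#' @examples
#' sim <- generate_responses(population_spec(n = 150, seed = 42), naqr_bank())
#' cal <- jmle_calibrate(sim$responses)
#' cal$bank$thresholds
#' @export
jmle_calibrate <- function(matrix, K = NULL, max_cycles = 200L, tol = 1e-4,
                           correct_bias = FALSE, verbose = FALSE) {
  X <- as.matrix(matrix)
  if (nrow(X) < 2L || ncol(X) < 2L)
    stop("calibration needs at least 2 persons and 2 items")
  if (is.null(K)) K <- max(X, na.rm = TRUE)
  K <- as.integer(K)
  labs <- seq_len(K)
  if (!all(X[!is.na(X)] %in% labs))
    stop("responses must be integer categories in 1..", K)
  seen <- sort(unique(X[!is.na(X)]))
  if (length(seen) < K)
    warning("categories never observed: ",
            paste(setdiff(labs, seen), collapse = ", "),
            "; consider collapsing categories")
  Xi <- X - 1L                                   # internal 0..K-1
  O <- !is.na(Xi)
  Xi0 <- ifelse(O, Xi, 0L)
  n_ans <- rowSums(O)
  if (any(n_ans == 0L)) stop("persons with zero answered items present")
  item_var <- apply(Xi, 2, stats::var, na.rm = TRUE)
  if (any(item_var == 0, na.rm = TRUE))
    stop("items with a single observed category cannot be calibrated: ",
         paste(which(item_var == 0), collapse = ", "))
  raw_int <- rowSums(Xi0)
  extreme_person <- raw_int == 0L | raw_int == n_ans * (K - 1L)
  est_rows <- which(!extreme_person)
  if (length(est_rows) < 2L)
    stop("fewer than 2 non-extreme persons; cannot calibrate")

  Oe <- O[est_rows, , drop = FALSE]
  Xe <- Xi0[est_rows, , drop = FALSE]
  ne <- length(est_rows)
  L <- ncol(X)

  # initial values: log-odds of proportion-of-maximum scores
  p_i <- colSums(Xe * Oe) / (colSums(Oe) * (K - 1L))
  p_i <- pmin(pmax(p_i, 0.01), 0.99)
  delta <- -stats::qlogis(p_i); delta <- delta - mean(delta)
  tau <- rep(0, K - 1L)
  p_n <- rowSums(Xe) / (rowSums(Oe) * (K - 1L))
  p_n <- pmin(pmax(p_n, 0.01), 0.99)
  theta <- stats::qlogis(p_n)

  clamp <- function(v, s = 1) pmax(pmin(v, s), -s)
  converged <- FALSE
  cycles <- 0L
  for (cycles in seq_len(max_cycles)) {
    old <- c(delta, tau)
    # person block: a few damped Newton sweeps at current item parameters
    for (it in 1:3) {
      m <- rsm_moments(theta, delta, tau)
      g <- rowSums((Xe - m$E) * Oe)
      info <- pmax(rowSums(m$W * Oe), 1e-8)
      theta <- theta + clamp(g / info)
    }
    # item block
    m <- rsm_moments(theta, delta, tau)
    gi <- colSums((m$E - Xe * 1) * Oe)           # dL/ddelta = sum(E - x)
    Ii <- pmax(colSums(m$W * Oe), 1e-8)
    delta <- delta + clamp(-gi / -Ii)            # delta + (sum(E-x))/sum(W)
    # threshold block (diagonal Newton on cumulative probabilities);
    # dL/dtau_j = sum over cells of P(x >= j) - [x >= j]
    m <- rsm_moments(theta, delta, tau, keep_probs = TRUE)
    Pge <- m$P[, , K]
    for (j in (K - 1L):1L) {                 # Pge = P(internal score >= j)
      gj <- sum((Pge - (Xe >= j)) * Oe)
      hj <- max(sum(Pge * (1 - Pge) * Oe), 1e-8)
      tau[j] <- tau[j] + clamp(gj / hj)
      if (j > 1L) Pge <- Pge + m$P[, , j]
    }
    # identification: thresholds sum to zero, difficulties average zero
    ct <- mean(tau); tau <- tau - ct; delta <- delta + ct
    cd <- mean(delta); delta <- delta - cd; theta <- theta - cd
    chg <- max(abs(c(delta, tau) - old))
    if (verbose) message(sprintf("cycle %d: max change %.6f", cycles, chg))
    if (chg < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("JMLE did not converge in ", max_cycles,
            " cycles; returning last iterate")
  if (correct_bias) delta <- delta * (L - 1) / L

  bank <- item_bank(delta = delta, thresholds = tau,
                    item_ids = colnames(X) %||% paste0("item", seq_len(L)),
                    n_categories = K)
  persons <- estimate_all(X, bank)
  resid <- rasch_residuals(X, bank, persons$theta)
  fit <- fit_statistics(X, bank, persons$theta)
  ptme <- point_measure_correlation(X, persons$theta)
  item_fit <- data.frame(item = bank$item_ids,
                         delta = unname(bank$delta),
                         infit = fit$item$infit, outfit = fit$item$outfit,
                         ptme = ptme, row.names = NULL)
  structure(
    list(bank = bank, persons = persons, item_fit = item_fit,
         person_fit = fit$person, residuals = resid,
         person_reliability = separation_reliability(persons),
         cronbach_alpha = cronbach_alpha(X),
         converged = converged, cycles = cycles,
         n_extreme_persons = sum(extreme_person)),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Rating scale JMLE calibration\n")
  cat("  ", nrow(x$persons), " persons (", x$n_extreme_persons,
      " extreme), ", length(x$bank$item_ids), " items, ",
      x$bank$n_categories, " categories\n", sep = "")
  cat("  converged:", x$converged, "in", x$cycles, "cycles\n")
  cat("  thresholds:", paste(round(x$bank$thresholds, 3), collapse = ", "),
      "\n")
  cat(sprintf("  person separation reliability: %.3f; Cronbach alpha: %.3f\n",
              x$person_reliability, x$cronbach_alpha))
  invisible(x)
}

#' Rasch residual table
#'
#' Raw residuals \eqn{r_{ni} = x_{ni} - E_{ni}}, model variances
#' \eqn{W_{ni}}, and standardized residuals
#' \eqn{z_{ni} = r_{ni}/\sqrt{W_{ni}}}, defined only where a response
#' exists. These feed the fit statistics and the principal components
#' analysis of residuals used for the unidimensionality check.
#'
#' @param matrix persons-by-items response matrix (external labels).
#' @param bank an [item_bank].
#' @param thetas person measures aligned with the rows.
#' @return A list of class \code{"residual_table"} with matrices
#'   \code{raw}, \code{W}, \code{z} (NA where unobserved).
#' @export
rasch_residuals <- function(matrix, bank, thetas) {
  stopifnot(inherits(bank, "item_bank"))
  X <- as.matrix(matrix)
  if (length(thetas) != nrow(X))
    stop("one theta per matrix row required")
  cat_idx <- matrix(match(X, bank$category_labels), nrow(X), ncol(X))
  Xi <- cat_idx - 1L
  m <- rsm_moments(thetas, unname(bank$delta), bank$thresholds)
  R <- Xi - m$E
  W <- m$W
  Z <- R / sqrt(pmax(W, 1e-12))
  R[is.na(Xi)] <- NA; W[is.na(Xi)] <- NA; Z[is.na(Xi)] <- NA
  dimnames(R) <- dimnames(W) <- dimnames(Z) <-
    list(rownames(X), bank$item_ids)
  structure(list(raw = R, W = W, z = Z), class = "residual_table")
}

#' Infit and outfit mean-square fit statistics
#'
#' Outfit is the unweighted mean of squared standardized residuals
#' (\eqn{\mathrm{outfit}_i = \sum_n z_{ni}^2 / N_i}); infit is the
#' information-weighted version
#' (\eqn{\mathrm{infit}_i = \sum_n r_{ni}^2 / \sum_n W_{ni}}). Both are
#' close to 1 when the data fit the rating scale model; the conventional
#' usable range for survey items is 0.5 to 1.5. Outfit is more sensitive
#' to unexpected responses far from a person's level (careless or
#' lucky endorsements), infit to inlying misfit.
#'
#' @inheritParams rasch_residuals
#' @return A list with data frames \code{item} (\code{item},
#'   \code{infit}, \code{outfit}) and \code{person} (\code{person},
#'   \code{infit}, \code{outfit}).
#' @export
fit_statistics <- function(matrix, bank, thetas) {
  res <- rasch_residuals(matrix, bank, thetas)
  degenerate <- !is.na(res$W) & res$W < 1e-10
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance cells excluded from fit")
    res$raw[degenerate] <- NA; res$W[degenerate] <- NA
    res$z[degenerate] <- NA
  }
  msq <- function(R, W, Z, margin) {
    n <- apply(!is.na(Z), margin, sum)
    outfit <- apply(Z^2, margin, sum, na.rm = TRUE) / pmax(n, 1)
    infit <- apply(R^2, margin, sum, na.rm = TRUE) /
      pmax(apply(W, margin, sum, na.rm = TRUE), 1e-12)
    list(infit = infit, outfit = outfit)
  }
  it <- msq(res$raw, res$W, res$z, 2)
  pe <- msq(res$raw, res$W, res$z, 1)
  list(item = data.frame(item = bank$item_ids, infit = it$infit,
                         outfit = it$outfit, row.names = NULL),
       person = data.frame(person = seq_len(nrow(as.matrix(matrix))),
                           infit = pe$infit, outfit = pe$outfit,
                           row.names = NULL))
}

#' Point-measure correlation (PTME)
#'
#' Pearson correlation between the observed responses to an item and
#' the person measures, the polytomous analogue of a corrected
#' item-total correlation. Values near zero or negative flag items that
#' do not discriminate along the measured trait.
#'
#' @inheritParams rasch_residuals
#' @return Named numeric vector, one correlation per item (\code{NA}
#'   for zero-variance items, with a warning).
#' @export
point_measure_correlation <- function(matrix, thetas) {
  X <- as.matrix(matrix)
  out <- vapply(seq_len(ncol(X)), function(i) {
    xi <- X[, i]
    ok <- !is.na(xi) & !is.na(thetas)
    if (sum(ok) < 3L || stats::sd(xi[ok]) == 0)
      return(NA_real_)
    stats::cor(xi[ok], thetas[ok])
  }, numeric(1))
  if (anyNA(out)) warning("zero-variance item(s); PTME undefined there")
  names(out) <- colnames(X)
  out
}

#' Person separation reliability
#'
#' The Rasch analogue of reliability: the proportion of observed
#' person-measure variance that is not measurement error,
#' \deqn{R = \frac{\mathrm{var}(\hat\theta) - \overline{SE^2}}
#'            {\mathrm{var}(\hat\theta)},}
#' clipped to \code{[0, 1]}.
#'
#' @param estimates a data frame with columns \code{theta} and
#'   \code{se} (as returned by [estimate_all()]), or a list of person
#'   estimates.
#' @return Scalar in \code{[0, 1]}.
#' @examples
#' separation_reliability(data.frame(theta = c(-2, 0, 2, 4),
#'                                   se = rep(0.5, 4)))
#' @export
separation_reliability <- function(estimates) {
  th <- estimates$theta; se <- estimates$se
  ok <- is.finite(th) & is.finite(se)
  th <- th[ok]; se <- se[ok]
  if (length(th) < 2L) stop("need at least 2 estimable persons")
  v <- stats::var(th)
  if (v == 0) { warning("zero person variance; reliability 0"); return(0) }
  min(max((v - mean(se^2)) / v, 0), 1)
}

#' Cronbach's alpha (classical reliability, for reference)
#'
#' @param matrix persons-by-items response matrix.
#' @return Scalar alpha from complete rows.
#' @export
cronbach_alpha <- function(matrix) {
  X <- as.matrix(matrix)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  k <- ncol(X)
  k / (k - 1) * (1 - sum(apply(X, 2, stats::var)) / stats::var(rowSums(X)))
}

#' Differential item functioning by anchored group contrast
#'
#' Screens each item for difficulty differences between two groups of
#' respondents after matching on the measured trait. Person measures
#' are anchored from the joint calibration (so both groups are on one
#' scale); each group's item difficulty is then re-estimated with those
#' measures fixed, and the contrast
#' \eqn{\hat\delta_i^{A} - \hat\delta_i^{B}} is tested with a Wald
#' chi-square \eqn{(\hat\delta^A-\hat\delta^B)^2 / (SE_A^2 + SE_B^2)}
#' on 1 degree of freedom — the standard item-trait interaction test
#' comparing each group's observed performance on the item with its
#' model-expected performance.
#'
#' @param matrix persons-by-items response matrix.
#' @param bank the jointly calibrated [item_bank].
#' @param groups vector with exactly two distinct values, one per
#'   person.
#' @param thetas optional anchored person measures; computed from the
#'   joint bank when omitted.
#' @return Data frame per item: \code{item}, \code{delta_a},
#'   \code{delta_b}, \code{contrast}, \code{se}, \code{chisq}, \code{p},
#'   \code{skipped} (items with no response variance in a group).
#' @examples
#' sim <- generate_responses(population_spec(n = 120, seed = 7), naqr_bank())
#' g <- rep(c("A", "B"), length.out = 120)
#' head(dif_analysis(sim$responses, naqr_bank(), g))
#' @export
dif_analysis <- function(matrix, bank, groups, thetas = NULL) {
  stopifnot(inherits(bank, "item_bank"))
  X <- as.matrix(matrix)
  lev <- unique(stats::na.omit(groups))
  if (length(lev) != 2L) stop("groups must take exactly 2 values")
  if (length(groups) != nrow(X)) stop("one group label per person required")
  if (is.null(thetas)) thetas <- estimate_all(X, bank)$theta
  fit_group_delta <- function(rows, col) {
    xi <- X[rows, col]
    ok <- !is.na(xi) & is.finite(thetas[rows])
    xi <- match(xi[ok], bank$category_labels) - 1L
    th <- thetas[rows][ok]
    if (length(xi) < 3L || stats::sd(xi) == 0) return(c(NA, NA))
    d <- unname(bank$delta[col])
    for (it in 1:50) {
      m <- rsm_moments(th, d, bank$thresholds)
      g <- sum(m$E) - sum(xi)                 # dL/dd
      info <- max(sum(m$W), 1e-8)
      step <- max(min(-g / -info, 1), -1)     # d <- d + (sum(E)-sum(x))/info
      d <- d + step
      if (abs(step) < 1e-8) break
    }
    c(d, 1 / sqrt(max(sum(rsm_moments(th, d, bank$thresholds)$W), 1e-8)))
  }
  ra <- which(groups == lev[1]); rb <- which(groups == lev[2])
  out <- t(vapply(seq_len(ncol(X)), function(i) {
    a <- fit_group_delta(ra, i); b <- fit_group_delta(rb, i)
    c(a[1], b[1], a[2], b[2])
  }, numeric(4)))
  contrast <- out[, 1] - out[, 2]
  se <- sqrt(out[, 3]^2 + out[, 4]^2)
  chisq <- (contrast / se)^2
  data.frame(item = bank$item_ids,
             delta_a = out[, 1], delta_b = out[, 2],
             contrast = contrast, se = se, chisq = chisq,
             p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
             skipped = is.na(contrast), row.names = NULL)
}
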