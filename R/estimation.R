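#' Adjust an extreme raw score so the likelihood has a finite maximum
#'
#' A person answering every administered item in the lowest (or highest)
#' category has a likelihood maximized at \eqn{\theta = -\infty}
#' (\eqn{+\infty}). The conventional remedy is to pull the raw score a
#' fraction of a score unit inside the floor or ceiling before solving
#' the score equation, which yields a finite measure below (above) every
#' non-extreme measure on the same item subset.
#'
#' @param raw external summed raw score, at the floor or ceiling.
#' @param n_items number of items administered.
#' @param K number of response categories.
#' @param adjust score units to move inward (default 0.3).
#' @param category_labels external labels (default \code{1:K}).
#' @return Adjusted raw score (floor + adjust, or ceiling - adjust).
#' @examples
#' extreme_score_adjust(22, 22, 5)    # 22.3
#' extreme_score_adjust(110, 22, 5)   # 109.7
#' @export
extreme_score_adjust <- function(raw, n_items, K, adjust = 0.3,
                                 category_labels = seq_len(K)) {
  lo <- n_items * min(category_labels)
  hi <- n_items * max(category_labels)
  if (raw == lo) return(raw + adjust)
  if (raw == hi) return(raw - adjust)
  stop("raw score ", raw, " is not extreme for ", n_items,
       " items with labels [", lo / n_items, ", ", hi / n_items, "]")
}

#' Solver settings for person-measure estimation
#'
#' @param max_iter maximum Newton-Raphson iterations.
#' @param tol convergence tolerance on the score equation
#'   \eqn{|\sum_i (x_i - E_i(\theta))|}.
#' @param step_clamp largest permitted update per iteration, in logits.
#' @param extreme_adjust score units used by [extreme_score_adjust()].
#' @return A list of class \code{"mle_config"}.
#' @export
mle_config <- function(max_iter = 50L, tol = 1e-8, step_clamp = 1.0,
                       extreme_adjust = 0.3) {
  stopifnot(max_iter >= 1, tol > 0, step_clamp > 0, extreme_adjust > 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 step_clamp = step_clamp, extreme_adjust = extreme_adjust),
            class = "mle_config")
}

#' Maximum-likelihood person measure by Newton-Raphson
#'
#' Solves the rating-scale score equation
#' \eqn{\sum_i (x_i - E_i(\theta)) = 0} over the administered items by
#' damped Newton-Raphson, \eqn{\theta \leftarrow \theta + \sum_i (x_i -
#' E_i) / \sum_i W_i(\theta)}, with each step clamped to
#' \code{step_clamp} logits. The raw score is sufficient for
#' \eqn{\theta} under the Rasch model, so persons with equal raw scores
#' on the same subset receive identical measures. All-floor or
#' all-ceiling response strings are routed through
#' [extreme_score_adjust()] (flagged, never an error) and solved against
#' the adjusted score. The standard error is
#' \eqn{1/\sqrt{\sum_i W_i(\hat\theta)}}.
#'
#' @param responses integer vector of external categories (1..K),
#'   aligned with \code{items}; \code{NA}s are treated as
#'   not-administered and dropped together with their item.
#' @param bank an [item_bank].
#' @param items ids or indices of the administered items; \code{NULL}
#'   means the responses cover the full bank in order.
#' @param config an [mle_config()].
#' @param start optional starting value in logits; default is the logit
#'   of the (adjusted) proportion-of-maximum score.
#' @return A list of class \code{"person_estimate"}: \code{theta},
#'   \code{se}, \code{n_items}, \code{raw_score} (external, unadjusted),
#'   \code{converged}, \code{iterations}, \code{extreme_adjusted}.
#' @examples
#' bank <- naqr_bank()
#' est <- mle_theta(rep(c(1, 2), 11), bank)
#' c(est$theta, est$se)
#' @export
mle_theta <- function(responses, bank, items = NULL, config = mle_config(),
                      start = NULL) {
  stopifnot(inherits(bank, "item_bank"))
  idx <- resolve_items(bank, items)
  if (length(responses) != length(idx))
    stop("responses and item subset lengths differ")
  keep <- !is.na(responses)
  idx <- idx[keep]
  responses <- responses[keep]
  if (length(idx) == 0L)
    return(structure(list(theta = NA_real_, se = NA_real_, n_items = 0L,
                          raw_score = NA_real_, converged = FALSE,
                          iterations = 0L, extreme_adjusted = FALSE),
                     class = "person_estimate"))
  K <- bank$n_categories
  labs <- bank$category_labels
  cat_idx <- match(responses, labs)
  if (anyNA(cat_idx))
    stop("responses must be categories in {",
         paste(labs, collapse = ", "), "}")
  x <- cat_idx - 1L                        # internal 0..K-1 scores
  raw_ext <- sum(labs[cat_idx])
  n <- length(idx)
  target <- sum(x)                         # internal raw score
  extreme <- target == 0L || target == n * (K - 1L)
  if (extreme)
    target <- extreme_score_adjust(target, n, K, config$extreme_adjust,
                                   category_labels = 0:(K - 1L))
  # start: logit of adjusted proportion-of-maximum
  p0 <- (target + 0.0) / (n * (K - 1L))
  p0 <- min(max(p0, 1e-3), 1 - 1e-3)
  theta <- if (is.null(start)) log(p0 / (1 - p0)) + mean(bank$delta[idx])
           else start
  delta <- unname(bank$delta[idx])
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(config$max_iter)) {
    m <- rsm_moments(theta, delta, bank$thresholds)
    g <- target - sum(m$E)
    if (abs(g) < config$tol) { converged <- TRUE; break }
    info <- sum(m$W)
    step <- g / max(info, 1e-10)
    step <- max(min(step, config$step_clamp), -config$step_clamp)
    theta <- theta + step
  }
  if (!converged) {                        # final check after last step
    g <- target - sum(rsm_moments(theta, delta, bank$thresholds)$E)
    converged <- abs(g) < max(config$tol, 1e-6)
  }
  info <- sum(rsm_moments(theta, delta, bank$thresholds)$W)
  structure(list(theta = theta, se = 1 / sqrt(info), n_items = n,
                 raw_score = raw_ext, converged = converged,
                 iterations = iter, extreme_adjusted = extreme),
            class = "person_estimate")
}

#' @export
print.person_estimate <- function(x, ...) {
  cat(sprintf("theta = %.3f (SE %.3f), %d items, raw %s%s\n",
              x$theta, x$se, x$n_items, format(x$raw_score),
              if (x$extreme_adjusted) " [extreme-adjusted]" else ""))
  invisible(x)
}

#' Estimate person measures for a whole response matrix
#'
#' Runs [mle_theta()] for each row of a persons-by-items matrix;
#' \code{NA} cells are treated as not-administered. Because the raw
#' score is sufficient, rows with the same answered subset and raw score
#' map to the same measure.
#'
#' @param matrix integer matrix or data frame, persons in rows, items in
#'   columns (columns aligned with the bank order), categories on the
#'   external labels.
#' @param bank an [item_bank].
#' @param config an [mle_config()].
#' @return A data frame with one row per person: \code{person},
#'   \code{theta}, \code{se}, \code{n_items}, \code{raw}, \code{converged},
#'   \code{extreme}. Persons with no answered items get \code{NA}
#'   measures.
#' @examples
#' sim <- generate_responses(population_spec(n = 20, seed = 1), naqr_bank())
#' head(estimate_all(sim$responses, naqr_bank()))
#' @export
estimate_all <- function(matrix, bank, config = mle_config()) {
  stopifnot(inherits(bank, "item_bank"))
  matrix <- as.matrix(matrix)
  if (nrow(matrix) == 0L || ncol(matrix) == 0L)
    stop("response matrix must be non-empty")
  if (ncol(matrix) != length(bank$item_ids))
    stop("matrix has ", ncol(matrix), " columns but the bank has ",
         length(bank$item_ids), " items")
  out <- lapply(seq_len(nrow(matrix)), function(i)
    mle_theta(matrix[i, ], bank, config = config))
  data.frame(
    person = if (!is.null(rownames(matrix))) rownames(matrix)
             else seq_len(nrow(matrix)),
    theta = vapply(out, `[[`, numeric(1), "theta"),
    se = vapply(out, `[[`, numeric(1), "se"),
    n_items = vapply(out, `[[`, integer(1), "n_items"),
    raw = vapply(out, `[[`, numeric(1), "raw_score"),
    converged = vapply(out, `[[`, logical(1), "converged"),
    extreme = vapply(out, `[[`, logical(1), "extreme_adjusted"),
    row.names = NULL)
}
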