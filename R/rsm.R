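#' Category probabilities under the Andrich rating scale model
#'
#' For a person at \eqn{\theta} answering an item of difficulty
#' \eqn{\delta} with shared step thresholds \eqn{\tau_1,\ldots,\tau_{K-1}},
#' the probability of internal category \eqn{k \in \{0,\ldots,K-1\}} is
#' \deqn{P(k) \propto \exp\Big(\sum_{j=1}^{k} (\theta - \delta - \tau_j)\Big),}
#' the empty sum being 0. With \eqn{K = 2} this reduces to the
#' dichotomous Rasch form
#' \eqn{P(1) = e^{\theta-\delta} / (1 + e^{\theta-\delta})}.
#'
#' The largest cumulative log-numerator is subtracted before
#' exponentiation so the computation cannot overflow for extreme
#' \eqn{|\theta - \delta|}.
#'
#' @param theta person measure in logits (scalar).
#' @param delta item difficulty in logits (scalar).
#' @param thresholds numeric vector of step difficulties (length
#'   \eqn{K - 1}).
#' @param category_labels external scores, default \code{1:K}.
#'
#' @return A list of class \code{"category_distribution"} with
#'   \code{probs} (length \eqn{K}, sums to 1), \code{expected}
#'   (expected external score) and \code{variance} (variance of the
#'   score, identical on the internal and external scales).
#'
#' @examples
#' ## flat distribution when theta sits at delta and all steps are zero
#' category_probabilities(0, 0, rep(0, 4))$probs
#'
#' ## NAQ-R item 1 for a person near the screening cutoff
#' category_probabilities(-4.2, -2.21, c(-3.39, -0.55, 1.11, 2.83))$expected
#' @export
category_probabilities <- function(theta, delta, thresholds,
                                   category_labels = NULL) {
  if (!is.finite(theta) || !is.finite(delta) || !all(is.finite(thresholds)))
    stop("theta, delta and thresholds must be finite")
  K <- length(thresholds) + 1L
  if (is.null(category_labels)) category_labels <- seq_len(K)
  if (length(category_labels) != K)
    stop("category_labels must have length K")
  k <- 0:(K - 1L)
  a <- k * (theta - delta) - c(0, cumsum(thresholds))
  e <- exp(a - max(a))
  p <- e / sum(e)
  expected <- sum(category_labels * p)
  variance <- sum(category_labels^2 * p) - expected^2
  structure(list(probs = p, expected = expected,
                 variance = max(variance, 0)),
            class = "category_distribution")
}

#' Item information under the rating scale model
#'
#' Fisher information of a single rating-scale item at \eqn{\theta},
#' equal to the variance of the response score under the model:
#' \eqn{I(\theta) = \sum_k k^2 P(k) - (\sum_k k P(k))^2}. It also equals
#' the derivative of the item's expected score with respect to
#' \eqn{\theta}, peaks near \eqn{\delta}, and vanishes as
#' \eqn{|\theta - \delta| \to \infty}. Adaptive item selection picks the
#' unanswered item maximizing this quantity at the provisional measure.
#'
#' @inheritParams category_probabilities
#' @return Non-negative scalar information, in logit^-2 units.
#' @examples
#' item_information(0, 0, thresholds = 0)   # dichotomous p(1-p) = 0.25
#' @export
item_information <- function(theta, delta, thresholds) {
  category_probabilities(theta, delta, thresholds)$variance
}

#' Test information and standard error for an item subset
#'
#' Information is additive over the items actually administered; the
#' standard error of a maximum-likelihood measure is
#' \eqn{1 / \sqrt{I_{test}(\theta)}}.
#'
#' @param theta person measure in logits.
#' @param bank an [item_bank].
#' @param items item ids (character) or indices of the administered
#'   subset; \code{NULL} means the full bank.
#' @return \code{test_information}: scalar summed information.
#'   \code{test_se}: the corresponding standard error in logits.
#' @examples
#' test_information(0, naqr_bank())
#' test_se(0, naqr_bank())
#' @export
test_information <- function(theta, bank, items = NULL) {
  stopifnot(inherits(bank, "item_bank"))
  idx <- resolve_items(bank, items)
  if (length(idx) == 0L) stop("item subset must be non-empty")
  sum(vapply(bank$delta[idx], function(d)
    item_information(theta, d, bank$thresholds), numeric(1)))
}

#' @rdname test_information
#' @export
test_se <- function(theta, bank, items = NULL) {
  1 / sqrt(test_information(theta, bank, items))
}

#' Test characteristic curve: expected raw summed score
#'
#' Maps a latent measure to the expected summed raw score over a set of
#' items on the external category labels (1..K for the NAQ-R, so the
#' 22-item full-test range is an open interval (22, 110)). The curve is
#' strictly increasing, which makes it invertible; it is how a logit
#' screening cutoff (e.g. -4.2) is translated into a traditional
#' summed-score cutoff (about 30).
#'
#' @inheritParams test_information
#' @return Expected summed score (scalar).
#' @examples
#' test_characteristic_curve(-4.2, naqr_bank())   # about 30
#' @export
test_characteristic_curve <- function(theta, bank, items = NULL) {
  stopifnot(inherits(bank, "item_bank"))
  idx <- resolve_items(bank, items)
  sum(vapply(bank$delta[idx], function(d)
    category_probabilities(theta, d, bank$thresholds,
                           bank$category_labels)$expected, numeric(1)))
}

#' Invert the test characteristic curve
#'
#' Finds the \eqn{\theta} whose expected summed score equals \code{raw}
#' by root finding (monotone bisection via [stats::uniroot]) to within
#' \code{tol} on the raw-score scale.
#'
#' @param raw summed raw score, strictly inside the open interval
#'   (n_items * min label, n_items * max label).
#' @inheritParams test_information
#' @param tol convergence tolerance on the raw-score scale.
#' @return \eqn{\theta} in logits.
#' @examples
#' raw_to_logit(30, naqr_bank())   # about -4.2
#' @export
raw_to_logit <- function(raw, bank, items = NULL, tol = 1e-6) {
  stopifnot(inherits(bank, "item_bank"))
  idx <- resolve_items(bank, items)
  lo <- length(idx) * min(bank$category_labels)
  hi <- length(idx) * max(bank$category_labels)
  if (raw <= lo || raw >= hi)
    stop("extreme raw score ", raw, ": must lie strictly inside (",
         lo, ", ", hi, "); apply extreme_score_adjust() first")
  f <- function(t) test_characteristic_curve(t, bank, idx) - raw
  span <- 10
  while (f(-span) > 0 || f(span) < 0) span <- span * 2
  stats::uniroot(f, c(-span, span), tol = tol / 10)$root
}

# Vectorized model kernel used by estimation and calibration: for a
# vector of person measures and a vector of item difficulties sharing
# one threshold set, returns expected internal scores E (persons x
# items), score variances W, and optionally the K category probability
# layers. Everything downstream (Newton updates, residuals, fit
# statistics) is built on these two matrices.
rsm_moments <- function(theta, delta, thresholds, keep_probs = FALSE) {
  K <- length(thresholds) + 1L
  Tk <- c(0, cumsum(thresholds))
  M <- outer(theta, delta, "-")          # persons x items
  A <- array(0, dim = c(length(theta), length(delta), K))
  for (k in seq_len(K)) A[, , k] <- (k - 1L) * M - Tk[k]
  amax <- apply(A, c(1, 2), max)
  S0 <- matrix(0, length(theta), length(delta))
  S1 <- S0; S2 <- S0
  P <- if (keep_probs) array(0, dim = dim(A)) else NULL
  for (k in seq_len(K)) {
    e <- exp(A[, , k] - amax)
    S0 <- S0 + e
    S1 <- S1 + (k - 1L) * e
    S2 <- S2 + (k - 1L)^2 * e
    if (keep_probs) P[, , k] <- e
  }
  E <- S1 / S0
  W <- pmax(S2 / S0 - E^2, 0)
  if (keep_probs) for (k in seq_len(K)) P[, , k] <- P[, , k] / S0
  list(E = E, W = W, P = P)
}
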