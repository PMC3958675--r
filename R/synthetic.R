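#' Specify a simulated respondent population
#'
#' Describes the latent-trait distribution from which simulated
#' respondents are drawn: either a single normal or a two-component
#' normal mixture. The default, N(0, 2), is a wide population matched
#' to a person SD large enough for a 22-item instrument to separate
#' persons reliably. The mixture preset
#' \code{population_spec(mixture = TRUE)} emulates a floor-heavy
#' workplace sample — a large mildly-exposed component around -5.4
#' logits plus a smaller bullied component around -3.1 logits —
#' mirroring the published group means for non-bullied and bullied
#' nurses.
#'
#' @param n number of persons.
#' @param mean,sd parameters of the normal (used when
#'   \code{mixture = FALSE}).
#' @param mixture use the two-component preset instead.
#' @param means,sds,weight mixture parameters: component means, SDs and
#'   the weight of the *first* component.
#' @param seed integer seed.
#' @return A list of class \code{"population_spec"}.
#' @examples
#' population_spec(n = 300, seed = 1)
#' population_spec(n = 300, mixture = TRUE, seed = 1)
#' @export
population_spec <- function(n = 300L, mean = 0, sd = 2, mixture = FALSE,
                            means = c(-5.4, -3.1), sds = c(1.5, 1.5),
                            weight = 0.76, seed = NULL) {
  stopifnot(n >= 1, sd > 0, all(sds > 0), weight >= 0, weight <= 1)
  structure(list(n = as.integer(n), mean = mean, sd = sd,
                 mixture = isTRUE(mixture), means = means, sds = sds,
                 weight = weight, seed = seed),
            class = "population_spec")
}

#' Draw latent measures from a population specification
#'
#' @param pop a [population_spec()].
#' @return Numeric vector of \code{pop$n} latent measures in logits.
#' @export
generate_thetas <- function(pop) {
  stopifnot(inherits(pop, "population_spec"))
  if (!is.null(pop$seed)) set.seed(pop$seed)
  if (!pop$mixture)
    return(stats::rnorm(pop$n, pop$mean, pop$sd))
  comp <- 1L + (stats::runif(pop$n) > pop$weight)
  stats::rnorm(pop$n, pop$means[comp], pop$sds[comp])
}

#' Simulate rating-scale responses from an item bank
#'
#' Draws each cell of a persons-by-items matrix from the rating scale
#' model at the person's true measure by inverse-CDF sampling over the
#' category probabilities. With the seed fixed the matrix is fully
#' reproducible.
#'
#' @param pop a [population_spec()] (its \code{seed} governs both the
#'   latent draws and the response draws).
#' @param bank an [item_bank].
#' @param thetas optional latent measures to use instead of drawing
#'   from \code{pop}.
#' @return A list with \code{responses} (integer matrix on the bank's
#'   external labels, persons x items, columns named by item id) and
#'   \code{theta} (the true latent measures).
#' @examples
#' sim <- generate_responses(population_spec(n = 5, seed = 9), naqr_bank())
#' sim$responses
#' @export
generate_responses <- function(pop, bank, thetas = NULL) {
  stopifnot(inherits(bank, "item_bank"))
  if (is.null(thetas)) {
    thetas <- generate_thetas(pop)
  } else if (!is.null(pop$seed)) {
    set.seed(pop$seed)
  }
  n <- length(thetas)
  K <- bank$n_categories
  m <- rsm_moments(thetas, unname(bank$delta), bank$thresholds,
                   keep_probs = TRUE)
  U <- matrix(stats::runif(n * length(bank$item_ids)), n)
  cum <- array(0, dim = dim(m$P))
  cum[, , 1] <- m$P[, , 1]
  for (k in 2:K) cum[, , k] <- cum[, , k - 1] + m$P[, , k]
  X <- matrix(1L, n, length(bank$item_ids))
  for (k in seq_len(K - 1L)) X <- X + (U > cum[, , k])
  X <- matrix(bank$category_labels[X], n)
  colnames(X) <- bank$item_ids
  list(responses = X, theta = thetas)
}

#' Simulate self-labeled victimization flags
#'
#' Attaches a binary "bullied" label to each simulated respondent
#' through a logistic link on the latent measure:
#' \eqn{P(\text{bullied}) = \mathrm{logit}^{-1}(a + b\,\theta)}. The
#' defaults (a = -1.39, b = 0.52) were calibrated once against the
#' default N(0, 2) population to give a prevalence near 24\% and a
#' measure-vs-label AUROC near 0.75, matching the published sample.
#' A zero slope makes the labels independent of the measure (null
#' AUROC 0.5); large slopes approach perfect separation.
#'
#' @param thetas latent measures.
#' @param intercept,slope logistic link parameters (slope must be
#'   non-negative).
#' @param seed optional integer seed.
#' @return Integer vector of 0/1 labels.
#' @examples
#' set.seed(4)
#' mean(generate_victim_labels(rnorm(1000, 0, 2)))   # about 0.24
#' @export
generate_victim_labels <- function(thetas, intercept = -1.39,
                                   slope = 0.52, seed = NULL) {
  stopifnot(slope >= 0)
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(length(thetas), 1L,
                stats::plogis(intercept + slope * thetas))
}
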