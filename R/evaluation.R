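#' Compare adaptive and full-test measures
#'
#' The adaptive test should reproduce the full-test (nonadaptive)
#' measures with fewer items. This pairs the two estimate sets per
#' person and reports the Pearson correlation of the measures, paired t
#' tests on test length (efficiency) and on the measures (precision —
#' expected non-significant), the mean adaptive length, and the
#' efficiency gain \eqn{1 - (\text{total adaptive responses} /
#' \text{total full-test responses})}.
#'
#' @param cat_estimates numeric vector of adaptive-test measures.
#' @param nat_estimates numeric vector of full-test measures, same
#'   persons in the same order.
#' @param cat_lengths items administered per person by the adaptive
#'   test.
#' @param nat_length full test length (scalar, e.g. 22).
#' @return A list of class \code{"comparison_report"}: \code{pearson_r},
#'   \code{t_theta} and \code{t_length} (each an \code{htest}),
#'   \code{mean_cat_length}, \code{efficiency_gain}, \code{n}.
#' @examples
#' compare_cat_nat(c(-1, 0, 1.2), c(-1.1, 0.2, 1.0), c(10, 12, 14), 22)
#' @export
compare_cat_nat <- function(cat_estimates, nat_estimates, cat_lengths,
                            nat_length) {
  n <- length(cat_estimates)
  if (length(nat_estimates) != n || length(cat_lengths) != n)
    stop("estimate and length vectors must be paired per person")
  if (n < 3L) stop("need at least 3 paired persons")
  identical_measures <- isTRUE(all.equal(cat_estimates, nat_estimates))
  t_theta <- if (identical_measures) NULL else
    stats::t.test(cat_estimates, nat_estimates, paired = TRUE)
  structure(list(
    pearson_r = stats::cor(cat_estimates, nat_estimates),
    t_theta = t_theta,
    t_length = stats::t.test(cat_lengths, rep(nat_length, n),
                             paired = TRUE),
    p_theta = if (identical_measures) 1 else t_theta$p.value,
    mean_cat_length = mean(cat_lengths),
    efficiency_gain = efficiency_gain(sum(cat_lengths), n * nat_length),
    n = n),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("CAT vs NAT over %d persons\n", x$n))
  cat(sprintf("  r = %.3f; paired theta difference p = %.3f\n",
              x$pearson_r, x$p_theta))
  cat(sprintf("  mean CAT length %.2f items; efficiency gain %.2f\n",
              x$mean_cat_length, x$efficiency_gain))
  invisible(x)
}

#' Efficiency gain of adaptive over full-length testing
#'
#' \eqn{1 - (\text{total adaptive responses} / \text{total full-test
#' responses})}; e.g. 4491 adaptive responses against 6600 full-test
#' responses gives a gain of 0.32.
#'
#' @param total_cat_responses total items answered adaptively.
#' @param total_nat_responses total items under full administration.
#' @return Fraction in \code{[0, 1)}.
#' @examples
#' efficiency_gain(4491, 6600)
#' @export
efficiency_gain <- function(total_cat_responses, total_nat_responses) {
  if (total_cat_responses <= 0 || total_nat_responses <= 0)
    stop("response totals must be positive")
  if (total_cat_responses > total_nat_responses)
    stop("adaptive total exceeds full-test total")
  1 - total_cat_responses / total_nat_responses
}

#' Total administration time saved
#'
#' Product of the mean seconds saved per item, the mean number of items
#' saved per person, and the number of persons.
#'
#' @param seconds_per_item mean response time per item, seconds.
#' @param items_saved_per_person mean items not administered per person.
#' @param n_persons sample size.
#' @return Seconds saved (scalar).
#' @examples
#' time_saving(25.07, 7.03, 300)
#' @export
time_saving <- function(seconds_per_item, items_saved_per_person,
                        n_persons) {
  stopifnot(seconds_per_item >= 0, items_saved_per_person >= 0,
            n_persons >= 0)
  seconds_per_item * items_saved_per_person * n_persons
}

#' ROC analysis and cutoff determination for bullying measures
#'
#' Evaluates how well the latent bullying measures separate self-labeled
#' victims from non-victims. The AUROC is computed by the rank
#' (Mann-Whitney) construction with midranks for ties, its 95\%
#' confidence interval by the Hanley-McNeil variance, and the operating
#' cutoff by maximizing Youden's \eqn{J = sensitivity + specificity -
#' 1} over the observed thresholds. When an item bank is supplied the
#' logit cutoff is also mapped to its traditional summed-score
#' equivalent through the test characteristic curve.
#'
#' @param measures person measures in logits.
#' @param labels binary victimization labels (1 = bullied, 0 = not);
#'   both classes must be present.
#' @param bank optional [item_bank] for the raw-score equivalent.
#' @param conf_level confidence level for the AUROC interval.
#' @return A list of class \code{"roc_result"}: \code{auroc},
#'   \code{ci_low}, \code{ci_high}, \code{cutoff_logit},
#'   \code{cutoff_raw} (NA without a bank), \code{sensitivity},
#'   \code{specificity}, \code{n_pos}, \code{n_neg}.
#' @examples
#' set.seed(1)
#' th <- rnorm(200, 0, 2)
#' y <- rbinom(200, 1, plogis(-1.39 + 0.52 * th))
#' roc_cutoff(th, y, naqr_bank())
#' @export
roc_cutoff <- function(measures, labels, bank = NULL, conf_level = 0.95) {
  ok <- is.finite(measures) & !is.na(labels)
  x <- measures[ok]; y <- as.integer(labels[ok])
  if (!all(y %in% 0:1)) stop("labels must be binary 0/1")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute a ROC curve")
  r <- rank(x)                              # midranks
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * as.numeric(n0))
  # Hanley-McNeil variance
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
        (n0 - 1) * (q2 - auc^2)) / (n1 * as.numeric(n0))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- auc + c(-1, 1) * zq * sqrt(max(v, 0))
  # Youden cutoff over thresholds midway between observed values, via
  # cumulative class counts along the sorted measures
  xs <- sort(unique(x))
  if (length(xs) > 1L) {
    cand <- (xs[-1] + xs[-length(xs)]) / 2
    o <- order(x)
    ends <- cumsum(tabulate(match(x[o], xs), length(xs)))
    pos_le <- cumsum(y[o] == 1)[ends][-length(xs)]
    neg_le <- cumsum(y[o] == 0)[ends][-length(xs)]
    sens <- (n1 - pos_le) / n1
    spec <- neg_le / n0
  } else {
    cand <- xs
    sens <- mean(x[y == 1] > cand)
    spec <- mean(x[y == 0] <= cand)
  }
  j <- sens + spec - 1
  best <- which.max(j)
  cutoff <- cand[best]
  structure(list(
    auroc = auc, ci_low = max(ci[1], 0), ci_high = min(ci[2], 1),
    cutoff_logit = cutoff,
    cutoff_raw = if (is.null(bank)) NA_real_
                 else test_characteristic_curve(cutoff, bank),
    sensitivity = sens[best], specificity = spec[best],
    n_pos = n1, n_neg = n0),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUROC %.3f (95%% CI %.3f-%.3f), %d bullied / %d not\n",
              x$auroc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  cat(sprintf("  cutoff %.2f logits%s; sensitivity %.2f, specificity %.2f\n",
              x$cutoff_logit,
              if (is.na(x$cutoff_raw)) ""
              else sprintf(" (raw score %.1f)", x$cutoff_raw),
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Individual probability of being a bullying victim
#'
#' Converts a person's measure into a probability of exceeding the
#' screening cutoff via the dichotomous Rasch form
#' \eqn{P = e^{\theta - c} / (1 + e^{\theta - c})}: a person at -1.5
#' logits against the -4.2 cutoff has probability 0.94. When a standard
#' error is supplied, a 95\% interval is obtained by pushing
#' \eqn{\theta \pm 1.96\,SE} through the same formula.
#'
#' @param theta person measure in logits.
#' @param cutoff screening cutoff in logits (default -4.2).
#' @param se optional standard error of \code{theta}.
#' @return Probability, or (with \code{se}) a named vector
#'   \code{probability}, \code{ci_low}, \code{ci_high}.
#' @examples
#' victim_probability(-1.5, -4.2)
#' victim_probability(-1.5, -4.2, se = 0.45)
#' @export
victim_probability <- function(theta, cutoff = -4.2, se = NULL) {
  stopifnot(is.finite(theta), is.finite(cutoff))
  p <- stats::plogis(theta - cutoff)
  if (is.null(se)) return(p)
  stopifnot(is.finite(se), se >= 0)
  c(probability = p,
    ci_low = stats::plogis(theta - 1.96 * se - cutoff),
    ci_high = stats::plogis(theta + 1.96 * se - cutoff))
}
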