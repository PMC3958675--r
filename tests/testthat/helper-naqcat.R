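# Shared fixtures and independent oracles for the test suite.

# Two-stage grid search over the log-likelihood: an estimation oracle
# independent of the Newton-Raphson solver. Coarse pass at 0.01 logits
# over [-12, 12], then a 1e-4 grid around the coarse argmax.
grid_mle <- function(responses, bank, items = NULL) {
  idx <- if (is.null(items)) seq_along(bank$item_ids)
         else naqcat:::resolve_items(bank, items)
  x <- match(responses, bank$category_labels)   # 1..K layer index
  loglik <- function(thetas) {
    m <- naqcat:::rsm_moments(thetas, unname(bank$delta[idx]),
                              bank$thresholds, keep_probs = TRUE)
    vapply(seq_along(thetas), function(g)
      sum(log(vapply(seq_along(idx), function(i)
        m$P[g, i, x[i]], numeric(1)))), numeric(1))
  }
  coarse <- seq(-12, 12, by = 0.01)
  t0 <- coarse[which.max(loglik(coarse))]
  fine <- seq(t0 - 0.02, t0 + 0.02, by = 1e-4)
  fine[which.max(loglik(fine))]
}

# Brute-force AUROC by exhaustive pair counting (ties count 1/2).
pairwise_auc <- function(x, y) {
  pos <- x[y == 1]; neg <- x[y == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# A tiny dichotomous bank for closed-form checks.
dich_bank <- function(delta = c(0, 0))
  item_bank(delta = delta, thresholds = 0)
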