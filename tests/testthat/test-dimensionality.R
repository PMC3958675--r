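test_that("parallel analysis separates noise from a common factor", {
  set.seed(91)
  noise <- matrix(rnorm(300 * 22), 300)
  pa0 <- parallel_analysis(noise, n_reps = 100, seed = 92)
  expect_identical(pa0$n_factors, 0L)
  # one common factor, loadings 0.7
  f <- rnorm(300)
  one <- sapply(1:22, function(i) 0.7 * f + sqrt(1 - 0.49) * rnorm(300))
  pa1 <- parallel_analysis(one, n_reps = 100, seed = 92)
  expect_identical(pa1$n_factors, 1L)
  # rating-scale data simulated from the NAQ-R bank is unidimensional
  sim <- generate_responses(population_spec(n = 300, seed = 93), naqr_bank())
  pa2 <- parallel_analysis(sim$responses, n_reps = 100, seed = 92)
  expect_identical(pa2$n_factors, 1L)
  expect_error(parallel_analysis(noise, n_reps = 50), "at least 100")
  noise[, 4] <- 1
  expect_warning(parallel_analysis(noise, n_reps = 100, seed = 92),
                 "constant")
})

test_that("residual PCA is small under the model and splits subscales", {
  bank <- naqr_bank()
  sim <- generate_responses(population_spec(n = 400, seed = 101), bank)
  cal <- jmle_calibrate(sim$responses)
  pca <- residual_pca(cal$residuals)
  expect_length(pca$loadings, 22L)
  expect_true(all(abs(pca$loadings) <= 1))
  # model-consistent data: loadings stay clustered inside +-0.6
  expect_true(all(abs(pca$loadings) < 0.6))
  # inject an orthogonal second factor into half the items' residual space
  set.seed(102)
  X <- sim$responses
  u <- rnorm(400)
  half <- 1:11
  for (i in half) X[, i] <- pmin(pmax(X[, i] + round(u), 1), 5)
  cal2 <- jmle_calibrate(X)
  pca2 <- residual_pca(cal2$residuals)
  s <- sign(pca2$loadings)
  expect_true(all(s[half] == s[half][1]))          # contaminated block
  expect_true(all(s[-half] == -s[half][1]))        # against the rest
  expect_gt(pca2$eigenvalue, pca$eigenvalue)
  # degenerate zero residual matrix handled gracefully
  zero <- list(z = matrix(0, 50, 5))
  expect_identical(residual_pca(zero)$eigenvalue, 0)
})

test_that("Smith subset t tests flag only real multidimensionality", {
  bank <- naqr_bank()
  # duplicated-item subsets with mirrored responses give t = 0
  dup <- item_bank(delta = rep(c(-1, 0, 1), 2),
                   thresholds = bank$thresholds)
  sim3 <- generate_responses(population_spec(n = 40, seed = 111),
                             item_bank(delta = c(-1, 0, 1),
                                       thresholds = bank$thresholds))
  X6 <- cbind(sim3$responses, sim3$responses)
  loadings <- c(0.3, 0.3, 0.3, -0.3, -0.3, -0.3)
  sm0 <- smith_subset_ttest(X6, dup, loadings, n_subset = 3)
  expect_true(sm0$applicable)
  expect_equal(sm0$t[!is.na(sm0$t)],
               rep(0, sum(!is.na(sm0$t))), tolerance = 1e-8)
  # unidimensional floor-heavy sample (the realistic workplace profile):
  # under 5% of persons outside +-1.96
  simf <- generate_responses(population_spec(n = 300, mixture = TRUE,
                                             seed = 113), bank)
  thf <- estimate_all(simf$responses, bank)$theta
  pcaf <- residual_pca(rasch_residuals(simf$responses, bank, thf))
  smf <- smith_subset_ttest(simf$responses, bank, pcaf$loadings)
  expect_lt(smf$proportion_outside, 0.05)
  # a well-spread population inflates the proportion through subset
  # selection, but stays far from the two-dimensional regime below
  sim <- generate_responses(population_spec(n = 300, seed = 112), bank)
  cal <- jmle_calibrate(sim$responses)
  pca <- residual_pca(cal$residuals)
  sm1 <- smith_subset_ttest(sim$responses, cal$bank, pca$loadings)
  expect_lt(sm1$proportion_outside, 0.15)
  # a +1 logit shift on one subset blows the proportion up
  shifted <- sim$responses
  ord <- order(pca$loadings, decreasing = TRUE)
  shifted[, ord[1:5]] <- pmin(shifted[, ord[1:5]] + 2L, 5L)
  sm2 <- smith_subset_ttest(shifted, cal$bank, pca$loadings)
  expect_gt(sm2$proportion_outside, 0.20)
  # partition impossible when all loadings share a sign
  sm3 <- smith_subset_ttest(sim$responses, cal$bank, abs(pca$loadings) + 0.1)
  expect_false(sm3$applicable)
  expect_true(is.na(sm3$proportion_outside))
})

test_that("the full three-step report runs end to end", {
  # floor-heavy sample scored against the published (anchored) bank
  sim <- generate_responses(population_spec(n = 250, mixture = TRUE,
                                            seed = 121), naqr_bank())
  rep <- dimensionality_report(sim$responses, bank = naqr_bank(),
                               n_reps = 100, seed = 121)
  expect_identical(rep$parallel$n_factors, 1L)
  expect_true(all(rep$item_fit$infit > 0.5 & rep$item_fit$infit < 1.5))
  # the strict <5% property is asserted in the dedicated Smith test
  expect_lt(rep$smith$proportion_outside, 0.10)
  expect_output(print(rep), "Unidimensionality")
})
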