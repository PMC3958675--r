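test_that("JMLE recovers simulated structure and applies constraints", {
  truth <- item_bank(delta = c(-1, 0, 1), thresholds = c(-1, 0, 1),
                     item_ids = c("easy", "mid", "hard"))
  sim <- generate_responses(population_spec(n = 500, seed = 31), truth)
  cal <- jmle_calibrate(sim$responses)
  expect_true(cal$converged)
  # identification: centered difficulties, zero-sum thresholds
  expect_lt(abs(mean(cal$bank$delta)), 1e-8)
  expect_lt(abs(sum(cal$bank$thresholds)), 1e-8)
  # difficulty ordering fully recovered (magnitudes carry the known
  # outward joint-estimation bias on a 3-item test)
  expect_equal(cor(cal$bank$delta, truth$delta, method = "spearman"), 1)
  # the (L-1)/L correction pulls short-test difficulties toward truth
  corrected <- jmle_calibrate(sim$responses, correct_bias = TRUE)
  expect_lt(max(abs(corrected$bank$delta - truth$delta)),
            max(abs(cal$bank$delta - truth$delta)))
})

test_that("items of equal true difficulty calibrate near zero", {
  truth <- item_bank(delta = rep(0, 6), thresholds = c(-1.5, 0, 1.5))
  sim <- generate_responses(population_spec(n = 500, seed = 37), truth)
  cal <- jmle_calibrate(sim$responses)
  expect_true(all(abs(cal$bank$delta) < 0.3))
  expect_lt(sd(cal$bank$delta), 0.2)
})

test_that("the published NAQ-R parameters are recovered from n=300", {
  bank <- naqr_bank()
  sim <- generate_responses(population_spec(n = 300, seed = 301), bank)
  cal <- jmle_calibrate(sim$responses)
  expect_true(cal$converged)
  expect_equal(cal$bank$thresholds, bank$thresholds, tolerance = 0.25)
  expect_true(all(abs(cal$bank$delta - bank$delta) < 0.35))
  expect_gt(cal$person_reliability, 0.8)
})

test_that("fit statistics are near 1 under the model and obey identities", {
  bank <- naqr_bank()
  sim <- generate_responses(population_spec(n = 500, seed = 52), bank)
  thetas <- estimate_all(sim$responses, bank)$theta
  fit <- fit_statistics(sim$responses, bank, thetas)
  expect_true(all(fit$item$infit > 0.5 & fit$item$infit < 1.5))
  expect_true(all(fit$item$outfit > 0.5 & fit$item$outfit < 1.5))
  expect_equal(mean(fit$item$infit), 1, tolerance = 0.1)
  expect_equal(mean(fit$item$outfit), 1, tolerance = 0.1)
  # infit is the information-weighted mean of z^2
  res <- rasch_residuals(sim$responses, bank, thetas)
  w_mean_z2 <- colSums(res$W * res$z^2) / colSums(res$W)
  expect_equal(fit$item$infit, unname(w_mean_z2), tolerance = 1e-12)
})

test_that("careless response patterns inflate outfit above infit", {
  bank <- naqr_bank()
  sim <- generate_responses(population_spec(n = 400, seed = 63), bank)
  X <- sim$responses
  # a low-exposure responder suddenly endorsing the hardest act daily
  low <- which(sim$theta < -2)[1:20]
  X[low, "naq22"] <- 5L
  thetas <- estimate_all(X, bank)$theta
  fit <- fit_statistics(X, bank, thetas)
  i22 <- match("naq22", fit$item$item)
  expect_gt(fit$item$outfit[i22], fit$item$infit[i22])
  expect_gt(fit$item$outfit[i22], 1.5)
})

test_that("point-measure correlations behave across signal levels", {
  bank <- naqr_bank()
  sim <- generate_responses(population_spec(n = 400, seed = 74), bank)
  thetas <- estimate_all(sim$responses, bank)$theta
  ptme <- point_measure_correlation(sim$responses, thetas)
  expect_true(all(ptme > 0.3 & ptme < 0.9))
  set.seed(75)
  noise <- matrix(sample(1:5, 400 * 22, replace = TRUE), 400)
  ptme_noise <- point_measure_correlation(noise, thetas)
  expect_true(all(abs(ptme_noise) < 0.2))
  flat <- noise; flat[, 1] <- 3L
  expect_warning(pm <- point_measure_correlation(flat, thetas),
                 "zero-variance")
  expect_true(is.na(pm[1]))
})

test_that("separation reliability follows its definition", {
  # observed variance 4, mean error variance 0.4 -> reliability 0.9
  th <- c(-3, -1, 1, 3) * sqrt(3 / 5)
  expect_equal(var(th), 4)
  expect_equal(separation_reliability(data.frame(theta = th,
                                                 se = sqrt(0.4))), 0.9)
  near_one <- separation_reliability(
    data.frame(theta = rnorm(50), se = rep(1e-8, 50)))
  expect_equal(near_one, 1, tolerance = 1e-8)
  expect_warning(
    zero <- separation_reliability(data.frame(theta = rep(1, 5),
                                              se = rep(0.5, 5))),
    "zero person variance")
  expect_identical(zero, 0)
})

test_that("DIF contrast is null for identical groups, detects injection", {
  bank <- naqr_bank()
  sim <- generate_responses(population_spec(n = 150, seed = 81), bank)
  X2 <- rbind(sim$responses, sim$responses)
  g <- rep(c("A", "B"), each = 150)
  d0 <- dif_analysis(X2, bank, g)
  expect_equal(d0$contrast, rep(0, 22), tolerance = 1e-6)
  expect_equal(d0$p, rep(1, 22), tolerance = 1e-4)
  # +1 logit injected on item 5 for group B
  set.seed(82)
  th <- rnorm(600, 0, 2)
  shifted <- bank; shifted$delta[5] <- shifted$delta[5] + 1
  Xa <- generate_responses(population_spec(n = 300), bank,
                           thetas = th[1:300])$responses
  Xb <- generate_responses(population_spec(n = 300), shifted,
                           thetas = th[301:600])$responses
  d1 <- dif_analysis(rbind(Xa, Xb), bank, rep(c("A", "B"), each = 300))
  expect_lt(d1$p[5], 0.05)
  expect_lt(d1$contrast[5], 0)   # item harder for group B
  expect_error(dif_analysis(sim$responses, bank, rep("A", 150)),
               "exactly 2")
})
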