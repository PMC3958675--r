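test_that("stopping configuration derives the SE threshold", {
  expect_equal(cat_config()$se_stop, sqrt(0.2))
  expect_equal(round(cat_config(target_reliability = 0.90)$se_stop, 2),
               0.32)
  expect_equal(cat_config(se_stop = 0.44)$se_stop, 0.44)
  expect_error(cat_config(min_items = 30, max_items = 22))
  expect_error(cat_config(target_reliability = 1.2))
})

test_that("the first item is uniform and reproducible", {
  bank <- naqr_bank()
  expect_identical(select_first_item(bank, seed = 5),
                   select_first_item(bank, seed = 5))
  set.seed(6)
  draws <- replicate(10000, unname(select_first_item(bank)))
  tab <- tabulate(draws, 22)
  gof <- chisq.test(tab)
  expect_gt(gof$p.value, 0.001)
  single <- item_bank(delta = 0.5, thresholds = c(-1, 1))
  expect_identical(unname(select_first_item(single, seed = 1)), 1L)
})

test_that("item selection maximizes information with indexed ties", {
  bank <- naqr_bank()
  # information peaks at the item whose difficulty matches theta
  iso <- item_bank(delta = c(-5, 0.3, 5), thresholds = bank$thresholds)
  expect_identical(unname(select_next_item(0.3, iso)), 2L)
  # brute-force argmax oracle over remaining items
  set.seed(12)
  for (rep in 1:20) {
    used <- sample(22, sample(0:20, 1))
    th <- runif(1, -6, 6)
    remaining <- setdiff(1:22, used)
    info <- sapply(bank$delta[remaining], function(d)
      item_information(th, d, bank$thresholds))
    expect_identical(unname(select_next_item(th, bank, used)),
                     remaining[which.max(info)])
  }
  twin <- item_bank(delta = c(1, 1), thresholds = bank$thresholds)
  expect_identical(unname(select_next_item(1, twin)), 1L)
  expect_error(select_next_item(0, twin, administered = 1:2), "exhausted")
})

test_that("sessions respect length bounds, stopping and reproducibility", {
  bank <- naqr_bank()
  sim <- generate_responses(population_spec(n = 40, seed = 21), bank)
  cfg <- cat_config(seed = 22)
  for (i in 1:40) {
    s <- run_cat_session(sim$responses[i, ], bank,
                         cat_config(seed = 100 + i))
    expect_gte(s$n_items, 10L)
    expect_lte(s$n_items, 22L)
    expect_identical(s$administered, unique(s$administered))
    expect_length(s$theta_trail, s$n_items)
    if (s$termination == "se_met") {
      expect_lt(s$se, cfg$se_stop)
      expect_gte(s$n_items, cfg$min_items)
    }
  }
  a <- run_cat_session(sim$responses[3, ], bank, cat_config(seed = 9))
  b <- run_cat_session(sim$responses[3, ], bank, cat_config(seed = 9))
  expect_identical(a$administered, b$administered)
  expect_identical(a$theta, b$theta)
})

test_that("a zero SE threshold degenerates to the full-test estimate", {
  bank <- naqr_bank()
  sim <- generate_responses(population_spec(n = 5, seed = 23), bank)
  nat <- estimate_all(sim$responses, bank)
  for (i in 1:5) {
    s <- run_cat_session(sim$responses[i, ], bank,
                         cat_config(se_stop = 0, seed = i))
    expect_identical(s$n_items, 22L)
    expect_identical(s$termination, "bank_exhausted")
    expect_equal(s$theta, nat$theta[i], tolerance = 1e-10)
    expect_equal(s$se, nat$se[i], tolerance = 1e-10)
  }
})

test_that("extreme responders and failing responders are handled", {
  bank <- naqr_bank()
  floor_s <- run_cat_session(rep(1, 22), bank, cat_config(seed = 31))
  expect_true(is.finite(floor_s$theta))
  expect_true(floor_s$n_items >= 10L)
  fail_after <- function(k) {
    count <- 0
    function(id, idx) {
      count <<- count + 1
      if (count > k) stop("respondent walked away")
      2
    }
  }
  s <- run_cat_session(fail_after(4), bank, cat_config(seed = 32))
  expect_identical(s$n_items, 4L)
  expect_match(s$error, "walked away")
  expect_length(s$theta_trail, 4L)
})

test_that("batch replay summarizes each person's session", {
  bank <- naqr_bank()
  sim <- generate_responses(population_spec(n = 25, seed = 41), bank)
  batch <- run_cat_batch(sim$responses, bank, cat_config(seed = 42))
  expect_identical(nrow(batch$summary), 25L)
  expect_true(all(batch$summary$n_items >= 10 & batch$summary$n_items <= 22))
  expect_equal(batch$summary$theta[7], batch$sessions[[7]]$theta)
  again <- run_cat_batch(sim$responses, bank, cat_config(seed = 42))
  expect_identical(batch$summary$theta, again$summary$theta)
})
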