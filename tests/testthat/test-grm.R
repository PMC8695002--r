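test_that("sampled item banks satisfy the GRM parameter ranges", {
  bank <- sample_item_bank(5, 5, seed = 7)
  expect_s3_class(bank, "item_bank")
  expect_length(bank$discriminations, 5)
  expect_true(all(bank$discriminations > 1 & bank$discriminations < 2))
  expect_equal(dim(bank$thresholds), c(5, 4))
  expect_true(all(apply(bank$thresholds, 1, function(b) all(diff(b) > 0))))

  minimal <- sample_item_bank(1, 2, seed = 1)
  expect_equal(minimal$n_items, 1L)
  expect_equal(ncol(minimal$thresholds), 1L)

  expect_error(sample_item_bank(0, 5), "n_items")
  expect_error(sample_item_bank(3, 1), "n_categories")
})

test_that("identical seeds reproduce identical banks and datasets", {
  expect_identical(sample_item_bank(5, 5, seed = 42),
                   sample_item_bank(5, 5, seed = 42))
  b <- sample_item_bank(5, 5, seed = 42)
  d1 <- simulate_responses(b, b, 30, 30, seed = 9)
  d2 <- simulate_responses(b, b, 30, 30, seed = 9)
  expect_identical(d1$responses, d2$responses)
  expect_identical(d1$theta_true, d2$theta_true)
})

test_that("uniform DIF shifts only the target item's thresholds", {
  bank <- item_bank(c(1, 1.5), rbind(c(-1, 0, 1, 2), c(-0.5, 0, 0.5, 1)))
  focal <- apply_uniform_dif(bank, 1, 0.4)
  expect_equal(focal$thresholds[1, ], c(-0.6, 0.4, 1.4, 2.4))
  expect_equal(focal$thresholds[2, ], bank$thresholds[2, ])
  expect_equal(bank$thresholds[1, ], c(-1, 0, 1, 2))  # input untouched

  expect_identical(apply_uniform_dif(bank, 1, 0), bank)
  big <- apply_uniform_dif(bank, 1, 0.8)
  expect_equal(big$thresholds[2, ], bank$thresholds[2, ])
  expect_error(apply_uniform_dif(bank, 3, 0.4), "target_item")
  expect_error(apply_uniform_dif(bank, 1, -0.1), "magnitude")
})

test_that("cumulative and category probabilities match the logistic form", {
  expect_equal(grm_cumulative_prob(1, 0, 0), 0.5)
  expect_equal(grm_cumulative_prob(2, 1, 0), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  expect_equal(grm_cumulative_prob(1.5, 50, 0), 1)
  expect_gt(grm_cumulative_prob(1, 1, 0), grm_cumulative_prob(1, 0, 0))
  expect_lt(grm_cumulative_prob(1, 0, 1), grm_cumulative_prob(1, 0, 0))

  p <- grm_category_probs(1, 0, c(-1, 0, 1, 2))
  expect_equal(p, c(0.26894, 0.23106, 0.23106, 0.14974, 0.11920),
               tolerance = 1e-4)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(grm_category_probs(1, -50, c(-1, 0, 1, 2)),
               c(1, 0, 0, 0, 0), tolerance = 1e-12)
  expect_error(grm_category_probs(1, 0, c(1, 0)), "increasing")
  expect_error(grm_cumulative_prob(-1, 0, 0), "discrimination")
})

test_that("category probabilities form a simplex and obey the shift identity", {
  set.seed(31)
  for (rep in 1:25) {
    a <- runif(1, 0.5, 2.5)
    theta <- rnorm(1)
    b <- sort(rnorm(sample(1:6, 1)))
    p <- grm_category_probs(a, theta, b)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    delta <- rnorm(1)
    expect_equal(grm_category_probs(a, theta, b + delta),
                 grm_category_probs(a, theta - delta, b),
                 tolerance = 1e-12)
  }
})

test_that("simulated responses have the right shape, range and group split", {
  b <- sample_item_bank(5, 5, seed = 11)
  ds <- simulate_responses(b, apply_uniform_dif(b, 1, 0.4), 50, 50, seed = 3)
  expect_equal(dim(ds$responses), c(100, 5))
  expect_true(all(ds$responses %in% 1:5))
  expect_equal(ds$n_ref, 50)
  expect_equal(ds$n_focal, 50)
  expect_equal(ds$group, rep(0:1, each = 50))
  expect_length(ds$theta_true, 100)

  b2 <- sample_item_bank(2, 5, seed = 1)
  expect_error(simulate_responses(b, b2, 10, 10), "share item count")
})

test_that("saturated thresholds force a near-certain single category", {
  bank <- item_bank(1.5, matrix(c(50, 51, 52, 53), 1))  # all thresholds >> theta
  ds <- simulate_responses(bank, bank, 200, 200, seed = 5)
  expect_true(all(ds$responses == 1L))
})

test_that("marginal category frequencies match the theta-integrated GRM", {
  # oracle: P(Y = j) = integral of the category probability against N(0,1)
  bank <- item_bank(1.4, matrix(c(-0.8, 0, 0.6, 1.3), 1))
  marginal <- vapply(1:5, function(j) {
    integrate(function(th)
      vapply(th, function(t) grm_category_probs(1.4, t, bank$thresholds[1, ])[j],
             numeric(1)) * dnorm(th),
      -8, 8)$value
  }, numeric(1))
  n <- 40000
  ds <- simulate_responses(bank, bank, n / 2, n / 2, seed = 17)
  freq <- tabulate(ds$responses[, 1], 5) / n
  se <- sqrt(marginal * (1 - marginal) / n)
  expect_true(all(abs(freq - marginal) < 4 * se + 1e-6))
})

test_that("response_dataset validates its invariants", {
  m <- matrix(1:4, 2, 2)
  expect_error(response_dataset(m, c(0, 1, 0)), "one entry per response row")
  expect_error(response_dataset(matrix(c(1, NA, 2, 3), 2, 2), c(0, 1)),
               "missing")
  expect_error(response_dataset(m, c(0, 2)), "coded 0")
  expect_error(response_dataset(matrix(c(0, 1, 2, 3), 2, 2), c(0, 1)),
               "lie in")
  ds <- response_dataset(m, c(0, 1))
  expect_equal(ds$n_ref + ds$n_focal, 2L)
})
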