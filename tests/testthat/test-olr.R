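test_that("intercept-only fit reproduces logits of cumulative proportions", {
  y <- rep(1:4, each = 25)
  fit <- fit_olr_ml(y)
  expect_equal(fit$intercepts, qlogis(c(0.25, 0.5, 0.75)), tolerance = 1e-8)
  expect_length(fit$slopes, 0)
  expect_true(fit$converged)

  y2 <- c(rep(1, 10), rep(2, 30), rep(3, 60))
  expect_equal(fit_olr_ml(y2)$intercepts, qlogis(c(0.1, 0.4)),
               tolerance = 1e-8)
})

test_that("ML fit agrees with MASS::polr on simulated data", {
  for (seed in c(2, 5, 8)) {
    ds <- make_dataset(seed, n = 150)
    d <- make_design(ds, 1)
    fit <- fit_olr_ml(d$y, d$x2)
    df <- data.frame(y = factor(d$y), score = d$x2[, 1], group = d$x2[, 2])
    ref <- MASS::polr(y ~ score + group, data = df, method = "logistic")
    # polr parameterizes logit P(Y<=j) = zeta_j - eta, so slopes flip sign
    expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$slopes), unname(-coef(ref)), tolerance = 1e-3)
    expect_equal(unname(fit$intercepts), unname(ref$zeta), tolerance = 1e-3)
    expect_true(all(diff(fit$intercepts) > 0))
  }
})

test_that("log-likelihood evaluation is self-consistent and matches by hand", {
  ds <- make_dataset(3)
  d <- make_design(ds, 2)
  fit <- fit_olr_ml(d$y, d$x2)
  expect_equal(loglik_olr(fit, d$y, d$x2), fit$loglik, tolerance = 1e-10)

  # manual evaluation on 3 observations with known parameters
  fit3 <- list(intercepts = c(-1, 0.5), slopes = c(score = 0.3))
  y3 <- c(1L, 2L, 3L)
  x3 <- cbind(score = c(0.2, -0.4, 1.1))
  by_hand <- log(plogis(-1 + 0.3 * 0.2)) +
    log(plogis(0.5 + 0.3 * -0.4) - plogis(-1 + 0.3 * -0.4)) +
    log(1 - plogis(0.5 + 0.3 * 1.1))
  expect_equal(loglik_olr(fit3, y3, x3), by_hand, tolerance = 1e-12)

  # a model predicting every observed category with probability ~1
  sure <- list(intercepts = c(100), slopes = numeric(0))
  expect_equal(loglik_olr(sure, c(1L, 1L, 1L)), 0, tolerance = 1e-10)

  expect_error(loglik_olr(fit3, c(1L, 4L), cbind(score = c(0, 0))),
               "outside the fit's category map")
})

test_that("the same design fitted twice gives identical results", {
  ds <- make_dataset(9)
  d <- make_design(ds, 1)
  f1 <- fit_olr_ml(d$y, d$x2)
  f2 <- fit_olr_ml(d$y, d$x2)
  expect_identical(f1$intercepts, f2$intercepts)
  expect_identical(f1$slopes, f2$slopes)
})

test_that("group slope is consistent under the null at large N", {
  ds <- make_dataset(13, n = 100000, n_items = 5, dif = 0)
  d <- make_design(ds, 1)
  fit <- fit_olr_ml(d$y, d$x2)
  expect_true(fit$converged)
  expect_lt(abs(fit$slopes[["group"]]), 0.03)
})

test_that("nested model log-likelihoods are ordered", {
  for (seed in c(4, 12, 21)) {
    ds <- make_dataset(seed, dif = 0.4)
    d <- make_design(ds, 1)
    x3 <- cbind(d$x2, interaction = d$x2[, 1] * d$x2[, 2])
    l1 <- suppressWarnings(fit_olr_ml(d$y, d$x1)$loglik)
    l2 <- suppressWarnings(fit_olr_ml(d$y, d$x2)$loglik)
    l3 <- suppressWarnings(fit_olr_ml(d$y, x3)$loglik)
    expect_gte(l2, l1 - 1e-8)
    expect_gte(l3, l2 - 1e-8)
  }
})

test_that("ML fit agrees with a generic numerical optimizer", {
  ds <- make_dataset(6, n = 150)
  d <- make_design(ds, 1)
  fit <- fit_olr_ml(d$y, d$x2)
  K <- fit$n_categories
  o <- optim(c(fit$intercepts + 0.3, fit$slopes * 0),
             function(par) -oracle_loglik(d$y, d$x2, par[1:(K - 1)],
                                          par[K:length(par)]),
             method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(c(fit$intercepts, unname(fit$slopes)), unname(o$par),
               tolerance = 1e-4)
  expect_lte(-o$value, fit$loglik + 1e-8)
})

test_that("degenerate and collapsed outcomes are handled", {
  expect_error(fit_olr_ml(rep(2L, 50)), "degenerate")
  y <- c(rep(1L, 40), rep(2L, 30), rep(5L, 30))  # categories 3, 4 unobserved
  expect_warning(fit <- fit_olr_ml(y, n_categories = 5), "collapsed")
  expect_length(fit$intercepts, 2)
  expect_equal(names(fit$category_map), c("1", "2", "5"))
})

test_that("likelihood-ratio test matches chi-square quantiles", {
  eq <- lr_test(-120, -120)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(lr_test(-100, -100 + 3.8415 / 2)$p_value, 0.05,
               tolerance = 1e-4)
  expect_equal(lr_test(-100, -100 + 6.6349 / 2)$p_value, 0.01,
               tolerance = 1e-4)
  expect_error(lr_test(-100, -100.5), "nesting violation")
  expect_equal(lr_test(-100, -100.5, strict = FALSE)$statistic, 0)
})
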